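#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in dependency order — census (expansion
#' calling) feeds phylo (mechanism classification) and selection (dN/dS);
#' kinetics and phenotype are independent — on synthetic inputs generated
#' under the global seed, or on user-supplied inputs. Each stage draws its
#' randomness from a named substream derived from the global seed, so rerunning
#' one stage in isolation reproduces its outputs. Writes a machine-readable
#' \code{summary.json}, a human-readable \code{report.md} and per-stage CSVs
#' into the output directory; the summary is byte-identical across runs with
#' the same config and seed.
#'
#' @param config optional list (or path to a JSON file) overriding defaults:
#'   \code{stages} (character subset of census, phylo, selection, kinetics,
#'   phenotype), \code{seed}, \code{out_dir}, and per-stage input paths
#'   (\code{annotations}, \code{taxonomy} TSVs for census; \code{species_tree},
#'   \code{gene_tree} Newick plus \code{focal} species for phylo;
#'   \code{alignment} FASTA for selection; \code{rates} CSV for kinetics;
#'   \code{competition} CSV for phenotype). Any stage without inputs runs on
#'   synthetic data.
#' @param seed global seed (overrides the config field).
#' @param outDir output directory (overrides the config field; created if
#'   missing). NULL disables file output.
#' @return invisibly, the report list (also serialized as summary.json).
#' @export
runPipeline <- function(config = NULL, seed = NULL, outDir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- list(stages = c("census", "phylo", "selection", "kinetics", "phenotype"),
              seed = 20180206, out_dir = NULL, expansion_sd_multiplier = 1,
              coverage_threshold = 0.25, bootstrap = 200, alpha = 0.05)
  cfg[names(config)] <- config
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(outDir)) cfg$out_dir <- outDir
  report <- list(config = cfg[c("stages", "seed", "expansion_sd_multiplier",
                                "coverage_threshold", "bootstrap", "alpha")])

  saveCsv <- function(df, name) {
    if (!is.null(cfg$out_dir)) {
      dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(df, file.path(cfg$out_dir, name), row.names = FALSE)
    }
  }
  runStage <- function(name, fn) {
    if (!name %in% cfg$stages) return(NULL)
    tryCatch(fn(deriveSeed(cfg$seed, name)),
             error = function(e) list(error = conditionMessage(e)))
  }

  report$census <- runStage("census", function(sd) {
    cen <- if (!is.null(cfg$annotations)) {
      buildCensus(cfg$annotations, cfg$taxonomy)
    } else {
      simulateCensus(nSuborders = 4, generaPerSuborder = 5, genomesPerGenus = 5,
                     roles = list(GLY = paste0("gly", 1:10),
                                  TCA = paste0("tca", 1:8)),
                     baseCopyRate = 1,
                     plantedExpansions = data.frame(
                       group = "so1_genus1", role = c("gly1", "gly2"),
                       added_mean = 3),
                     seed = sd)
    }
    calls <- callExpansions(cen, level = "genus",
                            sdMultiplier = cfg$expansion_sd_multiplier)
    rd <- SummarizedExperiment::rowData(cen)
    pws <- split(rownames(cen), rd$pathway)
    mat <- if (length(pws)) {
      pathwayMatrix(calls, pathways = pws, taxonomy = censusTaxonomy(cen))
    } else NULL
    saveCsv(calls, "expansion_calls.csv")
    out <- list(n_genomes = ncol(cen), n_roles = nrow(cen),
                n_flagged = sum(calls$flagged),
                flagged = calls[calls$flagged,
                                c("group", "role", "group_mean", "threshold")])
    if (!is.null(mat)) {
      fm <- formatExpansionMatrix(mat)
      saveCsv(as.data.frame(fm), "pathway_matrix.csv")
      out$pathway_matrix <- apply(fm, 1L, as.list, simplify = FALSE)
    }
    out
  })

  report$phylo <- runStage("phylo", function(sd) {
    if (!is.null(cfg$species_tree)) {
      sp <- readNewick(cfg$species_tree)
      gt <- readNewick(cfg$gene_tree)
      tipMap <- setNames(sub("_[0-9]+$", "", gt$tip.label), gt$tip.label)
      focal <- cfg$focal
    } else {
      spNwk <- "((((S1,S2),(S3,S4)),O1),O2);"
      sp <- readNewick(text = spNwk)
      g <- simulateGeneTree(spNwk,
                            duplications = list(c("S1", "S2", "S3", "S4")),
                            hgt = list(c("O1", "S3")))
      gt <- g$tree; tipMap <- g$tipMap
      focal <- c("S1", "S2", "S3", "S4")
    }
    calls <- classifyMechanism(sp, gt, tipMap, focal)
    score <- congruenceScore(sp, gt, tipMapB = tipMap, seed = deriveSeed(sd, "rf"))
    saveCsv(calls, "mechanism_calls.csv")
    list(congruence_rf = as.numeric(score),
         collapsed_copies = attr(score, "collapsed"),
         mechanism_calls = calls)
  })

  report$selection <- runStage("selection", function(sd) {
    if (!is.null(cfg$alignment)) {
      seqs <- Biostrings::readDNAStringSet(cfg$alignment)
      pair <- seqs[1:2]
    } else {
      pair <- simulateCodonPair(nCodons = 300, targetOmega = 0.45,
                                subsPerCodon = 0.4, seed = sd)
    }
    res <- dnds(pair[[1]], pair[[2]], nBootstrap = cfg$bootstrap,
                seed = deriveSeed(sd, "boot"))
    row <- data.frame(seq_a = names(pair)[1], seq_b = names(pair)[2],
                      N = res@nSites, S = res@sSites, Nd = res@nd, Sd = res@sd,
                      pN = res@pn, pS = res@ps, dN = res@dn, dS = res@ds,
                      omega = res@omega, se = res@seOmega,
                      n_codons = res@nCodonsUsed)
    saveCsv(row, "dnds.csv")
    list(omega = res@omega, se_omega = res@seOmega, dn = res@dn, ds = res@ds,
         purifying = isPurifying(res))
  })

  report$kinetics <- runStage("kinetics", function(sd) {
    pars <- pykKineticParameters()
    rows <- list()
    for (i in which(pars$substrate %in% c("ADP", "PEP"))) {
      p <- pars[i, ]
      grid <- if (p$model == "MM") c(0.05, 0.1, 0.25, 0.5, 1, 2, 3.5, 5) else
        seq(1, 20, length.out = 10)
      d <- if (!is.null(cfg$rates)) utils::read.csv(cfg$rates) else
        simulateRateData(p$model, p$vmax_U_per_mg, p$s50_mM,
                         hillN = ifelse(is.na(p$hill_n), 1, p$hill_n),
                         substrate = grid, noiseCv = 0.05,
                         seed = deriveSeed(sd, paste0("k", i)))
      fit <- if (p$model == "MM") fitMichaelisMenten(d) else fitHill(d)
      kp <- kineticParameters(fit)
      rows[[length(rows) + 1L]] <- data.frame(
        enzyme = p$enzyme, substrate = p$substrate, amp_mM = p$amp_mM,
        model = fit@model, vmax = kp[["vmax"]], s50 = kp[["s50"]],
        hill_n = kp[["hill_n"]], converged = fit@converged)
    }
    fits <- do.call(rbind, rows)
    saveCsv(fits, "kinetic_fits.csv")
    list(fits = fits,
         kcat_ratio_printed = pars$kcat_per_s[pars$enzyme == "Pyk1" &
                                                pars$substrate == "ADP" &
                                                pars$amp_mM == 1] /
           pars$kcat_per_s[pars$enzyme == "Pyk2" & pars$substrate == "ADP" &
                             pars$amp_mM == 1],
         vmax_fold_change_printed = as.numeric(
           round(pars$vmax_U_per_mg[3] / pars$vmax_U_per_mg[1], 1)))
  })

  report$phenotype <- runStage("phenotype", function(sd) {
    assay <- if (!is.null(cfg$competition)) utils::read.csv(cfg$competition) else
      simulateCompetition(m1 = 0.095, m2 = 0.101, n0 = 1e5, t = 68,
                          countNoiseCv = 0.1, replicates = 3, seed = sd,
                          strains = c("mutant", "wildtype"))
    fr <- relativeFitness(assay)
    per <- fitnessReplicates(fr)
    saveCsv(per, "fitness.csv")
    list(strains = fr@strains, mean_W = fr@meanW, sd_W = fr@sdW,
         p_value = fr@pValue, per_replicate_W = per$W)
  })

  report <- report[!vapply(report, is.null, logical(1))]
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", na = "null")
    writeLines(.reportMarkdown(report), file.path(cfg$out_dir, "report.md"))
  }
  invisible(report)
}

.reportMarkdown <- function(report) {
  lines <- c("# Pipeline report", "")
  if (!is.null(report$census)) {
    lines <- c(lines, "## Expansion census",
               sprintf("- %d genomes x %d roles; %d flagged (group, role) pairs",
                       report$census$n_genomes, report$census$n_roles,
                       report$census$n_flagged), "")
  }
  if (!is.null(report$phylo)) {
    mc <- report$phylo$mechanism_calls
    lines <- c(lines, "## Gene tree mechanisms",
               sprintf("- congruence (normalized RF): %.3f",
                       report$phylo$congruence_rf),
               if (is.data.frame(mc) && nrow(mc)) {
                 sprintf("- %s (%s): %s", mc$copy_id, mc$species, mc$mechanism)
               }, "")
  }
  if (!is.null(report$selection)) {
    lines <- c(lines, "## Selection",
               sprintf("- dN/dS = %.3f (SE %.3f)%s", report$selection$omega,
                       report$selection$se_omega,
                       if (isTRUE(report$selection$purifying)) " — purifying" else ""),
               "")
  }
  if (!is.null(report$kinetics) && is.data.frame(report$kinetics$fits)) {
    f <- report$kinetics$fits
    lines <- c(lines, "## Kinetic fits",
               sprintf("- %s / %s (AMP %s mM, %s): Vmax %.3g U/mg, S0.5 %.3g mM, n %.3g",
                       f$enzyme, f$substrate, f$amp_mM, f$model, f$vmax, f$s50,
                       f$hill_n), "")
  }
  if (!is.null(report$phenotype)) {
    lines <- c(lines, "## Fitness",
               sprintf("- W(%s / %s) = %.3f (SD %.3f, p = %.3g)",
                       report$phenotype$strains[1], report$phenotype$strains[2],
                       report$phenotype$mean_W, report$phenotype$sd_W,
                       report$phenotype$p_value), "")
  }
  lines
}

#' Demo pipeline run on synthetic inputs
#'
#' Convenience wrapper: runs every stage on synthetic data under one seed.
#'
#' @inheritParams runPipeline
#' @return the report list, invisibly.
#' @export
pipelineDemo <- function(seed = 1L, outDir = NULL) {
  runPipeline(config = NULL, seed = seed, outDir = outDir)
}

#' Compare recomputed quantities with printed reference values
#'
#' Rounding-aware consistency check: a recomputed value agrees with a printed
#' one when it rounds to the printed value at the printed precision (half-unit
#' in the last printed decimal place). Unknown keys are listed, not fatal.
#'
#' @param report named list (or flat named numeric vector) of recomputed
#'   values.
#' @param printedValues named list of printed values, as numbers or strings
#'   preserving the printed precision (e.g. \code{"73.3"}).
#' @return data.frame with key, printed, recomputed, abs_diff, tolerance,
#'   pass (NA for unknown keys).
#' @export
consistencyCheck <- function(report, printedValues) {
  if (length(printedValues) == 0L) {
    return(data.frame(key = character(), printed = numeric(),
                      recomputed = numeric(), abs_diff = numeric(),
                      tolerance = numeric(), pass = logical()))
  }
  flat <- unlist(report)
  rows <- lapply(names(printedValues), function(k) {
    printedRaw <- printedValues[[k]]
    printed <- suppressWarnings(as.numeric(gsub(",", "", printedRaw)))
    dec <- if (is.character(printedRaw) && grepl("\\.", printedRaw)) {
      nchar(sub(".*\\.", "", printedRaw))
    } else if (!is.character(printedRaw) && printed %% 1 != 0) {
      nchar(sub(".*\\.", "", format(printed)))
    } else 0L
    tol <- 0.5 * 10^(-dec)
    if (!k %in% names(flat)) {
      return(data.frame(key = k, printed = printed, recomputed = NA_real_,
                        abs_diff = NA_real_, tolerance = tol, pass = NA))
    }
    rec <- as.numeric(flat[[k]])
    data.frame(key = k, printed = printed, recomputed = rec,
               abs_diff = abs(printed - rec), tolerance = tol,
               pass = abs(printed - rec) <= tol)
  })
  do.call(rbind, rows)
}
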