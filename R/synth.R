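#' Simulate a multi-genus functional census with planted expansions
#'
#' Generates a copy-number census emulating a multi-suborder actinobacterial
#' annotation database: copy counts are Poisson at a base rate per genome per
#' role, and planted expansions add a fixed shift to the Poisson mean of every
#' genome in the chosen group for the chosen role. With no planted expansions
#' the census is a null model under which expansion calls occur only at the
#' mean-plus-SD exceedance rate.
#'
#' @param nSuborders,generaPerSuborder,genomesPerGenus structure of the
#'   taxonomy (all >= 1).
#' @param roles either a character vector of role names or a named list of
#'   pathways, each a character vector of roles.
#' @param baseCopyRate expected copies per genome per role (Poisson mean,
#'   >= 0; default 1).
#' @param plantedExpansions data.frame with columns \code{group} (a genus or
#'   suborder label), \code{role}, \code{added_mean} (> 0), or NULL.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return a \linkS4class{FunctionalCensus}. Genera are labelled
#'   \code{so<i>_genus<j>}, genomes \code{<genus>_gen<k>}.
#' @examples
#' cen <- simulateCensus(2, 3, 4, roles = c("pk", "pfk"), seed = 1)
#' dim(censusCounts(cen))
#' @export
simulateCensus <- function(nSuborders = 4, generaPerSuborder = 5,
                           genomesPerGenus = 5,
                           roles = paste0("role", sprintf("%02d", 1:20)),
                           baseCopyRate = 1.0, plantedExpansions = NULL,
                           seed = 1L) {
  assertScalarNumeric(nSuborders, "nSuborders", 1)
  assertScalarNumeric(generaPerSuborder, "generaPerSuborder", 1)
  assertScalarNumeric(genomesPerGenus, "genomesPerGenus", 1)
  assertScalarNumeric(baseCopyRate, "baseCopyRate", 0)
  pathways <- NULL
  if (is.list(roles)) {
    pathways <- roles
    roles <- unique(unlist(roles))
  }
  suborders <- paste0("so", seq_len(nSuborders))
  genera <- as.vector(t(outer(suborders, seq_len(generaPerSuborder),
                              function(s, j) paste0(s, "_genus", j))))
  genusSub <- rep(suborders, each = generaPerSuborder)
  genomes <- as.vector(t(outer(genera, seq_len(genomesPerGenus),
                               function(g, k) paste0(g, "_gen", k))))
  genomeGenus <- rep(genera, each = genomesPerGenus)
  genomeSub <- rep(genusSub, each = genomesPerGenus)

  lambda <- matrix(baseCopyRate, nrow = length(roles), ncol = length(genomes),
                   dimnames = list(roles, genomes))
  if (!is.null(plantedExpansions) && nrow(plantedExpansions) > 0L) {
    pe <- as.data.frame(plantedExpansions)
    if (!all(c("group", "role", "added_mean") %in% colnames(pe))) {
      stop("plantedExpansions needs columns group, role, added_mean")
    }
    if (any(pe$added_mean <= 0)) stop("planted added_mean must be > 0")
    for (i in seq_len(nrow(pe))) {
      if (!pe$role[i] %in% roles) {
        stop("planted role not in role catalog: ", pe$role[i])
      }
      inGroup <- genomeGenus == pe$group[i] | genomeSub == pe$group[i]
      if (!any(inGroup)) {
        stop("planted group not in taxonomy: ", pe$group[i])
      }
      lambda[pe$role[i], inGroup] <- lambda[pe$role[i], inGroup] + pe$added_mean[i]
    }
  }
  counts <- withSeed(seed, {
    matrix(rpois(length(lambda), as.vector(lambda)),
           nrow = nrow(lambda), dimnames = dimnames(lambda))
  })
  tax <- data.frame(genome_id = genomes, genus = genomeGenus,
                    suborder = genomeSub)
  FunctionalCensus(counts, tax, pathways = pathways)
}

## ---- gene trees ------------------------------------------------------------

# Minimal recursive clade representation for tree surgery: a tip is a
# character scalar, an internal node a list of children. Trees here are tiny
# (synthetic scenarios), so clarity beats efficiency.
.phyloToClade <- function(tree) {
  n <- length(tree$tip.label)
  rec <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    lapply(kids, rec)
  }
  rec(n + 1L)
}

.cladeToNewick <- function(cl) {
  if (is.character(cl)) return(cl)
  paste0("(", paste(vapply(cl, .cladeToNewick, character(1)), collapse = ","), ")")
}

.cladeTips <- function(cl) {
  if (is.character(cl)) return(cl)
  unlist(lapply(cl, .cladeTips))
}

# Apply f to the first clade (depth-first) whose tip set equals `tips`;
# error if absent. Only the first match is edited.
.editClade <- function(cl, tips, f) {
  hit <- FALSE
  rec <- function(node) {
    if (hit) return(node)
    if (is.character(node)) {
      if (length(tips) == 1L && node == tips) { hit <<- TRUE; return(f(node)) }
      return(node)
    }
    here <- .cladeTips(node)
    if (setequal(here, tips)) {
      sub <- NULL
      # prefer the deepest matching clade
      for (i in seq_along(node)) {
        if (setequal(.cladeTips(node[[i]]), tips)) { sub <- i; break }
      }
      if (is.null(sub)) { hit <<- TRUE; return(f(node)) }
    }
    lapply(node, rec)
  }
  out <- rec(cl)
  if (!hit) stop("no clade with tips {", paste(tips, collapse = ","), "} in tree")
  out
}

.suffixCopies <- function(cl, k) {
  if (is.character(cl)) return(paste0(cl, "_", k))
  lapply(cl, .suffixCopies, k = k)
}

#' Simulate a gene tree with planted duplication and HGT events
#'
#' Starts from a species topology in which every species carries one gene copy
#' and plants events: a duplication at the ancestral branch of a set of
#' retained lineages replaces that clade with two species-congruent copies of
#' itself (copy indices 1 and 2); a horizontal transfer grafts an additional
#' copy of the recipient species as sister to the donor tip, i.e. nested
#' within the donor's clade. Gene-tree tips are named
#' \code{<species>_<copy index>}.
#'
#' @param speciesNewick species topology as a Newick string, e.g.
#'   \code{"((A,B),C);"}.
#' @param duplications list of character vectors; each vector names the
#'   retained lineages (tip species) under the duplicated ancestral branch.
#' @param hgt list of \code{c(donor, recipient)} species pairs.
#' @param seed unused randomness hook, kept for interface symmetry with the
#'   other generators (event placement is deterministic).
#' @return list with \code{tree} (an \code{ape} \code{phylo}), \code{tipMap}
#'   (named character vector, tip label -> species), and \code{truth}
#'   (data.frame tip, mechanism for the planted extra copies).
#' @examples
#' g <- simulateGeneTree("((A,B),C);", duplications = list(c("A", "B")))
#' ape::write.tree(g$tree)
#' @export
simulateGeneTree <- function(speciesNewick, duplications = list(),
                             hgt = list(), seed = NULL) {
  sp <- tryCatch(ape::read.tree(text = speciesNewick),
                 error = function(e) NULL)
  if (is.null(sp)) stop("malformed Newick species topology")
  species <- sp$tip.label
  if (anyDuplicated(species)) stop("duplicate species tips")
  cl <- .phyloToClade(sp)

  truth <- data.frame(tip = character(), mechanism = character(),
                      stringsAsFactors = FALSE)
  copyIndex <- setNames(rep(1L, length(species)), species)

  for (ev in duplications) {
    if (!all(ev %in% species)) {
      stop("duplication event references unknown species: ",
           paste(setdiff(ev, species), collapse = ", "))
    }
    cl <- .editClade(cl, ev, function(node) {
      list(node, node)   # two retained, species-congruent copies
    })
    truth <- rbind(truth, data.frame(
      tip = paste0(ev, "_2"), mechanism = "duplication"))
    copyIndex[ev] <- 2L
  }

  for (ev in hgt) {
    donor <- ev[[1]]; recipient <- ev[[2]]
    if (!donor %in% species || !recipient %in% species) {
      stop("hgt event references unknown species")
    }
    newCopy <- copyIndex[[recipient]] + 1L
    copyIndex[[recipient]] <- newCopy
    tipLab <- paste0(recipient, "#", newCopy)   # placeholder, renamed below
    cl <- .editClade(cl, donor, function(node) list(node, tipLab))
    truth <- rbind(truth, data.frame(
      tip = paste0(recipient, "_", newCopy), mechanism = "hgt"))
  }

  # assign copy suffixes: duplicated clades got suffixed wholesale above via
  # the two-retained construction, so walk the tree and suffix vertical copies
  seen <- new.env()
  suffix <- function(node) {
    if (is.character(node)) {
      if (grepl("#", node, fixed = TRUE)) {       # grafted HGT copy
        return(sub("#", "_", node, fixed = TRUE))
      }
      k <- if (is.null(seen[[node]])) 1L else seen[[node]] + 1L
      seen[[node]] <- k
      return(paste0(node, "_", k))
    }
    lapply(node, suffix)
  }
  cl <- suffix(cl)

  nwk <- paste0(.cladeToNewick(cl), ";")
  gt <- ape::read.tree(text = nwk)
  tipMap <- setNames(sub("_[0-9]+$", "", gt$tip.label), gt$tip.label)
  list(tree = gt, tipMap = tipMap, truth = truth)
}

## ---- codon pairs -----------------------------------------------------------

senseCodons <- function(codeTable = Biostrings::GENETIC_CODE) {
  names(codeTable)[codeTable != "*"]
}

#' Simulate an in-frame codon-aligned sequence pair at a target dN/dS
#'
#' Draws a random stop-free coding sequence and derives a partner by per-codon
#' substitution sampling: the number of mutation events per codon is Poisson
#' with the given expected rate, each event proposes a random single-nucleotide
#' change, proposals creating a stop codon are rejected, synonymous proposals
#' are always accepted, and nonsynonymous proposals are accepted with
#' probability \code{targetOmega} (capped at 1). The realised
#' nonsynonymous-to-synonymous rate ratio is therefore proportional to
#' \code{targetOmega}; with \code{targetOmega = 0} every observed difference
#' is synonymous. This per-site acceptance scheme is an approximation to a
#' full codon-model simulation, adequate for estimator-recovery tests.
#'
#' @param nCodons number of codons (>= 10).
#' @param targetOmega target dN/dS ratio (>= 0; values > 1 are accepted at
#'   rate 1 for nonsynonymous and 1/targetOmega for synonymous proposals).
#' @param subsPerCodon expected substitution events per codon (> 0 for a
#'   diverged pair; 0 yields identical sequences).
#' @param seed integer seed.
#' @return \code{Biostrings::DNAStringSet} of two sequences named
#'   \code{"ancestor"} and \code{"derived"}.
#' @export
simulateCodonPair <- function(nCodons = 300, targetOmega = 0.5,
                              subsPerCodon = 0.3, seed = 1L) {
  assertScalarNumeric(nCodons, "nCodons", 10)
  assertScalarNumeric(targetOmega, "targetOmega", 0)
  assertScalarNumeric(subsPerCodon, "subsPerCodon", 0)
  code <- Biostrings::GENETIC_CODE
  sense <- senseCodons(code)
  nts <- c("A", "C", "G", "T")
  accN <- min(1, targetOmega)
  accS <- if (targetOmega > 1) 1 / targetOmega else 1

  withSeed(seed, {
    anc <- sample(sense, nCodons, replace = TRUE)
    der <- anc
    nEvents <- rpois(nCodons, subsPerCodon)
    for (i in which(nEvents > 0L)) {
      cod <- strsplit(der[i], "")[[1]]
      for (e in seq_len(nEvents[i])) {
        pos <- sample.int(3L, 1L)
        alt <- sample(setdiff(nts, cod[pos]), 1L)
        prop <- cod
        prop[pos] <- alt
        propStr <- paste(prop, collapse = "")
        if (code[[propStr]] == "*") next                  # no stops introduced
        syn <- code[[propStr]] == code[[paste(cod, collapse = "")]]
        if (targetOmega == 0) {
          # strictly neutral pairs must stay pathway-synonymous: multi-hit
          # chains of synonymous steps can otherwise leave the ancestor and
          # derived codons connected only through nonsynonymous pathways,
          # which difference counting would score as Nd > 0
          if (!syn) next
          pathOk <- tryCatch(
            codonDifferences(anc[i], propStr, code = code)[["nd"]] == 0,
            error = function(e) FALSE)
          if (!pathOk) next
        }
        if (runif(1) <= (if (syn) accS else accN)) cod <- prop
      }
      der[i] <- paste(cod, collapse = "")
    }
    Biostrings::DNAStringSet(c(ancestor = paste(anc, collapse = ""),
                               derived = paste(der, collapse = "")))
  })
}

## ---- kinetics --------------------------------------------------------------

# Hill rate law; n = 1 reduces to Michaelis-Menten.
hillRate <- function(s, vmax, s50, hillN = 1) {
  vmax * s^hillN / (s50^hillN + s^hillN)
}

#' Simulate saturation-kinetics rate measurements
#'
#' Rates follow the Michaelis-Menten or Hill law at the given parameters with
#' multiplicative Gaussian noise of constant coefficient of variation
#' (matching constant-CV assay error), truncated at zero, replicated per grid
#' point.
#'
#' @param model \code{"MM"} or \code{"Hill"}.
#' @param vmax maximal rate, U/mg (> 0).
#' @param s50 half-saturation concentration, mM (> 0).
#' @param hillN Hill coefficient (>= 1; forced to 1 for \code{model = "MM"}).
#' @param substrate numeric vector of substrate concentrations, mM (non-empty).
#' @param noiseCv coefficient of variation of the multiplicative noise (>= 0).
#' @param replicates measurements per concentration (default 3, matching
#'   triplicate assays).
#' @param seed integer seed.
#' @return data.frame with columns \code{substrate_mM}, \code{rate_U_per_mg},
#'   \code{replicate}.
#' @examples
#' simulateRateData("MM", vmax = 10, s50 = 0.5, substrate = c(0.5, 1),
#'                  noiseCv = 0, seed = 1)
#' @export
simulateRateData <- function(model = c("MM", "Hill"), vmax, s50, hillN = 1,
                             substrate, noiseCv = 0.05, replicates = 3,
                             seed = 1L) {
  model <- match.arg(model)
  assertScalarNumeric(vmax, "vmax", 0, strict = TRUE)
  assertScalarNumeric(s50, "s50", 0, strict = TRUE)
  assertScalarNumeric(hillN, "hillN", 1)
  assertScalarNumeric(noiseCv, "noiseCv", 0)
  if (length(substrate) == 0L) stop("empty substrate grid")
  if (model == "MM") hillN <- 1
  s <- rep(substrate, each = replicates)
  mu <- hillRate(s, vmax, s50, hillN)
  rate <- withSeed(seed, pmax(0, mu * (1 + rnorm(length(s), 0, noiseCv))))
  data.frame(substrate_mM = s, rate_U_per_mg = rate,
             replicate = rep(seq_len(replicates), times = length(substrate)))
}

## ---- competition -----------------------------------------------------------

#' Simulate a two-strain competition assay
#'
#' Each strain grows exponentially from its inoculum at its Malthusian rate;
#' final CFU counts get multiplicative Gaussian counting noise truncated at
#' zero. Defaults mirror a typical assay: about 1e5 CFU of each strain
#' inoculated, 68 h of growth, triplicate.
#'
#' @param m1,m2 Malthusian growth rates of the two competitors, per hour.
#' @param n0 initial CFU per strain (> 0).
#' @param t duration, hours (> 0).
#' @param countNoiseCv coefficient of variation of plating noise on the final
#'   counts (>= 0; applied to both strains, initial counts are taken as
#'   known).
#' @param replicates number of replicate assays (default 3).
#' @param seed integer seed.
#' @param strains labels of the competitors.
#' @return data.frame with columns \code{strain}, \code{replicate},
#'   \code{n0_cfu}, \code{nf_cfu}, \code{t_h} suitable for
#'   \code{\link{relativeFitness}}.
#' @export
simulateCompetition <- function(m1, m2, n0 = 1e5, t = 68,
                                countNoiseCv = 0, replicates = 3, seed = 1L,
                                strains = c("strain1", "strain2")) {
  assertScalarNumeric(n0, "n0", 0, strict = TRUE)
  assertScalarNumeric(t, "t", 0, strict = TRUE)
  assertScalarNumeric(countNoiseCv, "countNoiseCv", 0)
  m <- c(m1, m2)
  withSeed(seed, {
    rows <- do.call(rbind, lapply(seq_len(replicates), function(r) {
      nf <- n0 * exp(m * t)
      if (countNoiseCv > 0) {
        nf <- pmax(.Machine$double.eps,
                   nf * (1 + rnorm(2, 0, countNoiseCv)))
      }
      data.frame(strain = strains, replicate = r, n0_cfu = n0, nf_cfu = nf,
                 t_h = t)
    }))
    rownames(rows) <- NULL
    rows
  })
}
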