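#' Malthusian net growth rate
#'
#' \code{m = ln(Nf / N0) / t}: the net growth rate of a competitor estimated
#' from its initial and final population densities. Negative rates (decline)
#' are allowed.
#'
#' @param n0,nf initial and final CFU counts (> 0).
#' @param t duration in hours (> 0).
#' @return rate in 1/h.
#' @examples
#' malthusianRate(1e5, 1e8, 68)  # ~0.1016 per hour
#' @export
malthusianRate <- function(n0, nf, t) {
  if (any(n0 <= 0) || any(nf <= 0)) stop("CFU counts must be positive")
  if (any(t <= 0)) stop("duration must be positive")
  log(nf / n0) / t
}

#' Relative fitness from a two-strain competition assay
#'
#' Computes per-replicate Malthusian rates for both competitors and the
#' relative fitness \code{W = m1 / m2} (numerator strain first), then
#' summarises over replicates with the mean, SD and a two-sided one-sample
#' Welch/Student t test of W against 1. A strain competed against itself with
#' identical counts gives W = 1 exactly. Replicates in which the denominator
#' rate is 0 are excluded with a warning.
#'
#' @param assay data.frame with columns \code{strain}, \code{replicate},
#'   \code{n0_cfu}, \code{nf_cfu}, \code{t_h}; exactly two strains, both
#'   present in every replicate (e.g. from \code{\link{simulateCompetition}}).
#' @param numerator strain whose fitness is reported relative to the other;
#'   default the first strain level encountered.
#' @return a \linkS4class{FitnessResult}.
#' @export
relativeFitness <- function(assay, numerator = NULL) {
  assay <- as.data.frame(assay)
  need <- c("strain", "replicate", "n0_cfu", "nf_cfu", "t_h")
  if (!all(need %in% colnames(assay))) {
    stop("assay needs columns ", paste(need, collapse = ", "))
  }
  strains <- unique(assay$strain)
  if (length(strains) != 2L) stop("assay must contain exactly two strains")
  if (is.null(numerator)) numerator <- strains[1]
  if (!numerator %in% strains) stop("unknown numerator strain: ", numerator)
  denominator <- setdiff(strains, numerator)
  reps <- sort(unique(assay$replicate))
  rows <- lapply(reps, function(r) {
    sub <- assay[assay$replicate == r, , drop = FALSE]
    if (!all(strains %in% sub$strain)) {
      stop("replicate ", r, " lacks one of the competitors")
    }
    getRate <- function(s) {
      x <- sub[sub$strain == s, , drop = FALSE][1, ]
      malthusianRate(x$n0_cfu, x$nf_cfu, x$t_h)
    }
    data.frame(replicate = r, m1 = getRate(numerator),
               m2 = getRate(denominator))
  })
  per <- do.call(rbind, rows)
  bad <- per$m2 == 0
  excluded <- character(0)
  if (any(bad)) {
    warning(sum(bad), " replicate(s) excluded: competitor growth rate is 0")
    excluded <- as.character(per$replicate[bad])
    per <- per[!bad, , drop = FALSE]
  }
  if (nrow(per) == 0L) stop("no usable replicates")
  per$W <- per$m1 / per$m2
  tt <- if (nrow(per) >= 2L && sd(per$W) > 0) t.test(per$W, mu = 1) else NULL
  new("FitnessResult",
      strains = c(numerator, denominator),
      perReplicate = per,
      meanW = mean(per$W), sdW = if (nrow(per) >= 2L) sd(per$W) else NA_real_,
      tStat = if (is.null(tt)) NA_real_ else unname(tt$statistic),
      pValue = if (is.null(tt)) NA_real_ else tt$p.value,
      excluded = excluded)
}

#' Compare relative fitness between two competition experiments
#'
#' Two-sample Welch t test between the per-replicate W values of two
#' \linkS4class{FitnessResult} objects (e.g. two different mutants each
#' competed against the wild type).
#'
#' @param resultA,resultB \linkS4class{FitnessResult} objects.
#' @return list with \code{difference} (mean W difference), \code{tStat},
#'   \code{pValue}.
#' @export
compareFitness <- function(resultA, resultB) {
  stopifnot(is(resultA, "FitnessResult"), is(resultB, "FitnessResult"))
  wa <- resultA@perReplicate$W
  wb <- resultB@perReplicate$W
  tt <- t.test(wa, wb)
  list(difference = mean(wa) - mean(wb),
       tStat = unname(tt$statistic), pValue = tt$p.value)
}

#' Expression fold change by the comparative Ct method
#'
#' Reference-normalized qPCR fold change between two conditions:
#' per-sample \code{dCt = Ct_target - Ct_reference}, then
#' \code{ddCt = mean dCt(conditionA) - mean dCt(conditionB)} and
#' \code{fold = efficiency^-ddCt} (the familiar \code{2^-ddCt} at 100\%
#' amplification efficiency). A fold change above 1 means higher expression in
#' condition A. A Welch t test between the per-sample dCt groups accompanies
#' the estimate.
#'
#' @param qpcr data.frame with columns \code{sample}, \code{condition},
#'   \code{gene}, \code{ct}; the reference gene must be measured in every
#'   sample where the target is.
#' @param target target gene name.
#' @param conditionA,conditionB conditions to compare (A relative to B).
#' @param reference reference gene (default \code{"hrdB"}).
#' @param efficiency amplification factor per cycle (default 2 = 100\%
#'   efficiency).
#' @return list with \code{fold_change}, \code{ddct}, \code{dct_a},
#'   \code{dct_b} (per-sample values), \code{tStat}, \code{pValue}.
#' @examples
#' q <- data.frame(sample = rep(1:6, each = 2),
#'                 condition = rep(c("glucose", "tween"), each = 6),
#'                 gene = rep(c("pyk1", "hrdB"), 6),
#'                 ct = c(rbind(c(20, 20, 20, 22, 22, 22), rep(15, 6))))
#' ddctFoldChange(q, "pyk1", "glucose", "tween")$fold_change  # 4
#' @export
ddctFoldChange <- function(qpcr, target, conditionA, conditionB,
                           reference = "hrdB", efficiency = 2) {
  qpcr <- as.data.frame(qpcr)
  need <- c("sample", "condition", "gene", "ct")
  if (!all(need %in% colnames(qpcr))) {
    stop("qpcr data needs columns ", paste(need, collapse = ", "))
  }
  if (any(qpcr$ct <= 0)) stop("Ct values must be positive")
  assertScalarNumeric(efficiency, "efficiency", 1)
  dctFor <- function(cond) {
    sub <- qpcr[qpcr$condition == cond, , drop = FALSE]
    if (nrow(sub) == 0L) stop("no rows for condition: ", cond)
    samples <- unique(sub$sample[sub$gene == target])
    if (length(samples) == 0L) stop("target gene absent in condition: ", cond)
    vapply(samples, function(sm) {
      tg <- sub$ct[sub$sample == sm & sub$gene == target]
      rf <- sub$ct[sub$sample == sm & sub$gene == reference]
      if (length(rf) == 0L) {
        stop("reference gene '", reference, "' missing for sample ", sm)
      }
      mean(tg) - mean(rf)
    }, numeric(1))
  }
  dctA <- dctFor(conditionA)
  dctB <- dctFor(conditionB)
  ddct <- mean(dctA) - mean(dctB)
  tt <- if (length(dctA) >= 2L && length(dctB) >= 2L &&
            (sd(dctA) > 0 || sd(dctB) > 0)) t.test(dctA, dctB) else NULL
  list(fold_change = efficiency^(-ddct), ddct = ddct,
       dct_a = dctA, dct_b = dctB,
       tStat = if (is.null(tt)) NA_real_ else unname(tt$statistic),
       pValue = if (is.null(tt)) NA_real_ else tt$p.value)
}

#' Specific metabolite yield
#'
#' Yield of a spectrophotometrically quantified metabolite per unit biomass
#' (absorbance units per mg). Negative absorbances, which arise from blank
#' over-subtraction, are clamped to 0 with a warning.
#'
#' @param absorbance absorbance units (AU).
#' @param biomassMg biomass in mg (> 0).
#' @return yield in AU/mg.
#' @export
specificYield <- function(absorbance, biomassMg) {
  if (any(biomassMg <= 0)) stop("biomass must be positive")
  if (any(absorbance < 0)) {
    warning("negative absorbance clamped to 0 (blank over-subtraction)")
    absorbance <- pmax(0, absorbance)
  }
  absorbance / biomassMg
}
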