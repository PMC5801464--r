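.checkRateTable <- function(data) {
  data <- as.data.frame(data)
  # accept either the interchange column names or bare substrate/rate
  sCol <- intersect(c("substrate_mM", "substrate", "amp_mM", "activator_mM"),
                    colnames(data))[1]
  rCol <- intersect(c("rate_U_per_mg", "rate"), colnames(data))[1]
  if (is.na(sCol) || is.na(rCol)) {
    stop("rate table needs a substrate/activator column and a rate column")
  }
  out <- data.frame(s = as.numeric(data[[sCol]]), v = as.numeric(data[[rCol]]))
  if (any(!is.finite(out$s)) || any(!is.finite(out$v))) {
    stop("non-finite substrate or rate values")
  }
  if (any(out$s < 0) || any(out$v < 0)) stop("substrate and rate must be >= 0")
  if (length(unique(out$s[out$s > 0])) < 4L) {
    stop("need at least 4 distinct positive substrate levels to fit")
  }
  out
}

# Multi-start bounded Levenberg-Marquardt least squares of the Hill law.
# `fixN = TRUE` pins the Hill coefficient at 1 (Michaelis-Menten).
.fitSaturation <- function(d, fixN, nBounds = c(0.5, 12)) {
  vStart <- max(d$v)
  if (vStart <= 0) {
    return(list(ok = FALSE, why = "all rates are zero"))
  }
  sPos <- d$s[d$s > 0]
  s50Starts <- unique(quantile(sPos, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE))
  nStarts <- if (fixN) 1 else c(1, 2, 4, 8)
  ctl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15)
  best <- NULL
  for (s50s in s50Starts) {
    for (ns in nStarts) {
      fit <- tryCatch({
        if (fixN) {
          minpack.lm::nlsLM(
            v ~ vmax * s / (s50 + s), data = d,
            start = list(vmax = vStart, s50 = s50s),
            lower = c(vmax = 1e-12, s50 = 1e-12), control = ctl)
        } else {
          minpack.lm::nlsLM(
            v ~ vmax * s^n / (s50^n + s^n), data = d,
            start = list(vmax = vStart, s50 = s50s, n = ns),
            lower = c(vmax = 1e-12, s50 = 1e-12, n = nBounds[1]),
            upper = c(vmax = Inf, s50 = Inf, n = nBounds[2]),
            control = ctl)
        }
      }, error = function(e) NULL, warning = function(w) NULL)
      if (is.null(fit)) next
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12) {  # first-found tie-break
        best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best)) return(list(ok = FALSE, why = "no start converged"))
  c(best, ok = TRUE)
}

.kineticFitFrom <- function(best, model, nObs) {
  cf <- coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, length(cf)), names(cf)))
  hillN <- if ("n" %in% names(cf)) unname(cf[["n"]]) else 1
  seVec <- c(vmax = unname(se[["vmax"]]), s50 = unname(se[["s50"]]),
             hill_n = if ("n" %in% names(se)) unname(se[["n"]]) else 0)
  new("KineticFit", model = model, vmax = unname(cf[["vmax"]]),
      s50 = unname(cf[["s50"]]), hillN = hillN, se = seVec,
      rss = best$rss, converged = TRUE, nObs = as.integer(nObs))
}

.failedFit <- function(model, nObs, why) {
  warning("kinetic fit failed: ", why)
  new("KineticFit", model = model, vmax = NA_real_, s50 = NA_real_,
      hillN = if (model == "MM") 1 else NA_real_,
      se = c(vmax = NA_real_, s50 = NA_real_, hill_n = NA_real_),
      rss = NA_real_, converged = FALSE, nObs = as.integer(nObs))
}

#' Fit the Michaelis-Menten equation to rate data
#'
#' Bounded least-squares fit of \code{v = Vmax * S / (S0.5 + S)} by
#' Levenberg-Marquardt with multiple starts (Vmax at the maximum observed
#' rate, S0.5 over quantiles of the observed substrate range); the best
#' residual sum of squares wins, ties broken by first found. Standard errors
#' come from the local curvature at the optimum. Replicates are fitted pooled,
#' not averaged. Non-convergence from every start yields a flagged failure,
#' never a silent fallback.
#'
#' @param data data.frame with substrate and rate columns
#'   (\code{substrate_mM} / \code{rate_U_per_mg}, or \code{substrate} /
#'   \code{rate}); at least 4 distinct positive substrate levels.
#' @return a \linkS4class{KineticFit} with \code{model = "MM"} and
#'   \code{hillN} identically 1.
#' @examples
#' d <- simulateRateData("MM", vmax = 10, s50 = 0.5,
#'                       substrate = c(0.1, 0.25, 0.5, 1, 2, 5), noiseCv = 0)
#' kineticParameters(fitMichaelisMenten(d))
#' @export
fitMichaelisMenten <- function(data) {
  d <- .checkRateTable(data)
  best <- .fitSaturation(d, fixN = TRUE)
  if (!isTRUE(best$ok)) return(.failedFit("MM", nrow(d), best$why))
  .kineticFitFrom(best, "MM", nrow(d))
}

#' Fit the Hill equation to rate data
#'
#' Bounded least-squares fit of \code{v = Vmax * S^n / (S0.5^n + S^n)} with
#' the Hill coefficient constrained to [0.5, 12] and multi-start
#' initialization over S0.5 quantiles and n in {1, 2, 4, 8}. With n fixed at
#' 1 the model reduces exactly to Michaelis-Menten.
#'
#' @inheritParams fitMichaelisMenten
#' @param nBounds lower and upper bounds on the Hill coefficient.
#' @return a \linkS4class{KineticFit} with \code{model = "Hill"}.
#' @export
fitHill <- function(data, nBounds = c(0.5, 12)) {
  d <- .checkRateTable(data)
  best <- .fitSaturation(d, fixN = FALSE, nBounds = nBounds)
  if (!isTRUE(best$ok)) return(.failedFit("Hill", nrow(d), best$why))
  .kineticFitFrom(best, "Hill", nrow(d))
}

# Small-sample corrected information criterion for a least-squares fit.
.aicc <- function(rss, n, k) {
  # k model parameters + 1 for the error variance
  p <- k + 1
  if (n - p - 1 <= 0) return(Inf)
  n * log(rss / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

#' Choose between Michaelis-Menten and Hill kinetics
#'
#' Fits both models and selects Hill only when its small-sample corrected
#' information criterion improves on the Michaelis-Menten one by more than the
#' evidence margin; the hyperbolic model is preferred otherwise, as the
#' simpler of the nested pair. Sparse designs (fewer observations than twice
#' the Hill parameter count) are flagged low-confidence.
#'
#' @inheritParams fitMichaelisMenten
#' @param margin required improvement in the information criterion before the
#'   Hill model is selected (default 2).
#' @return list with \code{model} ("MM" or "Hill"), \code{mm} and \code{hill}
#'   fits, \code{aicc} (named vector), and \code{low_confidence}.
#' @export
selectKineticModel <- function(data, margin = 2) {
  mm <- fitMichaelisMenten(data)
  hill <- fitHill(data)
  if (!mm@converged && !hill@converged) stop("both kinetic fits failed")
  aicc <- c(MM = if (mm@converged) .aicc(mm@rss, mm@nObs, 2) else Inf,
            Hill = if (hill@converged) .aicc(hill@rss, hill@nObs, 3) else Inf)
  model <- if (aicc[["Hill"]] < aicc[["MM"]] - margin) "Hill" else "MM"
  list(model = model, mm = mm, hill = hill, aicc = aicc,
       low_confidence = mm@nObs < 8L)
}

#' Turnover number from specific activity
#'
#' Converts a maximal specific activity in U/mg (U = umol product per minute)
#' into a per-site turnover number in 1/s:
#' \code{kcat = vmax * molarMass / 60000 / sites}, with \code{molarMass} in
#' g/mol of the catalytic subunit.
#'
#' @param vmax maximal rate, U/mg (>= 0).
#' @param molarMass subunit molar mass, g/mol (> 0).
#' @param sites catalytic sites per subunit (default 1).
#' @return turnover number, 1/s.
#' @examples
#' turnoverNumber(73.3, 50000)  # ~61.1 per second
#' @export
turnoverNumber <- function(vmax, molarMass, sites = 1) {
  assertScalarNumeric(vmax, "vmax", 0)
  assertScalarNumeric(molarMass, "molarMass", 0, strict = TRUE)
  assertScalarNumeric(sites, "sites", 0, strict = TRUE)
  vmax * molarMass / 60000 / sites
}

#' Catalytic efficiency kcat / S0.5
#'
#' @param kcat turnover number, 1/s.
#' @param s50 half-saturation concentration, mM (> 0).
#' @return efficiency in 1/(mM s).
#' @export
catalyticEfficiency <- function(kcat, s50) {
  assertScalarNumeric(kcat, "kcat", 0)
  assertScalarNumeric(s50, "s50", 0, strict = TRUE)
  kcat / s50
}

#' Fit an allosteric activator dose-response
#'
#' Fits a Hill-form response of rate versus activator concentration (e.g. AMP
#' for a type II pyruvate kinase) at fixed substrate levels, returning the
#' activator half-saturation S0.5 and the maximal activated rate. A
#' zero-activator baseline, when present, is subtracted before fitting so the
#' response describes the activation itself.
#'
#' @param data data.frame with an activator column (\code{amp_mM},
#'   \code{activator_mM} or \code{substrate_mM}) and a rate column; at least 4
#'   distinct positive activator levels.
#' @param subtractBaseline subtract the mean rate at activator 0 (default
#'   TRUE when such rows are present).
#' @inheritParams fitHill
#' @return a \linkS4class{KineticFit} for the activator response.
#' @export
activationResponse <- function(data, subtractBaseline = TRUE,
                               nBounds = c(0.5, 12)) {
  d <- .checkRateTable(data)
  if (subtractBaseline && any(d$s == 0)) {
    base <- mean(d$v[d$s == 0])
    d <- d[d$s > 0, , drop = FALSE]
    d$v <- pmax(0, d$v - base)
  }
  best <- .fitSaturation(d, fixN = FALSE, nBounds = nBounds)
  if (!isTRUE(best$ok)) return(.failedFit("Hill", nrow(d), best$why))
  .kineticFitFrom(best, "Hill", nrow(d))
}

#' Fold change of a kinetic parameter between two fits
#'
#' Ratio of a named parameter between two fits of the same enzyme under two
#' conditions (e.g. with and without activator), reported at one decimal
#' place; the unrounded ratio is attached as attribute \code{"exact"}.
#'
#' @param fitA,fitB \linkS4class{KineticFit} objects (numerator first).
#' @param param one of \code{"vmax"}, \code{"s50"}, \code{"hill_n"}.
#' @return rounded ratio with attribute \code{exact}.
#' @examples
#' # Vmax 73.3 / 21.0 -> 3.5-fold activation
#' @export
foldChange <- function(fitA, fitB, param = c("vmax", "s50", "hill_n")) {
  param <- match.arg(param)
  pick <- function(f) {
    stopifnot(is(f, "KineticFit"))
    kineticParameters(f)[[param]]
  }
  a <- pick(fitA); b <- pick(fitB)
  if (!is.finite(b) || b == 0) stop("zero or non-finite denominator parameter")
  structure(round(a / b, 1), exact = a / b)
}
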