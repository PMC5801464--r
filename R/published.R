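#' Published kinetic parameter sets for the two pyruvate kinase isoenzymes
#'
#' The characterised kinetic parameters of the duplicated type II pyruvate
#' kinases Pyk1 and Pyk2 of *Streptomyces coelicolor*, for the substrates ADP
#' (Michaelis-Menten kinetics, at 5 mM PEP) and PEP (Hill kinetics, at 1.5 mM
#' ADP) with and without 1 mM of the allosteric activator AMP, and for the
#' AMP dose-response itself. These serve as generating truths for simulation
#' studies and as printed reference values for consistency checking.
#'
#' @return data.frame with columns \code{enzyme}, \code{substrate},
#'   \code{amp_mM}, \code{model}, \code{vmax_U_per_mg}, \code{s50_mM},
#'   \code{hill_n}, \code{kcat_per_s}.
#' @examples
#' subset(pykKineticParameters(), enzyme == "Pyk1" & substrate == "ADP")
#' @export
pykKineticParameters <- function() {
  data.frame(
    enzyme    = c("Pyk1", "Pyk2", "Pyk1", "Pyk2",
                  "Pyk1", "Pyk2", "Pyk1", "Pyk2",
                  "Pyk1", "Pyk2"),
    substrate = c(rep("ADP", 4), rep("PEP", 4), rep("AMP", 2)),
    amp_mM    = c(0, 0, 1, 1, 0, 0, 1, 1, NA, NA),
    model     = c(rep("MM", 4), rep("Hill", 4), "Hill", "Hill"),
    vmax_U_per_mg = c(21.0, 1.2, 73.3, 6.7,
                      14.1, 0.5, 65.5, 9.1,
                      8.2, 1.0),
    s50_mM    = c(0.6, 0.3, 0.2, 0.1,
                  3.5, 1.3, 1.1, 8.6,
                  0.01, 3.8),
    hill_n    = c(1, 1, 1, 1,
                  3.7, 1.5, 1.8, 7.1,
                  NA, NA),
    kcat_per_s = c(941, 39, 4703, 215,
                   350, 18, 4200, 336,
                   423.7, 42.0),
    stringsAsFactors = FALSE)
}
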