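#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' FunctionalCensus: a genome-by-role copy-number census
#'
#' An S4 container for a functional-role copy-number census across a set of
#' genomes, built on \linkS4class{SummarizedExperiment}. Rows are functional
#' roles (enzyme annotations), columns are genomes; the single assay
#' \code{"copies"} holds non-negative integer copy counts. The column data
#' carries the taxonomy (\code{genus}, \code{suborder}) of every genome, and
#' the row data optionally records pathway membership of each role.
#'
#' @slot ... see \linkS4class{SummarizedExperiment}.
#' @seealso \code{\link{FunctionalCensus}}, \code{\link{buildCensus}},
#'   \code{\link{callExpansions}}
#' @exportClass FunctionalCensus
setClass("FunctionalCensus", contains = "SummarizedExperiment")

setValidity("FunctionalCensus", function(object) {
  msg <- character()
  if (!"copies" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'copies' is required")
  } else {
    m <- SummarizedExperiment::assay(object, "copies")
    if (any(m < 0) || any(m != round(m))) {
      msg <- c(msg, "copy counts must be non-negative integers")
    }
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("genus", "suborder") %in% colnames(cd))) {
    msg <- c(msg, "colData must contain 'genus' and 'suborder' for every genome")
  } else if (anyNA(cd$genus) || anyNA(cd$suborder)) {
    msg <- c(msg, "taxonomy labels may not be NA")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FunctionalCensus
#'
#' @param counts integer matrix of copy numbers, roles in rows and genomes in
#'   columns (both dimnames required).
#' @param taxonomy data.frame with columns \code{genome_id}, \code{genus},
#'   \code{suborder}; must cover every genome in \code{counts}.
#' @param pathways optional named list mapping pathway names to character
#'   vectors of member roles; stored in \code{rowData} and used by
#'   \code{\link{pathwayMatrix}}.
#' @return a \linkS4class{FunctionalCensus}.
#' @examples
#' counts <- matrix(c(2L, 0L, 1L, 1L), 2, 2,
#'                  dimnames = list(c("pk", "pfk"), c("g1", "g2")))
#' tax <- data.frame(genome_id = c("g1", "g2"),
#'                   genus = c("Streptomyces", "Kitasatospora"),
#'                   suborder = "Streptomycineae")
#' FunctionalCensus(counts, tax)
#' @export
FunctionalCensus <- function(counts, taxonomy, pathways = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("'counts' must have role rownames and genome colnames")
  }
  storage.mode(counts) <- "integer"
  taxonomy <- as.data.frame(taxonomy)
  need <- c("genome_id", "genus", "suborder")
  if (!all(need %in% colnames(taxonomy))) {
    stop("taxonomy must have columns genome_id, genus, suborder")
  }
  missing <- setdiff(colnames(counts), taxonomy$genome_id)
  if (length(missing)) {
    stop("genomes without taxonomy entries: ", paste(missing, collapse = ", "))
  }
  tax <- taxonomy[match(colnames(counts), taxonomy$genome_id), , drop = FALSE]
  cd <- S4Vectors::DataFrame(genus = tax$genus, suborder = tax$suborder,
                             row.names = colnames(counts))
  rd <- S4Vectors::DataFrame(row.names = rownames(counts))
  rd$pathway <- rep(NA_character_, nrow(counts))
  if (!is.null(pathways)) {
    for (pw in names(pathways)) {
      unknown <- setdiff(pathways[[pw]], rownames(counts))
      if (length(unknown)) {
        stop(sprintf("pathway '%s' references unknown roles: %s",
                     pw, paste(unknown, collapse = ", ")))
      }
      rd$pathway[rownames(counts) %in% pathways[[pw]]] <- pw
    }
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(copies = counts), colData = cd, rowData = rd)
  new("FunctionalCensus", se)
}

#' @describeIn FunctionalCensus copy-count matrix (roles x genomes).
#' @param object,x a FunctionalCensus.
#' @export
censusCounts <- function(x) SummarizedExperiment::assay(x, "copies")

#' @describeIn FunctionalCensus taxonomy as a data.frame
#'   (genome_id, genus, suborder).
#' @export
censusTaxonomy <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(genome_id = rownames(cd), genus = cd$genus,
             suborder = cd$suborder, row.names = NULL)
}

setMethod("show", "FunctionalCensus", function(object) {
  cat(sprintf("FunctionalCensus: %d roles x %d genomes (%d genera, %d suborders)\n",
              nrow(object), ncol(object),
              length(unique(SummarizedExperiment::colData(object)$genus)),
              length(unique(SummarizedExperiment::colData(object)$suborder))))
})

#' PathwayExpansionMatrix: suborder-by-pathway expansion percentages
#'
#' Result of \code{\link{pathwayMatrix}}. The \code{percent} slot holds the
#' percentage of possible (genus, role) expansion events realised in each
#' (suborder, pathway) cell; cells with zero flagged events are reported as
#' \code{"NE"} (no expansion) when formatted, matching the convention of
#' pathway expansion summary tables.
#'
#' @slot percent numeric matrix, suborders x pathways, percentages in [0, 100].
#' @slot flags integer matrix of flagged (genus, role) pairs per cell.
#' @slot denominator integer matrix of n_genera x pathway size per cell.
#' @exportClass PathwayExpansionMatrix
setClass("PathwayExpansionMatrix",
         representation(percent = "matrix", flags = "matrix",
                        denominator = "matrix"))

#' @describeIn PathwayExpansionMatrix formatted character matrix with one
#'   decimal place and "NE" for empty cells.
#' @param object a PathwayExpansionMatrix.
#' @export
formatExpansionMatrix <- function(object) {
  stopifnot(is(object, "PathwayExpansionMatrix"))
  out <- matrix(sprintf("%.1f", object@percent),
                nrow = nrow(object@percent),
                dimnames = dimnames(object@percent))
  out[object@flags == 0L] <- "NE"
  out
}

#' @describeIn PathwayExpansionMatrix numeric percentage matrix (NA where NE).
#' @export
expansionPercent <- function(object) {
  p <- object@percent
  p[object@flags == 0L] <- NA_real_
  p
}

setMethod("show", "PathwayExpansionMatrix", function(object) {
  cat("PathwayExpansionMatrix:", nrow(object@percent), "suborders x",
      ncol(object@percent), "pathways\n")
  print(formatExpansionMatrix(object), quote = FALSE)
})

#' DnDsResult: pairwise Nei-Gojobori dN/dS estimate
#'
#' Holds site counts, difference counts, proportions, Jukes-Cantor corrected
#' distances, the omega ratio and its codon-bootstrap standard error for one
#' aligned sequence pair.
#'
#' @slot nSites,sSites average nonsynonymous / synonymous site counts.
#' @slot nd,sd pathway-averaged nonsynonymous / synonymous differences.
#' @slot pn,ps proportions of differences per site.
#' @slot dn,ds Jukes-Cantor corrected distances.
#' @slot omega dN/dS; NA when dS is 0 (undefined, not infinite).
#' @slot seOmega bootstrap standard error of omega (NA if not bootstrapped).
#' @slot nBootstrap number of bootstrap replicates performed.
#' @slot nCodonsUsed codons retained after pairwise deletion.
#' @slot nCodonsDropped codons dropped for non-ACGT symbols.
#' @slot seed bootstrap seed.
#' @exportClass DnDsResult
setClass("DnDsResult",
         representation(nSites = "numeric", sSites = "numeric",
                        nd = "numeric", sd = "numeric",
                        pn = "numeric", ps = "numeric",
                        dn = "numeric", ds = "numeric",
                        omega = "numeric", seOmega = "numeric",
                        nBootstrap = "integer", nCodonsUsed = "integer",
                        nCodonsDropped = "integer", seed = "integer"))

#' @describeIn DnDsResult the dN/dS ratio (NA when undefined).
#' @param object a DnDsResult.
#' @export
omega <- function(object) {
  stopifnot(is(object, "DnDsResult"))
  object@omega
}

#' @describeIn DnDsResult TRUE when omega < 1 (purifying selection), NA when
#'   omega is undefined.
#' @export
isPurifying <- function(object) {
  stopifnot(is(object, "DnDsResult"))
  if (is.na(object@omega)) NA else object@omega < 1
}

setMethod("show", "DnDsResult", function(object) {
  cat(sprintf("DnDsResult (%d codons):\n", object@nCodonsUsed))
  cat(sprintf("  N = %.3f, S = %.3f, Nd = %.3f, Sd = %.3f\n",
              object@nSites, object@sSites, object@nd, object@sd))
  cat(sprintf("  pN = %.5f, pS = %.5f, dN = %.5f, dS = %.5f\n",
              object@pn, object@ps, object@dn, object@ds))
  if (is.na(object@omega)) {
    cat("  dN/dS undefined (dS = 0)\n")
  } else {
    cat(sprintf("  dN/dS = %.4f", object@omega))
    if (!is.na(object@seOmega)) {
      cat(sprintf(" (bootstrap SE %.4f, %d replicates)", object@seOmega,
                  object@nBootstrap))
    }
    cat(if (object@omega < 1) "  [purifying]\n" else "\n")
  }
})

#' KineticFit: fitted saturation-kinetics model
#'
#' Result of \code{\link{fitMichaelisMenten}}, \code{\link{fitHill}} or
#' \code{\link{activationResponse}}: the fitted maximal rate, half-saturation
#' constant and Hill coefficient with standard errors from the local curvature
#' of the least-squares surface.
#'
#' @slot model "MM" or "Hill".
#' @slot vmax,s50,hillN fitted parameters (U/mg, mM, dimensionless); a
#'   Michaelis-Menten fit has hillN identically 1.
#' @slot se named numeric vector of standard errors.
#' @slot rss residual sum of squares.
#' @slot converged logical convergence flag; FALSE marks a flagged failure.
#' @slot nObs number of observations fitted.
#' @exportClass KineticFit
setClass("KineticFit",
         representation(model = "character", vmax = "numeric",
                        s50 = "numeric", hillN = "numeric",
                        se = "numeric", rss = "numeric",
                        converged = "logical", nObs = "integer"))

#' @describeIn KineticFit named vector of fitted parameters.
#' @param object a KineticFit.
#' @export
kineticParameters <- function(object) {
  stopifnot(is(object, "KineticFit"))
  c(vmax = object@vmax, s50 = object@s50, hill_n = object@hillN)
}

#' @describeIn KineticFit predicted rate at substrate concentrations `s`.
#' @param s numeric vector of substrate (or activator) concentrations, mM.
#' @export
predictRate <- function(object, s) {
  stopifnot(is(object, "KineticFit"))
  hillRate(s, object@vmax, object@s50, object@hillN)
}

setMethod("show", "KineticFit", function(object) {
  cat(sprintf("KineticFit [%s]%s: Vmax = %.4g U/mg (SE %.3g), S0.5 = %.4g mM (SE %.3g)",
              object@model, if (object@converged) "" else " (NOT CONVERGED)",
              object@vmax, object@se[["vmax"]],
              object@s50, object@se[["s50"]]))
  if (object@model == "Hill") {
    cat(sprintf(", n = %.3g (SE %.3g)", object@hillN, object@se[["hill_n"]]))
  }
  cat(sprintf("\n  RSS = %.4g on %d observations\n", object@rss, object@nObs))
})

#' FitnessResult: relative fitness from a competition assay
#'
#' Per-replicate Malthusian growth rates for two competitors, the per-replicate
#' relative fitness W (ratio of growth rates), and summary statistics including
#' a two-sided one-sample test of W against 1.
#'
#' @slot strains the two competitor labels, numerator first.
#' @slot perReplicate data.frame with replicate, m1, m2, W.
#' @slot meanW,sdW summary of W over replicates.
#' @slot tStat,pValue one-sample t test of W vs 1 (NA with < 2 replicates).
#' @slot excluded replicates dropped because the denominator rate was 0.
#' @exportClass FitnessResult
setClass("FitnessResult",
         representation(strains = "character", perReplicate = "data.frame",
                        meanW = "numeric", sdW = "numeric",
                        tStat = "numeric", pValue = "numeric",
                        excluded = "character"))

#' @describeIn FitnessResult mean relative fitness W across replicates.
#' @param object a FitnessResult.
#' @export
relativeFitnessW <- function(object) {
  stopifnot(is(object, "FitnessResult"))
  object@meanW
}

#' @describeIn FitnessResult per-replicate rates and W as a data.frame.
#' @export
fitnessReplicates <- function(object) {
  stopifnot(is(object, "FitnessResult"))
  object@perReplicate
}

setMethod("show", "FitnessResult", function(object) {
  cat(sprintf("FitnessResult: W(%s / %s) = %.4f (SD %.4f, %d replicates)\n",
              object@strains[1], object@strains[2], object@meanW, object@sdW,
              nrow(object@perReplicate)))
  if (!is.na(object@pValue)) {
    cat(sprintf("  one-sample t vs W = 1: t = %.3f, p = %.4g\n",
                object@tStat, object@pValue))
  }
  if (length(object@excluded)) {
    cat("  excluded replicates:", paste(object@excluded, collapse = ", "), "\n")
  }
})
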