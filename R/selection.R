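#' Nei-Gojobori site counts for one codon
#'
#' For each of the three codon positions, the synonymous site fraction is the
#' fraction of the possible single-nucleotide changes at that position that
#' leave the encoded amino acid unchanged; mutations creating a stop codon are
#' excluded from the denominator, so the fractions at a position are computed
#' over the remaining changes. Site fractions are normalized so that every
#' codon contributes exactly 3 sites (n + s = 3), the convention used by
#' standard distance-based implementations.
#'
#' @param codon a 3-letter sense codon (ACGT alphabet).
#' @param code named character vector mapping codons to amino acids
#'   (default: the standard genetic code; the bacterial code, table 11, is
#'   identical for coding changes).
#' @return named numeric vector \code{c(n = ..., s = ...)} with
#'   \code{n + s == 3}.
#' @examples
#' codonSites("TTT")  # s = 1/3: only the third position admits a synonymous change
#' @export
codonSites <- function(codon, code = Biostrings::GENETIC_CODE) {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon)) stop("codon must be 3 ACGT letters")
  aa <- code[[codon]]
  if (is.na(aa) || aa == "*") stop("stop codon has no site decomposition: ", codon)
  nts <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    chars <- strsplit(codon, "")[[1]]
    syn <- 0L; valid <- 0L
    for (alt in setdiff(nts, chars[pos])) {
      mut <- chars
      mut[pos] <- alt
      mutAa <- code[[paste(mut, collapse = "")]]
      if (mutAa == "*") next                 # stop mutations excluded
      valid <- valid + 1L
      if (mutAa == aa) syn <- syn + 1L
    }
    if (valid > 0L) s <- s + syn / valid     # normalized: position = 1 site
  }
  c(n = 3 - s, s = s)
}

# All orderings of the differing positions between two codons, as pathways of
# intermediate codons; used by codonDifferences.
.codonPaths <- function(a, b) {
  diffPos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(diffPos) == 0L) return(list())
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    }
    out
  }
  lapply(perms(diffPos), function(ord) {
    cur <- strsplit(a, "")[[1]]
    tgt <- strsplit(b, "")[[1]]
    steps <- character(length(ord))
    for (k in seq_along(ord)) {
      cur[ord[k]] <- tgt[ord[k]]
      steps[k] <- paste(cur, collapse = "")
    }
    steps
  })
}

#' Nei-Gojobori difference counts between two codons
#'
#' Counts synonymous and nonsynonymous differences by averaging over all
#' orderings of the differing positions (all mutational pathways between the
#' codons). Pathways passing through a stop codon are excluded and the average
#' renormalized over the remaining pathways; when no pathway is excluded,
#' \code{nd + sd} equals the number of differing positions.
#'
#' @param codonA,codonB sense codons.
#' @inheritParams codonSites
#' @return named numeric vector \code{c(nd = ..., sd = ...)}.
#' @examples
#' codonDifferences("TTT", "GTA")  # average over 2 pathways: (1.5, 0.5)
#' @export
codonDifferences <- function(codonA, codonB, code = Biostrings::GENETIC_CODE) {
  codonA <- toupper(codonA); codonB <- toupper(codonB)
  for (cd in c(codonA, codonB)) {
    if (!grepl("^[ACGT]{3}$", cd)) stop("codon must be 3 ACGT letters")
    if (code[[cd]] == "*") stop("stop codon in difference counting: ", cd)
  }
  if (codonA == codonB) return(c(nd = 0, sd = 0))
  paths <- .codonPaths(codonA, codonB)
  ndTot <- 0; sdTot <- 0; kept <- 0L
  for (p in paths) {
    if (any(vapply(p, function(x) code[[x]] == "*", logical(1)))) next
    prev <- codonA
    nd <- 0L; sdv <- 0L
    for (step in p) {
      if (code[[step]] == code[[prev]]) sdv <- sdv + 1L else nd <- nd + 1L
      prev <- step
    }
    ndTot <- ndTot + nd; sdTot <- sdTot + sdv; kept <- kept + 1L
  }
  if (kept == 0L) {
    stop(sprintf("all mutational pathways between %s and %s pass through stop codons",
                 codonA, codonB))
  }
  c(nd = ndTot / kept, sd = sdTot / kept)
}

.splitCodons <- function(x) {
  x <- toupper(as.character(x))
  if (nchar(x) %% 3 != 0) stop("sequence length not divisible by 3")
  substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
}

# Validate and codon-split an aligned pair; drops non-ACGT codons pairwise.
.preparePair <- function(seqA, seqB, code) {
  a <- .splitCodons(seqA); b <- .splitCodons(seqB)
  if (length(a) != length(b)) stop("sequences must have equal length")
  clean <- grepl("^[ACGT]{3}$", a) & grepl("^[ACGT]{3}$", b)
  dropped <- sum(!clean)
  if (dropped) {
    message(dropped, " codon(s) with non-ACGT symbols dropped pairwise")
  }
  a <- a[clean]; b <- b[clean]
  if (length(a) == 0L) stop("no usable codons after pairwise deletion")
  stops <- code[a] == "*" | code[b] == "*"
  if (any(stops)) stop("internal stop codon at codon position(s) ",
                       paste(which(stops), collapse = ", "))
  list(a = a, b = b, dropped = dropped)
}

# Per-codon site and difference statistics for a prepared pair; unique codons
# and codon pairs are evaluated once so bootstrap resampling stays cheap.
.pairStats <- function(pp, code) {
  uc <- unique(c(pp$a, pp$b))
  siteTab <- vapply(uc, codonSites, numeric(2), code = code)
  perN <- (siteTab["n", pp$a] + siteTab["n", pp$b]) / 2
  perS <- (siteTab["s", pp$a] + siteTab["s", pp$b]) / 2
  key <- paste(pp$a, pp$b)
  uniq <- !duplicated(key)
  diffTab <- mapply(function(x, y) codonDifferences(x, y, code = code),
                    pp$a[uniq], pp$b[uniq])
  colnames(diffTab) <- key[uniq]
  list(perN = unname(perN), perS = unname(perS),
       perNd = unname(diffTab["nd", key]), perSd = unname(diffTab["sd", key]))
}

# Aggregate per-codon statistics over a codon index set.
.ngFromStats <- function(st, ix) {
  nS <- sum(st$perN[ix]); sS <- sum(st$perS[ix])
  nd <- sum(st$perNd[ix]); sdv <- sum(st$perSd[ix])
  pn <- if (nS > 0) nd / nS else NA_real_
  ps <- if (sS > 0) sdv / sS else NA_real_
  dn <- if (!is.na(pn) && pn < 0.75) jukesCantor(pn) else NA_real_
  ds <- if (!is.na(ps) && ps < 0.75) jukesCantor(ps) else NA_real_
  om <- if (!is.na(dn) && !is.na(ds) && ds > 0) dn / ds else NA_real_
  list(nS = nS, sS = sS, nd = nd, sdv = sdv, pn = pn, ps = ps,
       dn = dn, ds = ds, om = om)
}

#' Nei-Gojobori counts and proportions for an aligned codon pair
#'
#' Computes the average nonsynonymous (N) and synonymous (S) site counts over
#' the two sequences, the pathway-averaged difference counts (Nd, Sd), and the
#' proportions pN = Nd/N, pS = Sd/S. Codons containing non-ACGT symbols are
#' dropped pairwise with a message.
#'
#' @param seqA,seqB in-frame aligned nucleotide sequences (character or
#'   \code{Biostrings::DNAString}) of equal length divisible by 3, no internal
#'   stop codons.
#' @inheritParams codonSites
#' @return list with \code{n_sites}, \code{s_sites}, \code{nd}, \code{sd},
#'   \code{pn}, \code{ps}, \code{n_codons}, \code{n_dropped}. \code{ps} is NA
#'   when S is 0.
#' @export
neiGojobori <- function(seqA, seqB, code = Biostrings::GENETIC_CODE) {
  pp <- .preparePair(seqA, seqB, code)
  st <- .pairStats(pp, code)
  full <- .ngFromStats(st, seq_along(pp$a))
  list(n_sites = full$nS, s_sites = full$sS, nd = full$nd, sd = full$sdv,
       pn = if (full$nS > 0) full$nd / full$nS else NA_real_,
       ps = if (full$sS > 0) full$sdv / full$sS else NA_real_,
       n_codons = length(pp$a), n_dropped = pp$dropped)
}

#' Jukes-Cantor distance correction
#'
#' Converts an observed proportion of differences per site into an estimated
#' number of substitutions per site: \code{d = -(3/4) * log(1 - 4p/3)}.
#' Defined for \code{0 <= p < 0.75}; at or beyond 0.75 the correction
#' saturates and an error is raised.
#'
#' @param p observed proportion of differences per site.
#' @return corrected distance \code{d >= p}.
#' @examples
#' jukesCantor(0.10)  # ~0.10733
#' @export
jukesCantor <- function(p) {
  if (any(!is.finite(p)) || any(p < 0)) stop("p must be in [0, 0.75)")
  if (any(p >= 0.75)) {
    stop("proportion of differences >= 0.75: Jukes-Cantor correction saturated")
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise dN/dS with codon bootstrap
#'
#' Full Nei-Gojobori dN/dS for an aligned codon pair: site and difference
#' counts, Jukes-Cantor corrected dN and dS, omega = dN/dS, and a bootstrap
#' standard error obtained by resampling codon columns with replacement.
#' When dS is 0 the ratio is reported as undefined (NA), never infinity.
#' The estimate is symmetric in the two sequences.
#'
#' @inheritParams neiGojobori
#' @param nBootstrap bootstrap replicates (default 1000; 0 disables).
#' @param seed bootstrap seed.
#' @return a \linkS4class{DnDsResult}.
#' @export
dnds <- function(seqA, seqB, code = Biostrings::GENETIC_CODE,
                 nBootstrap = 1000, seed = 1L) {
  pp <- .preparePair(seqA, seqB, code)
  st <- .pairStats(pp, code)
  full <- .ngFromStats(st, seq_along(pp$a))
  seOm <- NA_real_
  if (nBootstrap > 0) {
    oms <- withSeed(seed, {
      vapply(seq_len(nBootstrap), function(i) {
        ix <- sample.int(length(pp$a), replace = TRUE)
        tryCatch(.ngFromStats(st, ix)$om, error = function(e) NA_real_)
      }, numeric(1))
    })
    if (sum(!is.na(oms)) >= 2L) seOm <- sd(oms, na.rm = TRUE)
  }
  new("DnDsResult",
      nSites = full$nS, sSites = full$sS, nd = full$nd, sd = full$sdv,
      pn = full$pn, ps = full$ps,
      dn = if (is.na(full$dn)) NA_real_ else full$dn,
      ds = if (is.na(full$ds)) NA_real_ else full$ds,
      omega = full$om, seOmega = seOm,
      nBootstrap = as.integer(nBootstrap),
      nCodonsUsed = length(pp$a), nCodonsDropped = as.integer(pp$dropped),
      seed = as.integer(seed))
}
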