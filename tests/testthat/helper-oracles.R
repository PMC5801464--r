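# Independent oracles for the Nei-Gojobori machinery. These deliberately use
# a different code path from the package: translation goes through
# Biostrings::translate on assembled DNAStrings, orderings of differing
# positions are enumerated from hard-coded permutation tables, and nothing is
# shared with the implementation beyond the genetic code itself.

.oracleAaCache <- new.env(parent = emptyenv())
oracleTranslate <- function(codon) {
  hit <- .oracleAaCache[[codon]]
  if (!is.null(hit)) return(hit)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                           no.init.codon = TRUE))
  .oracleAaCache[[codon]] <- aa
  aa
}

oracleSenseCodons <- function() {
  all <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           c("A", "C", "G", "T")), 1, paste, collapse = "")
  all[vapply(all, oracleTranslate, character(1)) != "*"]
}

# Site counts: per position, classify the 3 mutants; drop stop mutants and
# renormalize the position to one site.
oracleCodonSites <- function(codon) {
  aa <- oracleTranslate(codon)
  s <- 0
  for (pos in 1:3) {
    syn <- 0; valid <- 0
    for (nt in c("A", "C", "G", "T")) {
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (mut == codon) next
      maa <- oracleTranslate(mut)
      if (maa == "*") next
      valid <- valid + 1
      if (maa == aa) syn <- syn + 1
    }
    if (valid > 0) s <- s + syn / valid
  }
  c(n = 3 - s, s = s)
}

# Hard-coded permutation tables for 1-3 differing positions.
.ORDERINGS <- list(
  matrix(1, 1, 1),
  rbind(c(1, 2), c(2, 1)),
  rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)))

oracleCodonDifferences <- function(a, b) {
  diffPos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  k <- length(diffPos)
  if (k == 0) return(c(nd = 0, sd = 0))
  orders <- .ORDERINGS[[k]]
  ndTot <- 0; sdTot <- 0; kept <- 0
  for (r in seq_len(nrow(orders))) {
    path <- diffPos[orders[r, ]]
    cur <- a
    nd <- 0; sdv <- 0; blocked <- FALSE
    for (pos in path) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      if (oracleTranslate(nxt) == "*") { blocked <- TRUE; break }
      if (oracleTranslate(nxt) == oracleTranslate(cur)) sdv <- sdv + 1
      else nd <- nd + 1
      cur <- nxt
    }
    if (!blocked) { ndTot <- ndTot + nd; sdTot <- sdTot + sdv; kept <- kept + 1 }
  }
  if (kept == 0) stop("all pathways blocked")
  c(nd = ndTot / kept, sd = sdTot / kept)
}

# Brute-force pairwise dN/dS for short codon vectors, built only on the
# oracle primitives above and the closed-form correction.
oracleDnds <- function(codonsA, codonsB) {
  sA <- rowSums(vapply(codonsA, oracleCodonSites, numeric(2)))
  sB <- rowSums(vapply(codonsB, oracleCodonSites, numeric(2)))
  N <- (sA[["n"]] + sB[["n"]]) / 2
  S <- (sA[["s"]] + sB[["s"]]) / 2
  d <- rowSums(mapply(oracleCodonDifferences, codonsA, codonsB))
  pn <- d[["nd"]] / N
  ps <- d[["sd"]] / S
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  jc(pn) / jc(ps)
}

# Non-trivial rooted clades via ape::prop.part, for congruence cross-checks.
oracleCladeSet <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  n <- length(labs)
  sets <- vapply(pp, function(ix) paste(sort(labs[ix]), collapse = "|"),
                 character(1))
  sizes <- lengths(pp)
  unique(sets[sizes >= 2 & sizes < n])
}

oracleRf <- function(a, b) {
  ca <- oracleCladeSet(a); cb <- oracleCladeSet(b)
  if (length(ca) + length(cb) == 0) return(0)
  (length(setdiff(ca, cb)) + length(setdiff(cb, ca))) / (length(ca) + length(cb))
}

splitCodonsChr <- function(x) {
  substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
}
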