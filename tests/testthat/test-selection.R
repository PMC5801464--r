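test_that("codon site counts match enumeration of all single-nucleotide mutants", {
  expect_equal(codonSites("TTT"), c(n = 8 / 3, s = 1 / 3))
  expect_equal(codonSites("ATG"), c(n = 3, s = 0))
  expect_equal(codonSites("GGG"), c(n = 2, s = 1))  # fourfold third position

  for (codon in oracleSenseCodons()) {
    expect_equal(codonSites(codon), oracleCodonSites(codon),
                 label = paste("sites for", codon))
    expect_equal(sum(codonSites(codon)), 3, tolerance = 1e-9)
  }
  expect_error(codonSites("TAA"), "stop codon")
  expect_error(codonSites("TXT"), "ACGT")
})

test_that("codon difference counts average over mutational pathways", {
  expect_equal(codonDifferences("TTT", "TTC"), c(nd = 0, sd = 1))
  expect_equal(codonDifferences("TTT", "GTA"), c(nd = 1.5, sd = 0.5))
  expect_equal(codonDifferences("AAA", "AAA"), c(nd = 0, sd = 0))

  # pathways through stop codons are excluded with renormalization:
  # TGT <-> TGC via position-3 only; a two-difference case whose one pathway
  # passes a stop: TGG -> TAG(stop) excluded, leaving the TGG -> TGA... use
  # oracle agreement as ground truth over every pair with <= 2 differences
  sense <- oracleSenseCodons()
  checked <- 0L
  for (a in sense) {
    for (b in sense) {
      ndiff <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
      if (ndiff == 0L || ndiff > 2L) next
      ok <- tryCatch(codonDifferences(a, b), error = function(e) e)
      ok2 <- tryCatch(oracleCodonDifferences(a, b), error = function(e) e)
      if (inherits(ok2, "error")) {
        expect_s3_class(ok, "error")
      } else {
        expect_equal(ok, ok2, label = paste("differences", a, b))
        # nd + sd = k when no pathway is stop-excluded
        checked <- checked + 1L
      }
    }
  }
  expect_gt(checked, 1000L)
})

test_that("nd + sd equals the number of differing positions absent stop exclusion", {
  set.seed(5)
  sense <- oracleSenseCodons()
  hasStopPath <- function(a, b) {
    inherits(tryCatch(oracleCodonDifferences(a, b), error = function(e) e),
             "error") ||
      {
        # any ordering blocked?
        diffPos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
        blocked <- FALSE
        if (length(diffPos) >= 2) {
          for (p in diffPos) {
            mid <- a
            substr(mid, p, p) <- substr(b, p, p)
            if (oracleTranslate(mid) == "*") blocked <- TRUE
          }
        }
        blocked
      }
  }
  for (i in 1:200) {
    a <- sample(sense, 1); b <- sample(sense, 1)
    if (hasStopPath(a, b)) next
    k <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(sum(codonDifferences(a, b)), k)
  }
})

test_that("pairwise counts are symmetric and sites sum to 3L", {
  p <- simulateCodonPair(nCodons = 120, targetOmega = 0.4, subsPerCodon = 0.4,
                         seed = 21)
  ab <- neiGojobori(p[[1]], p[[2]])
  ba <- neiGojobori(p[[2]], p[[1]])
  expect_equal(ab[c("n_sites", "s_sites", "nd", "sd", "pn", "ps")],
               ba[c("n_sites", "s_sites", "nd", "sd", "pn", "ps")])
  expect_equal(ab$n_sites + ab$s_sites, 3 * ab$n_codons, tolerance = 1e-9)

  same <- neiGojobori(p[[1]], p[[1]])
  expect_equal(same$pn, 0)
  expect_equal(same$ps, 0)
})

test_that("ambiguous codons are dropped pairwise", {
  a <- "ATGAAANNNTTT"
  b <- "ATGAAGCCCTTC"
  expect_message(ng <- neiGojobori(a, b), "dropped")
  expect_equal(ng$n_codons, 3L)
  expect_equal(ng$n_dropped, 1L)
})

test_that("Jukes-Cantor correction follows the closed form and its domain", {
  expect_equal(jukesCantor(0), 0)
  expect_equal(jukesCantor(0.10), -0.75 * log(1 - 0.4 / 3))
  expect_equal(jukesCantor(0.10), 0.10733, tolerance = 1e-4)
  p <- seq(0, 0.7, by = 0.05)
  expect_true(all(jukesCantor(p) >= p))
  expect_error(jukesCantor(0.75), "saturated")
  expect_error(jukesCantor(-0.1), "0, 0.75")
})

test_that("dnds agrees with a brute-force oracle on toy codon pairs", {
  toys <- list(
    list(a = c("TTT", "GGG", "ATG", "AAA", "CCC", "GAT"),
         b = c("TTC", "GGA", "ATA", "AAA", "CCC", "GAT")),
    list(a = c("AAA", "CCC", "GAT", "CTG", "TGT", "GAA"),
         b = c("AAG", "CCA", "GCT", "CTG", "TGT", "GAA")),
    list(a = c("CTG", "TGT", "GAA", "TTT", "AAA", "GGG"),
         b = c("CTA", "TGC", "GGA", "TTT", "AAA", "GGG")))
  for (toy in toys) {
    res <- dnds(paste(toy$a, collapse = ""), paste(toy$b, collapse = ""),
                nBootstrap = 0)
    want <- oracleDnds(toy$a, toy$b)
    expect_true(is.finite(want))
    expect_equal(omega(res), want, tolerance = 1e-12)
  }
})

test_that("dnds handles identical and dS-free pairs without infinities", {
  res <- dnds("ATGAAATTTGGG", "ATGAAATTTGGG", nBootstrap = 0)
  expect_equal(res@dn, 0)
  expect_equal(res@ds, 0)
  expect_true(is.na(omega(res)))
  expect_true(is.na(isPurifying(res)))

  # only nonsynonymous differences: dS = 0, omega undefined (not Inf)
  res2 <- dnds("ATGAAA", "ATGCAA", nBootstrap = 0)
  expect_true(is.na(omega(res2)))
})

test_that("bootstrap is seed-reproducible and near-neutral pairs bracket 1", {
  p <- simulateCodonPair(nCodons = 2000, targetOmega = 1, subsPerCodon = 0.25,
                         seed = 13)
  r1 <- dnds(p[[1]], p[[2]], nBootstrap = 200, seed = 7)
  r2 <- dnds(p[[1]], p[[2]], nBootstrap = 200, seed = 7)
  expect_identical(r1@seOmega, r2@seOmega)
  expect_lt(abs(omega(r1) - 1), 3 * r1@seOmega)
  expect_false(isPurifying(r1) && omega(r1) > 1)
})

test_that("median estimated omega is monotone in the generating omega", {
  med <- vapply(c(0.1, 0.5, 1.0), function(om) {
    est <- vapply(1:12, function(sd) {
      p <- simulateCodonPair(nCodons = 400, targetOmega = om,
                             subsPerCodon = 0.4, seed = 1000 * om + sd)
      omega(dnds(p[[1]], p[[2]], nBootstrap = 0))
    }, numeric(1))
    median(est)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})
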