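makeTax <- function(genomes, genus, suborder = "soA") {
  data.frame(genome_id = genomes, genus = genus, suborder = suborder)
}

# census with prescribed per-genome counts for a single role
censusFromCounts <- function(counts, genus, suborder = rep("soA", length(genus)),
                             role = "pk") {
  genomes <- sprintf("g%02d", seq_along(counts))
  m <- matrix(as.integer(counts), nrow = 1,
              dimnames = list(role, genomes))
  FunctionalCensus(m, data.frame(genome_id = genomes,
                                 genus = genus, suborder = suborder))
}

test_that("buildCensus counts features per role and flags bad input", {
  ann <- data.frame(genome_id = c("g1", "g1", "g2"),
                    feature_id = c("f1", "f2", "f9"),
                    role = c("pk", "pk", "pfk"))
  tax <- makeTax(c("g1", "g2"), c("gen1", "gen2"))
  cen <- buildCensus(ann, tax)
  m <- censusCounts(cen)
  expect_equal(m["pk", "g1"], 2L)
  expect_equal(m["pk", "g2"], 0L)     # absent role counts as zero
  expect_equal(m["pfk", "g2"], 1L)

  expect_warning(buildCensus(rbind(ann, ann[1, ]), tax), "deduplicated")
  expect_error(buildCensus(ann, makeTax("g1", "gen1")), "without taxonomy.*g2")
  expect_error(buildCensus(ann[0, ], tax), "empty annotation")
})

test_that("census TSV round-trips through write/read unchanged", {
  cen <- simulateCensus(2, 3, 3, roles = c("pk", "pfk", "me"), seed = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeCensus(cen, f)
  back <- readCensus(f)
  expect_identical(censusCounts(back)[rownames(cen), colnames(cen)],
                   censusCounts(cen))
  expect_equal(censusTaxonomy(back)[order(censusTaxonomy(back)$genome_id), ],
               censusTaxonomy(cen)[order(censusTaxonomy(cen)$genome_id), ],
               ignore_attr = TRUE)
})

test_that("group means are arithmetic means at both taxonomy levels", {
  cen <- censusFromCounts(c(1, 3, 5), genus = c("genA", "genA", "genB"),
                          suborder = c("soA", "soA", "soA"))
  gm <- groupMeans(cen, "genus")
  expect_equal(gm["genA", "pk"], 2.0)
  expect_equal(gm["genB", "pk"], 5.0)  # single-genome genus: mean = count

  # suborder mean is the genome-count-weighted combination of genus means
  sm <- groupMeans(cen, "suborder")
  expect_equal(sm["soA", "pk"], (2 * 2.0 + 1 * 5.0) / 3)
})

test_that("the mean-plus-SD rule flags exactly the exceeding groups", {
  cen <- censusFromCounts(c(1, 1, 1, 2, 1),
                          genus = paste0("gen", 1:5))
  calls <- callExpansions(cen, level = "genus")
  expect_equal(unique(calls$phylum_mean), 1.2)
  expect_equal(unique(calls$phylum_sd), sd(c(1, 1, 1, 2, 1)), tolerance = 1e-12)
  expect_equal(unique(calls$threshold), 1.2 + sqrt(0.2), tolerance = 1e-12)
  expect_identical(calls$group[calls$flagged], "gen4")

  # boundary: all groups identical, SD 0, inclusive comparison flags everyone
  cen0 <- censusFromCounts(c(2, 2, 2), genus = paste0("gen", 1:3))
  calls0 <- callExpansions(cen0)
  expect_true(all(calls0$flagged))

  # single group: SD undefined
  cen1 <- censusFromCounts(c(1, 2), genus = c("genA", "genA"))
  expect_error(callExpansions(cen1), "two groups")
})

test_that("expansion calls are invariant to genome and role order", {
  cen <- simulateCensus(2, 4, 3, roles = c("pk", "pfk", "me", "ppdk"),
                        baseCopyRate = 1.5, seed = 31)
  m <- censusCounts(cen)
  tax <- censusTaxonomy(cen)
  perm <- FunctionalCensus(m[rev(rownames(m)), sample(colnames(m))], tax)
  a <- callExpansions(cen)
  b <- callExpansions(perm)
  key <- function(d) d[order(d$group, d$role), c("group", "role", "flagged")]
  expect_equal(key(a), key(b), ignore_attr = TRUE)
})

test_that("raising a group's mean never unflags it at a fixed threshold", {
  cen <- simulateCensus(1, 6, 4, roles = "pk", baseCopyRate = 1,
                        plantedExpansions = data.frame(
                          group = "so1_genus3", role = "pk", added_mean = 2),
                        seed = 8)
  calls <- callExpansions(cen)
  flagged <- calls[calls$flagged, ]
  expect_gt(nrow(flagged), 0)
  # add one copy to every genome of a flagged group; against the original
  # threshold the group mean can only move further above it
  m <- censusCounts(cen)
  tax <- censusTaxonomy(cen)
  g <- flagged$group[1]
  bump <- m
  bump["pk", tax$genome_id[tax$genus == g]] <-
    bump["pk", tax$genome_id[tax$genus == g]] + 1L
  gm2 <- groupMeans(FunctionalCensus(bump, tax))[g, "pk"]
  expect_gte(gm2, flagged$threshold[1])
})

test_that("pathway matrix uses the genera-times-enzymes denominator and NE", {
  # 3 genera in soA flagged 7 times on a 10-enzyme pathway -> 23.3%
  # 2 genera in soB flagged 5 times on the same pathway -> 25.0%
  pw <- list(GLY = list(roles = sprintf("gly%d", 1:10), min_size = 10))
  tax <- data.frame(genus = c("gA", "gB", "gC", "gD", "gE"),
                    suborder = c("soA", "soA", "soA", "soB", "soB"))
  calls <- data.frame(
    group = c(rep("gA", 4), rep("gB", 3), rep("gD", 3), rep("gE", 2)),
    role = c(sprintf("gly%d", 1:4), sprintf("gly%d", 1:3),
             sprintf("gly%d", 1:3), sprintf("gly%d", 1:2)),
    flagged = TRUE)
  catalog <- sprintf("gly%d", 1:10)
  mat <- pathwayMatrix(calls, pw, tax, roleCatalog = catalog)
  pct <- expansionPercent(mat)
  expect_equal(pct["soA", "GLY"], 23.3)
  expect_equal(pct["soB", "GLY"], 25.0)

  # zero flags in a cell -> NE marker
  calls0 <- within(calls, flagged <- FALSE)
  mat0 <- pathwayMatrix(calls0, pw, tax, roleCatalog = catalog)
  expect_true(all(formatExpansionMatrix(mat0) == "NE"))
  expect_true(all(is.na(expansionPercent(mat0))))

  expect_error(pathwayMatrix(calls, list(X = "nope"), tax),
               "absent from the census")
  # percentages always within [0, 100]
  expect_true(all(mat@percent >= 0 & mat@percent <= 100))
})

test_that("copy-number summaries report histogram and single-copy percent", {
  counts <- c(rep(1L, 302), rep(2L, 25))
  cen <- censusFromCounts(counts, genus = rep(c("gA", "gB"), length.out = 327))
  sm <- copyNumberSummary(cen, "pk")
  expect_equal(sm$n, 327)
  expect_equal(sm$n_single, 302)
  expect_equal(sm$single_copy_percent, 92)

  counts2 <- c(rep(2L, 281), rep(1L, 3), 3L, 4L)
  cen2 <- censusFromCounts(counts2, genus = rep("gS", 286))
  sm2 <- copyNumberSummary(cen2, "pk")
  expect_equal(sm2$histogram, c("1" = 3L, "2" = 281L, "3" = 1L, "4" = 1L))

  cen3 <- censusFromCounts(rep(1L, 5), genus = paste0("g", 1:5))
  expect_equal(copyNumberSummary(cen3, "pk")$single_copy_percent, 100)

  expect_error(copyNumberSummary(cen, "pk", genomes = character(0)),
               "empty genome partition")
  expect_error(copyNumberSummary(cen, "nope"), "unknown role")
})
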