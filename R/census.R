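#' Build a functional census from annotation and taxonomy tables
#'
#' Turns a RAST-style feature annotation table into a
#' \linkS4class{FunctionalCensus}: the copy number of a role in a genome is the
#' number of distinct features in that genome annotated with the role. Genomes
#' lacking a role get count 0 — absence is information in a copy-number census.
#'
#' @param annotations data.frame (or path to a TSV) with columns
#'   \code{genome_id}, \code{feature_id}, \code{role}.
#' @param taxonomy data.frame (or path to a TSV) with columns
#'   \code{genome_id}, \code{genus}, \code{suborder}; must cover every genome
#'   appearing in \code{annotations} (a genome without taxonomy is a hard
#'   error listing the offenders).
#' @param pathways optional named list of pathway -> role vectors, recorded in
#'   the census role catalog.
#' @return a \linkS4class{FunctionalCensus}.
#' @details Duplicate (genome, feature, role) rows are collapsed with a
#'   warning: a feature contributes at most one copy per role.
#' @examples
#' ann <- data.frame(genome_id = c("g1", "g1", "g2"),
#'                   feature_id = c("f1", "f2", "f3"),
#'                   role = c("pyruvate kinase", "pyruvate kinase",
#'                            "phosphofructokinase"))
#' tax <- data.frame(genome_id = c("g1", "g2"),
#'                   genus = c("Streptomyces", "Frankia"),
#'                   suborder = c("Streptomycineae", "Frankineae"))
#' censusCounts(buildCensus(ann, tax))
#' @export
buildCensus <- function(annotations, taxonomy, pathways = NULL) {
  if (is.character(annotations) && length(annotations) == 1L) {
    annotations <- read.delim(annotations, stringsAsFactors = FALSE)
  }
  if (is.character(taxonomy) && length(taxonomy) == 1L) {
    taxonomy <- read.delim(taxonomy, stringsAsFactors = FALSE)
  }
  annotations <- as.data.frame(annotations)
  need <- c("genome_id", "feature_id", "role")
  if (!all(need %in% colnames(annotations))) {
    stop("annotations must have columns genome_id, feature_id, role")
  }
  if (nrow(annotations) == 0L) {
    stop("empty annotation stream: no features to census")
  }
  orphans <- setdiff(unique(annotations$genome_id), taxonomy$genome_id)
  if (length(orphans)) {
    stop("genomes without taxonomy entries: ", paste(orphans, collapse = ", "))
  }
  key <- paste(annotations$genome_id, annotations$feature_id, annotations$role,
               sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate (genome, feature) rows deduplicated")
    annotations <- annotations[!duplicated(key), , drop = FALSE]
  }
  counts <- table(factor(annotations$role),
                  factor(annotations$genome_id))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  FunctionalCensus(counts, taxonomy, pathways = pathways)
}

#' Read / write a census as a long-format TSV
#'
#' The interchange format is one row per (genome, role) with columns
#' \code{genome_id}, \code{genus}, \code{suborder}, \code{role}, \code{count}.
#' \code{readCensus(writeCensus(x, f))} reproduces \code{x}.
#'
#' @param census a \linkS4class{FunctionalCensus}.
#' @param path file path.
#' @return \code{readCensus} a FunctionalCensus; \code{writeCensus} the path,
#'   invisibly.
#' @export
writeCensus <- function(census, path) {
  stopifnot(is(census, "FunctionalCensus"))
  m <- censusCounts(census)
  tax <- censusTaxonomy(census)
  long <- data.frame(
    genome_id = rep(colnames(m), each = nrow(m)),
    genus = rep(tax$genus, each = nrow(m)),
    suborder = rep(tax$suborder, each = nrow(m)),
    role = rep(rownames(m), times = ncol(m)),
    count = as.integer(m))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCensus
#' @export
readCensus <- function(path) {
  long <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "genus", "suborder", "role", "count")
  if (!all(need %in% colnames(long))) {
    stop("census TSV must have columns ", paste(need, collapse = ", "))
  }
  roles <- unique(long$role)
  genomes <- unique(long$genome_id)
  m <- matrix(0L, length(roles), length(genomes),
              dimnames = list(roles, genomes))
  m[cbind(match(long$role, roles), match(long$genome_id, genomes))] <-
    as.integer(long$count)
  tax <- unique(long[, c("genome_id", "genus", "suborder")])
  FunctionalCensus(m, tax)
}

.groupLabels <- function(census, level = c("genus", "suborder")) {
  level <- match.arg(level)
  SummarizedExperiment::colData(census)[[level]]
}

#' Mean copy number per group and role
#'
#' Arithmetic mean of per-genome copy counts over the genomes of each group
#' (genus or suborder).
#'
#' @param census a \linkS4class{FunctionalCensus}.
#' @param level grouping level, \code{"genus"} (default) or \code{"suborder"}.
#' @return numeric matrix, groups x roles.
#' @export
groupMeans <- function(census, level = c("genus", "suborder")) {
  stopifnot(is(census, "FunctionalCensus"))
  if (ncol(census) == 0L) stop("empty census")
  g <- factor(.groupLabels(census, level))
  m <- censusCounts(census)
  sums <- t(rowsum(t(m), g))              # roles x groups
  t(sweep(sums, 2L, as.vector(table(g)), "/"))  # groups x roles
}

#' Call gene expansion events with the mean-plus-SD rule
#'
#' For each functional role, the phylum-wide mean and standard deviation of
#' the group means (over all groups at \code{level}) define a threshold
#' \code{phylum_mean + sd_multiplier * phylum_sd}; a group whose mean copy
#' number is equal to or higher than the threshold is flagged as a gene
#' expansion event for that role. The comparison is inclusive. When the SD is
#' zero (all groups identical) every group meets mean + 0 and is flagged; this
#' degenerate boundary case is deliberate.
#'
#' @param census a \linkS4class{FunctionalCensus} with at least two groups at
#'   \code{level} (the SD is otherwise undefined).
#' @param level grouping level for the rule, \code{"genus"} (default) or
#'   \code{"suborder"}.
#' @param sdMultiplier multiplier on the phylum SD (default 1).
#' @param sdType \code{"sample"} (n-1 denominator, default) or
#'   \code{"population"}.
#' @return data.frame with one row per (group, role): \code{group},
#'   \code{role}, \code{group_mean}, \code{phylum_mean}, \code{phylum_sd},
#'   \code{threshold}, \code{flagged}.
#' @examples
#' # genus means 1,1,1,2,1 for one role: threshold 1.2 + 0.447 = 1.647,
#' # only the genus with mean 2 is flagged
#' @export
callExpansions <- function(census, level = c("genus", "suborder"),
                           sdMultiplier = 1,
                           sdType = c("sample", "population")) {
  stopifnot(is(census, "FunctionalCensus"))
  sdType <- match.arg(sdType)
  gm <- groupMeans(census, level)
  if (nrow(gm) < 2L) {
    stop("expansion calling needs at least two groups (SD undefined for one)")
  }
  mu <- colMeans(gm)
  sdev <- apply(gm, 2L, sd)
  if (sdType == "population") {
    n <- nrow(gm)
    sdev <- sdev * sqrt((n - 1) / n)
  }
  thr <- mu + sdMultiplier * sdev
  out <- data.frame(
    group = rep(rownames(gm), times = ncol(gm)),
    role = rep(colnames(gm), each = nrow(gm)),
    group_mean = as.vector(gm),
    phylum_mean = rep(mu, each = nrow(gm)),
    phylum_sd = rep(sdev, each = nrow(gm)),
    threshold = rep(thr, each = nrow(gm)),
    stringsAsFactors = FALSE)
  out$flagged <- out$group_mean >= out$threshold
  out
}

#' Pathway-level expansion percentage matrix
#'
#' Aggregates genus-level expansion calls into a suborder x pathway matrix:
#' each cell is 100 x (flagged (genus, role) pairs with the genus in the
#' suborder and the role in the pathway) / (number of genera in the suborder x
#' number of enzymes in the minimum pathway). Cells with zero flagged events
#' are marked NE ("no expansion") when formatted.
#'
#' @param calls data.frame from \code{\link{callExpansions}} at genus level.
#' @param pathways named list; each element either a character vector of roles
#'   or a list with \code{roles} and optional \code{min_size} (defaults to
#'   \code{length(roles)}).
#' @param taxonomy data.frame with columns \code{genus}, \code{suborder}
#'   (e.g. from \code{\link{censusTaxonomy}}).
#' @param roleCatalog roles known to the census; pathway members must all be
#'   in it. Defaults to the roles appearing in \code{calls}, which is the full
#'   catalog when \code{calls} comes straight from
#'   \code{\link{callExpansions}}.
#' @return a \linkS4class{PathwayExpansionMatrix}.
#' @export
pathwayMatrix <- function(calls, pathways, taxonomy,
                          roleCatalog = unique(calls$role)) {
  stopifnot(is.data.frame(calls), all(c("group", "role", "flagged") %in%
                                        colnames(calls)))
  pw <- lapply(pathways, function(p) {
    if (is.list(p)) {
      list(roles = p$roles,
           min_size = if (is.null(p$min_size)) length(p$roles) else p$min_size)
    } else {
      list(roles = p, min_size = length(p))
    }
  })
  unknown <- setdiff(unique(unlist(lapply(pw, `[[`, "roles"))), roleCatalog)
  if (length(unknown)) {
    stop("pathways reference roles absent from the census: ",
         paste(unknown, collapse = ", "))
  }
  gentab <- unique(as.data.frame(taxonomy)[, c("genus", "suborder")])
  missing <- setdiff(unique(calls$group), gentab$genus)
  if (length(missing)) {
    stop("calls reference genera without suborder mapping: ",
         paste(missing, collapse = ", "))
  }
  suborders <- sort(unique(gentab$suborder))
  nGenera <- vapply(suborders,
                    function(s) sum(gentab$suborder == s), integer(1))
  flags <- matrix(0L, length(suborders), length(pw),
                  dimnames = list(suborders, names(pw)))
  denom <- flags
  callSub <- gentab$suborder[match(calls$group, gentab$genus)]
  for (j in seq_along(pw)) {
    inPath <- calls$role %in% pw[[j]]$roles
    for (i in seq_along(suborders)) {
      flags[i, j] <- sum(calls$flagged & inPath & callSub == suborders[i])
      denom[i, j] <- nGenera[i] * pw[[j]]$min_size
    }
  }
  new("PathwayExpansionMatrix",
      percent = round(100 * flags / denom, 1L),
      flags = flags, denominator = denom)
}

#' Copy-number histogram and single-copy percentage
#'
#' Summarises the copy-number distribution of one role over a genome subset:
#' the histogram of genomes per copy number and the percentage of genomes with
#' exactly one copy (rounded to the nearest integer for reporting, as in
#' "92\% (302 of 327) of genomes encoded a single copy").
#'
#' @param census a \linkS4class{FunctionalCensus}.
#' @param role a role name present in the census.
#' @param genomes character vector of genome ids (default: all genomes).
#' @return list with \code{histogram} (named integer vector, copy number ->
#'   genome count), \code{n} (partition size), \code{n_single} and
#'   \code{single_copy_percent}.
#' @export
copyNumberSummary <- function(census, role, genomes = colnames(census)) {
  stopifnot(is(census, "FunctionalCensus"))
  if (!role %in% rownames(census)) stop("unknown role: ", role)
  if (length(genomes) == 0L) stop("empty genome partition")
  bad <- setdiff(genomes, colnames(census))
  if (length(bad)) stop("genomes not in census: ", paste(bad, collapse = ", "))
  counts <- censusCounts(census)[role, genomes]
  hist <- table(counts)
  list(histogram = setNames(as.integer(hist), names(hist)),
       n = length(genomes),
       n_single = sum(counts == 1L),
       single_copy_percent = round(100 * sum(counts == 1L) / length(genomes)))
}
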