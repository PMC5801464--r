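#' Read and write Newick trees with validation
#'
#' Thin wrappers over \code{ape} that add the checks this pipeline relies on:
#' parse failures raise an error rather than returning NULL, and duplicate
#' tip labels are rejected (downstream species mapping requires unique tips).
#' Topology, tip labels and branch lengths round-trip losslessly.
#'
#' @param path file path (or, for \code{readNewick}, a literal Newick string
#'   via \code{text}).
#' @param text optional Newick string instead of a file.
#' @param tree an \code{ape} \code{phylo} object.
#' @return \code{readNewick}: a \code{phylo}; \code{writeNewick}: the path,
#'   invisibly.
#' @export
readNewick <- function(path = NULL, text = NULL) {
  tr <- tryCatch(
    if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e),
                             call. = FALSE),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w),
                               call. = FALSE))
  if (is.null(tr)) stop("Newick parse error: unreadable tree")
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  tr
}

#' @rdname readNewick
#' @export
writeNewick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Filter alignment-coverage records
#'
#' Retains records whose aligned-column coverage of the query is at least the
#' threshold (inclusive: "at least 25\%" keeps a record at exactly 0.25).
#' Idempotent.
#'
#' @param records data.frame with columns \code{query_id}, \code{subject_id},
#'   \code{aligned_cols}, \code{query_len}.
#' @param threshold minimum coverage fraction, default 0.25.
#' @return the retained subset with an added \code{coverage} column.
#' @export
coverageFilter <- function(records, threshold = 0.25) {
  records <- as.data.frame(records)
  need <- c("query_id", "subject_id", "aligned_cols", "query_len")
  if (!all(need %in% colnames(records))) {
    stop("coverage records need columns ", paste(need, collapse = ", "))
  }
  if (any(records$query_len <= 0)) stop("query_len must be positive")
  records$coverage <- records$aligned_cols / records$query_len
  if (any(records$coverage < 0 | records$coverage > 1)) {
    stop("coverage outside [0, 1]; check aligned_cols against query_len")
  }
  records[records$coverage >= threshold, , drop = FALSE]
}

# Non-trivial rooted clades of a tree as a set of sorted tip-label strings.
.cladeSet <- function(tree) {
  n <- length(tree$tip.label)
  internal <- setdiff(unique(tree$edge[, 1]), n + 1L)  # exclude the root
  out <- character(0)
  for (nd in internal) {
    tips <- tree$tip.label[.tipDescendants(tree, nd)]
    if (length(tips) >= 2L && length(tips) < n) {
      out <- c(out, paste(sort(tips), collapse = "\r"))
    }
  }
  unique(out)
}

# Tip indices descending from a node.
.tipDescendants <- function(tree, node) {
  n <- length(tree$tip.label)
  todo <- node
  tips <- integer(0)
  while (length(todo)) {
    nd <- todo[1]; todo <- todo[-1]
    if (nd <= n) tips <- c(tips, nd)
    else todo <- c(todo, tree$edge[tree$edge[, 1] == nd, 2])
  }
  tips
}

#' Normalized Robinson-Foulds congruence distance between rooted trees
#'
#' Quantifies gene-tree/species-tree congruence as the normalized
#' Robinson-Foulds distance over non-trivial rooted clades: 0 for identical
#' topologies, 1 when no clade is shared. When the gene tree carries multiple
#' copies per species, one copy per species is kept (chosen under the fixed
#' seed) so that the comparison is a bijection; the number of collapsed tips
#' is reported as an attribute.
#'
#' @param treeA,treeB \code{phylo} trees. Tip labels must map to the same
#'   species universe; use \code{tipMapB} to map gene-tree tips to species.
#' @param tipMapB optional named character vector mapping \code{treeB} tip
#'   labels to species names.
#' @param seed seed for the choice of retained copy in multi-copy species.
#' @return numeric in [0, 1], symmetric, with attribute \code{collapsed} (the
#'   number of extra copies dropped).
#' @export
congruenceScore <- function(treeA, treeB, tipMapB = NULL, seed = 1L) {
  stopifnot(inherits(treeA, "phylo"), inherits(treeB, "phylo"))
  collapsed <- 0L
  if (!is.null(tipMapB)) {
    unmapped <- setdiff(treeB$tip.label, names(tipMapB))
    if (length(unmapped)) {
      stop("unmapped gene-tree tips: ", paste(unmapped, collapse = ", "))
    }
    sp <- tipMapB[treeB$tip.label]
    keep <- withSeed(seed, {
      unlist(lapply(split(seq_along(sp), sp), function(ix) {
        if (length(ix) > 1L) sample(ix, 1L) else ix
      }))
    })
    collapsed <- length(sp) - length(keep)
    if (collapsed > 0L) {
      treeB <- ape::drop.tip(treeB, setdiff(seq_along(sp), keep))
      sp <- tipMapB[treeB$tip.label]
    }
    treeB$tip.label <- unname(sp)
  }
  if (length(intersect(treeA$tip.label, treeB$tip.label)) == 0L) {
    stop("disjoint tip sets; trees are not comparable")
  }
  if (!setequal(treeA$tip.label, treeB$tip.label)) {
    stop("tip universes differ after mapping: ",
         paste(union(setdiff(treeA$tip.label, treeB$tip.label),
                     setdiff(treeB$tip.label, treeA$tip.label)),
               collapse = ", "))
  }
  a <- .cladeSet(treeA)
  b <- .cladeSet(treeB)
  score <- if (length(a) + length(b) == 0L) {
    0
  } else {
    length(union(a, b) [!(union(a, b) %in% intersect(a, b))]) /
      (length(a) + length(b))
  }
  structure(score, collapsed = collapsed)
}

#' Classify extra gene copies as duplication or horizontal transfer
#'
#' Encodes, as an explicit rule, the visual topology reading used to assign a
#' mechanism to gene family expansions: focal-lineage gene copies are
#' partitioned into maximal clades whose tip species all belong to the focal
#' lineage. If such a clade contains more than one copy per species and splits
#' into two or more child clades that each recapitulate the focal-lineage
#' species membership (the bifurcating duplicated pattern), its copies are
#' labelled \code{duplication}. A focal copy whose smallest enclosing clade of
#' two or more tips contains only foreign-lineage species is labelled
#' \code{hgt}. Everything else among expanded species is \code{ambiguous}.
#' Species with a single copy in a congruent position generate no call: there
#' is no expansion to classify.
#'
#' @param speciesTree rooted \code{phylo} species tree; the focal lineage must
#'   be monophyletic in it.
#' @param geneTree rooted \code{phylo} gene tree.
#' @param tipMap named character vector mapping gene-tree tip labels to
#'   species; every tip must be mapped.
#' @param focalLineage character vector of focal species.
#' @return data.frame with columns \code{copy_id}, \code{species},
#'   \code{mechanism}, \code{evidence}.
#' @export
classifyMechanism <- function(speciesTree, geneTree, tipMap, focalLineage) {
  stopifnot(inherits(speciesTree, "phylo"), inherits(geneTree, "phylo"))
  unmapped <- setdiff(geneTree$tip.label, names(tipMap))
  if (length(unmapped)) {
    stop("unmapped gene-tree tips: ", paste(unmapped, collapse = ", "))
  }
  if (!all(focalLineage %in% speciesTree$tip.label)) {
    stop("focal lineage species absent from species tree")
  }
  if (length(focalLineage) > 1L && !ape::is.monophyletic(speciesTree, focalLineage)) {
    stop("focal lineage is not monophyletic in the species tree")
  }
  n <- length(geneTree$tip.label)
  tipSpecies <- unname(tipMap[geneTree$tip.label])
  focalTip <- tipSpecies %in% focalLineage

  copiesPerSpecies <- table(tipSpecies)
  expandedSpecies <- names(copiesPerSpecies)[copiesPerSpecies > 1L]
  focalExpanded <- intersect(expandedSpecies, focalLineage)
  if (length(focalExpanded) == 0L) {
    return(data.frame(copy_id = character(), species = character(),
                      mechanism = character(), evidence = character()))
  }

  # descendants per node
  nodes <- (n + 1L):(n + geneTree$Nnode)
  desc <- lapply(nodes, function(nd) .tipDescendants(geneTree, nd))
  names(desc) <- as.character(nodes)

  # maximal all-focal clades: focal-only nodes whose parent is not focal-only
  focalOnly <- vapply(desc, function(d) all(focalTip[d]), logical(1))
  parent <- function(nd) geneTree$edge[geneTree$edge[, 2] == nd, 1]
  mechanism <- setNames(rep(NA_character_, n), geneTree$tip.label)
  evidence <- setNames(rep("", n), geneTree$tip.label)

  maximalFocal <- list()
  for (i in seq_along(nodes)) {
    if (!focalOnly[i]) next
    p <- parent(nodes[i])
    pIsFocal <- length(p) == 1L &&
      !is.na(match(as.character(p), names(desc))) &&
      focalOnly[[as.character(p)]]
    if (!pIsFocal) maximalFocal <- c(maximalFocal, list(desc[[i]]))
  }
  # singleton focal tips whose parent clade is not all-focal
  for (tip in which(focalTip)) {
    inClade <- any(vapply(maximalFocal, function(d) tip %in% d, logical(1)))
    if (!inClade) maximalFocal <- c(maximalFocal, list(tip))
  }

  focalSpeciesPresent <- sort(unique(tipSpecies[focalTip]))

  # duplication: within a maximal focal clade, children that each carry one
  # copy per focal species present
  for (d in maximalFocal) {
    if (length(d) < 2L) next
    spHere <- tipSpecies[d]
    if (max(table(spHere)) < 2L) next   # no duplicated species inside
    nd <- nodes[vapply(desc, function(x) setequal(x, d), logical(1))][1]
    kids <- geneTree$edge[geneTree$edge[, 1] == nd, 2]
    kidTips <- lapply(kids, function(k) {
      if (k <= n) k else .tipDescendants(geneTree, k)
    })
    congruent <- vapply(kidTips, function(kt) {
      sp <- tipSpecies[kt]
      setequal(sp, focalSpeciesPresent) && !anyDuplicated(sp)
    }, logical(1))
    if (sum(congruent) >= 2L) {
      for (kt in kidTips[congruent]) {
        mechanism[kt] <- "duplication"
        evidence[kt] <- "member of species-congruent paralog clade"
      }
    }
  }

  # hgt: smallest enclosing clade (>= 2 tips) of the copy holds only foreign
  # species apart from the copy itself
  for (tip in which(focalTip)) {
    if (!is.na(mechanism[tip])) next
    if (!tipSpecies[tip] %in% focalExpanded) next
    nd <- parent(tip)
    enclosing <- .tipDescendants(geneTree, nd)
    others <- setdiff(enclosing, tip)
    if (length(others) >= 1L && all(!focalTip[others])) {
      mechanism[tip] <- "hgt"
      evidence[tip] <- paste0("nested within foreign clade {",
                              paste(sort(unique(tipSpecies[others])),
                                    collapse = ","), "}")
    }
  }

  # remaining copies of expanded focal species: ambiguous
  for (tip in which(focalTip)) {
    if (is.na(mechanism[tip]) && tipSpecies[tip] %in% focalExpanded) {
      mechanism[tip] <- "ambiguous"
      evidence[tip] <- "placement matches neither the duplication nor the transfer pattern"
    }
  }

  keep <- !is.na(mechanism)
  data.frame(copy_id = geneTree$tip.label[keep],
             species = tipSpecies[keep],
             mechanism = unname(mechanism[keep]),
             evidence = unname(evidence[keep]),
             row.names = NULL)
}
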