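# Chi-square decision tree over categorical amino-acid sites.
#
# Splits are binary partitions of the residues observed at one site. The
# candidate partitions at a site are generated by ordering its residues by
# their proportion of the node's majority class and scanning the contiguous
# cut points (the standard categorical-split heuristic; exhaustive
# 2^(k-1) enumeration is infeasible at k up to 20). The (site, partition)
# maximizing the Pearson chi-square of the branch x Kingdom table is taken
# when its p-value passes the significance level and both branches are big
# enough. Records with a gap at the split site are not routed; at prediction
# a gap (or a residue unseen in either branch set) yields Unclassified.

#' Decision-tree configuration
#'
#' @param alpha Chi-square significance level required to split (default 0.20).
#' @param maxDepth Maximum number of split levels (default 4).
#' @param minSplit Minimum node size to attempt a split (default 10).
#' @param minLeaf Minimum records per branch (default 4).
#' @param purityStop Stop splitting once the majority class reaches this
#'   fraction (default 0.95, "almost completely" one Kingdom).
#' @return Named list of settings.
#' @export
treeConfig <- function(alpha = 0.20, maxDepth = 4, minSplit = 10,
                       minLeaf = 4, purityStop = 0.95) {
  stopifnot(alpha > 0, alpha < 1, minLeaf <= minSplit, maxDepth >= 1)
  list(alpha = alpha, maxDepth = maxDepth, minSplit = minSplit,
       minLeaf = minLeaf, purityStop = purityStop)
}

#' Pearson chi-square of a contingency table
#'
#' \eqn{\sum (O - E)^2 / E} without continuity correction; all-zero rows and
#' columns are dropped before computing expectations.
#'
#' @param tab Integer matrix of counts.
#' @return List with \code{statistic}, \code{df}, \code{p}.
#' @export
chisqStatistic <- function(tab) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    return(list(statistic = 0, df = 0L, p = 1))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Best admissible chi-square split of a set of records
#'
#' @param residues Character matrix of node records (columns \code{s<site>}).
#' @param labels Kingdom label per record.
#' @param sites Candidate site indices.
#' @param config A [treeConfig()].
#' @return \code{NULL} when no admissible split exists, else a list with
#'   \code{site}, \code{left}/\code{right} residue sets, \code{statistic},
#'   \code{p}.
#' @export
bestSplit <- function(residues, labels, sites, config = treeConfig()) {
  if (nrow(residues) < config$minSplit) return(NULL)
  counts <- table(labels)
  majority <- names(counts)[which.max(counts)]
  best <- NULL
  for (s in sites) {
    col <- residues[, paste0("s", s)]
    keep <- col != .GAP
    if (sum(keep) < 2 * config$minLeaf) next
    res <- col[keep]
    lab <- labels[keep]
    levs <- sort(unique(res))
    if (length(levs) < 2) next
    propMaj <- vapply(levs, function(r) mean(lab[res == r] == majority),
                      numeric(1))
    ord <- levs[order(-propMaj, levs)]
    for (m in seq_len(length(ord) - 1L)) {
      left <- ord[seq_len(m)]
      inLeft <- res %in% left
      if (sum(inLeft) < config$minLeaf ||
          sum(!inLeft) < config$minLeaf) next
      tab <- rbind(table(factor(lab[inLeft], levels = names(counts))),
                   table(factor(lab[!inLeft], levels = names(counts))))
      cs <- chisqStatistic(tab)
      if (cs$p > config$alpha) next
      if (is.null(best) || cs$statistic > best$statistic + 1e-12)
        best <- list(site = s, left = left,
                     right = setdiff(ord, left),
                     statistic = cs$statistic, p = cs$p)
    }
  }
  best
}

#' Fit a chi-square decision tree on an enumerated alignment
#'
#' Recursive binary splitting on amino-acid sites, stopping on depth, node
#' size, near-purity, or when no split passes the chi-square significance
#' level. Deterministic: ties go to the lowest site index.
#'
#' @param alignment An \code{EnumeratedAlignment} with Kingdom labels (or
#'   \code{labels} supplied).
#' @param labels Optional label vector overriding the alignment's.
#' @param config A [treeConfig()].
#' @return A \code{BhlhDecisionTree}.
#' @aliases BhlhDecisionTree-class BhlhDecisionTree
#' @export
fitDecisionTree <- function(alignment, labels = NULL, config = treeConfig()) {
  if (is.null(labels)) labels <- kingdoms(alignment)
  keep <- !is.na(labels)
  if (!any(keep)) stop("no labelled records to fit on")
  res <- residueMatrix(alignment)[keep, , drop = FALSE]
  labels <- labels[keep]
  groups <- sort(unique(labels))
  sites <- fixedSites(coordinateMap(alignment))
  build <- function(idx, depth) {
    lab <- labels[idx]
    counts <- table(factor(lab, levels = groups))
    node <- list(counts = stats::setNames(as.integer(counts), groups),
                 n = length(idx),
                 label = groups[which.max(counts)],
                 depth = depth)
    purity <- max(counts) / length(idx)
    if (depth >= config$maxDepth || length(idx) < config$minSplit ||
        purity >= config$purityStop) {
      node$leaf <- TRUE
      return(node)
    }
    sp <- bestSplit(res[idx, , drop = FALSE], lab, sites, config)
    if (is.null(sp)) {
      node$leaf <- TRUE
      return(node)
    }
    col <- res[idx, paste0("s", sp$site)]
    node$leaf <- FALSE
    node$site <- sp$site
    node$left <- sp$left
    node$right <- sp$right
    node$statistic <- sp$statistic
    node$p <- sp$p
    node$children <- list(
      left = build(idx[col %in% sp$left], depth + 1L),
      right = build(idx[col %in% sp$right], depth + 1L))
    node
  }
  new("BhlhDecisionTree", root = build(seq_along(labels), 0L),
      config = config, groups = groups)
}

#' Predict Kingdoms with a decision tree
#'
#' Records are routed by residue membership in each node's branch sets. A gap
#' at a split site, or a residue unseen in either branch during training,
#' yields \code{Unclassified}.
#'
#' @param tree A \code{BhlhDecisionTree}.
#' @param alignment An \code{EnumeratedAlignment}.
#' @return Character vector of predictions, named by sequence id.
#' @export
predictTree <- function(tree, alignment) {
  res <- residueMatrix(alignment)
  one <- function(row) {
    node <- tree@root
    while (!node$leaf) {
      r <- row[paste0("s", node$site)]
      if (r %in% node$left) node <- node$children$left
      else if (r %in% node$right) node <- node$children$right
      else return(.UNCLASSIFIED)
    }
    node$label
  }
  stats::setNames(apply(res, 1L, one), seqIds(alignment))
}

#' Depth of a fitted tree
#'
#' @param tree A \code{BhlhDecisionTree}.
#' @return Number of split levels (0 for a single leaf).
#' @export
treeDepth <- function(tree) {
  go <- function(node) {
    if (node$leaf) return(node$depth)
    max(go(node$children$left), go(node$children$right))
  }
  go(tree@root)
}

#' Render a decision tree as an indented text key
#'
#' A dichotomous-key style rendering: each split shows the site and the
#' residue sets of its two branches, leaves show the assigned Kingdom and the
#' class counts.
#'
#' @param tree A \code{BhlhDecisionTree}.
#' @return Character vector of lines.
#' @export
treeKey <- function(tree) {
  lines <- character()
  go <- function(node, indent) {
    pad <- strrep("  ", indent)
    cnt <- paste(sprintf("%s=%d", names(node$counts), node$counts),
                 collapse = ", ")
    if (node$leaf) {
      lines <<- c(lines, sprintf("%s=> %s  [%s]", pad, node$label, cnt))
      return(invisible())
    }
    lines <<- c(lines,
                sprintf("%ssite %d (chi-square %.1f, p %.3g)  [%s]",
                        pad, node$site, node$statistic, node$p, cnt))
    lines <<- c(lines, sprintf("%s- in {%s}:", pad,
                               paste(node$left, collapse = "")))
    go(node$children$left, indent + 1L)
    lines <<- c(lines, sprintf("%s- in {%s}:", pad,
                               paste(node$right, collapse = "")))
    go(node$children$right, indent + 1L)
  }
  go(tree@root, 0L)
  lines
}

setMethod("show", "BhlhDecisionTree", function(object) {
  cat("BhlhDecisionTree over groups: ",
      paste(object@groups, collapse = ", "), "\n", sep = "")
  cat("  depth ", treeDepth(object), ", fitted on ", object@root$n,
      " record(s)\n", sep = "")
  writeLines(paste0("  ", utils::head(treeKey(object), 12)))
  if (length(treeKey(object)) > 12) cat("  ...\n")
})
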