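#' Group-level significance-thresholded graph
#'
#' Bundles the outcome of the edgewise group statistics into a weighted graph:
#' group-mean baseline-corrected weights on the retained (significant,
#' pruning-surviving) edges, zeros elsewhere, with per-edge sign and p-value.
#'
#' @param weights Symmetric matrix of group-mean corrected weights; entries of
#'   non-retained edges must be zero.
#' @param sign Symmetric matrix of edge signs (+1 increase, -1 decrease, 0).
#' @param p Symmetric matrix of p-values (NA where untested).
#' @param tested Symmetric logical matrix of the tested (mask-surviving) edges.
#' @param n_subjects Number of subjects behind the statistics.
#' @param meta Free-form metadata list (frequency, condition, ...).
#' @return Object of class `stat_graph`.
#' @export
stat_graph <- function(weights, sign, p, tested, n_subjects, meta = list()) {
  stopifnot(identical(dim(weights), dim(sign)), identical(dim(weights), dim(p)))
  retained <- weights != 0
  if (any(retained & !tested)) stop("retained edges must be tested", call. = FALSE)
  if (any(retained & (sign * weights < 0))) {
    stop("edge sign inconsistent with group-mean sign", call. = FALSE)
  }
  structure(list(weights = weights, sign = sign, p = p, tested = tested,
                 retained = retained, n_subjects = n_subjects, meta = meta),
            class = "stat_graph")
}

#' @export
print.stat_graph <- function(x, ...) {
  nr <- sum(ut_vec(x$retained))
  nt <- sum(ut_vec(x$tested))
  cat(sprintf("stat_graph: %d/%d edges retained (K = %.4f), %d nodes\n",
              nr, nt, if (nt > 0) nr / nt else NA, nrow(x$weights)))
  invisible(x)
}

#' Edge density K
#'
#' Fraction of retained edges of the given sign among all possible (tested)
#' edges.
#'
#' @param g A `stat_graph`.
#' @param sign `"positive"`, `"negative"` or `"all"`.
#' @param denominator Possible-edge count; defaults to the number of tested
#'   edges (i.e. excluding fidelity/leakage-masked pairs).
#' @return Edge density in `[0, 1]`.
#' @export
edge_density <- function(g, sign = c("all", "positive", "negative"),
                         denominator = NULL) {
  sign <- match.arg(sign)
  if (is.null(denominator)) denominator <- sum(ut_vec(g$tested))
  if (denominator <= 0) stop("denominator must be positive", call. = FALSE)
  keep <- switch(sign,
                 all = g$retained,
                 positive = g$retained & g$sign > 0,
                 negative = g$retained & g$sign < 0)
  sum(ut_vec(keep)) / denominator
}

#' Per-subject graph strength
#'
#' Unweighted mean of each subject's corrected edge weights over the
#' group-retained edge set.
#'
#' @param subject_weights Matrix subjects x edges (upper-triangular vector
#'   order), e.g. baseline-corrected iPLV.
#' @param retained Logical vector over the same edges (the group-retained set).
#' @return Numeric vector of GS per subject.
#' @export
graph_strength <- function(subject_weights, retained) {
  subject_weights <- as.matrix(subject_weights)
  stopifnot(ncol(subject_weights) == length(retained))
  if (!any(retained)) stop("retained edge set is empty", call. = FALSE)
  rowMeans(subject_weights[, retained, drop = FALSE])
}

#' Node degree and edge betweenness centralities
#'
#' Degree is the retained-edge count per node. Edge betweenness is computed on
#' the unweighted retained topology (hop-count shortest paths, fractional
#' credit shared among equal-length paths).
#'
#' @param g A `stat_graph` with at least one retained edge.
#' @return List with `degree` (per node) and `edges`: data frame (i, j,
#'   weight, betweenness) sorted by descending betweenness with lexicographic
#'   (i, j) tie-break.
#' @export
centralities <- function(g) {
  ret <- g$retained
  if (!any(ret)) stop("graph has no retained edges", call. = FALSE)
  deg <- rowSums(ret)
  pr <- which(upper.tri(ret) & ret, arr.ind = TRUE)
  ig <- igraph::graph_from_edgelist(pr, directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0, nrow(ret) - igraph::vcount(ig)))
  eb <- igraph::edge_betweenness(ig, directed = FALSE)
  out <- data.frame(i = pr[, 1], j = pr[, 2],
                    weight = g$weights[pr], betweenness = eb)
  out <- out[order(-out$betweenness, out$i, out$j), ]
  rownames(out) <- NULL
  list(degree = deg, edges = out)
}

#' Strongest edges by betweenness
#'
#' @param g A `stat_graph`.
#' @param n Number of edges to keep (the study default is 200); ties at the
#'   cut are broken by lexicographic (i, j) order.
#' @return Data frame of the top `n` edges from [centralities()].
#' @export
top_edges <- function(g, n = 200L) {
  ce <- centralities(g)$edges
  utils::head(ce, n)
}

#' Within/between-subsystem edge density
#'
#' Edge density for every unordered pair of node labels (including
#' within-system blocks), with the denominator equal to the number of possible
#' (tested) edges in that block.
#'
#' @param g A `stat_graph`.
#' @param labels Factor/character vector of node labels (every node labeled).
#' @param sign Edge sign filter, as in [edge_density()].
#' @return List with `K` (symmetric labels x labels density matrix),
#'   `count` and `possible` matrices.
#' @export
subsystem_density <- function(g, labels, sign = c("all", "positive", "negative")) {
  sign <- match.arg(sign)
  if (length(labels) != nrow(g$weights) || anyNA(labels)) {
    stop("every node must be labeled", call. = FALSE)
  }
  labels <- factor(labels)
  keep <- switch(sign,
                 all = g$retained,
                 positive = g$retained & g$sign > 0,
                 negative = g$retained & g$sign < 0)
  lv <- levels(labels)
  li <- as.integer(labels)
  nl <- length(lv)
  cnt <- matrix(0, nl, nl, dimnames = list(lv, lv))
  pos <- matrix(0, nl, nl, dimnames = list(lv, lv))
  pr <- edge_pairs(nrow(g$weights))
  a <- li[pr[, 1]]; b <- li[pr[, 2]]
  lo <- pmin(a, b); hi <- pmax(a, b)
  kv <- ut_vec(keep); tv <- ut_vec(g$tested)
  for (k in which(tv)) {
    pos[lo[k], hi[k]] <- pos[lo[k], hi[k]] + 1
    if (kv[k]) cnt[lo[k], hi[k]] <- cnt[lo[k], hi[k]] + 1
  }
  pos <- pos + t(pos) - diag(diag(pos))
  cnt <- cnt + t(cnt) - diag(diag(cnt))
  kmat <- ifelse(pos > 0, cnt / pos, NA)
  list(K = kmat, count = cnt, possible = pos)
}

#' Strength difference between two subsystem blocks
#'
#' For each subject, the mean corrected edge strength over the retained edges
#' of block A minus that of block B; group two-tailed Wilcoxon signed-rank
#' test against zero.
#'
#' @param subject_weights Matrix subjects x edges (upper-triangular order).
#' @param edges_a,edges_b Logical or integer index vectors of the two blocks'
#'   retained edges (both nonempty).
#' @return List with `delta` per subject, `mean_delta`, and `p`.
#' @export
delta_iplv <- function(subject_weights, edges_a, edges_b) {
  subject_weights <- as.matrix(subject_weights)
  ma <- subject_weights[, edges_a, drop = FALSE]
  mb <- subject_weights[, edges_b, drop = FALSE]
  if (ncol(ma) == 0 || ncol(mb) == 0) {
    stop("both blocks need at least one retained edge", call. = FALSE)
  }
  delta <- rowMeans(ma) - rowMeans(mb)
  p <- if (all(delta == 0)) 1 else
    suppressWarnings(stats::wilcox.test(delta, mu = 0)$p.value)
  list(delta = delta, mean_delta = mean(delta), p = p)
}
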