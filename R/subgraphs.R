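#' Leakage-aware edge exclusion mask
#'
#' Removes unreliable parcel pairs before statistics: every edge touching a
#' parcel whose source-reconstruction fidelity is below `fidelity_min`
#' (default 0.165), and every edge between parcels whose leakage neighborhoods
#' overlap too strongly. The leakage radius of a pair is the cosine similarity
#' of the two parcels' mixing rows — for unit-variance independent sources
#' mixed with zero lag, this equals the cross-parcel PLV induced by leakage
#' alone — and pairs above `radius_max` (default 0.35) are excluded.
#'
#' @param book A `parcel_book`.
#' @param fidelity_min Minimum per-parcel fidelity.
#' @param radius_max Maximum pairwise leakage radius.
#' @param level `"fine"` or `"coarse"` (mask on the collapsed parcellation).
#' @return Object of class `edge_mask`: list with `retained` (symmetric
#'   logical, FALSE diagonal), `reasons` (counts per exclusion rule),
#'   `fraction_excluded`, and the thresholds.
#' @export
exclude_edges <- function(book, fidelity_min = 0.165, radius_max = 0.35,
                          level = c("coarse", "fine")) {
  level <- match.arg(level)
  if (level == "fine") {
    mixing <- book$mixing
    fidelity <- book$fidelity
  } else {
    cb <- coarse_book(book)
    mixing <- cb$mixing
    fidelity <- cb$sampled_fidelity
  }
  p <- nrow(mixing)
  nrm <- sqrt(rowSums(mixing^2))
  cosim <- (mixing %*% t(mixing)) / outer(nrm, nrm)
  low_fid <- fidelity < fidelity_min
  bad_fid <- outer(low_fid, low_fid, "|")
  bad_rad <- cosim > radius_max
  diag(bad_fid) <- FALSE; diag(bad_rad) <- FALSE
  retained <- !(bad_fid | bad_rad)
  diag(retained) <- FALSE
  n_all <- p * (p - 1) / 2
  structure(list(
    retained = retained,
    reasons = c(low_fidelity = sum(ut_vec(bad_fid)),
                large_radius = sum(ut_vec(bad_rad & !bad_fid))),
    fraction_excluded = 1 - sum(ut_vec(retained)) / n_all,
    fidelity_min = fidelity_min, radius_max = radius_max, level = level
  ), class = "edge_mask")
}

#' @export
print.edge_mask <- function(x, ...) {
  cat(sprintf("edge_mask (%s): %.1f%% of edges excluded (%d low-fidelity, %d large-radius)\n",
              x$level, 100 * x$fraction_excluded, x$reasons["low_fidelity"],
              x$reasons["large_radius"]))
  invisible(x)
}

#' Union matrix across conditions
#'
#' Combines the per-condition retained graphs into one union graph: the union
#' support is the set union of retained edges, the weight of each union edge is
#' the mean strength over the conditions in which it is retained, and
#' per-condition membership flags are preserved.
#'
#' @param graphs Named list of three `stat_graph`s (Shape, Color, Location) on
#'   the same parcellation and mask.
#' @return Object of class `union_graph`: list with `weights`, `membership`
#'   (parcels x parcels x conditions logical), `conditions`, `tested`.
#' @export
build_union <- function(graphs) {
  stopifnot(length(graphs) >= 2, !is.null(names(graphs)))
  p <- nrow(graphs[[1]]$weights)
  for (g in graphs) {
    if (nrow(g$weights) != p) stop("parcellation mismatch", call. = FALSE)
    if (!identical(g$tested, graphs[[1]]$tested)) {
      stop("graphs must share the same tested mask", call. = FALSE)
    }
  }
  member <- array(FALSE, dim = c(p, p, length(graphs)),
                  dimnames = list(NULL, NULL, names(graphs)))
  wsum <- matrix(0, p, p)
  for (k in seq_along(graphs)) {
    member[, , k] <- graphs[[k]]$retained
    wsum <- wsum + abs(graphs[[k]]$weights)
  }
  nmem <- apply(member, c(1, 2), sum)
  weights <- ifelse(nmem > 0, wsum / pmax(nmem, 1), 0)
  structure(list(weights = weights, membership = member,
                 conditions = names(graphs), tested = graphs[[1]]$tested),
            class = "union_graph")
}

#' Bundle union edges into hyperedges by leakage adjacency
#'
#' Groups raw edges that plausibly originate from a single true interaction
#' smeared by source leakage. The similarity of two edges (a,b) and (c,d) is
#' the larger, over the two endpoint pairings, of the product of mixing-row
#' cosine similarities `cos(a,c) * cos(b,d)`; identical edges have similarity
#' 1 and edges in leakage-disconnected parcel groups have similarity 0 (with
#' identity mixing every edge is its own bundle). Hierarchical clustering on
#' `1 - similarity` is cut at `1 - cutoff`.
#'
#' Single linkage is the default: a spurious edge relates to its true edge
#' through one leakage step (similarity = one endpoint cosine), whereas two
#' spurious copies relate through two steps (a product of two cosines), so the
#' smear around one true edge is a connected component at a cutoff between
#' those two scales, while average linkage dilutes hub-centered smears.
#'
#' @param union A `union_graph`.
#' @param mixing Mixing matrix on the union's parcellation.
#' @param cutoff Similarity cutoff in (0, 1) (default 0.25).
#' @param min_size Bundles smaller than this are labeled `discarded_small`
#'   (default 3).
#' @param linkage `"single"` (default) or `"average"`.
#' @return Object of class `hyperedge_set`: list with `edges` (data frame i, j,
#'   bundle, per-condition membership), `bundles` (data frame bundle, size,
#'   per-condition counts, label), `cutoff`, `min_size`.
#' @export
bundle_hyperedges <- function(union, mixing, cutoff = 0.25, min_size = 3L,
                              linkage = c("single", "average")) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(union, "union_graph"))
  p <- nrow(union$weights)
  stopifnot(nrow(mixing) == p)
  support <- union$weights != 0
  pr <- which(upper.tri(support) & support, arr.ind = TRUE)
  ne <- nrow(pr)
  conds <- union$conditions
  if (ne == 0) {
    return(structure(list(
      edges = data.frame(i = integer(0), j = integer(0), bundle = integer(0)),
      bundles = data.frame(bundle = integer(0), size = integer(0),
                           label = character(0)),
      cutoff = cutoff, min_size = min_size), class = "hyperedge_set"))
  }
  nrm <- sqrt(rowSums(mixing^2))
  cosim <- (mixing %*% t(mixing)) / outer(nrm, nrm)
  if (ne == 1) {
    cl <- 1L
  } else {
    a <- pr[, 1]; b <- pr[, 2]
    s1 <- cosim[a, a] * cosim[b, b]   # pairing (a,c), (b,d)
    s2 <- cosim[a, b] * cosim[b, a]   # pairing (a,d), (b,c)
    s <- pmax(s1, s2)
    hc <- stats::hclust(stats::as.dist(1 - s), method = linkage)
    cl <- stats::cutree(hc, h = 1 - cutoff)
  }
  memb <- matrix(FALSE, ne, length(conds), dimnames = list(NULL, conds))
  for (k in seq_along(conds)) {
    memb[, k] <- union$membership[, , k][pr]
  }
  edges <- data.frame(i = pr[, 1], j = pr[, 2], bundle = as.integer(cl))
  edges <- cbind(edges, as.data.frame(memb))
  sizes <- tabulate(cl)
  counts <- rowsum(memb + 0, cl)
  bundles <- data.frame(bundle = seq_along(sizes), size = sizes)
  bundles <- cbind(bundles, as.data.frame(counts))
  bundles$label <- ifelse(sizes < min_size, "discarded_small", "unclassified")
  structure(list(edges = edges, bundles = bundles,
                 cutoff = cutoff, min_size = min_size),
            class = "hyperedge_set")
}

#' @export
print.hyperedge_set <- function(x, ...) {
  cat(sprintf("hyperedge_set: %d edges in %d bundles (min size %d)\n",
              nrow(x$edges), nrow(x$bundles), x$min_size))
  if ("label" %in% names(x$bundles)) print(table(x$bundles$label))
  invisible(x)
}

#' Classify hyperedges as shared or condition-specific
#'
#' For each bundle, condition participations are the density-normalized shares
#' `p_c = (n_c / K_c) / sum_c' (n_c' / K_c')`, where `n_c` is the number of the
#' bundle's raw edges retained in condition `c` and `K_c` the condition's edge
#' density. A bundle is `shared` when at least two conditions have
#' participation above `threshold` (exact ties count as exceeding, favoring
#' shared); otherwise it is specific to the condition with the largest
#' participation. Bundles below the minimum size keep `discarded_small`.
#'
#' @param hs A `hyperedge_set`.
#' @param k_cond Named vector of per-condition edge densities (all > 0).
#' @param threshold Participation threshold (default 0.3).
#' @return The `hyperedge_set` with filled `label` and participation columns.
#' @export
classify_hyperedges <- function(hs, k_cond, threshold = 0.3) {
  stopifnot(inherits(hs, "hyperedge_set"), threshold > 0, threshold < 1)
  conds <- intersect(names(hs$bundles), names(k_cond))
  if (length(conds) < 2) stop("need per-condition densities", call. = FALSE)
  if (any(k_cond[conds] <= 0)) stop("condition densities must be > 0", call. = FALSE)
  b <- hs$bundles
  nmat <- as.matrix(b[, conds, drop = FALSE])
  w <- sweep(nmat, 2, k_cond[conds], "/")
  part <- w / pmax(rowSums(w), 1e-300)
  lab <- character(nrow(b))
  for (r in seq_len(nrow(b))) {
    if (b$size[r] < hs$min_size) { lab[r] <- "discarded_small"; next }
    over <- part[r, ] >= threshold
    if (sum(over) >= 2) {
      lab[r] <- "shared"
    } else {
      mx <- which(part[r, ] == max(part[r, ]))
      lab[r] <- if (length(mx) > 1) "shared" else conds[mx]
    }
  }
  colnames(part) <- paste0("p_", conds)
  hs$bundles <- cbind(b[, setdiff(names(b), c("label", colnames(part)))],
                      part, label = lab)
  hs$threshold <- threshold
  hs
}

#' Shared versus condition-specific edge proportions
#'
#' Raw-edge-weighted proportions of each classified label (bundles labeled
#' `discarded_small` are excluded from the denominator).
#'
#' @param hs A classified `hyperedge_set`.
#' @return Named numeric vector of proportions summing to 1 over the labels
#'   present.
#' @export
shared_fraction <- function(hs) {
  b <- hs$bundles
  if (!"label" %in% names(b) || any(b$label == "unclassified")) {
    stop("hyperedge set must be classified first", call. = FALSE)
  }
  b <- b[b$label != "discarded_small", , drop = FALSE]
  if (nrow(b) == 0) return(stats::setNames(numeric(0), character(0)))
  tot <- tapply(b$size, b$label, sum)
  tot / sum(tot)
}
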