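#' Edgewise Wilcoxon signed-rank test
#'
#' Two-tailed one-sample signed-rank test of each edge (column) against `mu0`,
#' vectorized over edges so that calibration runs with millions of columns are
#' practical. Columns without ties or zeros use the exact null distribution of
#' the rank sum (`psignrank`); columns with ties or zero differences fall back
#' to the normal approximation with tie correction and continuity correction,
#' matching `stats::wilcox.test`. Zero differences are dropped (the standard
#' Wilcoxon convention); an all-zero column gets p = 1 and sign 0.
#'
#' @param values Numeric matrix, subjects x edges.
#' @param mu0 Null location (default 0).
#' @return List with `p` (two-tailed p per edge), `sign` (sign of the median
#'   difference), `stat` (rank sum of positive differences) and `n_used`
#'   (non-zero differences per edge).
#' @export
edgewise_wilcoxon <- function(values, mu0 = 0) {
  values <- as.matrix(values)
  s <- nrow(values); e <- ncol(values)
  if (s < 6) stop("need at least 6 subjects", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  d <- values - mu0

  # median sign per column via two order statistics
  sorted <- apply(d, 2, sort)
  med <- if (s %% 2 == 1) sorted[(s + 1) / 2, ] else
    (sorted[s / 2, ] + sorted[s / 2 + 1, ]) / 2
  sgn <- sign(med)

  a <- abs(d)
  has_zero <- colSums(a == 0) > 0
  # tie detection on |d| within columns
  has_tie <- apply(a, 2, function(x) anyDuplicated(x) > 0)
  clean <- !has_zero & !has_tie

  p <- rep(1, e)
  v <- rep(NA_real_, e)
  n_used <- colSums(a > 0)

  if (any(clean)) {
    ac <- a[, clean, drop = FALSE]
    dc <- d[, clean, drop = FALSE]
    ec <- ncol(ac)
    o <- order(rep(seq_len(ec), each = s), as.vector(ac))
    r <- integer(s * ec); r[o] <- rep(seq_len(s), ec)
    vv <- colSums(matrix(r, s, ec) * (dc > 0))
    pl <- stats::psignrank(vv, s)
    pu <- stats::psignrank(vv - 1, s, lower.tail = FALSE)
    p[clean] <- pmin(1, 2 * pmin(pl, pu))
    v[clean] <- vv
  }
  for (k in which(!clean)) {
    dk <- d[a[, k] > 0, k]
    nk <- length(dk)
    if (nk == 0) { p[k] <- 1; v[k] <- 0; next }
    rk <- rank(abs(dk))
    vk <- sum(rk[dk > 0])
    mu <- nk * (nk + 1) / 4
    ties <- table(rk)
    sig2 <- nk * (nk + 1) * (2 * nk + 1) / 24 -
      sum(ties^3 - ties) / 48
    if (sig2 <= 0) { p[k] <- 1; v[k] <- vk; next }
    zz <- (vk - mu - sign(vk - mu) * 0.5) / sqrt(sig2)
    p[k] <- min(1, 2 * stats::pnorm(-abs(zz)))
    v[k] <- vk
  }
  list(p = p, sign = sgn, stat = v, n_used = n_used)
}

#' False-positive pruning of a significant set
#'
#' Pools the significant observations and discards the `ceiling(alpha *
#' n_tests)` least-significant (largest p) of them — the number of discoveries
#' expected to be false at level `alpha` over the whole test family — keeping
#' the survivors. If the significant set is smaller than the predicted
#' false-discovery count, everything is discarded.
#'
#' @param pvals P-values of the significant observations (each <= `alpha`).
#' @param alpha Test level.
#' @param n_tests Total number of tests performed in the family.
#' @param effect Optional effect sizes (e.g. absolute group-mean differences)
#'   used to order observations with tied p-values: among equally significant
#'   observations the weakest effects are discarded first. This matters with
#'   exact rank tests at small n, where many edges share the minimum attainable
#'   p. Without `effect`, ties are broken by position.
#' @return Logical vector along `pvals`: TRUE for survivors.
#' @export
fp_prune <- function(pvals, alpha = 0.05, n_tests, effect = NULL) {
  if (length(pvals) == 0) return(logical(0))
  if (any(pvals > alpha + 1e-12)) {
    stop("fp_prune expects only significant p-values (<= alpha)", call. = FALSE)
  }
  if (n_tests < length(pvals)) stop("n_tests smaller than significant set", call. = FALSE)
  n_drop <- ceiling(alpha * n_tests)
  n_keep <- max(0L, length(pvals) - n_drop)
  keep <- logical(length(pvals))
  ord <- if (is.null(effect)) order(pvals) else order(pvals, -abs(effect))
  if (n_keep > 0) keep[ord[seq_len(n_keep)]] <- TRUE
  keep
}

#' Simulated-null density threshold Q
#'
#' Estimates the residual fraction of "significant" edges that survives the
#' Wilcoxon + false-positive pruning pipeline when there is no effect at all:
#' each simulation draws i.i.d. standard normal subject-by-edge differences
#' (the signed-rank test is distribution-free under exchangeable signs), runs
#' [edgewise_wilcoxon()] and [fp_prune()], and records the surviving edge
#' fraction. `Q` aggregates the per-simulation fractions with `q_rule`
#' (default: maximum). Observed networks with edge density above `Q` are
#' unlikely to be pure chance.
#'
#' @param n_tests Number of edges tested in the real analysis.
#' @param n_subjects Number of subjects.
#' @param alpha Test level.
#' @param n_sims Number of null simulations (>= 100).
#' @param q_rule Aggregation function over per-simulation residual fractions.
#' @param seed Integer seed.
#' @return Object of class `null_threshold`: list with `Q`, `fractions`, and
#'   the configuration.
#' @export
estimate_Q <- function(n_tests, n_subjects, alpha = 0.05, n_sims = 200L,
                       q_rule = max, seed = 1L) {
  if (n_sims < 100) stop("n_sims must be at least 100", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(child_seed(seed, 31L))
  fr <- numeric(n_sims)
  for (b in seq_len(n_sims)) {
    d <- matrix(stats::rnorm(n_subjects * n_tests), n_subjects, n_tests)
    wt <- edgewise_wilcoxon(d)
    sig <- which(wt$p <= alpha)
    keep <- fp_prune(wt$p[sig], alpha, n_tests)
    fr[b] <- sum(keep) / n_tests
  }
  structure(list(Q = q_rule(fr), fractions = fr,
                 config = list(n_tests = n_tests, n_subjects = n_subjects,
                               alpha = alpha, n_sims = n_sims)),
            class = "null_threshold")
}

#' @export
print.null_threshold <- function(x, ...) {
  cat(sprintf("null_threshold: Q = %.4g (%.3f%% edge density) over %d sims [%d tests, %d subjects, alpha %.3g]\n",
              x$Q, 100 * x$Q, x$config$n_sims, x$config$n_tests,
              x$config$n_subjects, x$config$alpha))
  invisible(x)
}

#' Edgewise Pearson correlation with behavior
#'
#' Sample Pearson correlation of each edge's strength with per-subject hit
#' rates, with the usual t-based two-tailed p. Zero-variance edges are excluded
#' and counted.
#'
#' @param strengths Matrix, subjects x edges.
#' @param hr Numeric vector of per-subject hit rates (variance > 0).
#' @return List with `r`, `p` per edge (NA for excluded edges) and
#'   `n_excluded`.
#' @export
edgewise_hr_correlation <- function(strengths, hr) {
  strengths <- as.matrix(strengths)
  n <- nrow(strengths)
  if (n < 4) stop("need at least 4 subjects", call. = FALSE)
  if (stats::sd(hr) == 0) stop("HR has zero variance", call. = FALSE)
  xc <- scale(strengths, center = TRUE, scale = FALSE)
  yc <- hr - mean(hr)
  sx <- sqrt(colSums(xc^2))
  r <- as.vector(crossprod(xc, yc)) / (sx * sqrt(sum(yc^2)))
  bad <- sx == 0
  r[bad] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1e-300, 1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[bad] <- NA_real_
  list(r = r, p = p, n_excluded = sum(bad))
}

#' Pairwise repeated-measures t contrasts of graph strength
#'
#' Paired two-tailed t-tests between every pair of condition columns; no
#' multiplicity correction across the pairs (raw pairwise contrasts are
#' reported). A constant nonzero within-subject shift with zero variance is an
#' exact degeneracy and is flagged with infinite t and p = 0.
#'
#' @param gs Matrix, subjects x conditions, with condition column names.
#' @return Data frame with columns a, b, t, p, mean_diff.
#' @export
gs_contrast <- function(gs) {
  gs <- as.matrix(gs)
  if (nrow(gs) < 3) stop("need at least 3 subjects", call. = FALSE)
  if (any(is.na(gs))) stop("paired complete data required", call. = FALSE)
  cn <- colnames(gs)
  if (is.null(cn)) cn <- paste0("cond", seq_len(ncol(gs)))
  pairs <- utils::combn(ncol(gs), 2)
  out <- data.frame(a = cn[pairs[1, ]], b = cn[pairs[2, ]],
                    t = NA_real_, p = NA_real_, mean_diff = NA_real_)
  for (k in seq_len(ncol(pairs))) {
    d <- gs[, pairs[1, k]] - gs[, pairs[2, k]]
    out$mean_diff[k] <- mean(d)
    if (stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
      out$t[k] <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      out$p[k] <- if (mean(d) == 0) 1 else 0
    } else {
      tt <- stats::t.test(d)
      out$t[k] <- unname(tt$statistic)
      out$p[k] <- tt$p.value
    }
  }
  out
}

#' Data-driven frequency clustering into contiguous bands
#'
#' Vectorizes each frequency's signed significance pattern (+1 retained
#' increase, -1 retained decrease, 0 otherwise), measures the similarity of
#' frequencies by the Pearson correlation of these vectors, and agglomerates
#' *adjacent* frequencies (average linkage, contiguity-constrained) while the
#' best adjacent-cluster similarity exceeds `cutoff`. Frequencies with empty
#' graphs correlate with nothing and therefore stay as singleton separators,
#' which is what splits spatially distinct bands.
#'
#' @param stat_graphs List of `stat_graph` objects, one per frequency,
#'   ordered by frequency.
#' @param freqs Numeric vector of center frequencies (same order).
#' @param cutoff Minimum average similarity for merging (default 0.25).
#' @return Data frame with one row per band: `f_lo`, `f_hi`, `n_freqs`,
#'   `n_edges` (total retained edges across the band's frequencies) and
#'   `nontrivial` (TRUE for bands of >= 2 frequencies with retained edges).
#' @export
cluster_frequencies <- function(stat_graphs, freqs, cutoff = 0.25) {
  nf <- length(stat_graphs)
  stopifnot(nf == length(freqs))
  if (nf < 3) stop("need at least 3 frequencies", call. = FALSE)
  vecs <- lapply(stat_graphs, function(g) {
    ut_vec(unclass(g$weights) != 0) * ut_vec(sign(unclass(g$sign)))
  })
  n_edges <- vapply(vecs, function(v) sum(v != 0), numeric(1))
  if (all(n_edges == 0)) {
    warning("all stat graphs are empty; returning a single trivial band")
    return(data.frame(f_lo = freqs[1], f_hi = freqs[nf], n_freqs = nf,
                      n_edges = 0, nontrivial = FALSE))
  }
  sim <- function(a, b) {
    va <- vecs[[a]]; vb <- vecs[[b]]
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(0)
    stats::cor(va, vb)
  }
  clusters <- as.list(seq_len(nf))
  repeat {
    if (length(clusters) == 1) break
    best <- -Inf; best_k <- 0L
    for (k in seq_len(length(clusters) - 1)) {
      pairsim <- outer(clusters[[k]], clusters[[k + 1]], Vectorize(sim))
      avg <- mean(pairsim)
      if (avg > best) { best <- avg; best_k <- k }
    }
    if (best < cutoff) break
    clusters[[best_k]] <- c(clusters[[best_k]], clusters[[best_k + 1]])
    clusters[[best_k + 1]] <- NULL
  }
  out <- do.call(rbind, lapply(clusters, function(ix) {
    data.frame(f_lo = freqs[min(ix)], f_hi = freqs[max(ix)],
               n_freqs = length(ix), n_edges = sum(n_edges[ix]))
  }))
  out$nontrivial <- out$n_freqs >= 2 & out$n_edges > 0
  out
}
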