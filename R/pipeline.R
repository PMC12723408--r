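#' Subject-level baseline-corrected connectome stack
#'
#' Runs the estimation chain for every subject and frequency: Morlet filtering,
#' pooled iPLV per condition in the baseline, early and late windows, averaging
#' of the two retention windows, collapse to the coarse parcellation, and
#' baseline subtraction. This is the input to the group edge statistics.
#'
#' @param study A `sim_study`.
#' @param freqs Wavelet center frequencies to analyse (Hz).
#' @param m Morlet time-frequency compromise parameter.
#' @param collapse If TRUE (default) collapse to the coarse parcellation.
#' @param verbose Print progress.
#' @return Object of class `connectome_stack`: list with `corrected` (list per
#'   frequency of arrays subjects x conditions x edges, upper-triangular
#'   order), `freqs`, `conditions`, `n_parcels`.
#' @export
compute_connectomes <- function(study, freqs, m = 5, collapse = TRUE,
                                verbose = FALSE) {
  stopifnot(inherits(study, "sim_study"))
  conds <- c("Shape", "Color", "Location")
  p_out <- if (collapse) n_coarse(study$book) else study$book$n_fine
  n_e <- p_out * (p_out - 1) / 2
  corrected <- lapply(freqs, function(f)
    array(NA_real_, dim = c(study$n_subjects, length(conds), n_e)))
  names(corrected) <- as.character(freqs)
  for (s in seq_len(study$n_subjects)) {
    raw <- get_epochs(study, s)
    for (fi in seq_along(freqs)) {
      nb <- filter_epochs(raw, freqs[fi], m = m)
      ws <- matched_window_samples(nb)
      for (ci in seq_along(conds)) {
        base <- iplv_pooled(nb, "baseline", condition = conds[ci],
                            samples = ws$baseline)
        early <- iplv_pooled(nb, "early", condition = conds[ci],
                             samples = ws$early)
        late <- iplv_pooled(nb, "late", condition = conds[ci],
                            samples = ws$late)
        corr <- baseline_correct(early, base, late = late)
        if (collapse) corr <- collapse_parcellation(corr, study$book)
        corrected[[fi]][s, ci, ] <- ut_vec(unclass(corr))
      }
    }
    if (verbose) message("subject ", s, "/", study$n_subjects, " done")
  }
  structure(list(corrected = corrected, freqs = freqs, conditions = conds,
                 n_parcels = p_out, n_subjects = study$n_subjects,
                 collapsed = collapse),
            class = "connectome_stack")
}

#' Group edge statistics and significance graphs
#'
#' For each frequency and condition: edgewise Wilcoxon signed-rank test of the
#' baseline-corrected weights against zero over the mask-surviving edges,
#' false-positive pruning at `alpha`, and assembly into a [stat_graph()]. A
#' simulated-null density threshold `Q` (shared across frequencies, since the
#' test family has the same size everywhere) flags which graphs exceed chance
#' density.
#'
#' @param conn A `connectome_stack`.
#' @param mask An `edge_mask` on the same parcellation (or NULL to test all
#'   edges).
#' @param alpha Test level (default 0.05).
#' @param n_null Null simulations for [estimate_Q()] (0 skips the Q stage).
#' @param q_rule Aggregation rule over null simulations.
#' @param seed Seed for the null simulations.
#' @return Object of class `group_stats`: list with `graphs` (per frequency: a
#'   named list of `stat_graph`s per condition), `K` (data frame of signed edge
#'   densities), `Q` (a `null_threshold` or NULL), `tested` (edge vector).
#' @export
group_stats <- function(conn, mask = NULL, alpha = 0.05, n_null = 200L,
                        q_rule = max, seed = 1L) {
  stopifnot(inherits(conn, "connectome_stack"))
  p <- conn$n_parcels
  tested <- if (is.null(mask)) rep(TRUE, p * (p - 1) / 2) else {
    stopifnot(nrow(mask$retained) == p)
    ut_vec(mask$retained)
  }
  n_tests <- sum(tested)
  qth <- if (n_null > 0) {
    estimate_Q(n_tests, conn$n_subjects, alpha, n_sims = n_null,
               q_rule = q_rule, seed = seed)
  } else NULL
  tested_m <- ut_mat(tested, p) > 0
  graphs <- list()
  krows <- list()
  for (fi in seq_along(conn$freqs)) {
    gl <- list()
    for (ci in seq_along(conn$conditions)) {
      vals <- conn$corrected[[fi]][, ci, tested, drop = TRUE]
      wt <- edgewise_wilcoxon(vals)
      gmean <- colMeans(vals)
      sig <- which(wt$p <= alpha)
      keep <- sig[fp_prune(wt$p[sig], alpha, n_tests, effect = gmean[sig])]
      ret_vec <- logical(n_tests); ret_vec[keep] <- TRUE
      wv <- numeric(n_tests); wv[keep] <- gmean[keep]
      sv <- numeric(n_tests); sv[keep] <- sign(gmean[keep])
      full <- function(v) { out <- rep(0, length(tested)); out[tested] <- v; out }
      pv <- rep(NA_real_, length(tested)); pv[tested] <- wt$p
      g <- stat_graph(weights = ut_mat(full(wv), p),
                      sign = ut_mat(full(sv), p),
                      p = ut_mat(pv, p),
                      tested = tested_m,
                      n_subjects = conn$n_subjects,
                      meta = list(frequency = conn$freqs[fi],
                                  condition = conn$conditions[ci]))
      gl[[conn$conditions[ci]]] <- g
      krows[[length(krows) + 1L]] <- data.frame(
        frequency = conn$freqs[fi], condition = conn$conditions[ci],
        K = edge_density(g), K_pos = edge_density(g, "positive"),
        K_neg = edge_density(g, "negative"),
        exceeds_Q = if (is.null(qth)) NA else edge_density(g) > qth$Q)
    }
    graphs[[as.character(conn$freqs[fi])]] <- gl
  }
  structure(list(graphs = graphs, K = do.call(rbind, krows), Q = qth,
                 tested = tested, alpha = alpha,
                 freqs = conn$freqs, conditions = conn$conditions),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat("group_stats over", length(x$freqs), "frequencies x",
      length(x$conditions), "conditions\n")
  if (!is.null(x$Q)) cat(sprintf("  Q = %.4g\n", x$Q$Q))
  print(utils::head(x$K[order(-x$K$K), ], 6))
  invisible(x)
}

#' Single-trial decoding of the memorized condition
#'
#' For each frequency: builds the top-`mask_k` edge mask from the group-average
#' retention-minus-baseline connectome (fine parcellation, computed from the
#' same data, mirroring the study procedure and its documented leakage caveat),
#' extracts masked single-trial iPLV vectors for the baseline window and for
#' the retention windows (early/late averaged), and runs random-forest
#' cross-validated decoding per subject. The retention-minus-baseline accuracy
#' contrast isolates retention-period information from block effects.
#'
#' @param study A `sim_study`.
#' @param freqs Frequencies to decode at.
#' @param mask_k Mask size (edges); capped at the available edge count.
#' @param cv,k_folds,num_trees,seed Passed to [rf_loocv()].
#' @param m Morlet parameter.
#' @return List with `acc_retention`, `acc_baseline` (subjects x frequencies),
#'   and `contrast` (from [retention_vs_baseline()]).
#' @export
decode_study <- function(study, freqs, mask_k = 100L, cv = "kfold",
                         k_folds = 10L, num_trees = 200L, seed = 1L, m = 5) {
  stopifnot(inherits(study, "sim_study"))
  ns <- study$n_subjects
  p <- study$book$n_fine
  n_e <- p * (p - 1) / 2
  mask_k <- min(mask_k, n_e)
  nf <- length(freqs)
  st_base <- vector("list", ns * nf)
  st_ret <- vector("list", ns * nf)
  gavg <- matrix(0, n_e, nf)
  for (s in seq_len(ns)) {
    raw <- get_epochs(study, s)
    for (fi in seq_len(nf)) {
      nb <- filter_epochs(raw, freqs[fi], m = m)
      ws <- matched_window_samples(nb)
      k <- (fi - 1L) * ns + s
      st_base[[k]] <- iplv_single_trial_all(nb, "baseline", samples = ws$baseline)
      st_ret[[k]] <- (iplv_single_trial_all(nb, "early", samples = ws$early) +
                        iplv_single_trial_all(nb, "late", samples = ws$late)) / 2
      base <- iplv_pooled(nb, "baseline", samples = ws$baseline)
      early <- iplv_pooled(nb, "early", samples = ws$early)
      late <- iplv_pooled(nb, "late", samples = ws$late)
      gavg[, fi] <- gavg[, fi] +
        ut_vec(unclass(baseline_correct(early, base, late = late)))
    }
  }
  acc_r <- matrix(NA_real_, ns, nf)
  acc_b <- matrix(NA_real_, ns, nf)
  for (fi in seq_len(nf)) {
    mask <- build_mask(gavg[, fi] / ns, mask_k)
    for (s in seq_len(ns)) {
      k <- (fi - 1L) * ns + s
      tf_r <- featurize(st_ret[[k]], study$condition, mask, "retention")
      tf_b <- featurize(st_base[[k]], study$condition, mask, "baseline")
      sd_seed <- child_seed(seed, 10000L + 100L * fi + s)
      acc_r[s, fi] <- rf_loocv(tf_r, cv = cv, k = k_folds,
                               num_trees = num_trees, seed = sd_seed)$accuracy
      acc_b[s, fi] <- rf_loocv(tf_b, cv = cv, k = k_folds,
                               num_trees = num_trees, seed = sd_seed)$accuracy
    }
  }
  list(acc_retention = acc_r, acc_baseline = acc_b,
       contrast = retention_vs_baseline(acc_r, acc_b, freqs))
}

#' Shared versus condition-specific subgraph analysis at one frequency
#'
#' Chains the subgraph stage: union of the three conditions' retained graphs,
#' hyperedge bundling by leakage adjacency on the coarse mixing matrix, and
#' participation-based classification into shared and condition-specific
#' bundles.
#'
#' @param graphs Named list of the three conditions' `stat_graph`s (one
#'   frequency).
#' @param book The `parcel_book` (for the coarse mixing matrix).
#' @param cutoff,min_size Passed to [bundle_hyperedges()].
#' @param threshold Participation threshold for [classify_hyperedges()].
#' @return List with `union`, `hyperedges` (classified), `shared_fraction`,
#'   and `K` (per-condition densities used for normalization).
#' @export
subgraph_analysis <- function(graphs, book, cutoff = 0.25, min_size = 3L,
                              threshold = 0.3) {
  un <- build_union(graphs)
  k_cond <- vapply(graphs, edge_density, numeric(1))
  hs <- bundle_hyperedges(un, coarse_book(book)$mixing,
                          cutoff = cutoff, min_size = min_size)
  hs <- classify_hyperedges(hs, k_cond, threshold = threshold)
  list(union = un, hyperedges = hs,
       shared_fraction = shared_fraction(hs), K = k_cond)
}

#' Bundle-label accuracy against planted ground truth
#'
#' For every planted retention-period coupling, locates the hyperedge bundle
#' containing its coarse edge (if the edge survived into the union graph and
#' its bundle was not discarded as too small) and scores whether the bundle's
#' label matches the coupling's scope: `shared` for couplings active in all
#' three conditions, the condition name for condition-specific couplings.
#'
#' @param hs A classified `hyperedge_set`.
#' @param study The `sim_study` with ground truth.
#' @return List with `accuracy`, `n_scored` (planted couplings found in a
#'   labeled bundle), `n_planted`, and the per-coupling table.
#' @export
hyperedge_label_accuracy <- function(hs, study) {
  gt <- study$ground_truth
  gt <- gt[grepl("early|late", gt$windows), ]
  key <- unique(gt[, c("ci", "cj", "scope", "condition")])
  # collapse per planted coarse edge: shared scope wins if mixed
  agg <- stats::aggregate(cbind(n = rep(1, nrow(key))) ~ ci + cj, data = key,
                          FUN = length)
  rows <- lapply(seq_len(nrow(agg)), function(r) {
    sub <- key[key$ci == agg$ci[r] & key$cj == agg$cj[r], ]
    expect <- if (any(sub$scope == "shared") || nrow(sub) == 3) "shared"
              else sub$condition[1]
    data.frame(ci = agg$ci[r], cj = agg$cj[r], expected = expect)
  })
  tab <- do.call(rbind, rows)
  e <- hs$edges
  b <- hs$bundles
  tab$label <- NA_character_
  for (r in seq_len(nrow(tab))) {
    hit <- which(e$i == tab$ci[r] & e$j == tab$cj[r])
    if (length(hit) == 1) {
      lab <- b$label[b$bundle == e$bundle[hit]]
      if (!identical(lab, "discarded_small")) tab$label[r] <- lab
    }
  }
  scored <- !is.na(tab$label)
  list(accuracy = if (any(scored)) mean(tab$label[scored] == tab$expected[scored])
                  else NA_real_,
       n_scored = sum(scored), n_planted = nrow(tab), table = tab)
}

#' Recovery of planted couplings from a stat graph
#'
#' Compares a retained coarse edge set against the study's ground truth:
#' sensitivity (fraction of planted coarse edges recovered) and false-edge
#' rate (fraction of retained edges not attributable to any planted coupling).
#'
#' With zero-lag leakage mixing, a planted lagged coupling between parcels i
#' and j also produces genuine lagged dependence between any parcel pair whose
#' leakage neighborhoods contain i and j — these are real properties of the
#' observed signals, which no phase statistic can (or should) reject. Under
#' `attribution = "leakage"` (the default) a retained edge therefore counts as
#' true when its endpoints' leakage neighborhoods cover a planted edge's
#' endpoints; `"strict"` counts only the planted coarse pairs themselves.
#'
#' @param g A `stat_graph` on the coarse parcellation.
#' @param study The `sim_study` that produced it.
#' @param condition Condition to evaluate (planted edges active in it).
#' @param windows Regular expression the planted edges' window scope must
#'   match (default: retention edges).
#' @param attribution `"leakage"` or `"strict"`.
#' @param support_tol Minimum coarse mixing weight that defines the leakage
#'   neighborhood.
#' @param sign Which retained edges to evaluate: increases (`"positive"`, the
#'   right choice for retention-period couplings), decreases (`"negative"`,
#'   for baseline-only suppressed couplings) or `"all"`.
#' @return List with `sensitivity`, `false_edge_rate`, `n_true`, `n_retained`.
#' @export
recovery_rates <- function(g, study, condition, windows = "early|late",
                           attribution = c("leakage", "strict"),
                           support_tol = 0.01,
                           sign = c("positive", "negative", "all")) {
  attribution <- match.arg(attribution)
  sign <- match.arg(sign)
  gt <- study$ground_truth
  gt <- gt[gt$condition == condition & grepl(windows, gt$windows), ]
  p <- nrow(g$weights)
  truth <- matrix(FALSE, p, p)
  if (nrow(gt) > 0) truth[cbind(gt$ci, gt$cj)] <- TRUE
  truth <- truth | t(truth)
  attributable <- truth
  if (attribution == "leakage" && nrow(gt) > 0) {
    cm <- coarse_book(study$book)$mixing
    b <- (cm > support_tol) | diag(p) > 0
    # edge (a,b) attributable if a ~ ci and b ~ cj (either pairing)
    attributable <- (b %*% truth %*% t(b)) > 0
    diag(attributable) <- FALSE
  }
  ret <- switch(sign,
                all = g$retained,
                positive = g$retained & g$sign > 0,
                negative = g$retained & g$sign < 0)
  tv <- ut_vec(truth); rv <- ut_vec(ret); av <- ut_vec(attributable)
  list(sensitivity = if (sum(tv) > 0) sum(tv & rv) / sum(tv) else NA_real_,
       false_edge_rate = if (sum(rv) > 0) sum(rv & !av) / sum(rv) else 0,
       n_true = sum(tv), n_retained = sum(rv),
       n_attributable_retained = sum(rv & av))
}
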