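#' Top-k edge mask from a group-average connectome
#'
#' Selects the `k` largest entries of a group-average (retention minus
#' baseline) edge vector among the tested edges; ties at the cut are broken by
#' lexicographic (i, j) order. The same mask is then applied to every subject
#' and trial (the study default is k = 1000 on the full parcellation).
#'
#' @param group_avg Numeric edge vector (upper-triangular order) of
#'   group-average corrected iPLV.
#' @param k Mask size (<= number of tested edges).
#' @param tested Optional logical vector of testable edges (default: all).
#' @return Integer vector of `k` edge indices, sorted ascending.
#' @export
build_mask <- function(group_avg, k, tested = NULL) {
  if (is.null(tested)) tested <- rep(TRUE, length(group_avg))
  idx <- which(tested)
  if (k > length(idx)) stop("mask size exceeds tested edge count", call. = FALSE)
  o <- idx[order(-group_avg[idx], idx)]
  sort(o[seq_len(k)])
}

#' Masked single-trial feature vectors
#'
#' Applies an edge mask to single-trial synchronization vectors (or passes
#' amplitude vectors through unchanged) and attaches the labels the classifier
#' needs.
#'
#' @param values Matrix trials x edges (single-trial iPLV) or trials x parcels
#'   (amplitudes).
#' @param labels Condition label per trial.
#' @param mask Integer edge indices from [build_mask()], or NULL for the
#'   amplitude path (all columns kept).
#' @param window Window tag carried through for bookkeeping.
#' @return Object of class `trial_features`: list with `x`, `y`, `window`.
#' @export
featurize <- function(values, labels, mask = NULL, window = NA_character_) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(labels))
  x <- if (is.null(mask)) values else values[, mask, drop = FALSE]
  structure(list(x = x, y = factor(labels), window = window),
            class = "trial_features")
}

#' Random-forest decoding with trial-level cross-validation
#'
#' Trains a random forest on single-trial feature vectors and estimates
#' accuracy by cross-validation at the trial level: exact leave-one-trial-out
#' (`cv = "loocv"`), or the stratified k-fold approximation (`cv = "kfold"`,
#' default k = 20) that preserves the retention-versus-baseline contrast at a
#' fraction of the cost.
#'
#' @param tf A `trial_features` object (>= 2 trials per class).
#' @param cv `"kfold"` or `"loocv"`.
#' @param k Number of folds for `cv = "kfold"`.
#' @param num_trees Trees per forest (default 500).
#' @param mtry Features per split (default: square root of the feature count).
#' @param seed Integer seed; predictions are deterministic given the seed.
#' @return List with `accuracy`, `predictions` (per trial), `y`.
#' @export
rf_loocv <- function(tf, cv = c("kfold", "loocv"), k = 20L, num_trees = 500L,
                     mtry = NULL, seed = 1L) {
  stopifnot(inherits(tf, "trial_features"))
  cv <- match.arg(cv)
  y <- tf$y
  if (nlevels(droplevels(y)) < 2) stop("need at least 2 classes", call. = FALSE)
  if (any(table(y) < 2)) stop("need >= 2 trials per class", call. = FALSE)
  n <- length(y)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(tf$x))))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(child_seed(seed, 53L))

  folds <- if (cv == "loocv") seq_len(n) else {
    # stratified assignment: cycle folds within each class
    f <- integer(n)
    for (cl in levels(y)) {
      ix <- sample(which(y == cl))
      f[ix] <- rep_len(seq_len(min(k, length(ix))), length(ix))
    }
    f
  }
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  df <- data.frame(y = y, tf$x)
  for (fd in sort(unique(folds))) {
    test <- folds == fd
    fit <- ranger::ranger(y ~ ., data = df[!test, , drop = FALSE],
                          num.trees = num_trees, mtry = mtry,
                          seed = child_seed(seed, 100L + fd),
                          num.threads = 1, verbose = FALSE)
    pred[test] <- stats::predict(fit, df[test, , drop = FALSE],
                                 num.threads = 1)$predictions
  }
  list(accuracy = mean(pred == y), predictions = pred, y = y)
}

#' Retention-versus-baseline decoding contrast
#'
#' Per-subject accuracy difference (retention minus baseline) at each
#' frequency, with a group two-tailed Wilcoxon signed-rank test against zero.
#'
#' @param acc_retention,acc_baseline Matrices subjects x frequencies of
#'   decoding accuracies.
#' @param freqs Frequency labels (default: column index).
#' @return Data frame with columns frequency, mean_delta, p.
#' @export
retention_vs_baseline <- function(acc_retention, acc_baseline, freqs = NULL) {
  acc_retention <- as.matrix(acc_retention)
  acc_baseline <- as.matrix(acc_baseline)
  stopifnot(identical(dim(acc_retention), dim(acc_baseline)))
  if (is.null(freqs)) freqs <- seq_len(ncol(acc_retention))
  d <- acc_retention - acc_baseline
  p <- apply(d, 2, function(x) {
    if (all(x == 0)) 1 else
      suppressWarnings(stats::wilcox.test(x, mu = 0)$p.value)
  })
  data.frame(frequency = freqs, mean_delta = colMeans(d), p = p)
}
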