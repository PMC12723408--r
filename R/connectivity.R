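#' Edge matrix container
#'
#' A symmetric parcel-by-parcel matrix of synchronization weights with the
#' metadata needed for safe baseline correction (subject, frequency, condition,
#' window, load).
#'
#' @param weights Symmetric numeric matrix, zero diagonal.
#' @param subject,frequency,condition,window,load Metadata fields.
#' @return Object of class `edge_matrix` (the matrix, with a `meta` attribute).
#' @export
edge_matrix <- function(weights, subject = NA, frequency = NA,
                        condition = NA, window = NA, load = NA) {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  if (max(abs(weights - t(weights))) > 1e-10) {
    stop("edge matrix must be symmetric", call. = FALSE)
  }
  diag(weights) <- 0
  structure(weights, meta = list(subject = subject, frequency = frequency,
                                 condition = condition, window = window,
                                 load = load),
            class = c("edge_matrix", "matrix", "array"))
}

#' @export
print.edge_matrix <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("edge_matrix: %d x %d  [subject %s, %s Hz, %s, %s window]\n",
              nrow(x), ncol(x), m$subject, format(m$frequency), m$condition,
              m$window))
  cat(sprintf("  weight range: [%.4f, %.4f]\n", min(x), max(x)))
  invisible(x)
}

# unit phasors, parcels x pooled-samples, for a trial set and sample set
.pooled_phasors <- function(nb, s, trials) {
  z <- nb$z[trials, , s, drop = FALSE]
  # -> parcels x (trial, sample)
  u <- matrix(aperm(z, c(2, 1, 3)), dim(z)[2], dim(z)[1] * dim(z)[3])
  mod <- Mod(u)
  mod[mod == 0] <- 1
  u / mod
}

#' Pooled iPLV connectome
#'
#' For each parcel pair, the absolute imaginary part of the mean complex phase
#' difference exponential, pooled over the valid samples of the window and
#' across the given trials: `iPLV_ij = | Im( mean e^{i(phi_i - phi_j)} ) |`.
#' The iPLV is insensitive to zero-lag interactions, so instantaneous linear
#' leakage between parcels produces no spurious raw coupling.
#'
#' @param nb A `narrowband_epochs` object.
#' @param window One of `"baseline"`, `"early"`, `"late"`.
#' @param trials Trial indices to pool over (default: all).
#' @param condition Convenience filter: pool over trials of this condition.
#' @param samples Optional explicit output-sample indices (e.g. from
#'   [matched_window_samples()] to equalize the estimator's small-sample bias
#'   across windows); defaults to all valid samples of `window`.
#' @return An `edge_matrix` with raw iPLV weights in `[0, 1]`.
#' @export
iplv_pooled <- function(nb, window, trials = NULL, condition = NULL,
                        samples = NULL) {
  stopifnot(inherits(nb, "narrowband_epochs"))
  if (is.null(trials)) trials <- seq_len(dim(nb$z)[1])
  if (!is.null(condition)) trials <- trials[nb$condition[trials] == condition]
  if (length(trials) < 1) stop("trial set is empty", call. = FALSE)
  if (is.null(samples)) samples <- .window_samples(nb, window)
  if (length(samples) < 1) {
    stop(sprintf("window '%s' has no valid samples at f0 = %.2f Hz",
                 window, nb$f0), call. = FALSE)
  }
  u <- .pooled_phasors(nb, samples, trials)
  if (ncol(u) < 2) stop("need at least 2 pooled samples", call. = FALSE)
  c_mat <- (u %*% Conj(t(u))) / ncol(u)
  w <- abs(Im(c_mat))
  w <- (w + t(w)) / 2
  edge_matrix(w, subject = nb$subject, frequency = nb$f0,
              condition = if (is.null(condition)) "all" else condition,
              window = window)
}

#' Single-trial iPLV edge vector
#'
#' Same estimator as [iplv_pooled()] but pooled over the within-trial time
#' points of one trial only; returns the upper-triangular edge vector of
#' length `P(P-1)/2`.
#'
#' @param nb A `narrowband_epochs` object.
#' @param window Analysis window name.
#' @param trial Single trial index.
#' @param samples Optional explicit sample indices (see [iplv_pooled()]).
#' @return Numeric vector of per-edge iPLV values.
#' @export
iplv_single_trial <- function(nb, window, trial, samples = NULL) {
  stopifnot(length(trial) == 1)
  if (is.null(samples)) samples <- .window_samples(nb, window)
  if (length(samples) < 1) {
    stop(sprintf("window '%s' has no valid samples at f0 = %.2f Hz",
                 window, nb$f0), call. = FALSE)
  }
  u <- .pooled_phasors(nb, samples, trial)
  if (ncol(u) < 2) stop("trial has fewer than 2 valid window samples", call. = FALSE)
  c_mat <- (u %*% Conj(t(u))) / ncol(u)
  ut_vec(abs(Im(c_mat)))
}

#' Single-trial iPLV for all trials
#'
#' Vectorized convenience wrapper: one row per trial, one column per edge.
#'
#' @inheritParams iplv_single_trial
#' @param trials Trial indices (default all).
#' @return Matrix trials x edges.
#' @export
iplv_single_trial_all <- function(nb, window, trials = NULL, samples = NULL) {
  if (is.null(trials)) trials <- seq_len(dim(nb$z)[1])
  s <- if (is.null(samples)) .window_samples(nb, window) else samples
  if (length(s) < 2) {
    stop(sprintf("window '%s' has fewer than 2 valid samples at f0 = %.2f Hz",
                 window, nb$f0), call. = FALSE)
  }
  p <- dim(nb$z)[2]
  out <- matrix(0, length(trials), p * (p - 1) / 2)
  for (k in seq_along(trials)) {
    u <- nb$z[trials[k], , s]
    mod <- Mod(u); mod[mod == 0] <- 1
    u <- u / mod
    c_mat <- (u %*% Conj(t(u))) / length(s)
    out[k, ] <- ut_vec(abs(Im(c_mat)))
  }
  out
}

#' Baseline-correct retention estimates
#'
#' Elementwise retention minus baseline. Metadata must match except for the
#' window. When `early` and `late` are both supplied they are first averaged
#' into a single retention estimate.
#'
#' @param retention An `edge_matrix` (or the average of early/late, see
#'   `late`), or a numeric vector/matrix of amplitudes.
#' @param baseline Matching baseline estimate.
#' @param late Optional second retention-window `edge_matrix` to average with
#'   `retention` before subtraction.
#' @return Corrected values with the same shape; for edge matrices an
#'   `edge_matrix` with window `"retention-baseline"`.
#' @export
baseline_correct <- function(retention, baseline, late = NULL) {
  if (inherits(retention, "edge_matrix")) {
    if (!is.null(late)) {
      .check_meta(retention, late, except = "window")
      retention <- edge_matrix((unclass(retention) + unclass(late)) / 2,
                               subject = attr(retention, "meta")$subject,
                               frequency = attr(retention, "meta")$frequency,
                               condition = attr(retention, "meta")$condition,
                               window = "retention")
    }
    .check_meta(retention, baseline, except = "window")
    m <- attr(retention, "meta")
    return(edge_matrix(unclass(retention) - unclass(baseline),
                       subject = m$subject, frequency = m$frequency,
                       condition = m$condition, window = "retention-baseline"))
  }
  if (!identical(dim(retention), dim(baseline)) &&
      length(retention) != length(baseline)) {
    stop("retention and baseline shapes differ", call. = FALSE)
  }
  if (!is.null(late)) retention <- (retention + late) / 2
  retention - baseline
}

.check_meta <- function(a, b, except = character(0)) {
  ma <- attr(a, "meta"); mb <- attr(b, "meta")
  keys <- setdiff(names(ma), except)
  for (k in keys) {
    if (!identical(ma[[k]], mb[[k]])) {
      stop(sprintf("metadata mismatch on '%s'", k), call. = FALSE)
    }
  }
  if (!identical(dim(a), dim(b))) stop("shape mismatch", call. = FALSE)
  invisible(TRUE)
}

#' Collapse an edge matrix to the coarse parcellation
#'
#' Each coarse edge (A, B), A != B, is the unweighted mean of the fine edges
#' between the members of A and the members of B (four fine edges under the
#' 2-to-1 map); the diagonal is zero.
#'
#' @param m An `edge_matrix` (or plain symmetric matrix) on fine parcels.
#' @param book The `parcel_book` defining the coarse map.
#' @return An `edge_matrix` on coarse parcels with the same metadata.
#' @export
collapse_parcellation <- function(m, book) {
  stopifnot(nrow(m) == book$n_fine)
  s <- .collapse_operator(book)
  w <- s %*% unclass(m) %*% t(s)
  w <- (w + t(w)) / 2
  meta <- attr(m, "meta")
  if (is.null(meta)) meta <- list(subject = NA, frequency = NA, condition = NA,
                                  window = NA, load = NA)
  edge_matrix(w, subject = meta$subject, frequency = meta$frequency,
              condition = meta$condition, window = meta$window,
              load = meta$load)
}
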