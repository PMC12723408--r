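#' Simulate a trial-epoched multi-parcel study
#'
#' Generates the synthetic stand-in for a delayed match-to-sample working
#' memory study: for each subject, trial-epoched parcel time series at 600 Hz
#' spanning -0.7 s to +2.0 s around the sample stimulus, with three conditions
#' (Shape, Color, Location) and two memory loads. Each parcel signal is the sum
#' of planted narrowband carriers (pairs phase-coupled through von Mises
#' jittered phase differences at a fixed lag, gated by the edge's condition and
#' window scope) and independent 1/f background noise, then left-multiplied by
#' the book's zero-lag leakage mixing matrix.
#'
#' Subject epochs are materialized lazily and deterministically: the returned
#' study object is light-weight, and [get_epochs()] regenerates any subject's
#' data from per-subject seeds derived from `seed`, independent of call order.
#'
#' @param book A `parcel_book`.
#' @param design A `coupling_design`.
#' @param n_subjects Number of subjects.
#' @param n_trials Trials per condition (each subject has `3 * n_trials`).
#' @param seed Integer seed.
#' @param fs Sampling rate (Hz), default 600.
#' @param t_range Epoch range in seconds relative to the sample stimulus.
#' @return Object of class `sim_study` with the study layout, per-trial
#'   condition and load labels, and `ground_truth` edge lists per condition.
#' @export
simulate_dataset <- function(book, design, n_subjects = 12L, n_trials = 120L,
                             seed = 1L, fs = 600, t_range = c(-0.7, 2.0)) {
  stopifnot(inherits(book, "parcel_book"), inherits(design, "coupling_design"))
  e <- design$edges
  if (nrow(e) > 0) {
    if (any(e$freq >= fs / 2)) {
      stop("carrier frequencies must be below the Nyquist rate fs/2", call. = FALSE)
    }
    if (any(e$i < 1 | e$i > book$n_fine | e$j < 1 | e$j > book$n_fine)) {
      stop("planted edge references unknown parcel", call. = FALSE)
    }
  }
  n_s <- round(diff(t_range) * fs)
  tt <- t_range[1] + (seq_len(n_s) - 1) / fs
  cond <- rep(c("Shape", "Color", "Location"), each = n_trials)
  load <- rep(rep(c(2L, 4L), length.out = n_trials), times = 3)
  structure(list(
    book = book, design = design,
    n_subjects = as.integer(n_subjects), n_trials = as.integer(n_trials),
    fs = fs, t = tt, condition = cond, load = load,
    seed = as.integer(seed),
    ground_truth = ground_truth_edges(design, book)
  ), class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("sim_study:", x$n_subjects, "subjects x", length(x$condition),
      "trials x", x$book$n_fine, "parcels x", length(x$t), "samples @",
      x$fs, "Hz\n")
  cat("  planted edges:", nrow(x$design$edges), "\n")
  invisible(x)
}

#' Materialize one subject's raw epochs
#'
#' @param study A `sim_study`.
#' @param subject Subject index in `1..n_subjects`.
#' @return Object of class `raw_epochs`: list with `data` (trials x parcels x
#'   samples), `condition`, `load`, `subject`, `fs`, and `t` (seconds relative
#'   to the sample stimulus).
#' @export
get_epochs <- function(study, subject) {
  stopifnot(inherits(study, "sim_study"),
            subject >= 1, subject <= study$n_subjects)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(child_seed(study$seed, 1000L + subject))

  book <- study$book
  p <- book$n_fine
  n_s <- length(study$t)
  n_tr <- length(study$condition)
  gain <- rep_len(study$design$subject_gain, study$n_subjects)[subject]

  x <- .pink_noise(n_tr, p, n_s, study$design$noise_exponent)
  e <- study$design$edges
  if (nrow(e) > 0) {
    for (k in seq_len(nrow(e))) {
      ek <- e[k, ]
      in_scope <- study$condition %in%
        strsplit(as.character(ek$conditions), ",")[[1]]
      gate_on <- .window_gate(study$t,
                              strsplit(as.character(ek$windows), ",")[[1]],
                              study$fs)
      # Both endpoints oscillate in every trial and window at constant
      # amplitude; the gate crossfades parcel j between an independent phase
      # walk and one locked to parcel i (lag + von Mises jitter), and is
      # active only in the edge's window scope and condition scope. Only the
      # phase *coupling* is window- and condition-dependent, so all windows
      # and conditions share the same single-parcel signal structure and
      # baseline subtraction isolates coupling changes.
      hold <- max(1L, round(study$fs * 5 / (2 * pi * ek$freq)))
      dstep <- sqrt(study$design$phase_diffusion / study$fs)
      fj <- study$design$freq_jitter
      for (tr in seq_len(n_tr)) {
        gate <- if (in_scope[tr]) gate_on else 0
        f_tr <- ek$freq + stats::rnorm(1, 0, fj)
        ramp <- 2 * pi * f_tr * study$t
        th_i <- ramp + stats::runif(1, 0, 2 * pi) +
          cumsum(stats::rnorm(n_s, 0, dstep))
        th_free <- ramp + stats::runif(1, 0, 2 * pi) +
          cumsum(stats::rnorm(n_s, 0, dstep))
        # phase jitter sampled at wavelet-scale knots and linearly
        # interpolated (a zero-order hold would add broadband splatter)
        n_hold <- ceiling(n_s / hold) + 1L
        knots <- rvonmises(n_hold, 0, ek$kappa)
        eta <- stats::approx(x = seq(0, by = hold, length.out = n_hold),
                             y = knots, xout = seq_len(n_s) - 1L)$y
        a_i <- exp(stats::rnorm(1, 0, 0.25))
        a_j <- exp(stats::rnorm(1, 0, 0.25))
        x[tr, ek$i, ] <- x[tr, ek$i, ] + ek$amp * gain * a_i * cos(th_i)
        x[tr, ek$j, ] <- x[tr, ek$j, ] + ek$amp * gain * a_j *
          (gate * cos(th_i - ek$lag + eta) + (1 - gate) * cos(th_free))
      }
    }
  }
  # zero-lag leakage: left-multiply every time point by the mixing matrix
  if (!isTRUE(all.equal(book$mixing, diag(p), check.attributes = FALSE))) {
    for (tr in seq_len(n_tr)) {
      x[tr, , ] <- book$mixing %*% x[tr, , ]
    }
  }
  structure(list(data = x, condition = study$condition, load = study$load,
                 subject = as.integer(subject), fs = study$fs, t = study$t),
            class = "raw_epochs")
}

# 1/f^a Gaussian noise, unit variance per parcel/trial, via FFT shaping.
# Generated in trial chunks to bound memory.
.pink_noise <- function(n_tr, p, n_s, exponent) {
  freqs <- c(1, seq_len(n_s - 1))            # avoid the DC singularity
  f_idx <- pmin(freqs, n_s - freqs + 1)      # two-sided spectrum
  shape <- 1 / f_idx^(exponent / 2)
  shape[1] <- 0
  # expected per-sample variance of the shaped series (scalar normalization)
  norm <- sqrt(sum(shape^2) / n_s)
  chunk <- max(1L, floor(4e6 / n_s))
  starts <- seq(1L, n_tr * p, by = chunk)
  flat <- matrix(0, n_s, n_tr * p)
  for (s0 in starts) {
    cols <- s0:min(s0 + chunk - 1L, n_tr * p)
    w <- matrix(stats::rnorm(n_s * length(cols)), n_s, length(cols))
    z <- stats::mvfft(w) * shape
    flat[, cols] <- Re(stats::mvfft(z, inverse = TRUE)) / (n_s * norm)
  }
  # columns enumerate (trial, parcel) with trial fastest
  out <- aperm(array(flat, dim = c(n_s, n_tr, p)), c(2, 3, 1))
  out
}

# smooth activation gate over the union of named windows (50 ms cosine ramps)
.window_gate <- function(tt, windows, fs, ramp = 0.05) {
  spans <- analysis_windows()[windows]
  g <- numeric(length(tt))
  for (w in spans) {
    lo <- w[1]; hi <- w[2]
    g <- pmax(g, ifelse(tt < lo - ramp | tt > hi + ramp, 0,
                 ifelse(tt < lo, 0.5 + 0.5 * cos(pi * (lo - tt) / ramp),
                 ifelse(tt > hi, 0.5 + 0.5 * cos(pi * (tt - hi) / ramp), 1))))
  }
  g
}

#' Analysis time windows
#'
#' The three analysis windows relative to the sample stimulus: baseline
#' (-0.7 to -0.1 s), early retention (0.6 to 1.2 s) and late retention
#' (1.2 to 1.8 s).
#'
#' @return Named list of `c(start, end)` pairs in seconds.
#' @export
analysis_windows <- function() {
  list(baseline = c(-0.7, -0.1), early = c(0.6, 1.2), late = c(1.2, 1.8))
}

#' Generate a behavioral table with known gain dependence
#'
#' Hit rates are an affine function of the per-subject coupling gain plus
#' Gaussian noise, clipped to [0, 1]; with `noise_sd = 0` and positive slope
#' the sample Pearson correlation between HR and gain is exactly 1 (within a
#' condition and load, absent clipping). Reaction times decrease weakly with
#' gain. This gives the edge-level behavioral correlation stage a ground truth.
#'
#' @param subject_gain Per-subject coupling gains.
#' @param slope HR change per unit gain.
#' @param noise_sd Standard deviation of the HR noise (>= 0).
#' @param base Baseline hit rate.
#' @param seed Integer seed.
#' @return Data frame with columns subject, condition, load, HR, RT.
#' @export
make_behavior <- function(subject_gain, slope = 0.1, noise_sd = 0.02,
                          base = 0.75, seed = 1L) {
  stopifnot(noise_sd >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(child_seed(seed, 77L))
  n <- length(subject_gain)
  grid <- expand.grid(subject = seq_len(n),
                      condition = c("Shape", "Color", "Location"),
                      load = c(2L, 4L), stringsAsFactors = FALSE)
  cond_off <- c(Shape = -0.03, Color = 0.01, Location = 0)
  g <- subject_gain[grid$subject]
  hr <- base + slope * g + cond_off[grid$condition] -
    0.04 * (grid$load == 4L) + stats::rnorm(nrow(grid), 0, noise_sd)
  rt <- 0.55 + 0.05 * (grid$load == 4L) - 0.05 * (g - 1) +
    stats::rnorm(nrow(grid), 0, noise_sd / 2)
  grid$HR <- pmin(1, pmax(0, hr))
  grid$RT <- pmax(0.2, rt)
  grid
}
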