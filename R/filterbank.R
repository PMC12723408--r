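#' Build a Morlet filterbank
#'
#' Center frequencies are geometrically (log-linearly) spaced between `f_min`
#' and `f_max`. Each wavelet is a complex Morlet with time-frequency compromise
#' parameter `m`: the temporal Gaussian has standard deviation
#' `sigma_t = m / (2 pi f0)`, giving a relative spectral bandwidth of about
#' `1/m`. The study default is 38 wavelets from 3 to 120 Hz with `m = 5`.
#'
#' @param n_wavelets Number of wavelets.
#' @param f_min,f_max Frequency range in Hz (`f_min < f_max`).
#' @param m Time-frequency compromise parameter (> 0).
#' @return Object of class `filterbank`: list with `freqs`, `m`.
#' @export
build_filterbank <- function(n_wavelets = 38L, f_min = 3, f_max = 120, m = 5) {
  stopifnot(m > 0, n_wavelets >= 1)
  if (f_min >= f_max) stop("f_min must be below f_max", call. = FALSE)
  freqs <- if (n_wavelets == 1) f_min else
    exp(seq(log(f_min), log(f_max), length.out = n_wavelets))
  structure(list(freqs = freqs, m = m), class = "filterbank")
}

# Discrete complex Morlet wavelet at sampling rate fs, truncated at +-3 sigma,
# scaled so a real sinusoid of amplitude a at f0 yields analytic magnitude a.
.morlet <- function(f0, fs, m) {
  sigma <- m / (2 * pi * f0)
  half <- ceiling(3 * sigma * fs)
  tw <- (-half:half) / fs
  w <- exp(2i * pi * f0 * tw) * exp(-tw^2 / (2 * sigma^2))
  # response of conv(w, x) to x = exp(2 pi i f0 t) is sum_k w_k e^{-2 pi i f0 k/fs}
  gain <- abs(sum(w * exp(-2i * pi * f0 * tw)))
  list(w = 2 * w / gain, half = half, sigma = sigma)
}

#' Filter raw epochs into complex narrowband analytic signals
#'
#' Convolves every trial and parcel with a complex Morlet wavelet at `f0`
#' (FFT convolution with zero padding), flags samples within the truncated
#' wavelet half-support of either epoch edge as contaminated, and decimates to
#' an output rate of five times the center frequency by nearest-index
#' selection.
#'
#' @param raw A `raw_epochs` object.
#' @param f0 Wavelet center frequency (Hz); `raw$fs` must be at least 2.5 x f0.
#' @param m Time-frequency compromise parameter.
#' @param out_rate_factor Output sampling rate as a multiple of `f0`.
#' @return Object of class `narrowband_epochs`: complex array `z`
#'   (trials x parcels x output samples), `f0`, `fs_out`, `t` (output sample
#'   times relative to the sample stimulus), `valid` (logical per output
#'   sample, FALSE where edge-contaminated), plus trial metadata.
#' @export
filter_epochs <- function(raw, f0, m = 5, out_rate_factor = 5) {
  stopifnot(inherits(raw, "raw_epochs"))
  if (raw$fs < 2.5 * f0) stop("sampling rate below 2.5 x center frequency", call. = FALSE)
  n_s <- dim(raw$data)[3]
  wv <- .morlet(f0, raw$fs, m)
  if (2 * wv$half + 1 > n_s) stop("epoch shorter than wavelet support", call. = FALSE)

  n_tr <- dim(raw$data)[1]
  p <- dim(raw$data)[2]
  nfft <- stats::nextn(n_s + 2 * wv$half, c(2, 3, 5))
  wf <- stats::fft(c(wv$w, rep(0, nfft - length(wv$w))))

  fs_out <- out_rate_factor * f0
  dur <- (n_s - 1) / raw$fs
  n_out <- floor(dur * fs_out) + 1L
  # nearest raw-sample index for each output time
  out_t <- (seq_len(n_out) - 1) / fs_out
  idx <- pmin(n_s, round(out_t * raw$fs) + 1L)

  z <- array(0i, dim = c(n_tr, p, n_out))
  flat <- matrix(aperm(raw$data, c(3, 1, 2)), n_s, n_tr * p)
  chunk <- max(1L, floor(4e6 / nfft))
  for (s0 in seq(1L, ncol(flat), by = chunk)) {
    cols <- s0:min(s0 + chunk - 1L, ncol(flat))
    xpad <- rbind(flat[, cols, drop = FALSE],
                  matrix(0, nfft - n_s, length(cols)))
    y <- stats::mvfft(stats::mvfft(xpad) * wf, inverse = TRUE) / nfft
    # "same" alignment: convolution output sample n + half corresponds to input n
    y <- y[wv$half + seq_len(n_s), , drop = FALSE]
    z[cbind(rep((cols - 1L) %% n_tr + 1L, each = n_out),
            rep((cols - 1L) %/% n_tr + 1L, each = n_out),
            rep(seq_len(n_out), times = length(cols)))] <- as.vector(y[idx, ])
  }
  valid <- idx > wv$half & idx <= n_s - wv$half
  structure(list(z = z, f0 = f0, fs_out = fs_out, m = m,
                 t = raw$t[idx], valid = valid,
                 condition = raw$condition, load = raw$load,
                 subject = raw$subject),
            class = "narrowband_epochs")
}

#' @export
print.narrowband_epochs <- function(x, ...) {
  d <- dim(x$z)
  cat(sprintf("narrowband_epochs: f0 = %.2f Hz, %d trials x %d parcels x %d samples @ %.1f Hz (%d valid)\n",
              x$f0, d[1], d[2], d[3], x$fs_out, sum(x$valid)))
  invisible(x)
}

# indices of valid output samples inside a named analysis window
.window_samples <- function(nb, window) {
  w <- analysis_windows()[[match.arg(window, names(analysis_windows()))]]
  which(nb$t >= w[1] & nb$t < w[2] & nb$valid)
}

#' Bias-matched window sample sets
#'
#' The raw iPLV magnitude `|Im<e^{i dphi}>|` has a positive small-sample bias
#' that shrinks with the number of pooled samples, so windows with different
#' valid-sample counts (edge flagging removes more of the baseline window than
#' of the retention windows) would acquire a spurious offset after baseline
#' subtraction. This helper trims every window to the same number of
#' contiguous valid samples (the minimum across windows, keeping the native
#' sampling interval) so the bias cancels in baseline-corrected values.
#'
#' @param nb A `narrowband_epochs` object.
#' @param windows Window names to match (default: all three).
#' @return Named list of equal-length sample index vectors.
#' @export
matched_window_samples <- function(nb, windows = names(analysis_windows())) {
  idx <- lapply(windows, function(w) .window_samples(nb, w))
  names(idx) <- windows
  n <- vapply(idx, length, integer(1))
  if (any(n == 0)) {
    stop(sprintf("window '%s' has no valid samples at f0 = %.2f Hz",
                 windows[which(n == 0)[1]], nb$f0), call. = FALSE)
  }
  lapply(idx, function(s) s[seq_len(min(n))])
}

#' Mean oscillation amplitude in a time window
#'
#' Mean of the analytic-signal magnitude over the valid samples of a window,
#' per parcel; optionally per trial (single-trial amplitude vectors for the
#' decoding stage).
#'
#' @param nb A `narrowband_epochs` object.
#' @param window One of `"baseline"`, `"early"`, `"late"`.
#' @param trials Trial indices (default: all trials).
#' @param per_trial If TRUE return a trials x parcels matrix instead of the
#'   trial-pooled parcel vector.
#' @return Numeric vector (parcels) or matrix (trials x parcels).
#' @export
window_amplitude <- function(nb, window, trials = NULL, per_trial = FALSE) {
  stopifnot(inherits(nb, "narrowband_epochs"))
  if (is.null(trials)) trials <- seq_len(dim(nb$z)[1])
  if (!length(trials)) stop("trial set is empty", call. = FALSE)
  s <- .window_samples(nb, window)
  if (!length(s)) {
    stop(sprintf("window '%s' has no valid samples at f0 = %.2f Hz", window, nb$f0),
         call. = FALSE)
  }
  a <- abs(nb$z[trials, , s, drop = FALSE])
  if (per_trial) apply(a, c(1, 2), mean) else apply(a, 2, mean)
}
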