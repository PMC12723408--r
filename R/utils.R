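#' Upper-triangular edge indexing
#'
#' Connectomes are symmetric parcel-by-parcel matrices; most statistics act on
#' the vector of unordered parcel pairs. These helpers map between the two.
#'
#' @param p Number of parcels (nodes).
#' @return `edge_pairs()` returns a two-column integer matrix with one row per
#'   unordered pair (i < j), in column-major upper-triangle order.
#' @export
edge_pairs <- function(p) {
  stopifnot(p >= 2)
  j <- rep.int(seq_len(p), pmax(seq_len(p) - 1L, 0L))
  i <- sequence(pmax(seq_len(p) - 1L, 0L))
  cbind(i = i, j = j)
}

#' @rdname edge_pairs
#' @param m Symmetric matrix.
#' @return `ut_vec()` returns the upper-triangular entries of `m` as a vector.
#' @export
ut_vec <- function(m) m[upper.tri(m)]

#' @rdname edge_pairs
#' @param v Vector of length `p * (p - 1) / 2`.
#' @return `ut_mat()` rebuilds the symmetric matrix (zero diagonal) from `v`.
#' @export
ut_mat <- function(v, p) {
  m <- matrix(0, p, p)
  m[upper.tri(m)] <- v
  m + t(m)
}

# Derive a reproducible child seed (kept below 2^31) from a base seed and an
# integer stream index, so per-subject simulation is order-independent.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 1009 * as.double(stream)) %% 2147483629) + 1L
}

#' Draw from a von Mises distribution
#'
#' Best–Fisher rejection sampler. Used for the phase jitter of planted
#' couplings; with concentration `kappa` the expected phase-locking value of
#' the jittered pair is the Bessel ratio `I1(kappa)/I0(kappa)`.
#'
#' @param n Number of draws.
#' @param mu Mean direction (radians).
#' @param kappa Concentration (>= 0); 0 gives the uniform distribution.
#' @return Numeric vector of angles in (-pi, pi] shifted by `mu`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0, n >= 0)
  if (n == 0) return(numeric(0))
  if (kappa < 1e-9) return(((stats::runif(n, -pi, pi) + mu + pi) %% (2 * pi)) - pi)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0) {
      out[got + seq_len(k)] <- sign(u3[ok] - 0.5) * acos(f[ok])
      got <- got + k
    }
  }
  ((out + mu + pi) %% (2 * pi)) - pi
}

#' Expected phase-locking value under von Mises phase jitter
#'
#' Closed form `I1(kappa)/I0(kappa)`; with a phase lag strictly between 0 and
#' pi the same quantity bounds the iPLV from above (and equals it at lag pi/2).
#'
#' @param kappa Concentration parameter(s).
#' @return Expected PLV in `[0, 1)`.
#' @export
plv_vonmises <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}
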