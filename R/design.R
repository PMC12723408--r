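#' Specify planted phase couplings for the synthetic study
#'
#' A coupling design lists the narrowband edges planted in the synthetic data:
#' each edge couples two fine parcels at a carrier frequency with a fixed phase
#' lag, von Mises phase jitter of concentration `kappa`, and is active only in
#' the listed task conditions and time windows. Edges active only in the
#' baseline window model retention-period desynchronization (coupling that is
#' suppressed during memory maintenance).
#'
#' @param edges Data frame with columns `i`, `j` (fine parcel indices),
#'   `freq` (carrier, Hz), `lag` (radians, must lie strictly inside (0, pi)
#'   for a detectable edge since the iPLV is blind to 0 and pi lags), `kappa`
#'   (von Mises concentration, >= 0), `amp` (carrier amplitude relative to the
#'   unit-variance background noise), `conditions` (comma-joined subset of
#'   Shape,Color,Location) and `windows` (comma-joined subset of
#'   baseline,early,late).
#' @param subject_gain Per-subject multiplicative coupling gain (length is the
#'   number of subjects the design is simulated for, recycled if shorter).
#' @param noise_exponent Spectral exponent of the 1/f^a background noise.
#' @param phase_diffusion Brownian phase-diffusion coefficient of each carrier
#'   (rad^2/s). Oscillators drift in phase so that *independent* carriers at
#'   the same frequency decorrelate within a trial (their finite-trial
#'   phase-locking would otherwise masquerade as coupling); a coupled pair
#'   shares its carrier's diffusion, so planted coupling is unaffected.
#' @param freq_jitter Per-trial standard deviation of each carrier's frequency
#'   (Hz), modelling the cycle-to-cycle variability of neural rhythms; shared
#'   by a coupled pair.
#' @return Object of class `coupling_design`.
#' @export
coupling_design <- function(edges, subject_gain = 1, noise_exponent = 1,
                            phase_diffusion = 5, freq_jitter = 0.5) {
  need <- c("i", "j", "freq", "lag", "kappa", "amp", "conditions", "windows")
  if (!all(need %in% names(edges))) {
    stop("edges must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(edges) > 0) {
    if (any(edges$kappa < 0)) stop("kappa must be >= 0", call. = FALSE)
    if (any(edges$lag <= 0 | edges$lag >= pi)) {
      stop("phase lag must lie strictly in (0, pi)", call. = FALSE)
    }
    cs <- strsplit(as.character(edges$conditions), ",", fixed = TRUE)
    if (any(lengths(cs) == 0) ||
        !all(unlist(cs) %in% c("Shape", "Color", "Location"))) {
      stop("conditions must be a nonempty subset of Shape,Color,Location",
           call. = FALSE)
    }
    ws <- strsplit(as.character(edges$windows), ",", fixed = TRUE)
    if (!all(unlist(ws) %in% c("baseline", "early", "late"))) {
      stop("windows must be a subset of baseline,early,late", call. = FALSE)
    }
  }
  structure(list(edges = edges, subject_gain = subject_gain,
                 noise_exponent = noise_exponent,
                 phase_diffusion = phase_diffusion,
                 freq_jitter = freq_jitter),
            class = "coupling_design")
}

#' Default planted-coupling design for a parcel book
#'
#' Mirrors the topology the analysis is designed to resolve:
#' condition-specific alpha-carrier couplings inside the condition-relevant
#' visual subdivisions (Shape -> LOC, Color -> V4V8, Location -> Dorsal),
#' shared alpha couplings among dorsal-attention / fronto-parietal parcels
#' (active in all three conditions), and theta-carrier couplings active only
#' at baseline (i.e. suppressed during retention). Planted endpoints avoid
#' low-fidelity parcels and never share a coarse parcel.
#'
#' @param book A `parcel_book`.
#' @param n_subjects Number of subjects the design will serve (sets the length
#'   of `subject_gain`).
#' @param alpha_freq,theta_freq Carrier frequencies (Hz).
#' @param kappa Phase-jitter concentration of planted couplings.
#' @param amp Carrier amplitude relative to unit-variance background noise.
#' @param n_specific Condition-specific edges per condition.
#' @param n_shared Shared edges (all three conditions).
#' @param n_theta Baseline-only theta edges.
#' @param gain_sd Log-sd of the lognormal per-subject coupling gain.
#' @param seed Seed for endpoint sampling and gains.
#' @return A `coupling_design`.
#' @export
default_design <- function(book, n_subjects = 12L, alpha_freq = 12,
                           theta_freq = 7, kappa = 6, amp = 1,
                           n_specific = 2L, n_shared = 8L, n_theta = 3L,
                           gain_sd = 0.2, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(child_seed(seed, 23L))

  good <- which(book$fidelity >= 0.165)
  pick_pairs <- function(pool, n) {
    pool <- intersect(pool, good)
    # eligible pairs: different coarse parcels, not immediate layout neighbors
    elig <- NULL
    if (length(pool) >= 2) {
      cmb <- utils::combn(sort(pool), 2)
      ok <- book$coarse_map[cmb[1, ]] != book$coarse_map[cmb[2, ]] &
        abs(cmb[1, ] - cmb[2, ]) > 1
      elig <- cmb[, ok, drop = FALSE]
    }
    if (is.null(elig) || ncol(elig) < 1) {
      stop("not enough eligible parcels for design", call. = FALSE)
    }
    # prefer endpoint-disjoint pairs; fall back to endpoint reuse
    best <- matrix(integer(0), 0, 2)
    for (try in 1:50) {
      ord <- sample(ncol(elig))
      pairs <- matrix(integer(0), 0, 2)
      used <- integer(0)
      for (k in ord) {
        a <- elig[1, k]; b <- elig[2, k]
        if (a %in% used || b %in% used) next
        pairs <- rbind(pairs, c(a, b))
        used <- c(used, a, b)
        if (nrow(pairs) >= n) break
      }
      if (nrow(pairs) > nrow(best)) best <- pairs
      if (nrow(best) >= n) break
    }
    while (nrow(best) < n && ncol(elig) > nrow(best)) {
      have <- apply(elig, 2, function(pr)
        any(apply(best, 1, function(x) all(x == pr))))
      extra <- which(!have)[1]
      if (is.na(extra)) break
      best <- rbind(best, elig[, extra])
    }
    if (nrow(best) < n) stop("not enough eligible parcels for design", call. = FALSE)
    best[seq_len(n), , drop = FALSE]
  }

  sub_pool <- function(s) which(book$visual_subdivision == s)
  specific <- list(Shape = "LOC", Color = "V4V8", Location = "Dorsal")
  used_visual <- integer(0)
  rows <- list()
  for (cond in names(specific)) {
    pool <- sub_pool(specific[[cond]])
    # widen to the unused remainder of the visual system when low-fidelity
    # parcels leave the subdivision too small for the requested edge count
    if (length(intersect(pool, good)) < 2 * n_specific) {
      pool <- union(pool, setdiff(which(book$system == "Visual"), used_visual))
    }
    pr <- pick_pairs(pool, n_specific)
    used_visual <- c(used_visual, as.vector(pr))
    rows[[cond]] <- data.frame(i = pr[, 1], j = pr[, 2], freq = alpha_freq,
                               lag = pi / 2, kappa = kappa, amp = amp,
                               conditions = cond, windows = "early,late")
  }
  fp_pool <- which(book$system %in% c("DAN", "FPN"))
  pr <- pick_pairs(fp_pool, n_shared)
  rows$shared <- data.frame(i = pr[, 1], j = pr[, 2], freq = alpha_freq,
                            lag = pi / 2, kappa = kappa, amp = amp,
                            conditions = "Shape,Color,Location",
                            windows = "early,late")
  th_pool <- which(book$system %in% c("VAN", "DMN"))
  pr <- pick_pairs(th_pool, n_theta)
  rows$theta <- data.frame(i = pr[, 1], j = pr[, 2], freq = theta_freq,
                           lag = pi / 2, kappa = kappa, amp = amp,
                           conditions = "Shape,Color,Location",
                           windows = "baseline")
  gains <- exp(stats::rnorm(n_subjects, 0, gain_sd))
  coupling_design(do.call(rbind, rows), subject_gain = gains)
}

#' Ground-truth edge lists of a design
#'
#' @param design A `coupling_design`.
#' @param book The `parcel_book` the design refers to.
#' @return Data frame with one row per (edge, condition): fine endpoints,
#'   coarse endpoints, carrier, windows, and a `scope` column
#'   (`shared` if the edge is active in all three conditions, else `specific`).
#' @export
ground_truth_edges <- function(design, book) {
  e <- design$edges
  if (nrow(e) == 0) {
    return(data.frame(i = integer(0), j = integer(0), ci = integer(0),
                      cj = integer(0), freq = numeric(0),
                      condition = character(0), windows = character(0),
                      scope = character(0)))
  }
  conds <- strsplit(as.character(e$conditions), ",", fixed = TRUE)
  n_rep <- lengths(conds)
  out <- data.frame(
    i = rep(e$i, n_rep), j = rep(e$j, n_rep),
    ci = book$coarse_map[rep(e$i, n_rep)],
    cj = book$coarse_map[rep(e$j, n_rep)],
    freq = rep(e$freq, n_rep),
    condition = unlist(conds),
    windows = rep(as.character(e$windows), n_rep),
    scope = rep(ifelse(n_rep == 3, "shared", "specific"), n_rep)
  )
  sw <- pmin(out$ci, out$cj); out$cj <- pmax(out$ci, out$cj); out$ci <- sw
  out
}
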