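test_that("iPLV is blind to zero lag and maximal at quadrature", {
  n <- 500
  base <- cumsum(rnorm(n, 0.4, 0.3))
  nb0 <- nb_from_phases(rbind(base, base))
  expect_equal(iplv_pooled(nb0, "early")[1, 2], 0, tolerance = 1e-12)
  nbq <- nb_from_phases(rbind(base, base - pi / 2))
  expect_equal(iplv_pooled(nbq, "early")[1, 2], 1, tolerance = 1e-12)
})

test_that("pooled iPLV at von Mises coupling matches the Bessel ratio", {
  set.seed(11)
  n <- 1e5
  base <- runif(n, 0, 2 * pi)
  for (kap in c(0.5, 2)) {
    dphi <- rvonmises(n, pi / 2, kap)
    nb <- nb_from_phases(rbind(base, base - dphi))
    got <- iplv_pooled(nb, "early")[1, 2]
    expect_equal(got, plv_vonmises(kap), tolerance = 0.01)
  }
})

test_that("null iPLV at n pooled samples matches a Monte-Carlo oracle", {
  set.seed(12)
  n <- 1000
  oracle <- vapply(1:400, function(b) {
    abs(mean(sin(runif(n, 0, 2 * pi))))
  }, numeric(1))
  got <- vapply(1:400, function(b) {
    nb <- nb_from_phases(rbind(runif(n, 0, 2 * pi), runif(n, 0, 2 * pi)))
    iplv_pooled(nb, "early")[1, 2]
  }, numeric(1))
  expect_lt(abs(mean(got) - mean(oracle)), 0.15 * mean(oracle))
  # theoretical mean of |N(0, 1/(2n))| = sqrt(1/(pi * n))
  expect_lt(abs(mean(got) - sqrt(1 / (pi * n))), 0.1 * mean(got))
})

test_that("single-trial iPLV equals the pooled estimator on one trial", {
  fx <- tiny_study()
  nb <- fx$nb
  v1 <- iplv_single_trial(nb, "early", trial = 5)
  m1 <- iplv_pooled(nb, "early", trials = 5)
  expect_equal(v1, ut_vec(unclass(m1)), tolerance = 1e-12)
  # brute-force per-trial oracle, bit-exact
  s <- oscnet:::.window_samples(nb, "early")
  z <- nb$z[5, , s]
  u <- z / Mod(z)
  p <- nrow(u)
  want <- matrix(0, p, p)
  for (a in 1:(p - 1)) for (b in (a + 1):p) {
    want[a, b] <- abs(Im(mean(u[a, ] * Conj(u[b, ]))))
  }
  expect_equal(v1, ut_vec(want + t(want)), tolerance = 1e-12)
  # vectorized all-trials variant agrees
  allm <- iplv_single_trial_all(nb, "early", trials = c(5, 6))
  expect_equal(allm[1, ], v1, tolerance = 1e-12)
})

test_that("iPLV <= PLV <= 1 and trial order does not matter", {
  fx <- tiny_study()
  nb <- fx$nb
  s <- oscnet:::.window_samples(nb, "early")
  u <- oscnet:::.pooled_phasors(nb, s, 1:30)
  plv <- abs((u %*% Conj(t(u))) / ncol(u))
  ip <- unclass(iplv_pooled(nb, "early", trials = 1:30))
  expect_true(all(ip <= ut_mat(ut_vec(plv), nrow(ip)) + 1e-12))
  expect_true(all(ip >= 0 & ip <= 1))
  ip_perm <- unclass(iplv_pooled(nb, "early", trials = sample(1:30)))
  expect_equal(ip, ip_perm, tolerance = 1e-12)
})

test_that("baseline correction subtracts elementwise and checks metadata", {
  w1 <- ut_mat(runif(15, 0, 0.6), 6)
  w2 <- ut_mat(runif(15, 0, 0.6), 6)
  ret <- edge_matrix(w1, subject = 1, frequency = 10, condition = "Shape",
                     window = "early")
  lat <- edge_matrix(w2, subject = 1, frequency = 10, condition = "Shape",
                     window = "late")
  bas <- edge_matrix(w2, subject = 1, frequency = 10, condition = "Shape",
                     window = "baseline")
  corr <- baseline_correct(ret, bas, late = lat)
  expect_equal(unclass(corr), (w1 + w2) / 2 - w2, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(abs(unclass(corr)) <= 1))
  same <- baseline_correct(ret, edge_matrix(w1, 1, 10, "Shape", "baseline"))
  expect_true(all(unclass(same) == 0))
  other <- edge_matrix(w2, subject = 2, frequency = 10, condition = "Shape",
                       window = "baseline")
  expect_error(baseline_correct(ret, other), "mismatch")
})

test_that("planted retention edge is positive after correction, nulls near 0", {
  fx <- tiny_study()
  nb <- fx$nb
  ws <- matched_window_samples(nb)
  b <- iplv_pooled(nb, "baseline", condition = "Shape", samples = ws$baseline)
  e <- iplv_pooled(nb, "early", condition = "Shape", samples = ws$early)
  l <- iplv_pooled(nb, "late", condition = "Shape", samples = ws$late)
  corr <- baseline_correct(e, b, late = l)
  expect_gt(corr[1, 7], 0.3)
  cm <- unclass(corr)
  cm[1, 7] <- NA; cm[7, 1] <- NA
  expect_lt(abs(median(ut_vec(cm), na.rm = TRUE)), 0.05)
})

test_that("coarse collapse averages the four fine edges", {
  b <- make_parcel_book(8, seed = 1, locality = 0)
  w <- matrix(0.3, 8, 8); diag(w) <- 0
  em <- edge_matrix(w, 1, 10, "Shape", "early")
  cc <- collapse_parcellation(em, b)
  expect_equal(nrow(cc), 4)
  expect_true(all(abs(ut_vec(unclass(cc)) - 0.3) < 1e-12))
  # explicit four-edge average
  w2 <- matrix(0, 8, 8)
  w2[1, 3] <- 0.1; w2[1, 4] <- 0.2; w2[2, 3] <- 0.3; w2[2, 4] <- 0.4
  w2 <- w2 + t(w2)
  cc2 <- collapse_parcellation(edge_matrix(w2, 1, 10, "Shape", "early"), b)
  expect_equal(cc2[1, 2], 0.25, tolerance = 1e-12)
  # collapse commutes with baseline correction
  wb <- ut_mat(runif(28, 0, 0.5), 8)
  wr <- ut_mat(runif(28, 0, 0.5), 8)
  emb <- edge_matrix(wb, 1, 10, "Shape", "baseline")
  emr <- edge_matrix(wr, 1, 10, "Shape", "early")
  a1 <- collapse_parcellation(baseline_correct(emr, emb), b)
  a2 <- baseline_correct(collapse_parcellation(emr, b),
                         collapse_parcellation(emb, b))
  expect_equal(unclass(a1), unclass(a2), tolerance = 1e-12)
})

test_that("zero-lag mixtures stay below the independent null floor", {
  # two parcels as zero-lag mixtures of common sources, one valid sample per
  # trial pooled across trials (independent across trials)
  set.seed(13)
  n_tr <- 200
  # analytic signals: common narrowband source mixed with zero lag
  phi_s <- runif(n_tr, 0, 2 * pi)
  z1 <- 0.8 * exp(1i * phi_s) + 0.2 * exp(1i * runif(n_tr, 0, 2 * pi))
  z2 <- 0.7 * exp(1i * phi_s) + 0.3 * exp(1i * runif(n_tr, 0, 2 * pi))
  ip_mixed <- abs(Im(mean(z1 / Mod(z1) * Conj(z2 / Mod(z2)))))
  null_draws <- vapply(1:500, function(b) {
    za <- exp(1i * runif(n_tr, 0, 2 * pi))
    zb <- exp(1i * runif(n_tr, 0, 2 * pi))
    abs(Im(mean(za * Conj(zb))))
  }, numeric(1))
  expect_lt(ip_mixed, quantile(null_draws, 0.95))
})
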