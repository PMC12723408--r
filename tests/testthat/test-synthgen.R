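test_that("parcel book satisfies its structural invariants", {
  b <- make_parcel_book(n_fine = 20, seed = 7, locality = 0.02)
  expect_equal(max(abs(rowSums(b$mixing) - 1)), 0, tolerance = 1e-12)
  expect_true(all(b$mixing >= 0))
  # symmetric support
  expect_equal(unname(b$mixing > 0), unname(t(b$mixing) > 0))
  # 2 -> 1 coarse map: 10 targets, each with exactly 2 sources
  expect_equal(max(b$coarse_map), 10)
  expect_true(all(tabulate(b$coarse_map) == 2))
  expect_true(all(b$fidelity > 0 & b$fidelity <= 1))
  expect_equal(diag(b$mixing), b$fidelity)
  # every Visual parcel has a subdivision
  vis <- b$system == "Visual"
  expect_true(all(b$visual_subdivision[vis] != "none"))
  expect_true(all(b$visual_subdivision[!vis] == "none"))
  # deterministic under seed
  b2 <- make_parcel_book(n_fine = 20, seed = 7, locality = 0.02)
  expect_identical(b$mixing, b2$mixing)
  expect_error(make_parcel_book(n_fine = 3), "even")
})

test_that("locality -> 0 yields identity mixing", {
  b <- make_parcel_book(20, seed = 1, locality = 0)
  expect_identical(b$mixing, diag(20))
  b2 <- make_parcel_book(20, seed = 1, locality = 1e-6)
  expect_equal(b2$mixing, diag(diag(b2$mixing)), tolerance = 1e-10)
})

test_that("configurable fraction of parcels falls below the fidelity cut", {
  b <- make_parcel_book(400, seed = 2, frac_low_fidelity = 0.065)
  expect_equal(sum(b$fidelity < 0.165), round(0.065 * 400))
  b0 <- make_parcel_book(100, seed = 2, frac_low_fidelity = 0)
  expect_equal(sum(b0$fidelity < 0.165), 0)
})

test_that("von Mises sampler matches the Bessel-ratio resultant", {
  set.seed(4)
  for (kap in c(0.5, 2, 8)) {
    th <- rvonmises(2e4, pi / 2, kap)
    r <- abs(mean(exp(1i * th)))
    expect_equal(r, plv_vonmises(kap), tolerance = 0.02)
    expect_equal(Arg(mean(exp(1i * th))), pi / 2, tolerance = 0.05)
  }
  expect_equal(abs(mean(exp(1i * rvonmises(2e4, 0, 0)))), 0, tolerance = 0.03)
})

test_that("simulator validates its inputs", {
  b <- make_parcel_book(12, seed = 1)
  bad <- coupling_design(
    data.frame(i = 1, j = 99, freq = 10, lag = pi / 2, kappa = 1, amp = 1,
               conditions = "Shape", windows = "early"))
  expect_error(simulate_dataset(b, bad, 2, 10, 1), "unknown parcel")
  fast <- coupling_design(
    data.frame(i = 1, j = 2, freq = 400, lag = pi / 2, kappa = 1, amp = 1,
               conditions = "Shape", windows = "early"))
  expect_error(simulate_dataset(b, fast, 2, 10, 1), "Nyquist")
  expect_error(coupling_design(
    data.frame(i = 1, j = 2, freq = 10, lag = 0, kappa = 1, amp = 1,
               conditions = "Shape", windows = "early")), "lag")
  expect_error(coupling_design(
    data.frame(i = 1, j = 2, freq = 10, lag = 1, kappa = 1, amp = 1,
               conditions = "Taste", windows = "early")), "conditions")
})

test_that("epochs are reproducible, finite, and correctly shaped", {
  fx <- tiny_study()
  raw <- fx$raw
  expect_s3_class(raw, "raw_epochs")
  expect_equal(dim(raw$data), c(90, 12, 1620))
  expect_false(anyNA(raw$data))
  expect_true(all(apply(raw$data[1:5, , ], 1:2, stats::var) > 0))
  raw2 <- get_epochs(fx$study, 1)
  expect_identical(raw$data, raw2$data)
  expect_equal(sort(unique(raw$condition)), c("Color", "Location", "Shape"))
  expect_equal(sort(unique(raw$load)), c(2L, 4L))
})

test_that("mixing preserves per-row variance bounds (row-stochasticity)", {
  b <- make_parcel_book(12, seed = 3, locality = 0.05)
  des <- coupling_design(
    data.frame(i = integer(0), j = integer(0), freq = numeric(0),
               lag = numeric(0), kappa = numeric(0), amp = numeric(0),
               conditions = character(0), windows = character(0)))
  st <- simulate_dataset(b, des, n_subjects = 1, n_trials = 4, seed = 3)
  raw <- get_epochs(st, 1)
  # reconstruct unmixed trial and compare variances
  v_mixed <- apply(raw$data[1, , ], 1, stats::var)
  # mixed variance cannot exceed the max input variance by much more than
  # row-stochastic averaging of ~unit-variance inputs allows
  expect_true(all(v_mixed < 1.5))
  expect_true(all(v_mixed > 0.1))
})

test_that("behavioral table has the designed gain dependence", {
  g <- seq(0.8, 1.2, length.out = 12)
  bh <- make_behavior(g, slope = 0.1, noise_sd = 0, seed = 1)
  expect_true(all(bh$HR >= 0 & bh$HR <= 1))
  expect_true(all(bh$RT > 0))
  one <- bh[bh$condition == "Shape" & bh$load == 2, ]
  expect_equal(cor(one$HR[order(one$subject)], g), 1, tolerance = 1e-12)
  # slope 0: no expected correlation (check it is small over replicates)
  rs <- vapply(1:50, function(s) {
    b0 <- make_behavior(g, slope = 0, noise_sd = 0.02, seed = s)
    o <- b0[b0$condition == "Shape" & b0$load == 2, ]
    cor(o$HR[order(o$subject)], g)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.15)
  # Monte-Carlo: empirical r distribution matches direct simulation oracle
  oracle <- vapply(1:300, function(s) {
    set.seed(s)
    hr <- 0.75 + 0.1 * g + rnorm(12, 0, 0.02)
    cor(hr, g)
  }, numeric(1))
  ours <- vapply(1:300, function(s) {
    b1 <- make_behavior(g, slope = 0.1, noise_sd = 0.02, seed = s)
    o <- b1[b1$condition == "Location" & b1$load == 2, ]
    cor(o$HR[order(o$subject)], g)
  }, numeric(1))
  expect_lt(abs(mean(ours) - mean(oracle)), 0.06)
  expect_lt(abs(sd(ours) - sd(oracle)), 0.5 * sd(oracle))
})

test_that("ground-truth serialization round-trips losslessly", {
  fx <- tiny_study()
  gt <- fx$study$ground_truth
  path <- tempfile(fileext = ".json")
  write_ground_truth(gt, path)
  back <- read_ground_truth(path)
  expect_equal(back, gt)
  unlink(path)
})

test_that("parcel book and hyperedge sets write as plain text", {
  b <- make_parcel_book(8, seed = 1, locality = 0.02)
  stem <- tempfile()
  paths <- write_parcel_book(b, stem)
  tab <- read.delim(paste0(stem, "_parcels.tsv"))
  expect_equal(nrow(tab), 8)
  expect_equal(tab$fidelity, b$fidelity, tolerance = 1e-12)
  mix <- as.matrix(read.delim(paste0(stem, "_mixing.tsv"), header = FALSE))
  expect_equal(unname(mix), b$mixing, tolerance = 1e-12)
  unlink(paste0(stem, c("_parcels.tsv", "_mixing.tsv")))
})
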