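test_that("edge exclusion follows the fidelity and radius rules", {
  # identity mixing, perfect fidelity: nothing excluded
  b <- make_parcel_book(10, seed = 1, locality = 0, frac_low_fidelity = 0)
  b$fidelity[] <- 1; b$mixing <- diag(10)
  m <- exclude_edges(b, level = "fine")
  expect_equal(m$fraction_excluded, 0)
  expect_false(any(diag(m$retained)))
  # one low-fidelity parcel removes exactly its 9 incident edges
  b2 <- b
  b2$fidelity[4] <- 0.1
  m2 <- exclude_edges(b2, level = "fine")
  expect_equal(unname(m2$reasons["low_fidelity"]), 9)
  expect_true(all(!m2$retained[4, -4]))
  expect_true(all(m2$retained[-4, -4] | diag(9) > 0))
  # defaults are the study thresholds
  expect_equal(formals(exclude_edges)$fidelity_min, 0.165)
  expect_equal(formals(exclude_edges)$radius_max, 0.35)
  # strong leakage (broad kernel, low fidelity) triggers radius exclusions
  b3 <- make_parcel_book(20, seed = 2, locality = 0.12,
                         fidelity_range = c(0.3, 0.45), frac_low_fidelity = 0)
  m3 <- exclude_edges(b3, level = "fine")
  expect_gt(unname(m3$reasons["large_radius"]), 0)
  expect_equal(m3$retained, t(m3$retained))
})

test_that("union graph combines retained supports and mean weights", {
  g1 <- random_stat_graph(8, 0.3, seed = 61)
  g2 <- random_stat_graph(8, 0.3, seed = 62)
  g3 <- random_stat_graph(8, 0.3, seed = 63)
  un <- build_union(list(Shape = g1, Color = g2, Location = g3))
  sup <- un$weights != 0
  expect_equal(ut_vec(sup),
               ut_vec(g1$retained | g2$retained | g3$retained))
  # union density >= each condition's density
  expect_gte(sum(ut_vec(sup)), max(sum(ut_vec(g1$retained)),
                                   sum(ut_vec(g2$retained)),
                                   sum(ut_vec(g3$retained))))
  # identical graphs: union equals each input, all edges 3-condition members
  un2 <- build_union(list(Shape = g1, Color = g1, Location = g1))
  expect_equal(un2$weights, abs(g1$weights), ignore_attr = TRUE)
  nmem <- apply(un2$membership, c(1, 2), sum)
  expect_true(all(nmem[g1$retained] == 3))
  # disjoint graphs: union density = sum of densities
  w1 <- matrix(0, 8, 8); w1[1, 2] <- 0.3; w1 <- w1 + t(w1)
  w2 <- matrix(0, 8, 8); w2[5, 6] <- 0.4; w2 <- w2 + t(w2)
  t8 <- matrix(TRUE, 8, 8) & !diag(8)
  gg1 <- stat_graph(w1, sign(w1), ifelse(w1 != 0, 0.01, NA) * 1, t8, 12)
  gg2 <- stat_graph(w2, sign(w2), ifelse(w2 != 0, 0.01, NA) * 1, t8, 12)
  un3 <- build_union(list(Shape = gg1, Color = gg2))
  expect_equal(sum(ut_vec(un3$weights != 0)), 2)
  # mean-over-members weight: edge in 1 condition keeps its strength
  expect_equal(un3$weights[1, 2], 0.3)
})

test_that("bundling respects mixing structure", {
  t8 <- matrix(TRUE, 8, 8) & !diag(8)
  w <- matrix(0, 8, 8)
  w[1, 5] <- 0.3; w[2, 5] <- 0.2; w[1, 6] <- 0.25  # a smeared clump
  w[3, 8] <- 0.4                                    # an isolated edge
  w <- w + t(w)
  g <- stat_graph(w, sign(w), ifelse(w != 0, 0.01, NA) * 1, t8, 12)
  un <- build_union(list(Shape = g, Color = g, Location = g))
  # identity mixing: every edge its own bundle
  hs_id <- bundle_hyperedges(un, diag(8))
  expect_equal(nrow(hs_id$bundles), 4)
  expect_true(all(hs_id$bundles$size == 1))
  # local mixing around parcels 1-2 and 5-6 bundles the clump, not the far edge
  mix <- diag(8) * 0.8
  mix[1, 2] <- mix[2, 1] <- 0.2
  mix[5, 6] <- mix[6, 5] <- 0.2
  mix <- mix / rowSums(mix)
  hs <- bundle_hyperedges(un, mix, cutoff = 0.2, min_size = 2)
  cl <- hs$edges$bundle
  key <- paste(hs$edges$i, hs$edges$j)
  clump <- cl[key %in% c("1 5", "2 5", "1 6")]
  expect_equal(length(unique(clump)), 1)
  expect_false(cl[key == "3 8"] %in% clump)
  # partition property
  expect_equal(sum(hs$bundles$size), 4)
  # empty union
  w0 <- matrix(0, 8, 8)
  g0 <- stat_graph(w0, w0, w0 * NA, t8, 12)
  hs0 <- bundle_hyperedges(build_union(list(Shape = g0, Color = g0)), diag(8))
  expect_equal(nrow(hs0$edges), 0)
})

test_that("participation classification follows the worked arithmetic", {
  mk_hs <- function(nmat, sizes) {
    bundles <- data.frame(bundle = seq_len(nrow(nmat)), size = sizes)
    bundles <- cbind(bundles, as.data.frame(nmat))
    bundles$label <- "unclassified"
    structure(list(
      edges = data.frame(i = integer(0), j = integer(0), bundle = integer(0)),
      bundles = bundles, cutoff = 0.25, min_size = 3L),
      class = "hyperedge_set")
  }
  k_eq <- c(Shape = 0.02, Color = 0.02, Location = 0.02)
  # n = (8,1,1), equal densities -> p = (0.8, 0.1, 0.1) -> Shape-specific
  hs <- mk_hs(matrix(c(8, 1, 1), 1, dimnames = list(NULL, names(k_eq))), 10)
  out <- classify_hyperedges(hs, k_eq, threshold = 0.3)
  expect_equal(out$bundles$p_Shape, 0.8, tolerance = 1e-12)
  expect_equal(out$bundles$p_Color, 0.1, tolerance = 1e-12)
  expect_equal(out$bundles$label, "Shape")
  # n = (4,4,4) -> p = (1/3, 1/3, 1/3), all above 0.3 -> shared
  hs2 <- mk_hs(matrix(c(4, 4, 4), 1, dimnames = list(NULL, names(k_eq))), 4)
  expect_equal(classify_hyperedges(hs2, k_eq, 0.3)$bundles$label, "shared")
  # single-condition bundle -> that condition
  hs3 <- mk_hs(matrix(c(0, 5, 0), 1, dimnames = list(NULL, names(k_eq))), 5)
  expect_equal(classify_hyperedges(hs3, k_eq, 0.3)$bundles$label, "Color")
  # density normalization: the rare condition's edges weigh more, so a bundle
  # with n = (5,2,5) under K = (0.10, 0.01, 0.10) has p = (1/6, 2/3, 1/6)
  # and only Color clears the threshold -> Color-specific
  k_un <- c(Shape = 0.10, Color = 0.01, Location = 0.10)
  hs4 <- mk_hs(matrix(c(5, 2, 5), 1, dimnames = list(NULL, names(k_un))), 12)
  out4 <- classify_hyperedges(hs4, k_un, 0.3)
  expect_equal(out4$bundles$label, "Color")
  expect_equal(out4$bundles$p_Color, 2 / 3, tolerance = 1e-12)
  expect_gt(out4$bundles$p_Color, out4$bundles$p_Shape)
  # exact tie at the threshold counts as exceeding (shared-favoring)
  k3 <- c(Shape = 0.05, Color = 0.05, Location = 0.05)
  hs5 <- mk_hs(matrix(c(3, 3, 4), 1, dimnames = list(NULL, names(k3))), 10)
  out5 <- classify_hyperedges(hs5, k3, threshold = 0.3)
  expect_equal(out5$bundles$label, "shared")
  # small bundles stay discarded
  hs6 <- mk_hs(matrix(c(2, 0, 0), 1, dimnames = list(NULL, names(k3))), 2)
  expect_equal(classify_hyperedges(hs6, k3, 0.3)$bundles$label,
               "discarded_small")
  # raising the threshold never increases the number of shared bundles
  set.seed(64)
  nmat <- matrix(rpois(60, 3), 20, 3, dimnames = list(NULL, names(k3)))
  hs7 <- mk_hs(nmat, rowSums(nmat))
  n_shared <- vapply(c(0.2, 0.3, 0.4, 0.45), function(th) {
    sum(classify_hyperedges(hs7, k3, th)$bundles$label == "shared")
  }, numeric(1))
  expect_true(all(diff(n_shared) <= 0))
})

test_that("shared fractions are label proportions over classified edges", {
  bundles <- data.frame(bundle = 1:4, size = c(6, 3, 1, 3),
                        Shape = c(2, 3, 1, 0), Color = c(2, 0, 0, 0),
                        Location = c(2, 0, 0, 3),
                        label = c("shared", "Shape", "discarded_small",
                                  "Location"))
  hs <- structure(list(edges = NULL, bundles = bundles, min_size = 3L),
                  class = "hyperedge_set")
  fr <- shared_fraction(hs)
  expect_equal(sum(fr), 1)
  expect_equal(unname(fr["shared"]), 6 / 12)
  expect_equal(unname(fr["Shape"]), 3 / 12)
})
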