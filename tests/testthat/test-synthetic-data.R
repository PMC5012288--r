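test_that("growth simulator: exponential and degenerate limits are exact", {
  g <- simulate_growth_curve(0.69, 1e4, noise_cv = 0, lag_h = 0,
                             sample_interval_h = 24, duration_h = 48)
  expect_equal(g$value, 1e4 * exp(0.69 * c(0, 1, 2)))
  g0 <- simulate_growth_curve(0, 1e4, noise_cv = 0)
  expect_true(all(g0$value == 1e4))
  # lag holds density constant, then growth resumes
  gl <- simulate_growth_curve(1, 100, lag_h = 48, noise_cv = 0)
  expect_equal(gl$value[1:3], rep(100, 3))
  expect_equal(gl$value[4], 100 * exp(1))
  # logistic saturation approaches the carrying capacity from below
  gk <- simulate_growth_curve(1.5, 100, carrying_capacity = 1e4,
                              noise_cv = 0, duration_h = 400)
  expect_true(all(diff(gk$value) >= 0))
  expect_true(all(gk$value <= 1e4))
  expect_gt(max(gk$value), 0.99e4)
  expect_error(simulate_growth_curve(-1, 10), "non-negative")
  expect_error(simulate_growth_curve(1, 0), "positive")
  expect_error(simulate_growth_curve(1, 10, carrying_capacity = 5), ">=")
  expect_error(simulate_growth_curve(1, 10, duration_h = 24), "3 samples")
})

test_that("simulators are byte-identical under a fixed seed", {
  expect_identical(simulate_growth_curve(1, 10, noise_cv = 0.2, seed = 5),
                   simulate_growth_curve(1, 10, noise_cv = 0.2, seed = 5))
  expect_identical(simulate_fame_profiles(3, 2, seed = 5),
                   simulate_fame_profiles(3, 2, seed = 5))
  expect_identical(simulate_dose_response(1, 0.3, noise_cv = 0.1, seed = 5),
                   simulate_dose_response(1, 0.3, noise_cv = 0.1, seed = 5))
  a <- simulate_alignment(5, 100, 0.1, gap_column_fraction = 0.1, seed = 5)
  b <- simulate_alignment(5, 100, 0.1, gap_column_fraction = 0.1, seed = 5)
  expect_identical(a$alignment, b$alignment)
  expect_equal(ape::write.tree(a$tree), ape::write.tree(b$tree))
})

test_that("noise and densities respect their physical domains", {
  g <- simulate_growth_curve(0.7, 1e3, noise_cv = 0.5, seed = 31)
  expect_true(all(g$value > 0))
  sim <- simulate_fame_profiles(4, 3, within_phylotype_sd = 0.4, seed = 31)
  expect_true(all(sim$profiles >= 0))
  expect_equal(unname(rowSums(sim$profiles)), rep(100, 12), tolerance = 1e-9)
})

test_that("fame simulator: sd = 0 clones the phylotype base profile", {
  sim <- simulate_fame_profiles(2, 3, within_phylotype_sd = 0, seed = 11)
  for (k in 1:2) {
    block <- sim$profiles[sim$phylotype == k, ]
    expect_equal(max(apply(block, 2, function(x) diff(range(x)))), 0)
  }
  expect_error(simulate_fame_profiles(2, 2, species_pool = character(0)),
               "non-empty")
})

test_that("adding a strain does not reshuffle existing phylotype draws", {
  s2 <- simulate_fame_profiles(2, 2, within_phylotype_sd = 0.2, seed = 9)
  s3 <- simulate_fame_profiles(2, 3, within_phylotype_sd = 0.2, seed = 9)
  shared <- rownames(s2$profiles)
  expect_equal(s3$profiles[shared, ], s2$profiles[shared, ])
})

test_that("dose-response simulator honours the Hill mean and floor", {
  # noise-free at c = ec50 the rate is exactly mu0/2
  panel <- simulate_dose_response(0.9, 0.3,
                                  concentrations = c(0.1, 0.3, 1),
                                  noise_cv = 0, seed = 1)
  r <- analyze_panel(panel)
  expect_equal(r$mean_rate[r$concentration == 0.3], 0.45, tolerance = 1e-9)
  expect_equal(r$mean_rate[r$concentration == 0], 0.9, tolerance = 1e-9)
  # pre-noise means are non-increasing in concentration
  mu_c <- 0.9 / (1 + (c(0.1, 0.3, 1) / 0.3)^2)
  expect_true(all(diff(mu_c) < 0))
  # floor: concentrations with mean below 0.05 d^-1 stay flat
  p2 <- simulate_dose_response(1, 0.1, hill = 3,
                               concentrations = c(0.1, 3.2), seed = 2)
  top <- p2[p2$concentration == 3.2 & p2$replicate == 1, ]
  expect_equal(diff(range(top$fluorescence)), 0)
  expect_error(simulate_dose_response(1, 0.3, concentrations = c(1, 0.1)),
               "ascending")
})

test_that("alignment simulator: rate-0 limit, gap counts, duplicates", {
  s0 <- simulate_alignment(4, 200, 0, seed = 1)
  expect_equal(length(unique(apply(s0$alignment, 1, paste, collapse = ""))), 1)
  expect_true(all(as.matrix(pairwise_distance(s0$alignment)) == 0))
  # ~10% of 1000 columns contain a gap (binomial +- 3 sigma)
  sg <- simulate_alignment(6, 1000, 0.1, gap_column_fraction = 0.1, seed = 2)
  n_gap <- sum(apply(sg$alignment, 2, function(col) any(col == "-")))
  expect_gt(n_gap, 100 - 3 * sqrt(1000 * 0.1 * 0.9))
  expect_lt(n_gap, 100 + 3 * sqrt(1000 * 0.1 * 0.9))
  # duplicated tips appear in both alignment and tree
  sd <- simulate_alignment(5, 300, 0.1, phylotype_pairs = 2, seed = 3)
  dups <- grep("_dup$", rownames(sd$alignment), value = TRUE)
  expect_equal(length(dups), 2)
  expect_setequal(rownames(sd$alignment), sd$tree$tip.label)
  expect_error(simulate_alignment(2, 100, 0.1), "at least 3")
})

test_that("NJ recovers the generating topology from long simulated sequences", {
  sim <- simulate_alignment(8, 5000, 0.1, gap_column_fraction = 0.1,
                            seed = 11)
  cleaned <- clean_alignment(sim$alignment)
  tr <- neighbor_joining(pairwise_distance(cleaned$alignment))
  expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(sim$tree)), 0)
})
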