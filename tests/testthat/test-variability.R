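test_that("CV map equals sigma/mu and honours proportional and zero-variance cases", {
  atl <- tiny_atlas(2)
  res <- interindividual_cv(rmap(c(10, 20), atl),
                            rmap(c(2, 4), atl, "std"))
  expect_equal(unname(res$cv_map$values), c(0.2, 0.2))
  expect_true(all(res$retained))

  res0 <- interindividual_cv(rmap(c(10, 20), atl),
                             rmap(c(0, 0), atl, "std"))
  expect_equal(unname(res0$cv_map$values), c(0, 0))
})

test_that("low-binding filter applies the hand-derived 21-region rule", {
  # 21 regions: one at 0.05, twenty >= 1.0. The 5th percentile of the 21
  # means (linear interpolation) sits at the second-smallest value, so only
  # the 0.05 region is both in the bottom tail and below 0.1.
  atl <- cortex_atlas(21)
  mu <- c(0.05, seq(1.0, 2.9, by = 0.1))
  sg <- 0.1 * mu
  res <- interindividual_cv(rmap(mu, atl), rmap(sg, atl, "std"))
  expect_false(res$retained[1])
  expect_true(all(res$retained[-1]))
  expect_equal(unname(res$cv_map$values[-1]), rep(0.1, 20))
  expect_true(is.nan(res$cv_map$values[1]))
})

test_that("filter combine modes and monotonicity in the absolute threshold", {
  atl <- cortex_atlas(21)
  mu <- c(0.05, seq(1.0, 2.9, by = 0.1))
  sg <- 0.1 * mu
  mm <- rmap(mu, atl); sm <- rmap(sg, atl, "std")

  # OR omits anything below the absolute cut even outside the bottom tail
  pol_or <- filter_policy(combine = "or", absolute_threshold = 1.05)
  res_or <- interindividual_cv(mm, sm, pol_or)
  expect_identical(which(!res_or$retained), c(1L, 2L))

  # percentile_only ignores the absolute cut entirely; with 21 regions the
  # interpolated 5th percentile lands exactly on the second-smallest mean,
  # which the inclusive boundary also omits
  pol_p <- filter_policy(combine = "percentile_only", absolute_threshold = 99)
  res_p <- interindividual_cv(mm, sm, pol_p)
  expect_identical(which(!res_p$retained), c(1L, 2L))

  # raising absolute_threshold never un-omits a region
  thresholds <- c(0, 0.01, 0.1, 0.5, 1.5, 3)
  prev <- rep(FALSE, 21)
  for (th in thresholds) {
    om <- !interindividual_cv(mm, sm,
      filter_policy(absolute_threshold = th, combine = "or"))$retained
    expect_true(all(om | !prev))  # omitted set only grows
    prev <- om
  }
})

test_that("nonpositive retained means are invalidated with a warning, not an error", {
  # a percentile-only policy at the 0th percentile omits only the minimum,
  # so the second (still negative) mean survives the filter and must be
  # invalidated by the nonpositive-denominator guard instead
  atl <- cortex_atlas(21)
  mu <- c(-1, -0.5, seq(1, 2.8, by = 0.1))
  pol <- filter_policy(percentile_cut = 0, combine = "percentile_only")
  expect_warning(
    res <- interindividual_cv(rmap(mu, atl), rmap(abs(mu) * 0.1, atl, "std"),
                              pol),
    "nonpositive")
  expect_identical(which(!res$retained), c(1L, 2L))
  expect_true(all(res$retained[-(1:2)]))
})

test_that("inter-regional CV uses the n-1 convention per compartment", {
  atl <- cortex_atlas(3)
  expect_equal(interregional_cv(rmap(c(2, 4, 6), atl), "cortex"), 0.5)
  expect_equal(interregional_cv(rmap(c(3, 3, 3), atl), "cortex"), 0)

  one <- rmap(c(5, NaN, NaN), atl)
  expect_error(interregional_cv(one, "cortex"), ">= 2 valid")
  expect_error(interregional_cv(rmap(c(-2, -4, 6), atl), "cortex"),
               "unstable")

  # compartments are separated: subcortex values never leak into cortex
  mixed <- rmap(c(2, 4, 6, 100, 200), tiny_atlas(5))
  ctx <- mixed$regions$compartment == "cortex"
  expect_equal(interregional_cv(mixed, "cortex"),
               sd(mixed$values[ctx]) / mean(mixed$values[ctx]))
})

test_that("CV ratio is inter-regional over mean inter-individual CV", {
  atl <- cortex_atlas(2)
  expect_equal(cv_ratio(0.4, rmap(c(0.2, 0.2), atl, "cv")), 2)
  expect_equal(cv_ratio(0.2, rmap(c(0.1, 0.3), atl, "cv")), 1)
  expect_equal(cv_ratio(0.25, rmap(c(0.25, 0.25), atl, "cv")), 1)
  expect_error(cv_ratio(0.2, rmap(c(0, 0), atl, "cv")), "positive")
})

test_that("min-max scaling spans [0,1], passes masks through, rejects constants", {
  atl <- cortex_atlas(3)
  expect_equal(unname(minmax_scale(rmap(c(1, 2, 3), atl, "cv"))$values),
               c(0, 0.5, 1))
  got <- minmax_scale(rmap(c(5, NaN, 10), atl, "cv"))
  expect_equal(unname(got$values[c(1, 3)]), c(0, 1))
  expect_true(is.nan(got$values[2]))
  expect_error(minmax_scale(rmap(c(2, 2, 2), atl, "cv")), "degenerate")

  # invariance under positive affine transforms
  v <- withr::with_seed(4, runif(10, 1, 9))
  atl10 <- cortex_atlas(10)
  s1 <- minmax_scale(rmap(v, atl10, "cv"))$values
  s2 <- minmax_scale(rmap(3.7 * v + 11, atl10, "cv"))$values
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("scale invariance: (k*mu, k*sigma) leaves CV statistics unchanged", {
  # rescales that stay above the absolute low-binding cut (the 0.1 cut is
  # dimensioned in binding units and is not meant to be scale-free)
  atl <- default_atlas
  maps <- random_study_maps(atl, seed = 8)
  for (k in c(0.5, 1, 250)) {
    a <- interindividual_cv(maps$mean_map, maps$std_map)
    b <- interindividual_cv(
      regional_map(k * maps$mean_map$values, atl, "mean"),
      regional_map(k * maps$std_map$values, atl, "std"))
    expect_identical(a$retained, b$retained)
    expect_equal(a$cv_map$values, b$cv_map$values, tolerance = 1e-12)
    expect_equal(interregional_cv(maps$mean_map, "cortex"),
                 interregional_cv(regional_map(k * maps$mean_map$values,
                                               atl, "mean"), "cortex"),
                 tolerance = 1e-12)
  }
})

test_that("std-mean scaling recovers exact proportionality and power laws", {
  atl <- cortex_atlas(50)
  mu <- withr::with_seed(6, runif(50, 0.5, 5))
  prop <- std_mean_scaling(rmap(mu, atl), rmap(0.1 * mu, atl, "std"))
  expect_equal(prop$spearman_r, 1)
  expect_equal(prop$log_log_slope, 1, tolerance = 1e-10)

  quad <- std_mean_scaling(rmap(mu, atl), rmap(0.03 * mu^2, atl, "std"))
  expect_equal(quad$log_log_slope, 2, tolerance = 1e-10)

  expect_error(std_mean_scaling(rmap(c(1, 2, NaN), cortex_atlas(3)),
                                rmap(c(1, 2, 3), cortex_atlas(3), "std")),
               ">= 3 regions")
})

test_that("shuffled std is uncorrelated with the mean on large maps", {
  # null bound derived by simulation: the spread of Spearman r under
  # independent permutation of 100 values is ~1/sqrt(99); 1000 draws stay
  # well within |r| < 0.5
  atl <- cortex_atlas(100)
  mu <- withr::with_seed(13, runif(100, 0.5, 5))
  rs <- withr::with_seed(14, vapply(1:1000, function(i) {
    std_mean_scaling(rmap(mu, atl),
                     rmap(sample(0.1 * mu), atl, "std"))$spearman_r
  }, 0))
  expect_lt(max(abs(rs)), 0.5)
  expect_lt(abs(mean(rs)), 0.02)
})
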