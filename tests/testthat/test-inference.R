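test_that("bootstrap p matches the exhaustive enumeration oracle", {
  # oracle: enumerate all 27 equally likely ordered resamples of 3 values
  vals <- c(0.1, 0.2, 0.6)
  grid <- expand.grid(vals, vals, vals)
  exact <- mean(rowMeans(grid) >= 0.4)
  expect_equal(exact, 7 / 27)

  bt <- bootstrap_compare(vals, inter_regional = 0.4, n_boot = 200000,
                          seed = 1)
  expect_lt(abs(bt$p_value - exact), 0.005)
})

test_that("bootstrap degenerate thresholds give exact p = 1 and p = 0", {
  vals <- c(0.1, 0.2, 0.6)
  expect_identical(bootstrap_compare(vals, 0.05, n_boot = 10000,
                                     seed = 3)$p_value, 1)
  expect_identical(bootstrap_compare(vals, 0.7, n_boot = 10000,
                                     seed = 3)$p_value, 0)
})

test_that("bootstrap is seed-reproducible, monotone in threshold, compartment-aware", {
  atl <- tiny_atlas(40)
  cvv <- withr::with_seed(21, runif(40, 0.1, 0.6))
  cvm <- rmap(cvv, atl, "cv")

  a <- bootstrap_compare(cvm, 0.35, "cortex", n_boot = 5000, seed = 99)
  b <- bootstrap_compare(cvm, 0.35, "cortex", n_boot = 5000, seed = 99)
  expect_identical(a$null_means, b$null_means)
  expect_identical(a$p_value, b$p_value)

  # p is non-increasing in the threshold for fixed resamples
  ps <- vapply(seq(0.2, 0.5, by = 0.05), function(th)
    bootstrap_compare(cvm, th, "cortex", n_boot = 5000, seed = 99)$p_value, 0)
  expect_true(all(diff(ps) <= 0))

  # only the requested compartment's regions are resampled
  expect_identical(a$n_regions,
                   sum(cvm$regions$compartment == "cortex"))

  empty <- restrict_map(cvm, rep(FALSE, 40))
  expect_error(bootstrap_compare(empty, 0.3, "cortex", n_boot = 10, seed = 1),
               "no retained")
})

test_that("spatial Spearman has the rank-correlation properties", {
  atl <- cortex_atlas(30)
  v <- withr::with_seed(31, runif(30))
  a <- rmap(v, atl); b <- rmap(rev(sort(v))[rank(v)], atl)

  expect_equal(spearman_spatial(a, a), 1)
  expect_equal(spearman_spatial(a, rmap(exp(v), atl)), 1)   # monotone map
  expect_equal(spearman_spatial(a, rmap(-v, atl)), -1)      # rank reversal
  expect_equal(spearman_spatial(a, rmap(max(v) + min(v) - v, atl)), -1)

  # symmetry
  w <- withr::with_seed(32, rmap(runif(30), atl))
  expect_equal(spearman_spatial(a, w), spearman_spatial(w, a))

  # joint-validity: only regions valid in both maps enter
  v2 <- v; v2[1:5] <- NaN
  expect_equal(spearman_spatial(rmap(v2, atl), w),
               cor(v[-(1:5)], w$values[-(1:5)], method = "spearman"))

  expect_error(spearman_spatial(rmap(c(v[1:2], rep(NaN, 28)), atl), w),
               ">= 3 jointly valid")
  expect_error(spearman_spatial(rmap(rep(1, 30), atl), w), "zero variance")
})

test_that("mean consistency averages pairwise r, single-other reduces to one r", {
  atl <- cortex_atlas(30)
  v <- withr::with_seed(33, runif(30))
  orig <- rmap(v, atl)

  expect_equal(mean_consistency(orig, list(orig))$mean_consistency, 1)

  w1 <- withr::with_seed(34, rmap(runif(30), atl))
  w2 <- withr::with_seed(35, rmap(runif(30), atl))
  rec <- mean_consistency(orig, list(w1, w2))
  expect_equal(rec$pairwise_r,
               c(spearman_spatial(orig, w1), spearman_spatial(orig, w2)))
  expect_equal(rec$mean_consistency, mean(rec$pairwise_r))

  single <- mean_consistency(orig, list(w1))
  expect_equal(single$mean_consistency, spearman_spatial(orig, w1))

  # all-pairs mode also includes the among-others correlation
  ap <- mean_consistency(orig, list(w1, w2), mode = "all_pairs")
  expect_length(ap$pairwise_r, 3)
  expect_true(spearman_spatial(w1, w2) %in% ap$pairwise_r)

  expect_error(mean_consistency(orig, list()), "at least one")
})

test_that("ratio-vs-consistency permutation test: exact ranks, constant guard, null calibration", {
  expect_equal(ratio_vs_consistency(1:8, (1:8)^2, n_perm = 100, seed = 1)$r, 1)
  expect_error(ratio_vs_consistency(1:8, rep(2, 8)), "constant")
  expect_error(ratio_vs_consistency(1:3, 1:3), ">= 4 paired")

  # under independence the permutation p should be roughly uniform:
  # check mean and the rejection rate over seeded replicates
  ps <- vapply(1:200, function(i) {
    xy <- withr::with_seed(1000 + i, list(x = sample(8), y = sample(8)))
    ratio_vs_consistency(xy$x, xy$y, n_perm = 400, seed = i)$p_perm
  }, 0)
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("covariate diagnostics correlate mean CV with N and age", {
  atl <- cortex_atlas(10)
  mk_study <- function(n, age) {
    maps <- random_study_maps(atl, seed = n)
    tracer_study("R", paste0("t", n), "BP_ND", n_subjects = n,
                 age_mean = age, mean_map = maps$mean_map,
                 std_map = maps$std_map)
  }
  studies <- lapply(1:6, function(i) mk_study(10 * i, 20 + 3 * i))

  # CV monotone in N by construction -> r = 1 for n_subjects
  tab <- covariate_diagnostics(studies, mean_cvs = seq(0.1, 0.6, 0.1),
                               n_perm = 500, seed = 2)
  expect_equal(tab$spearman_r[tab$covariate == "n_subjects"], 1)

  # constant CV -> not testable, no error
  tab2 <- covariate_diagnostics(studies, mean_cvs = rep(0.3, 6),
                                n_perm = 100, seed = 2)
  expect_true(all(tab2$note == "not testable"))
  expect_true(all(is.na(tab2$spearman_r)))

  # missing covariate drops the study with a warning
  studies[[1]]$age_mean <- NA_real_
  expect_warning(
    tab3 <- covariate_diagnostics(studies, seq(0.1, 0.6, 0.1),
                                  n_perm = 100, seed = 2),
    "dropped")
  expect_equal(tab3$n[tab3$covariate == "age_mean"], 5)
})

test_that("CV independent of N yields mostly non-significant diagnostics", {
  # simulation calibration: 50 seeded replicates of 8 studies whose mean
  # CVs are independent of N; expect p > 0.05 in the vast majority
  atl <- cortex_atlas(5)
  maps <- random_study_maps(atl, seed = 1)
  studies <- lapply(c(8, 16, 25, 36, 49, 64, 81, 100), function(n)
    tracer_study("R", paste0("t", n), "BP_ND", n_subjects = n,
                 age_mean = 30, mean_map = maps$mean_map,
                 std_map = maps$std_map))
  hits <- vapply(1:50, function(i) {
    cvs <- withr::with_seed(500 + i, runif(8, 0.1, 0.5))
    tab <- covariate_diagnostics(studies, cvs, n_perm = 400, seed = i)
    tab$p_perm[tab$covariate == "n_subjects"] <= 0.05
  }, TRUE)
  expect_gte(mean(!hits), 0.9)
})
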