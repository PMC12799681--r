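#' Bootstrap comparison of inter-regional vs inter-individual CV
#'
#' Resamples the retained inter-individual CV values of one compartment
#' with replacement (resample size = number of retained regions), records
#' each resample's mean, and reports p as the fraction of the `n_boot`
#' null means that are greater than or equal to the empirical
#' inter-regional CV. Small p means inter-regional variation significantly
#' exceeds inter-individual variation — the receptor's spatial profile is
#' stable across people. The estimator is the verbatim count over
#' bootstrap means, with no +1 correction.
#'
#' @param cv_map CV `regional_map` (or a bare numeric vector of CV values,
#'   in which case `compartment`/`retained` are ignored).
#' @param inter_regional empirical inter-regional CV (the threshold).
#' @param compartment "cortex" or "subcortex".
#' @param retained optional logical retained mask (defaults to validity).
#' @param n_boot number of bootstrap resamples; default 10000.
#' @param seed integer seed; resampling is bit-reproducible given the seed.
#' @return An object of class `bootstrap_result`: `null_means`, `p_value`,
#'   `n_boot`, `seed`, `compartment`, `n_regions`, `inter_regional`.
#' @export
bootstrap_compare <- function(cv_map, inter_regional,
                              compartment = c("cortex", "subcortex"),
                              retained = NULL, n_boot = 10000L, seed = 1L) {
  n_boot <- as.integer(n_boot)
  stopifnot(n_boot >= 1L, is.finite(inter_regional))
  if (inherits(cv_map, "regional_map")) {
    compartment <- match.arg(compartment)
    m <- if (is.null(retained)) cv_map else restrict_map(cv_map, retained)
    vals <- unname(map_values(m, compartment, valid_only = TRUE))
  } else {
    compartment <- NA_character_
    vals <- as.numeric(cv_map)
    vals <- vals[is.finite(vals)]
  }
  k <- length(vals)
  if (k < 1L)
    stop("no retained CV values to resample", call. = FALSE)
  null_means <- with_seed(seed, {
    draws <- sample.int(k, n_boot * k, replace = TRUE)
    colMeans(matrix(vals[draws], nrow = k))
  })
  structure(
    list(null_means = null_means,
         p_value = mean(null_means >= inter_regional),
         n_boot = n_boot, seed = as.integer(seed),
         compartment = compartment, n_regions = k,
         inter_regional = inter_regional),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "Bootstrap null of mean inter-individual CV (%s, %d regions, %d reps)\n",
    ifelse(is.na(x$compartment), "vector input", x$compartment),
    x$n_regions, x$n_boot))
  cat(sprintf("  inter-regional CV = %.4g, p = %.4g%s\n", x$inter_regional,
              x$p_value, ifelse(x$p_value < 0.05, "  (*)", "")))
  invisible(x)
}

#' Spatial Spearman correlation between two regional maps
#'
#' Spearman rank correlation over the jointly valid regions; ties receive
#' average ranks. Invariant under strictly increasing transforms of either
#' map, which is why it is the standard for comparing brain annotation
#' maps on different scales.
#'
#' @param map_a,map_b `regional_map`s sharing an atlas.
#' @param compartment optionally restrict to one compartment.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_spatial <- function(map_a, map_b, compartment = NULL) {
  stopifnot(inherits(map_a, "regional_map"),
            inherits(map_b, "regional_map"))
  check_shared_atlas(map_a, map_b)
  sel <- map_a$valid & map_b$valid
  if (!is.null(compartment)) {
    compartment <- match.arg(compartment, c("cortex", "subcortex"))
    sel <- sel & map_a$regions$compartment == compartment
  }
  if (sum(sel) < 3L)
    stop("need >= 3 jointly valid regions, got ", sum(sel), call. = FALSE)
  a <- map_a$values[sel]
  b <- map_b$values[sel]
  if (length(unique(a)) == 1L || length(unique(b)) == 1L)
    stop("zero variance in ranks: constant map", call. = FALSE)
  stats::cor(a, b, method = "spearman")
}

#' Mean spatial consistency of replicate group maps
#'
#' How reproducible is a receptor's group-average spatial profile across
#' cohorts/tracers? Default mode correlates the original map with each
#' replicate ("other") map and averages; with a single other map the score
#' is simply that one Spearman r. Mode "all_pairs" averages over every
#' pair among {original, others}.
#'
#' @param original the study's group-mean `regional_map`.
#' @param others list of replicate group-mean maps (>= 1).
#' @param receptor label stored on the record.
#' @param mode "original_vs_others" (default) or "all_pairs".
#' @param compartment optionally restrict correlations to one compartment.
#' @return An object of class `consistency_record`: `pairwise_r`,
#'   `mean_consistency`, `n_maps`, `receptor`, `mode`.
#' @export
mean_consistency <- function(original, others, receptor = "",
                             mode = c("original_vs_others", "all_pairs"),
                             compartment = NULL) {
  mode <- match.arg(mode)
  if (inherits(others, "regional_map")) others <- list(others)
  if (!length(others))
    stop("need at least one other map", call. = FALSE)
  maps <- c(list(original), others)
  if (mode == "original_vs_others") {
    pairs <- cbind(1L, seq_along(others) + 1L)
  } else {
    pairs <- t(utils::combn(length(maps), 2L))
  }
  r <- apply(pairs, 1L, function(p)
    spearman_spatial(maps[[p[1]]], maps[[p[2]]], compartment = compartment))
  structure(
    list(receptor = receptor, pairwise_r = as.numeric(r),
         mean_consistency = mean(r), n_maps = length(others),
         mode = mode),
    class = "consistency_record"
  )
}

#' @export
print.consistency_record <- function(x, ...) {
  cat(sprintf("Spatial consistency%s: mean Spearman r = %.3f over %d %s\n",
              ifelse(nzchar(x$receptor), paste0(" [", x$receptor, "]"), ""),
              x$mean_consistency, length(x$pairwise_r),
              ifelse(x$mode == "all_pairs", "map pairs",
                     "original-vs-other comparisons")))
  invisible(x)
}

# Spearman r plus a two-sided permutation p (shuffle y n_perm times) and
# the asymptotic p for comparison. Plain-proportion p, matching the
# bootstrap estimator convention.
perm_spearman <- function(x, y, n_perm = 10000L, seed = 1L) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L)
    stop("need >= 4 paired observations, got ", length(x), call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("constant vector: ranks undefined", call. = FALSE)
  r <- stats::cor(x, y, method = "spearman")
  null_r <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i)
      stats::cor(x, sample(y), method = "spearman"), 0)
  })
  p_asym <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)$p.value)
  list(r = r, p_perm = mean(abs(null_r) >= abs(r) - 1e-12),
       p_asymptotic = p_asym, n = length(x), n_perm = as.integer(n_perm))
}

#' Correlate CV ratio with spatial consistency across receptors
#'
#' Tests whether receptors that vary more across regions than individuals
#' (ratio > 1) also have more reproducible spatial profiles. Spearman r
#' across receptors; p from a two-sided permutation test (the receptor
#' count is small, so the asymptotic approximation is reported only for
#' comparison).
#'
#' @param ratios per-receptor regional-to-population CV ratios.
#' @param consistencies per-receptor mean spatial consistencies.
#' @param n_perm permutations; default 10000.
#' @param seed integer seed.
#' @return List with `r`, `p_perm`, `p_asymptotic`, `n`, `n_perm`.
#' @export
ratio_vs_consistency <- function(ratios, consistencies, n_perm = 10000L,
                                 seed = 1L) {
  perm_spearman(as.numeric(ratios), as.numeric(consistencies),
                n_perm = n_perm, seed = seed)
}

#' Cohort covariate diagnostics
#'
#' Correlates each study's mean inter-individual CV against cohort size
#' and mean age across studies. A strong dependence would suggest the
#' variability estimates reflect study design rather than biology. Studies
#' with a missing covariate are dropped with a warning; a constant CV
#' vector is reported as not testable instead of erroring.
#'
#' @param studies list of `tracer_study` objects.
#' @param mean_cvs per-study mean inter-individual CV (same order).
#' @param n_perm,seed permutation-test settings.
#' @return data.frame with columns covariate, n, spearman_r, p_perm, note.
#' @export
covariate_diagnostics <- function(studies, mean_cvs, n_perm = 10000L,
                                  seed = 1L) {
  stopifnot(length(studies) == length(mean_cvs))
  covs <- list(
    n_subjects = vapply(studies, function(s) as.numeric(s$n_subjects), 0),
    age_mean = vapply(studies, function(s) as.numeric(s$age_mean), 0)
  )
  rows <- lapply(names(covs), function(cn) {
    x <- covs[[cn]]
    ok <- is.finite(x) & is.finite(mean_cvs)
    if (any(!ok))
      warning(sum(!ok), " studies dropped from ", cn,
              " diagnostic (missing values)", call. = FALSE)
    res <- tryCatch(
      perm_spearman(x[ok], mean_cvs[ok], n_perm = n_perm,
                    seed = derive_seed(seed, cn)),
      error = function(e) NULL)
    if (is.null(res))
      data.frame(covariate = cn, n = sum(ok), spearman_r = NA_real_,
                 p_perm = NA_real_, note = "not testable",
                 stringsAsFactors = FALSE)
    else
      data.frame(covariate = cn, n = res$n, spearman_r = res$r,
                 p_perm = res$p_perm, note = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
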