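#' Specify a synthetic PET cohort
#'
#' Defines the ground truth for a simulated tracer study: per-region true
#' mean binding, per-region true inter-individual CV, a fluctuation-scaling
#' exponent (sigma = c * mu^beta, so a constant-CV field corresponds to
#' beta = 1), the subject-level noise family, and an optional
#' subject-specific global multiplicative baseline shift. The shift models
#' the "conserved spatial profile, individual-specific baseline" scenario:
#' it inflates every region's inter-individual CV without disturbing the
#' rank order of the group-mean map.
#'
#' @param atlas a `parcellation_atlas`.
#' @param true_mean per-region positive means in binding units.
#' @param true_cv per-region CV in `(0, 1.5)`, or 0 for noiseless regions.
#' @param n_subjects cohort size (>= 2).
#' @param subject_noise "gaussian" (zero-truncated) or "lognormal".
#' @param baseline_shift_sd sd of the log subject shift (>= 0; 0 = none).
#' @param scaling_exponent recorded beta when `true_cv` was built from a
#'   scaling law; informational.
#' @param seed integer seed making the cohort deterministic.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(atlas, true_mean, true_cv, n_subjects,
                        subject_noise = c("gaussian", "lognormal"),
                        baseline_shift_sd = 0, scaling_exponent = 1,
                        seed = 1L) {
  subject_noise <- match.arg(subject_noise)
  stopifnot(inherits(atlas, "parcellation_atlas"))
  n_regions <- nrow(atlas$regions)
  true_mean <- as.numeric(true_mean)
  true_cv <- rep_len(as.numeric(true_cv), n_regions)
  if (length(true_mean) != n_regions)
    stop("true_mean must have one value per region", call. = FALSE)
  if (any(!is.finite(true_mean)) || any(true_mean <= 0))
    stop("true_mean must be positive everywhere", call. = FALSE)
  if (any(true_cv < 0) || any(true_cv >= 1.5))
    stop("true_cv must lie in [0, 1.5)", call. = FALSE)
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 2L) stop("n_subjects must be >= 2", call. = FALSE)
  stopifnot(baseline_shift_sd >= 0)
  structure(
    list(atlas = atlas, true_mean = true_mean, true_cv = true_cv,
         n_subjects = n_subjects, subject_noise = subject_noise,
         baseline_shift_sd = as.numeric(baseline_shift_sd),
         scaling_exponent = as.numeric(scaling_exponent),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic cohort
#'
#' Subject s, region r gets `shift_s * (mu_r + eps_{s,r})` where eps has
#' standard deviation `cv_r * mu_r` under the chosen noise family and
#' `shift_s ~ lognormal(0, baseline_shift_sd)`. Gaussian noise is clamped
#' at zero (binding measures are nonnegative); at the CV levels typical of
#' PET binding the truncation bias is negligible. Deterministic given the
#' spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `synthetic_cohort`: `data` (subjects x
#'   regions matrix) plus the generating `spec` and the realized `shifts`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  R <- length(spec$true_mean)
  mu <- spec$true_mean
  sg <- spec$true_cv * mu
  with_seed(spec$seed, {
    shifts <- if (spec$baseline_shift_sd > 0)
      exp(stats::rnorm(n, 0, spec$baseline_shift_sd)) else rep(1, n)
    x <- matrix(0, nrow = n, ncol = R)
    if (spec$subject_noise == "gaussian") {
      eps <- matrix(stats::rnorm(n * R), n, R) *
        matrix(sg, n, R, byrow = TRUE)
      x <- matrix(mu, n, R, byrow = TRUE) + eps
      x[x < 0] <- 0
    } else {
      sdlog <- sqrt(log(1 + spec$true_cv^2))
      meanlog <- log(mu) - sdlog^2 / 2
      x <- matrix(
        stats::rlnorm(n * R, meanlog = rep(meanlog, each = n),
                      sdlog = rep(sdlog, each = n)), n, R)
      x[, spec$true_cv == 0] <-
        matrix(mu[spec$true_cv == 0], n, sum(spec$true_cv == 0),
               byrow = TRUE)
    }
    x <- x * shifts
    dimnames(x) <- list(paste0("sub-", seq_len(n)),
                        spec$atlas$regions$region_id)
    structure(list(data = x, spec = spec, shifts = shifts),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d subjects x %d regions (%s noise, shift sd %.2g, seed %d)\n",
    nrow(x$data), ncol(x$data), x$spec$subject_noise,
    x$spec$baseline_shift_sd, x$spec$seed))
  invisible(x)
}

#' Group statistics of a cohort
#'
#' Region-wise mean and sample (n-1) standard deviation across subjects —
#' the "group mean and standard deviation images" that real contributing
#' sites share.
#'
#' @param cohort a `synthetic_cohort` (or bare subjects x regions matrix
#'   with an `atlas` supplied).
#' @param atlas required when `cohort` is a bare matrix.
#' @param units_label unit annotation for the resulting maps.
#' @return List with `mean_map` and `std_map` (`regional_map`s).
#' @export
group_statistics <- function(cohort, atlas = NULL, units_label = "") {
  if (inherits(cohort, "synthetic_cohort")) {
    atlas <- cohort$spec$atlas
    x <- cohort$data
  } else {
    x <- as.matrix(cohort)
    if (is.null(atlas)) stop("atlas required for matrix input", call. = FALSE)
  }
  if (nrow(x) < 2L)
    stop("need >= 2 subjects for group statistics", call. = FALSE)
  mu <- colMeans(x)
  sg <- apply(x, 2L, stats::sd)
  list(mean_map = regional_map(mu, atlas, quantity = "mean",
                               units_label = units_label),
       std_map = regional_map(sg, atlas, quantity = "std",
                              units_label = units_label))
}

#' Deterministic positive mean profile with a target inter-regional CV
#'
#' Builds a right-skewed positive regional profile (lognormal-shaped
#' quantiles, seeded random region assignment) rescaled affinely so its
#' sample CV across regions equals `target_cv` exactly and its mean equals
#' `scale`. Errors if the rescale would push any region nonpositive.
#'
#' @param n_regions number of regions.
#' @param target_cv target sample CV across regions.
#' @param scale target mean level in binding units.
#' @param seed integer seed for the region shuffle.
#' @return Positive numeric vector of length `n_regions`.
#' @export
make_mean_profile <- function(n_regions, target_cv, scale = 1, seed = 1L) {
  stopifnot(n_regions >= 2L, target_cv >= 0, scale > 0)
  p <- (seq_len(n_regions) - 0.5) / n_regions
  s <- sqrt(log(1 + max(target_cv, 1e-8)^2))
  base <- exp(s * stats::qnorm(p))
  base <- with_seed(seed, sample(base))
  m <- mean(base)
  cv0 <- stats::sd(base) / m
  k <- if (cv0 > 0) target_cv / cv0 else 0
  prof <- scale * (1 + k * (base / m - 1))
  if (any(prof <= 0))
    stop("target_cv too large for a positive profile", call. = FALSE)
  prof
}

#' Built-in synthetic tracer templates
#'
#' Metadata mirrors real multi-site receptor mapping cohorts (receptor,
#' tracer, binding measure, cohort size, demographics); the generative
#' parameters encode the variability archetypes the analysis must
#' distinguish: a stable low-CV receptor, a high-turnout transporter, a
#' reference-region-excluded opioid receptor, a conserved-profile receptor
#' with an individual baseline shift, a noisy ionotropic receptor, and a
#' striatum-only low-affinity dopamine tracer.
#'
#' @return data.frame of template parameters, one row per tracer.
#' @export
tracer_templates <- function() {
  data.frame(
    receptor = c("5-HT1A", "5-HTT", "MOR", "CB1", "GABAA-a1", "D2"),
    tracer = c("[11C]CUMI-101", "[11C]DASB", "[11C]carfentanil",
               "[18F]FMPEP-d2", "[11C]Ro15-4513", "[11C]raclopride"),
    measure = c("B_max", "B_max", "BP_ND", "V_T", "V_T", "BP_ND"),
    n_subjects = c(8L, 100L, 86L, 20L, 27L, 16L),
    n_female = c(5L, 71L, 42L, 0L, 1L, 7L),
    age_mean = c(28.4, 25.1, 35.6, 24.4, 45.96, 32.7),
    age_sd = c(8.8, 5.8, 9.9, 3.0, 7.4, 8.8),
    mean_scale = c(2.0, 3.0, 1.5, 1.2, 4.0, 2.5),
    spatial_cv = c(0.5, 0.45, 0.55, 0.4, 0.45, 0.8),
    cv_low = c(0.15, 0.18, 0.30, 0.18, 0.50, 0.25),
    cv_high = c(0.25, 0.28, 0.45, 0.28, 0.70, 0.40),
    baseline_shift_sd = c(0, 0, 0, 0.3, 0, 0),
    occipital_reference = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    striatum_only = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Build a suite of synthetic tracer studies
#'
#' Generates one `tracer_study` per template row: a ground-truth mean
#' profile and CV field, a seeded subject cohort, group statistics, and
#' the masking rules (occipital reference exclusion, striatal
#' restriction). Each tracer draws from its own random stream derived from
#' `(seed, receptor|tracer)`, so adding or removing a tracer never
#' perturbs the others. Replicate cohorts (for spatial-consistency
#' scoring) are generated from independent streams of the same ground
#' truth.
#'
#' @param templates template data.frame as from [tracer_templates()].
#' @param atlas atlas to simulate on; default [synthetic_atlas()].
#' @param seed top-level integer seed.
#' @param n_replicates replicate group-mean maps per tracer (>= 0).
#' @return List of `tracer_study` objects, each carrying attributes
#'   `truth` (the generating `cohort_spec`) and `other_maps` (list of
#'   replicate group-mean `regional_map`s).
#' @export
make_tracer_suite <- function(templates = tracer_templates(),
                              atlas = synthetic_atlas(), seed = 1L,
                              n_replicates = 1L) {
  if (is.null(templates) || nrow(templates) == 0L) return(list())
  needed <- c("receptor", "tracer", "measure", "n_subjects", "mean_scale",
              "spatial_cv", "cv_low", "cv_high")
  missing <- setdiff(needed, names(templates))
  if (length(missing))
    stop("unknown template format; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  n_regions <- nrow(atlas$regions)
  lapply(seq_len(nrow(templates)), function(i) {
    tp <- templates[i, ]
    id <- paste(tp$receptor, tp$tracer, sep = "|")
    sseed <- derive_seed(seed, id)
    true_mean <- make_mean_profile(n_regions, tp$spatial_cv,
                                   scale = tp$mean_scale, seed = sseed)
    true_cv <- with_seed(derive_seed(sseed, "cvfield"),
                         stats::runif(n_regions, tp$cv_low, tp$cv_high))
    shift <- if ("baseline_shift_sd" %in% names(tp))
      tp$baseline_shift_sd else 0
    spec <- cohort_spec(atlas, true_mean, true_cv, tp$n_subjects,
                        baseline_shift_sd = shift,
                        seed = derive_seed(sseed, "cohort"))
    gs <- group_statistics(generate_cohort(spec),
                           units_label = tp$measure)
    excl <- if (isTRUE(tp$occipital_reference))
      region_preset(atlas, "occipital") else integer(0)
    study <- tracer_study(
      receptor = tp$receptor, tracer = tp$tracer, measure = tp$measure,
      n_subjects = tp$n_subjects,
      n_female = if ("n_female" %in% names(tp)) tp$n_female else NA,
      age_mean = if ("age_mean" %in% names(tp)) tp$age_mean else NA,
      age_sd = if ("age_sd" %in% names(tp)) tp$age_sd else NA,
      mean_map = gs$mean_map, std_map = gs$std_map,
      reference_exclusion = excl,
      striatum_only = isTRUE(tp$striatum_only))
    others <- lapply(seq_len(max(0L, n_replicates)), function(j) {
      rspec <- spec
      rspec$seed <- derive_seed(sseed, paste0("replicate", j))
      group_statistics(generate_cohort(rspec))$mean_map
    })
    attr(study, "truth") <- spec
    attr(study, "other_maps") <- others
    study
  })
}
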