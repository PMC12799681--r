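#' Fit the variability analysis for one tracer study
#'
#' The package's central estimator. For one tracer study it:
#' \enumerate{
#'   \item applies the study's masking rules (reference-region exclusion,
#'     striatal restriction) to the mean and std maps;
#'   \item computes the inter-individual CV map (sigma/mu per region) with
#'     the low-binding filter;
#'   \item per compartment, computes the inter-regional CV of group-mean
#'     binding over the retained regions, the mean inter-individual CV,
#'     and their ratio (the regional-to-population CV ratio);
#'   \item compares the inter-regional CV against a bootstrap null of mean
#'     inter-individual CVs (p = fraction of null means >= the empirical
#'     inter-regional CV).
#' }
#' Both CV statistics are evaluated over the same retained region set so
#' the ratio and the bootstrap compare like with like. A compartment with
#' too few retained regions (e.g. the cortex of a striatum-only tracer)
#' is reported as NA rather than failing the fit.
#'
#' @param study a `tracer_study`, or a mean `regional_map` if `std_map`
#'   is supplied directly.
#' @param std_map std `regional_map` when `study` is a mean map.
#' @param policy low-binding [filter_policy()].
#' @param n_boot bootstrap resamples; default 10000.
#' @param seed top-level seed; the bootstrap stream is derived from
#'   `(seed, receptor|tracer, compartment)`.
#' @param compartments compartments to analyse.
#' @param alpha significance level for the bootstrap flag; default 0.05.
#' @param keep_null keep the bootstrap null means on the object.
#' @return An object of class `receptor_variability` with components
#'   `cv_map`, `scaled_cv`, `retained`, per-compartment statistics
#'   (`compartments`), the masked input maps, the policy and seeds.
#' @examples
#' suite <- make_tracer_suite(tracer_templates()[2, ], seed = 42)
#' fit <- receptor_variability(suite[[1]], n_boot = 1000, seed = 42)
#' fit
#' coef(fit)
#' @export
receptor_variability <- function(study, std_map = NULL,
                                 policy = filter_policy(),
                                 n_boot = 10000L, seed = 1L,
                                 compartments = c("cortex", "subcortex"),
                                 alpha = 0.05, keep_null = FALSE) {
  if (inherits(study, "regional_map")) {
    stopifnot(inherits(std_map, "regional_map"))
    study <- tracer_study("unknown", "unknown", "BP_ND",
                          n_subjects = 2L,
                          mean_map = study, std_map = std_map)
  }
  stopifnot(inherits(study, "tracer_study"))
  compartments <- match.arg(compartments, several.ok = TRUE)

  mean_map <- apply_exclusions(study$mean_map, study)
  smap <- apply_exclusions(study$std_map, study)
  civ <- interindividual_cv(mean_map, smap, policy)
  cv_map <- civ$cv_map
  retained <- civ$retained
  mean_retained <- restrict_map(mean_map, retained)

  comp <- lapply(compartments, function(cm) {
    out <- list(compartment = cm, n_retained = sum(
      retained & cv_map$regions$compartment == cm))
    stats_ok <- tryCatch({
      ir <- interregional_cv(mean_retained, cm)
      mcv <- mean(map_values(cv_map, cm, valid_only = TRUE))
      bt <- bootstrap_compare(
        cv_map, ir, cm, n_boot = n_boot,
        seed = derive_seed(seed, paste(study_id(study), cm, sep = "|")))
      out$inter_regional_cv <- ir
      out$mean_interindividual_cv <- mcv
      out$ratio <- ir / mcv
      out$p_boot <- bt$p_value
      out$significant <- bt$p_value < alpha
      out$n_boot <- bt$n_boot
      out$boot_seed <- bt$seed
      if (keep_null) out$null_means <- bt$null_means
      TRUE
    }, error = function(e) {
      out$error <<- conditionMessage(e)
      out$inter_regional_cv <<- NA_real_
      out$mean_interindividual_cv <<- NA_real_
      out$ratio <<- NA_real_
      out$p_boot <<- NA_real_
      out$significant <<- NA
      FALSE
    })
    out
  })
  names(comp) <- compartments

  scaled <- tryCatch(minmax_scale(cv_map), error = function(e) NULL)
  structure(
    list(receptor = study$receptor, tracer = study$tracer,
         measure = study$measure, n_subjects = study$n_subjects,
         study = study, policy = policy, seed = as.integer(seed),
         alpha = alpha, mean_map = mean_map, std_map = smap,
         cv_map = cv_map, scaled_cv = scaled, retained = retained,
         compartments = comp),
    class = "receptor_variability"
  )
}

#' @export
print.receptor_variability <- function(x, ...) {
  cat(sprintf("Receptor variability fit: %s  %s (%s), N = %d\n",
              x$receptor, x$tracer, x$measure, x$n_subjects))
  cat(sprintf("  %d/%d regions retained after exclusions + filter\n",
              sum(x$retained), nrow(x$cv_map$regions)))
  for (cm in x$compartments) {
    if (is.na(cm$ratio)) {
      cat(sprintf("  %-9s not estimable (%s)\n", cm$compartment,
                  cm$error %||% "too few retained regions"))
    } else {
      cat(sprintf(
        "  %-9s inter-regional CV %.3f / mean CV %.3f = ratio %.2f, p = %.4g%s\n",
        cm$compartment, cm$inter_regional_cv,
        cm$mean_interindividual_cv, cm$ratio, cm$p_boot,
        ifelse(isTRUE(cm$significant), " *", "")))
    }
  }
  invisible(x)
}

#' @export
summary.receptor_variability <- function(object, ...) {
  rows <- lapply(object$compartments, function(cm)
    data.frame(receptor = object$receptor, tracer = object$tracer,
               compartment = cm$compartment, n_retained = cm$n_retained,
               inter_regional_cv = cm$inter_regional_cv,
               mean_interindividual_cv = cm$mean_interindividual_cv,
               ratio = cm$ratio, p_boot = cm$p_boot,
               significant = cm$significant, stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("summary.receptor_variability", "data.frame")
  out
}

#' @export
coef.receptor_variability <- function(object, ...) {
  s <- summary(object)
  m <- as.matrix(s[c("inter_regional_cv", "mean_interindividual_cv",
                     "ratio", "p_boot")])
  rownames(m) <- s$compartment
  m
}

#' Plot the CV distribution of a fitted tracer
#'
#' Histogram of retained inter-individual CV values of one compartment
#' with the inter-regional CV as a dashed vertical line — a ratio above 1
#' puts the line to the right of the bulk of the histogram.
#'
#' @param x a `receptor_variability` fit.
#' @param compartment which compartment to show.
#' @param ... passed to [graphics::hist()].
#' @export
plot.receptor_variability <- function(x, compartment = "cortex", ...) {
  compartment <- match.arg(compartment, c("cortex", "subcortex"))
  v <- map_values(x$cv_map, compartment, valid_only = TRUE)
  if (!length(v)) stop("no retained regions in ", compartment, call. = FALSE)
  cm <- x$compartments[[compartment]]
  graphics::hist(v, col = "orange", border = "white",
                 main = sprintf("%s %s (%s)", x$receptor, x$tracer,
                                compartment),
                 xlab = "inter-individual CV",
                 xlim = range(c(v, cm$inter_regional_cv), na.rm = TRUE),
                 ...)
  if (is.finite(cm$inter_regional_cv))
    graphics::abline(v = cm$inter_regional_cv, lty = 2, lwd = 2,
                     col = "purple")
  invisible(x)
}

#' Simulate cohorts from a fitted variability model
#'
#' Uses the fitted mean map as true means and the estimated CV map as the
#' true CV field to generate parametric-bootstrap cohorts, closing the
#' loop between estimator and generator. Regions not retained in the fit
#' are dropped from the simulated atlas support (their truth is unknown).
#'
#' @param object a `receptor_variability` fit.
#' @param nsim number of cohorts.
#' @param seed integer seed.
#' @param n_subjects cohort size; defaults to the study's N.
#' @param ... unused.
#' @return List of `synthetic_cohort` objects of length `nsim`.
#' @export
simulate.receptor_variability <- function(object, nsim = 1, seed = 1L,
                                          n_subjects = NULL, ...) {
  n_subjects <- n_subjects %||% object$n_subjects
  keep <- object$retained
  mu <- ifelse(keep, object$mean_map$values, 1)  # placeholder off-support
  cv <- ifelse(keep, object$cv_map$values, 0)
  atlas <- synthetic_atlas_from_regions(object$cv_map$regions)
  lapply(seq_len(nsim), function(i) {
    spec <- cohort_spec(atlas, mu, pmin(cv, 1.49), n_subjects,
                        seed = derive_seed(seed, paste0("sim", i)))
    cohort <- generate_cohort(spec)
    cohort$data[, !keep] <- NA_real_
    cohort
  })
}

# Minimal atlas wrapper for simulate(): one voxel block per region.
synthetic_atlas_from_regions <- function(regions) {
  n <- nrow(regions)
  d <- c(n, 2L, 1L)
  lab <- array(rep(regions$region_id, 2L), dim = d)
  parcellation_atlas(lab, regions)
}
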