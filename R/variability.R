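#' Low-binding filter policy
#'
#' The coefficient of variation is unstable when its denominator (mean
#' binding) approaches zero, so low-binding regions are omitted before CV
#' is computed. The default rule omits a region iff its mean binding falls
#' in the bottom `percentile_cut` percent of the map's valid regions AND is
#' below `absolute_threshold` binding units — the conditional reading of
#' the rule "bottom fifth percentile, if binding is below 0.1". `combine`
#' selects the conjunction ("and"), the union ("or"), or the percentile
#' rule alone.
#'
#' @param percentile_cut percentile in `[0, 100]`; default 5.
#' @param absolute_threshold binding-unit cut; default 0.1.
#' @param combine "and" (default), "or" or "percentile_only".
#' @return An object of class `filter_policy`.
#' @export
filter_policy <- function(percentile_cut = 5, absolute_threshold = 0.1,
                          combine = c("and", "or", "percentile_only")) {
  combine <- match.arg(combine)
  stopifnot(percentile_cut >= 0, percentile_cut <= 100,
            absolute_threshold >= 0)
  structure(list(percentile_cut = percentile_cut,
                 absolute_threshold = absolute_threshold,
                 combine = combine),
            class = "filter_policy")
}

# Regions omitted by the policy, evaluated jointly over all valid regions
# of the map (not per compartment). Percentile uses linear interpolation
# (quantile type 7) with an inclusive boundary.
filter_omitted <- function(mu, valid, policy) {
  omitted <- rep(FALSE, length(mu))
  if (!any(valid)) return(omitted)
  q <- stats::quantile(mu[valid], probs = policy$percentile_cut / 100,
                       type = 7, names = FALSE)
  in_pct <- valid & mu <= q
  below <- valid & mu < policy$absolute_threshold
  switch(policy$combine,
         and = in_pct & below,
         or = in_pct | below,
         percentile_only = in_pct)
}

#' Inter-individual coefficient of variation map
#'
#' For each region retained by the low-binding filter, CV = sigma / mu:
#' the group standard deviation of tracer binding normalized by the group
#' mean. Regions invalid in either input, or omitted by the filter, are
#' invalid in the output. A retained region with mu <= 0 (possible in
#' V_T/BP_ND maps from upstream modelling noise) is invalidated with a
#' warning rather than producing a negative or infinite CV.
#'
#' @param mean_map,std_map `regional_map`s sharing an atlas.
#' @param policy a [filter_policy()].
#' @return List with `cv_map` (a `regional_map`, quantity "cv") and
#'   `retained` (logical per region).
#' @export
interindividual_cv <- function(mean_map, std_map, policy = filter_policy()) {
  stopifnot(inherits(mean_map, "regional_map"),
            inherits(std_map, "regional_map"),
            inherits(policy, "filter_policy"))
  check_shared_atlas(mean_map, std_map, "mean_map and std_map")
  valid <- mean_map$valid & std_map$valid
  omitted <- filter_omitted(mean_map$values, valid, policy)
  retained <- valid & !omitted
  mu <- mean_map$values
  nonpos <- retained & mu <= 0
  if (any(nonpos)) {
    warning(sum(nonpos), " retained region(s) with nonpositive mean ",
            "binding invalidated (unstable CV)", call. = FALSE)
    retained <- retained & !nonpos
  }
  cv <- rep(NaN, length(mu))
  cv[retained] <- std_map$values[retained] / mu[retained]
  list(cv_map = regional_map(cv, mean_map$regions, quantity = "cv"),
       retained = retained)
}

#' Inter-regional coefficient of variation
#'
#' Dispersion of group-mean binding across the regions of one compartment:
#' the sample (n-1) standard deviation of mean binding across valid
#' regions divided by its mean. One number per map and compartment.
#'
#' @param mean_map a `regional_map` of group means.
#' @param compartment "cortex" or "subcortex".
#' @return Unitless scalar.
#' @export
interregional_cv <- function(mean_map, compartment = c("cortex", "subcortex")) {
  compartment <- match.arg(compartment)
  v <- map_values(mean_map, compartment, valid_only = TRUE)
  if (length(v) < 2L)
    stop("need >= 2 valid ", compartment, " regions, got ", length(v),
         call. = FALSE)
  m <- mean(v)
  if (m <= 0)
    stop("unstable coefficient of variation: nonpositive mean binding",
         call. = FALSE)
  stats::sd(v) / m
}

#' Regional-to-population CV ratio
#'
#' Inter-regional CV divided by the mean inter-individual CV over the
#' retained regions of the compartment. Values above 1 mark receptors that
#' vary more across brain regions than across individuals (stable spatial
#' expression); below 1, the reverse.
#'
#' @param inter_regional inter-regional CV of the compartment.
#' @param cv_map CV `regional_map` from [interindividual_cv()].
#' @param compartment "cortex" or "subcortex".
#' @param retained optional logical retained mask; defaults to the map's
#'   validity.
#' @return Unitless scalar.
#' @export
cv_ratio <- function(inter_regional, cv_map,
                     compartment = c("cortex", "subcortex"),
                     retained = NULL) {
  compartment <- match.arg(compartment)
  m <- if (is.null(retained)) cv_map else restrict_map(cv_map, retained)
  v <- map_values(m, compartment, valid_only = TRUE)
  if (!length(v))
    stop("no retained ", compartment, " regions", call. = FALSE)
  mcv <- mean(v)
  if (mcv <= 0)
    stop("mean inter-individual CV must be positive", call. = FALSE)
  inter_regional / mcv
}

#' Min-max scale a regional map for display
#'
#' Rescales valid values to span exactly [0, 1], the convention used to
#' show the spatial organization of CV maps side by side. Invalid regions
#' stay invalid. A constant map has no range to scale and errors.
#'
#' @param map a `regional_map`.
#' @param scope "all" (whole map), "cortex" or "subcortex"; compartment
#'   scopes scale within that compartment and invalidate the rest.
#' @return A `regional_map` with quantity "scaled_cv".
#' @export
minmax_scale <- function(map, scope = c("all", "cortex", "subcortex")) {
  scope <- match.arg(scope)
  stopifnot(inherits(map, "regional_map"))
  sel <- map$valid
  if (scope != "all") sel <- sel & map$regions$compartment == scope
  v <- map$values[sel]
  if (length(v) < 2L)
    stop("need >= 2 valid regions to scale", call. = FALSE)
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("degenerate range: map is constant over its valid regions",
         call. = FALSE)
  out <- rep(NaN, length(map$values))
  out[sel] <- (map$values[sel] - rng[1]) / (rng[2] - rng[1])
  regional_map(out, map$regions, quantity = "scaled_cv")
}

#' Fluctuation-scaling diagnostic (std vs mean)
#'
#' In biological measurements the standard deviation typically scales with
#' the mean, sigma ~ c * mu^beta — the reason CV (not raw sigma) is the
#' variability measure of choice. This diagnostic quantifies the scaling
#' on one tracer's group maps: the Spearman correlation between sigma and
#' mu across regions, and the OLS slope of log sigma on log mu (the
#' scaling exponent beta).
#'
#' @param mean_map,std_map `regional_map`s sharing an atlas.
#' @return List with `spearman_r`, `log_log_slope` and `n_regions`.
#' @export
std_mean_scaling <- function(mean_map, std_map) {
  stopifnot(inherits(mean_map, "regional_map"),
            inherits(std_map, "regional_map"))
  check_shared_atlas(mean_map, std_map, "mean_map and std_map")
  sel <- mean_map$valid & std_map$valid &
    mean_map$values > 0 & std_map$values > 0
  if (sum(sel) < 3L)
    stop("need >= 3 regions with positive mean and std", call. = FALSE)
  mu <- mean_map$values[sel]
  sg <- std_map$values[sel]
  slope <- unname(stats::coef(stats::lm(log(sg) ~ log(mu)))[2])
  list(spearman_r = stats::cor(mu, sg, method = "spearman"),
       log_log_slope = slope, n_regions = sum(sel))
}
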