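#' Construct a tracer study
#'
#' One contributed dataset: a receptor/transporter mapped by one PET tracer
#' in one cohort, represented by its group mean and group standard
#' deviation regional maps plus the metadata needed downstream (cohort
#' size, demographics, binding measure, masking rules). Standard deviation
#' maps are treated as given; whether the contributing site used the
#' sample (n-1) or population (n) denominator is unknowable downstream and
#' does not enter any statistic computed here.
#'
#' @param receptor receptor/transporter label (e.g. "5-HT1A", "MOR").
#' @param tracer tracer label (e.g. "[11C]carfentanil").
#' @param measure binding measure: "BP_ND", "V_T", "B_max" or "SUVR".
#' @param n_subjects cohort size (>= 2).
#' @param mean_map,std_map `regional_map`s of group mean and group standard
#'   deviation on a shared atlas.
#' @param n_female number of female participants.
#' @param age_mean,age_sd cohort age summary in years.
#' @param reference_exclusion integer region ids forced invalid (tracer
#'   quantification reference regions).
#' @param striatum_only flag for tracers reliable only in the striatum.
#' @return An object of class `tracer_study`.
#' @export
tracer_study <- function(receptor, tracer,
                         measure = c("BP_ND", "V_T", "B_max", "SUVR"),
                         n_subjects, mean_map, std_map,
                         n_female = NA_integer_, age_mean = NA_real_,
                         age_sd = NA_real_,
                         reference_exclusion = integer(0),
                         striatum_only = FALSE) {
  measure <- match.arg(measure)
  stopifnot(inherits(mean_map, "regional_map"),
            inherits(std_map, "regional_map"))
  check_shared_atlas(mean_map, std_map, "mean_map and std_map")
  if (any(std_map$values[std_map$valid] < 0))
    stop("std_map values must be nonnegative", call. = FALSE)
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 2L)
    stop("n_subjects must be >= 2", call. = FALSE)
  structure(
    list(receptor = as.character(receptor), tracer = as.character(tracer),
         measure = measure, n_subjects = n_subjects,
         n_female = as.integer(n_female), age_mean = as.numeric(age_mean),
         age_sd = as.numeric(age_sd), mean_map = mean_map,
         std_map = std_map,
         reference_exclusion = as.integer(reference_exclusion),
         striatum_only = isTRUE(striatum_only)),
    class = "tracer_study"
  )
}

#' @export
print.tracer_study <- function(x, ...) {
  cat(sprintf("Tracer study: %s  %s  (%s), N = %d\n",
              x$receptor, x$tracer, x$measure, x$n_subjects))
  if (!is.na(x$age_mean))
    cat(sprintf("  age %.1f +/- %.1f, %s female\n", x$age_mean,
                ifelse(is.na(x$age_sd), 0, x$age_sd),
                ifelse(is.na(x$n_female), "?", x$n_female)))
  if (length(x$reference_exclusion))
    cat("  reference exclusion:", length(x$reference_exclusion),
        "regions\n")
  if (x$striatum_only) cat("  striatum-only quantification\n")
  invisible(x)
}

study_id <- function(study) paste(study$receptor, study$tracer, sep = "|")
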