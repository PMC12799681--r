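#' Construct a regional map
#'
#' A regional map carries one scalar per atlas region together with a
#' validity mask. Invalid regions (excluded reference regions, filtered
#' low-binding regions, regions with no voxel data) hold `NaN` and are
#' skipped by every downstream statistic.
#'
#' @param values numeric vector, one value per region (NA/NaN allowed, they
#'   mark the region invalid).
#' @param regions region table (as in [parcellation_atlas()]) or an atlas.
#' @param quantity one of "mean", "std", "cv", "scaled_cv".
#' @param valid optional logical mask; defaults to `is.finite(values)`.
#' @param units_label free-text unit annotation (e.g. "BP_ND"); CV maps are
#'   unitless.
#' @return An object of class `regional_map`.
#' @export
regional_map <- function(values, regions,
                         quantity = c("mean", "std", "cv", "scaled_cv"),
                         valid = NULL, units_label = "") {
  quantity <- match.arg(quantity)
  if (inherits(regions, "parcellation_atlas")) regions <- regions$regions
  regions <- validate_regions(regions)
  values <- as.numeric(values)
  if (length(values) != nrow(regions))
    stop("length(values) must equal the atlas region count (",
         nrow(regions), ")", call. = FALSE)
  if (is.null(valid)) valid <- is.finite(values)
  valid <- as.logical(valid) & is.finite(values)
  if (length(valid) != length(values))
    stop("valid mask length mismatch", call. = FALSE)
  values[!valid] <- NaN
  if (quantity == "std" && any(values[valid] < 0))
    stop("std map values must be nonnegative", call. = FALSE)
  structure(
    list(values = values, valid = valid, quantity = quantity,
         units_label = units_label, regions = regions),
    class = "regional_map"
  )
}

#' @export
print.regional_map <- function(x, ...) {
  cat("Regional map (", x$quantity,
      if (nzchar(x$units_label)) paste0(", ", x$units_label), "): ",
      nrow(x$regions), " regions, ", sum(x$valid), " valid\n", sep = "")
  v <- x$values[x$valid]
  if (length(v))
    cat(sprintf("  range %.4g .. %.4g, median %.4g\n",
                min(v), max(v), stats::median(v)))
  invisible(x)
}

#' Extract values of a regional map
#'
#' @param map a `regional_map`.
#' @param compartment optionally restrict to "cortex" or "subcortex".
#' @param valid_only drop invalid regions (default keeps NaN placeholders).
#' @return Named numeric vector (names are region ids).
#' @export
map_values <- function(map, compartment = NULL, valid_only = FALSE) {
  stopifnot(inherits(map, "regional_map"))
  keep <- rep(TRUE, nrow(map$regions))
  if (!is.null(compartment)) {
    compartment <- match.arg(compartment, c("cortex", "subcortex"))
    keep <- map$regions$compartment == compartment
  }
  if (valid_only) keep <- keep & map$valid
  stats::setNames(map$values[keep], map$regions$region_id[keep])
}

#' Invalidate regions of a map
#'
#' Returns a copy of `map` with validity restricted to `mask` (logical per
#' region or integer region ids). Used to apply exclusion and filter masks.
#'
#' @param map a `regional_map`.
#' @param mask logical vector (TRUE = keep) or integer region ids to keep.
#' @return A `regional_map`.
#' @export
restrict_map <- function(map, mask) {
  stopifnot(inherits(map, "regional_map"))
  if (is.numeric(mask)) mask <- map$regions$region_id %in% mask
  stopifnot(is.logical(mask), length(mask) == nrow(map$regions))
  regional_map(ifelse(mask & map$valid, map$values, NaN), map$regions,
               quantity = map$quantity, units_label = map$units_label)
}

check_shared_atlas <- function(a, b, what = "maps") {
  if (!same_atlas(a$regions, b$regions))
    stop(what, " do not share an atlas (region tables differ)",
         call. = FALSE)
  invisible(TRUE)
}
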