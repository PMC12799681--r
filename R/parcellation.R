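#' Parcellate a voxelwise volume to regional means
#'
#' Each region's value is the unweighted arithmetic mean of its voxels,
#' ignoring NaN voxels. A region whose voxels are all NaN, or whose label
#' does not occur in the volume's grid, becomes invalid. No partial-volume
#' weighting is applied.
#'
#' @param volume 3-D numeric array, same grid as the atlas.
#' @param atlas a `parcellation_atlas`.
#' @param quantity quantity tag for the resulting map.
#' @param units_label unit annotation carried onto the map.
#' @return A `regional_map` over the atlas regions.
#' @export
parcellate_volume <- function(volume, atlas, quantity = "mean",
                              units_label = "") {
  stopifnot(inherits(atlas, "parcellation_atlas"))
  if (!identical(dim(volume), dim(atlas$label_volume)))
    stop("volume and atlas grids differ: ",
         paste(dim(volume), collapse = "x"), " vs ",
         paste(dim(atlas$label_volume), collapse = "x"), call. = FALSE)
  lab <- as.vector(atlas$label_volume)
  v <- as.vector(as.numeric(volume))
  keep <- lab > 0L & is.finite(v)
  ids <- atlas$regions$region_id
  vals <- rep(NaN, length(ids))
  if (any(keep)) {
    sums <- rowsum(v[keep], lab[keep])
    counts <- rowsum(rep(1, sum(keep)), lab[keep])
    m <- sums[, 1] / counts[, 1]
    # a constant region's mean is that constant, bitwise: sum/count can be
    # off by one ulp, which would break the piecewise-constant round trip
    lo <- tapply(v[keep], lab[keep], min)[rownames(sums)]
    hi <- tapply(v[keep], lab[keep], max)[rownames(sums)]
    const <- lo == hi
    m[const] <- lo[const]
    idx <- match(as.integer(rownames(sums)), ids)
    vals[idx] <- m
  }
  regional_map(vals, atlas, quantity = quantity, units_label = units_label)
}

#' Apply tracer-specific region exclusions
#'
#' Implements the masking rules attached to a tracer study: regions listed
#' in `reference_exclusion` (e.g. the occipital reference region of a
#' mu-opioid carfentanil study) become invalid; if the study is flagged
#' `striatum_only` (low-affinity D2 tracers such as raclopride, reliable
#' only where D2 density is high) every non-striatal region becomes
#' invalid. All other values pass through unchanged.
#'
#' @param map a `regional_map` on the study's atlas.
#' @param study a `tracer_study`, or a list with elements
#'   `reference_exclusion` (integer ids) and `striatum_only` (flag).
#' @param striatum_ids region ids forming the striatum; defaults to the
#'   atlas "striatum" preset when the map's region names carry the tag.
#' @return A `regional_map` with the exclusions applied.
#' @export
apply_exclusions <- function(map, study, striatum_ids = NULL) {
  stopifnot(inherits(map, "regional_map"))
  excl <- as.integer(study$reference_exclusion %||% integer(0))
  unknown <- setdiff(excl, map$regions$region_id)
  if (length(unknown))
    stop("exclusion ids not in atlas: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  keep <- !(map$regions$region_id %in% excl)
  if (isTRUE(study$striatum_only)) {
    if (is.null(striatum_ids))
      striatum_ids <- map$regions$region_id[
        grepl("striatum", map$regions$region_name, fixed = TRUE)]
    if (!length(striatum_ids))
      stop("striatum_only study but no striatal ids available", call. = FALSE)
    keep <- keep & map$regions$region_id %in% as.integer(striatum_ids)
  }
  restrict_map(map, keep)
}

#' Embed a regional map back into voxel space
#'
#' Every voxel takes its region's value; background voxels and invalid
#' regions become NaN. Together with [parcellate_volume()] this is an exact
#' round trip on piecewise-constant volumes, which is how the synthetic
#' NIfTI fixtures are produced.
#'
#' @param map a `regional_map`.
#' @param atlas the matching `parcellation_atlas`.
#' @return 3-D numeric array on the atlas grid.
#' @export
embed_regional <- function(map, atlas) {
  stopifnot(inherits(map, "regional_map"),
            inherits(atlas, "parcellation_atlas"))
  check_shared_atlas(map, list(regions = atlas$regions))
  lab <- as.vector(atlas$label_volume)
  idx <- match(lab, map$regions$region_id)
  vals <- map$values[idx]
  vals[is.na(idx)] <- NaN
  vals[is.na(vals)] <- NaN
  array(vals, dim = dim(atlas$label_volume))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
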