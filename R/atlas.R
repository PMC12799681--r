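#' Construct a parcellation atlas
#'
#' Bundles an integer label volume with a region lookup table. Labels are the
#' positive integers stored in the volume; 0 is background. Every nonzero
#' label in the volume must appear in `regions`, and each voxel carries
#' exactly one label, so regions never overlap.
#'
#' @param label_volume 3-D integer array of region labels (0 = background).
#' @param regions data.frame with columns `region_id` (unique positive
#'   integers), `region_name` (character), `compartment` ("cortex" or
#'   "subcortex") and `hemisphere` ("L", "R" or NA).
#' @param voxel_dims numeric length-3 voxel edge lengths in mm.
#' @return An object of class `parcellation_atlas`.
#' @export
parcellation_atlas <- function(label_volume, regions, voxel_dims = c(2, 2, 2)) {
  if (length(dim(label_volume)) != 3L)
    stop("label_volume must be a 3-D array", call. = FALSE)
  storage.mode(label_volume) <- "integer"
  regions <- validate_regions(regions)
  labs <- unique(as.vector(label_volume))
  labs <- labs[labs != 0L]
  missing <- setdiff(labs, regions$region_id)
  if (length(missing))
    stop("labels in volume missing from region table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  stopifnot(length(voxel_dims) == 3L, all(voxel_dims > 0))
  structure(
    list(label_volume = label_volume, regions = regions,
         voxel_dims = as.numeric(voxel_dims)),
    class = "parcellation_atlas"
  )
}

validate_regions <- function(regions) {
  required <- c("region_id", "region_name", "compartment", "hemisphere")
  if (!is.data.frame(regions) || !all(required %in% names(regions)))
    stop("regions must be a data.frame with columns ",
         paste(required, collapse = ", "), call. = FALSE)
  regions <- regions[required]
  regions$region_id <- as.integer(regions$region_id)
  if (anyDuplicated(regions$region_id))
    stop("region_id values must be unique", call. = FALSE)
  if (any(regions$region_id <= 0L))
    stop("region_id values must be positive", call. = FALSE)
  bad <- !regions$compartment %in% c("cortex", "subcortex")
  if (any(bad))
    stop("compartment must be 'cortex' or 'subcortex'", call. = FALSE)
  ok_hemi <- regions$hemisphere %in% c("L", "R") | is.na(regions$hemisphere)
  if (!all(ok_hemi))
    stop("hemisphere must be 'L', 'R' or NA", call. = FALSE)
  rownames(regions) <- NULL
  regions
}

#' Synthetic cortical + subcortical atlas pair
#'
#' Generates a small-volume stand-in for the default 100-region cortical /
#' 54-region subcortical parcellation pair used throughout the package.
#' Region labels are assigned as contiguous voxel blocks on a compact grid;
#' the last cortical regions are named `occipital-*` and the first
#' subcortical regions `striatum-*` so that [region_preset()] can resolve
#' the anatomical exclusion targets (reference-region masking, striatal
#' restriction). The geometry is synthetic: it preserves the label/region
#' bookkeeping of a real atlas, not anatomy.
#'
#' @param n_cortex,n_subcortex number of cortical and subcortical regions.
#' @param dim 3-D grid dimensions; must give at least 2 voxels per region.
#' @param n_occipital number of trailing cortical regions tagged occipital.
#' @param n_striatum number of leading subcortical regions tagged striatum.
#' @return A `parcellation_atlas` with `n_cortex + n_subcortex` regions.
#' @examples
#' atl <- synthetic_atlas()
#' table(atl$regions$compartment)
#' @export
synthetic_atlas <- function(n_cortex = 100L, n_subcortex = 54L,
                            dim = c(12L, 12L, 6L),
                            n_occipital = 8L, n_striatum = 10L) {
  n_regions <- n_cortex + n_subcortex
  n_occipital <- min(n_occipital, n_cortex)
  n_striatum <- min(n_striatum, n_subcortex)
  n_vox <- prod(dim)
  per <- n_vox %/% (n_regions + 1L)  # leave headroom for background
  if (per < 2L)
    stop("grid too small: need at least 2 voxels per region", call. = FALSE)
  labels <- integer(n_vox)
  labels[seq_len(n_regions * per)] <- rep(seq_len(n_regions), each = per)
  label_volume <- array(labels, dim = dim)

  ctx_names <- if (n_cortex > 0L)
    paste0("ctx-", rep(c("L", "R"), length.out = n_cortex),
           "-region", seq_len(n_cortex)) else character(0)
  if (n_occipital > 0L) {
    occ <- seq(n_cortex - n_occipital + 1L, n_cortex)
    ctx_names[occ] <- paste0("ctx-occipital-", seq_along(occ))
  }
  sub_names <- if (n_subcortex > 0L)
    paste0("sub-", rep(c("L", "R"), length.out = n_subcortex),
           "-region", seq_len(n_subcortex)) else character(0)
  if (n_striatum > 0L)
    sub_names[seq_len(n_striatum)] <-
      paste0("sub-striatum-", seq_len(n_striatum))

  regions <- data.frame(
    region_id = seq_len(n_regions),
    region_name = c(ctx_names, sub_names),
    compartment = rep(c("cortex", "subcortex"), c(n_cortex, n_subcortex)),
    hemisphere = rep(c("L", "R"), length.out = n_regions),
    stringsAsFactors = FALSE
  )
  parcellation_atlas(label_volume, regions)
}

#' Resolve a named anatomical region preset to atlas label ids
#'
#' The exclusion rules are anatomical ("occipital cortex", "the striatum");
#' label lists depend on the atlas. Presets are resolved by region-name
#' matching so custom atlases work as long as their names carry the tags.
#'
#' @param atlas a `parcellation_atlas`.
#' @param preset "occipital" or "striatum".
#' @return Integer vector of region ids.
#' @export
region_preset <- function(atlas, preset = c("occipital", "striatum")) {
  preset <- match.arg(preset)
  ids <- atlas$regions$region_id[grepl(preset, atlas$regions$region_name,
                                       fixed = TRUE)]
  if (!length(ids))
    stop("atlas has no regions tagged '", preset, "'", call. = FALSE)
  ids
}

#' @export
print.parcellation_atlas <- function(x, ...) {
  tab <- table(x$regions$compartment)
  cat("Parcellation atlas:", nrow(x$regions), "regions (",
      paste(paste0(names(tab), "=", tab), collapse = ", "), ")\n")
  cat("Label volume:", paste(dim(x$label_volume), collapse = " x "),
      "voxels,", paste(x$voxel_dims, collapse = " x "), "mm\n")
  invisible(x)
}

same_atlas <- function(a, b) {
  identical(a$region_id, b$region_id) &&
    identical(a$compartment, b$compartment)
}
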