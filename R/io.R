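#' Read a 3-D NIfTI volume
#'
#' Thin wrapper around RNifti that enforces the package's contract: volumes
#' are 3-D, co-registered grids; NaN voxels are preserved as missing data.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return The image as a numeric 3-D array (an RNifti image, which keeps
#'   the spatial metadata as attributes).
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("volume file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (length(dim(img)) != 3L)
    stop("expected 3-D volume, got ", length(dim(img)), "-D: ", path,
         call. = FALSE)
  img
}

#' Write a 3-D volume to NIfTI
#'
#' @param volume 3-D numeric array.
#' @param path output `.nii` / `.nii.gz` path.
#' @param voxel_dims voxel edge lengths in mm.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, voxel_dims = c(2, 2, 2)) {
  if (length(dim(volume)) != 3L)
    stop("expected 3-D volume", call. = FALSE)
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- voxel_dims
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write regional maps to a TSV table
#'
#' One row per region with the fixed header `region_id`, `region_name`,
#' `compartment`, `hemisphere`, followed by one column per map. Invalid
#' regions are written as the literal string `NaN`, so the table is
#' diff-able and [read_regional_table()] inverts it exactly.
#'
#' @param maps a `regional_map` or named list of them (names become column
#'   headers; unnamed maps use their quantity).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regional_table <- function(maps, path) {
  if (inherits(maps, "regional_map")) maps <- list(maps)
  stopifnot(length(maps) >= 1L)
  lapply(maps, function(m) stopifnot(inherits(m, "regional_map")))
  for (m in maps[-1]) check_shared_atlas(maps[[1]], m)
  nm <- names(maps)
  if (is.null(nm)) nm <- rep("", length(maps))
  fallback <- vapply(maps, function(m) m$quantity, "")
  nm <- ifelse(nzchar(nm), nm, fallback)
  if (anyDuplicated(nm))
    nm <- make.unique(nm, sep = "_")
  out <- maps[[1]]$regions
  for (i in seq_along(maps)) out[[nm[i]]] <- maps[[i]]$values
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NaN")
  invisible(path)
}

#' Read a regional table written by [write_regional_table()]
#'
#' @param path TSV path.
#' @return Named list of `regional_map` objects, one per value column.
#'   Empty or `NaN` cells reconstruct as invalid regions. Value columns are
#'   mapped back to quantities by column name where the name is one of the
#'   known quantities, otherwise "mean".
#' @export
read_regional_table <- function(path) {
  if (!file.exists(path))
    stop("regional table not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = c("NA", "NaN", ""))
  required <- c("region_id", "region_name", "compartment", "hemisphere")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("regional table missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab$region_id))
    stop("duplicate region_id in regional table", call. = FALSE)
  tab$hemisphere <- as.character(tab$hemisphere)
  regions <- validate_regions(tab[required])
  value_cols <- setdiff(names(tab), required)
  if (!length(value_cols))
    stop("regional table has no value columns", call. = FALSE)
  known <- c("mean", "std", "cv", "scaled_cv")
  maps <- lapply(value_cols, function(cn) {
    qty <- sub("_[0-9]+$", "", cn)
    if (!qty %in% known) qty <- "mean"
    regional_map(tab[[cn]], regions, quantity = qty)
  })
  stats::setNames(maps, value_cols)
}
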