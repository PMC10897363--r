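#' Label contiguous patches of natural space
#'
#' Connected-component labelling of the 1-cells of a binary raster. Patch
#' area is cell count times the cell area, so a 0.5 ha patch is 50 cells at
#' 10 m resolution. Nodata cells are background.
#'
#' @param binary Binary `{0, 1, nodata}` [ugrid].
#' @param connectivity 4 (edge-sharing neighbours only) or 8 (diagonal
#'   touching also joins a patch; the default, the more inclusive reading of
#'   "contiguous").
#' @return A `patch_set`: list with `labels` (integer [ugrid], 0 =
#'   background), `areas_m2` (named by label) and `n_patches`.
#' @export
label_patches <- function(binary, connectivity = 8) {
  stopifnot(inherits(binary, "ugrid"))
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8", call. = FALSE)
  check_binary(binary)
  lab <- label_patches_cpp(binary$values + 0, as.integer(connectivity))
  n_lab <- max(lab, 0L, na.rm = TRUE)
  counts <- tabulate(lab[!is.na(lab) & lab > 0], nbins = n_lab)
  areas <- counts * binary$cell_size^2
  names(areas) <- seq_len(n_lab)
  structure(
    list(labels = ugrid(lab, cell_size = binary$cell_size, origin = binary$origin,
                        crs_tag = binary$crs_tag, nodata = binary$nodata),
         areas_m2 = areas, n_patches = length(areas)),
    class = "patch_set"
  )
}

#' @export
print.patch_set <- function(x, ...) {
  cat("<patch_set>", x$n_patches, "patch(es)")
  if (x$n_patches) cat("; areas", min(x$areas_m2), "-", max(x$areas_m2), "m^2")
  cat("\n")
  invisible(x)
}

check_binary <- function(grid) {
  v <- grid$values
  if (any(!is.na(v) & v != 0 & v != 1)) {
    stop("grid is not binary: values must be 0, 1 or nodata", call. = FALSE)
  }
  invisible(TRUE)
}

#' Drop natural-space patches below a minimum area
#'
#' Keeps only cells belonging to contiguous patches of at least
#' `min_area_m2`, zeroing the rest. The 0.5 ha (5,000 m2) default follows the
#' WHO public-greenspace unit and excludes most private lawns and gardens.
#' Idempotent; never adds cells.
#'
#' @inheritParams label_patches
#' @param min_area_m2 Minimum patch area in square metres (default 5,000).
#' @return Binary [ugrid] of the surviving patches.
#' @export
filter_small_patches <- function(binary, min_area_m2 = 5000, connectivity = 8) {
  if (!is.numeric(min_area_m2) || length(min_area_m2) != 1L || min_area_m2 <= 0) {
    stop("`min_area_m2` must be a positive area", call. = FALSE)
  }
  ps <- label_patches(binary, connectivity)
  keep_labels <- which(ps$areas_m2 >= min_area_m2)
  lab <- ps$labels$values
  out <- lab
  valid <- !is.na(lab)
  out[valid] <- as.numeric(lab[valid] %in% keep_labels)
  ugrid(out, cell_size = binary$cell_size, origin = binary$origin,
        crs_tag = binary$crs_tag, nodata = binary$nodata)
}

#' Flag cells with walkable access to sizeable natural space
#'
#' For every 10 m cell, sums the filtered natural-space area within a
#' Euclidean buffer of `radius_m` of the cell centre (discrete disk of cell
#' centres, focal cell included) and flags the cell when that area reaches
#' `min_area_m2`. The 1,000 m default operationalises a 15-minute walk.
#' Because the input is pre-filtered to patches >= `min_area_m2`, partial
#' slivers of large patches inside the buffer count toward the total. Area
#' outside the raster contributes nothing; nodata cells contribute nothing
#' and their own flag is nodata.
#'
#' @param filtered Binary [ugrid], normally from [filter_small_patches()].
#' @param radius_m Buffer radius in metres (default 1,000).
#' @param min_area_m2 Minimum natural area within the buffer (default 5,000).
#' @return Binary 10 m access-flag [ugrid].
#' @export
buffer_access <- function(filtered, radius_m = 1000, min_area_m2 = 5000) {
  stopifnot(inherits(filtered, "ugrid"))
  if (!is.numeric(radius_m) || length(radius_m) != 1L || radius_m <= 0) {
    stop("`radius_m` must be a positive distance", call. = FALSE)
  }
  check_binary(filtered)
  counts <- focal_disk_sum_cpp(filtered$values + 0, radius_m / filtered$cell_size)
  flags <- (counts * filtered$cell_size^2 >= min_area_m2) + 0
  flags[is.na(filtered$values)] <- NA
  ugrid(flags, cell_size = filtered$cell_size, origin = filtered$origin,
        crs_tag = filtered$crs_tag, nodata = filtered$nodata)
}

#' Aggregate 10 m access flags to 100 m access fractions
#'
#' Area-weighted mean of the binary flags over 10 x 10 blocks: each 100 m
#' cell becomes the fraction of its area with access to sufficient nearby
#' natural space.
#'
#' @param flags Binary 10 m access [ugrid] from [buffer_access()].
#' @param factor Aggregation factor (default 10, i.e. 10 m to 100 m).
#' @return Fractional [ugrid] in \[0, 1\] at the coarse resolution.
#' @export
access_fraction_100m <- function(flags, factor = 10) {
  check_binary(flags)
  block_aggregate(flags, factor, reducer = "mean")
}
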