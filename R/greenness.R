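#' Bundle near-infrared and red reflectance rasters for one acquisition date
#'
#' @param nir,vis Aligned [ugrid]s of non-negative reflectance (NIR is
#'   Sentinel-2 band B8, VIS the visible red band B4). Any common scaling
#'   (0-1 floats or integer digital numbers) is accepted: NDVI is invariant
#'   to it.
#' @param date_tag Opaque label for the acquisition date.
#' @return A `band_pair` object.
#' @export
band_pair <- function(nir, vis, date_tag = "") {
  stopifnot(inherits(nir, "ugrid"), inherits(vis, "ugrid"))
  stop_if_misaligned(nir, vis, "bands")
  if (any(nir$values < 0, na.rm = TRUE) || any(vis$values < 0, na.rm = TRUE)) {
    stop("reflectances must be >= 0 or nodata", call. = FALSE)
  }
  structure(list(nir = nir, vis = vis, date_tag = as.character(date_tag)),
            class = "band_pair")
}

#' Normalized difference vegetation index
#'
#' NDVI = (NIR - VIS) / (NIR + VIS) per cell, in \[-1, 1\]. Cells where either
#' band is nodata, or where NIR + VIS = 0 (the ratio is undefined), are
#' nodata; greenest-pixel compositing normally fills the latter.
#'
#' @param bands A [band_pair()].
#' @return NDVI [ugrid] with valid values in \[-1, 1\].
#' @export
compute_ndvi <- function(bands) {
  stopifnot(inherits(bands, "band_pair"))
  nir <- bands$nir$values
  vis <- bands$vis$values
  denom <- nir + vis
  v <- (nir - vis) / denom
  v[!is.na(denom) & denom == 0] <- NA
  ugrid(v, cell_size = bands$nir$cell_size, origin = bands$nir$origin,
        crs_tag = bands$nir$crs_tag, nodata = bands$nir$nodata)
}

#' Greenest-pixel composite over multiple dates
#'
#' Per-cell maximum NDVI across all acquisition dates of the year. Taking the
#' greenest day per pixel removes cloudy observations (clouds depress NDVI)
#' and captures peak growing season in both hemispheres. Nodata dates are
#' ignored per cell; a cell is nodata only when no date observes it.
#'
#' @param layers List of aligned NDVI [ugrid]s, one per date.
#' @return Composite NDVI [ugrid].
#' @export
greenest_composite <- function(layers) {
  if (!is.list(layers) || length(layers) == 0L) {
    stop("need at least one NDVI layer", call. = FALSE)
  }
  lapply(layers, function(l) stopifnot(inherits(l, "ugrid")))
  first <- layers[[1]]
  if (length(layers) > 1L) {
    for (l in layers[-1]) stop_if_misaligned(first, l, "NDVI layers")
  }
  acc <- first$values
  for (l in layers[-1]) {
    v <- l$values
    take <- !is.na(v) & (is.na(acc) | v > acc)
    acc[take] <- v[take]
  }
  ugrid(acc, cell_size = first$cell_size, origin = first$origin,
        crs_tag = first$crs_tag, nodata = first$nodata)
}

#' Fuse surface water into an NDVI layer (natural-space NDVI)
#'
#' Builds the combined green + blue exposure layer: open-water cells are set
#' to 1 (blue space is equated with the highest NDVI), and cells with a
#' negative composite NDVI — indicative of residual cloud or unmapped water —
#' are also treated as blue space and set to 1. All other cells keep their
#' NDVI.
#'
#' @param ndvi Composite NDVI [ugrid].
#' @param landcover Aligned categorical landcover [ugrid].
#' @param scheme A [worldcover_scheme()].
#' @return Natural-space NDVI [ugrid].
#' @export
fuse_natural_ndvi <- function(ndvi, landcover, scheme = worldcover_scheme()) {
  stopifnot(inherits(ndvi, "ugrid"), inherits(landcover, "ugrid"),
            inherits(scheme, "landcover_scheme"))
  stop_if_misaligned(ndvi, landcover, "NDVI and landcover")
  v <- ndvi$values
  water <- !is.na(landcover$values) & landcover$values == scheme$water_code
  v[water] <- 1
  v[!water & !is.na(v) & v < 0] <- 1
  ugrid(v, cell_size = ndvi$cell_size, origin = ndvi$origin,
        crs_tag = ndvi$crs_tag, nodata = ndvi$nodata)
}

#' Threshold a natural-space NDVI layer into a binary natural mask
#'
#' A cell is natural (1) when its fused NDVI is at or above `t` (inclusive).
#' Water cells carry the fused value 1, so they are included at any threshold
#' `t <= 1`.
#'
#' @param natural_ndvi Fused NDVI [ugrid] from [fuse_natural_ndvi()].
#' @param t NDVI threshold in \[-1, 1\], typically the per-city prediction at
#'   75% green area (see [convert_qtc()]).
#' @return Binary [ugrid] at the input resolution.
#' @export
threshold_natural <- function(natural_ndvi, t) {
  stopifnot(inherits(natural_ndvi, "ugrid"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < -1 || t > 1) {
    stop("threshold must be a single value in [-1, 1]", call. = FALSE)
  }
  v <- natural_ndvi$values
  keep <- !is.na(v)
  v[keep] <- as.numeric(v[keep] >= t)
  ugrid(v, cell_size = natural_ndvi$cell_size, origin = natural_ndvi$origin,
        crs_tag = natural_ndvi$crs_tag, nodata = natural_ndvi$nodata)
}
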