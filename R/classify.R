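#' The ESA WorldCover landcover scheme
#'
#' Encodes the 11 WorldCover classes and the subset treated as greenspace.
#' The default green set contains the seven vegetated classes (trees,
#' shrubland, grassland, cropland, herbaceous wetland, mangroves,
#' moss/lichen); built-up, bare/sparse, snow/ice and open water are excluded.
#' Open water is the blue-space class: natural space is green plus water.
#' Permeable but unvegetated surfaces are not counted as green; adjust
#' `green_classes` to change that.
#'
#' @param class_codes Named integer vector mapping class names to raster
#'   codes. Defaults to the WorldCover convention (trees = 10, ...,
#'   moss_lichen = 100).
#' @param green_classes Character vector of class names counted as greenspace.
#' @param water_class Name of the surface-water class.
#' @return A `landcover_scheme` object.
#' @examples
#' sch <- worldcover_scheme()
#' sch$green_codes
#' @export
worldcover_scheme <- function(class_codes = c(
                                trees = 10L, shrubland = 20L, grassland = 30L,
                                cropland = 40L, built_up = 50L, bare_sparse = 60L,
                                snow_ice = 70L, open_water = 80L,
                                herbaceous_wetland = 90L, mangroves = 95L,
                                moss_lichen = 100L
                              ),
                              green_classes = c("trees", "shrubland", "grassland",
                                                "cropland", "herbaceous_wetland",
                                                "mangroves", "moss_lichen"),
                              water_class = "open_water") {
  if (anyDuplicated(class_codes)) stop("class codes must be unique", call. = FALSE)
  if (anyDuplicated(names(class_codes))) stop("class names must be unique", call. = FALSE)
  missing_green <- setdiff(green_classes, names(class_codes))
  if (length(missing_green)) {
    stop("green classes not in scheme: ", paste(missing_green, collapse = ", "),
         call. = FALSE)
  }
  if (!water_class %in% names(class_codes)) {
    stop("water class not in scheme: ", water_class, call. = FALSE)
  }
  structure(
    list(class_codes = class_codes,
         green_classes = green_classes,
         water_class = water_class,
         green_codes = unname(class_codes[green_classes]),
         water_code = unname(class_codes[water_class])),
    class = "landcover_scheme"
  )
}

#' @export
print.landcover_scheme <- function(x, ...) {
  cat("<landcover_scheme>", length(x$class_codes), "classes;",
      length(x$green_classes), "green;", "water =", x$water_class, "\n")
  invisible(x)
}

check_landcover_codes <- function(landcover, scheme) {
  v <- landcover$values
  known <- v %in% scheme$class_codes | is.na(v)
  if (!all(known)) {
    bad <- sort(unique(v[!known]))
    stop("unknown landcover code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

reclassify_binary <- function(landcover, codes_one) {
  out <- landcover$values
  keep <- !is.na(out)
  out[keep] <- as.numeric(out[keep] %in% codes_one)
  ugrid(out, cell_size = landcover$cell_size, origin = landcover$origin,
        crs_tag = landcover$crs_tag, nodata = landcover$nodata)
}

#' Binary greenspace mask from a landcover raster
#'
#' A 10 m cell is green (1) when its landcover class is in the scheme's green
#' set, 0 otherwise; nodata propagates. This is the binary layer the Quality
#' Total Cover target is evaluated on.
#'
#' @param landcover Categorical [ugrid] of landcover codes.
#' @param scheme A [worldcover_scheme()].
#' @return Binary [ugrid].
#' @export
classify_green <- function(landcover, scheme = worldcover_scheme()) {
  stopifnot(inherits(landcover, "ugrid"), inherits(scheme, "landcover_scheme"))
  check_landcover_codes(landcover, scheme)
  reclassify_binary(landcover, scheme$green_codes)
}

#' Binary natural-space (green + blue) mask from a landcover raster
#'
#' As [classify_green()], but open-water cells are also 1: natural space is
#' the union of green and blue space. This layer feeds the Equitable Spatial
#' Distribution accessibility metric.
#'
#' @inheritParams classify_green
#' @return Binary [ugrid].
#' @export
classify_natural <- function(landcover, scheme = worldcover_scheme()) {
  stopifnot(inherits(landcover, "ugrid"), inherits(scheme, "landcover_scheme"))
  check_landcover_codes(landcover, scheme)
  reclassify_binary(landcover, c(scheme$green_codes, scheme$water_code))
}
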