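#' City-level summary of greenness, natural space and access
#'
#' Means over the 100 m cells inside the city boundary: unweighted means for
#' NDVI and the green/natural/access fractions, and a population-weighted
#' access share `access_fraction_pop = sum(pop * access) / sum(pop)` — the
#' proportion of the (adult) population living in cells with walkable access
#' to natural space. Cells with zero population still count in area means but
#' contribute nothing to the population-weighted share.
#'
#' @param ndvi_100m,natural_ndvi_100m 100 m composite and fused NDVI [ugrid]s.
#' @param green_frac_100m,natural_frac_100m 100 m green/natural area-fraction
#'   [ugrid]s.
#' @param access_frac_100m 100 m access-fraction [ugrid] from
#'   [access_fraction_100m()].
#' @param pop_100m 100 m population-count [ugrid], or `NULL` if unavailable
#'   (the population-weighted share is then reported `NA`).
#' @param mask 100 m [ugrid] city mask (truthy inside the boundary).
#' @return One-row tibble: `mean_ndvi`, `mean_natural_ndvi`, `green_fraction`,
#'   `natural_fraction`, `access_fraction_area`, `access_fraction_pop`,
#'   `n_cells`.
#' @export
summarize_city <- function(ndvi_100m, natural_ndvi_100m, green_frac_100m,
                           natural_frac_100m, access_frac_100m,
                           pop_100m = NULL, mask) {
  grids <- list(ndvi_100m, natural_ndvi_100m, green_frac_100m,
                natural_frac_100m, access_frac_100m)
  for (g in grids) stop_if_misaligned(g, mask, "layer and mask")
  inside <- !is.na(mask$values) & mask$values != 0
  if (!any(inside)) stop("empty city mask", call. = FALSE)

  city_mean <- function(g) mean(g$values[inside], na.rm = TRUE)

  access_pop <- NA_real_
  if (!is.null(pop_100m)) {
    stop_if_misaligned(pop_100m, mask, "population and mask")
    pop <- pop_100m$values[inside]
    acc <- access_frac_100m$values[inside]
    ok <- !is.na(pop) & !is.na(acc)
    total_pop <- sum(pop[ok])
    if (is.finite(total_pop) && total_pop > 0) {
      access_pop <- sum(pop[ok] * acc[ok]) / total_pop
    } else {
      warning("total population is zero; population-weighted access is undefined",
              call. = FALSE)
    }
  }

  tibble::tibble(
    mean_ndvi = city_mean(ndvi_100m),
    mean_natural_ndvi = city_mean(natural_ndvi_100m),
    green_fraction = city_mean(green_frac_100m),
    natural_fraction = city_mean(natural_frac_100m),
    access_fraction_area = city_mean(access_frac_100m),
    access_fraction_pop = access_pop,
    n_cells = sum(inside)
  )
}

#' Evaluate city metrics against the two Urban Nature Declaration targets
#'
#' Quality Total Cover: 30-40% of the city area is greenspace; passes are
#' reported at both ends of the range. Equitable Spatial Distribution: 70% of
#' the population has walkable access to green or blue space. All comparisons
#' are inclusive ("at least").
#'
#' @param metrics One-row tibble from [summarize_city()].
#' @param qtc_range Length-2 numeric, the lower and upper Quality Total Cover
#'   levels (default `c(0.30, 0.40)`).
#' @param esd_threshold Equitable Spatial Distribution population share
#'   (default 0.70).
#' @return One-row tibble: `qtc_pass_30`, `qtc_pass_40`, `esd_pass` plus the
#'   thresholds used.
#' @export
evaluate_targets <- function(metrics, qtc_range = c(0.30, 0.40),
                             esd_threshold = 0.70) {
  stopifnot(is.data.frame(metrics), nrow(metrics) == 1L,
            length(qtc_range) == 2L, qtc_range[1] <= qtc_range[2])
  tibble::tibble(
    qtc_pass_30 = metrics$green_fraction >= qtc_range[1],
    qtc_pass_40 = metrics$green_fraction >= qtc_range[2],
    esd_pass = if (is.na(metrics$access_fraction_pop)) NA
               else metrics$access_fraction_pop >= esd_threshold,
    qtc_lower = qtc_range[1],
    qtc_upper = qtc_range[2],
    esd_threshold = esd_threshold
  )
}
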