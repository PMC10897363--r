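#' Recipe for a synthetic city
#'
#' Parameters of the synthetic-city generator, which emulates the four data
#' layers the pipeline consumes: a spatially autocorrelated 10 m landcover
#' raster over the 11 WorldCover classes (with stamped water bodies), per-date
#' 10 m NIR/red reflectance pairs whose NDVI is a class-conditional field with
#' seasonal depression and cloud dropouts, a 100 m adult-population raster
#' concentrated in built-up cells, and an irregular city boundary mask at both
#' resolutions.
#'
#' Default class mixture gives roughly 43% green and 4% water area, matching
#' the magnitude of green (0.427) and natural (0.464) city-mean area shares
#' typical of large cities. Per-class NDVI means follow the usual ordering of
#' vegetation density (trees 0.75 down to built-up 0.15, water -0.20 before
#' fusion).
#'
#' @param shape 10 m grid dimensions `(rows, cols)`; both multiples of 10.
#' @param seed Integer seed; all randomness flows from it.
#' @param cell_size Fine cell edge in metres (default 10).
#' @param origin,crs_tag Georeferencing carried onto every layer.
#' @param corr_len Correlation length (cells) of the landcover random
#'   field; the default 60 cells (600 m) gives district-scale landcover
#'   structure.
#' @param mixture Named proportions over the 11 WorldCover classes; must sum
#'   to 1 and be non-negative.
#' @param core_gradient Strength of the urban-core gradient: 0 gives
#'   spatially stationary landcover; larger values concentrate built-up and
#'   bare classes toward the city centre and vegetation toward the
#'   periphery, the way dense central districts displace greenspace in real
#'   cities. Class proportions over the whole grid are preserved.
#' @param n_water_bodies,water_body_radius_m Contiguous water blobs stamped
#'   on top of the mixture field.
#' @param ndvi_class_mean Named per-class clear-sky NDVI means.
#' @param ndvi_sd Standard deviation of the correlated NDVI noise field.
#' @param n_dates Number of acquisition dates (>= 1).
#' @param seasonal_depression Per-date NDVI depression; defaults to equal
#'   steps from 0 (peak season) to 0.3; the minimum is always shifted to 0.
#' @param cloud_prob Per-date, per-cell probability of a cloud dropout.
#' @param cloud_depression NDVI depression applied to clouded cells, large
#'   enough for the greenest-pixel composite to discard them.
#' @param population_total Total adult population inside the boundary.
#' @param builtup_concentration Exponent concentrating population in
#'   built-up 100 m cells.
#' @param pop_noise_sd Lognormal sd of multiplicative population noise.
#' @param boundary_fraction Fraction of the grid inside the city boundary.
#' @param boundary_irregularity 0 = smooth ellipse-like boundary; larger
#'   values roughen it with the correlated field.
#' @return A `city_recipe` object.
#' @export
city_recipe <- function(shape = c(1000, 1000), seed = 1, cell_size = 10,
                        origin = c(0, 0), crs_tag = "synthetic-utm-m",
                        corr_len = 60,
                        mixture = c(trees = 0.16, shrubland = 0.04,
                                    grassland = 0.12, cropland = 0.06,
                                    built_up = 0.43, bare_sparse = 0.10,
                                    snow_ice = 0, open_water = 0.04,
                                    herbaceous_wetland = 0.03, mangroves = 0,
                                    moss_lichen = 0.02),
                        n_water_bodies = 2, water_body_radius_m = 200,
                        ndvi_class_mean = c(trees = 0.75, shrubland = 0.55,
                                            grassland = 0.50, cropland = 0.60,
                                            herbaceous_wetland = 0.55,
                                            mangroves = 0.70, moss_lichen = 0.35,
                                            built_up = 0.15, bare_sparse = 0.10,
                                            snow_ice = 0.05, open_water = -0.20),
                        core_gradient = 2, ndvi_sd = 0.05, n_dates = 4,
                        seasonal_depression = NULL, cloud_prob = 0.10,
                        cloud_depression = 0.8,
                        population_total = 5e5, builtup_concentration = 2,
                        pop_noise_sd = 0.3,
                        boundary_fraction = 0.6, boundary_irregularity = 0.3) {
  if (length(shape) != 2L || any(shape < 10) || any(shape %% 10 != 0)) {
    stop("`shape` must be two multiples of 10, each >= 10", call. = FALSE)
  }
  if (any(mixture < 0)) stop("impossible mixture: negative proportion", call. = FALSE)
  if (abs(sum(mixture) - 1) > 1e-8) stop("mixture proportions must sum to 1", call. = FALSE)
  scheme <- worldcover_scheme()
  if (!all(names(mixture) %in% names(scheme$class_codes))) {
    stop("mixture names must be WorldCover class names", call. = FALSE)
  }
  if (is.null(seasonal_depression)) {
    seasonal_depression <- seq(0, 0.3, length.out = max(n_dates, 1))
  }
  if (length(seasonal_depression) != n_dates) {
    stop("`seasonal_depression` must have one value per date", call. = FALSE)
  }
  seasonal_depression <- seasonal_depression - min(seasonal_depression)
  if (n_dates < 1) stop("need at least one date", call. = FALSE)
  if (cloud_prob < 0 || cloud_prob > 1) stop("cloud_prob must be in [0, 1]", call. = FALSE)
  if (n_water_bodies > 0 &&
      2 * water_body_radius_m >= min(shape) * cell_size) {
    stop("shape too small for requested water bodies", call. = FALSE)
  }
  structure(
    list(shape = as.integer(shape), seed = as.integer(seed),
         cell_size = cell_size, origin = origin, crs_tag = crs_tag,
         corr_len = corr_len, mixture = mixture,
         core_gradient = core_gradient,
         n_water_bodies = n_water_bodies,
         water_body_radius_m = water_body_radius_m,
         ndvi_class_mean = ndvi_class_mean, ndvi_sd = ndvi_sd,
         n_dates = as.integer(n_dates),
         seasonal_depression = seasonal_depression,
         cloud_prob = cloud_prob, cloud_depression = cloud_depression,
         population_total = population_total,
         builtup_concentration = builtup_concentration,
         pop_noise_sd = pop_noise_sd,
         boundary_fraction = boundary_fraction,
         boundary_irregularity = boundary_irregularity,
         scheme = scheme),
    class = "city_recipe"
  )
}

# Stationary Gaussian random field with ~Gaussian correlation, unit variance,
# generated by spectral (FFT) smoothing of white noise; periodic wraparound.
gaussian_field <- function(nr, nc, corr_len) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (corr_len <= 0) return(z)
  fr <- (seq_len(nr) - 1) / nr; fr[fr > 0.5] <- fr[fr > 0.5] - 1
  fc <- (seq_len(nc) - 1) / nc; fc[fc > 0.5] <- fc[fc > 0.5] - 1
  h <- exp(-2 * pi^2 * corr_len^2 * outer(fr^2, fc^2, `+`))
  f <- Re(stats::fft(stats::fft(z) * h, inverse = TRUE)) / (nr * nc)
  s <- stats::sd(f)
  # a correlation length much larger than the grid smooths the field flat
  if (s < 1e-12) return(matrix(0, nr, nc))
  (f - mean(f)) / s
}

disk_cells <- function(nr, nc, center, radius_cells) {
  r <- ceiling(radius_cells)
  rows <- max(1, center[1] - r):min(nr, center[1] + r)
  cols <- max(1, center[2] - r):min(nc, center[2] + r)
  idx <- expand.grid(i = rows, j = cols)
  d2 <- (idx$i - center[1])^2 + (idx$j - center[2])^2
  idx[d2 <= radius_cells^2, , drop = FALSE]
}

clamp <- function(x, lo = -1, hi = 1) pmin(pmax(x, lo), hi)

bands_from_ndvi <- function(v, cell_size, origin, crs_tag, date_tag) {
  band_pair(
    nir = ugrid((1 + v) / 2, cell_size, origin, crs_tag),
    vis = ugrid((1 - v) / 2, cell_size, origin, crs_tag),
    date_tag = date_tag
  )
}

#' Generate a synthetic city bundle
#'
#' Draws all input layers for one city from a [city_recipe()]. Landcover is a
#' spatially correlated field thresholded at the mixture proportions, with
#' contiguous water bodies stamped on top. For each date, the per-cell target
#' NDVI is the class mean plus a correlated noise field, minus that date's
#' seasonal depression; clouded cells are further depressed so the
#' greenest-pixel composite discards them wherever the peak date is clear.
#' Reflectance bands are synthesised as `nir = (1 + v) / 2`,
#' `vis = (1 - v) / 2`, so [compute_ndvi()] recovers the target field
#' exactly. Population is proportional to built-up density (raised to the
#' concentration exponent) with lognormal noise, normalised to the recipe
#' total inside the boundary. Deterministic for a fixed seed.
#'
#' @param recipe A [city_recipe()].
#' @return A `city_bundle`: list with `landcover` (10 m [ugrid]), `bands`
#'   (list of [band_pair()], one per date), `population` (100 m [ugrid]),
#'   `mask_10m`, `mask_100m` ([ugrid]s), `recipe`, and `ground_truth`
#'   (clear-sky NDVI grid, cloud masks, true green/natural fractions, class
#'   NDVI parameters).
#' @export
generate_city <- function(recipe) {
  stopifnot(inherits(recipe, "city_recipe"))
  withr::with_seed(recipe$seed, generate_city_impl(recipe))
}

generate_city_impl <- function(recipe) {
  nr <- recipe$shape[1]; nc <- recipe$shape[2]
  cs <- recipe$cell_size
  scheme <- recipe$scheme
  mk <- function(v) ugrid(v, cs, recipe$origin, recipe$crs_tag)

  # landcover: threshold a correlated field, tilted by an urban-core
  # gradient, at the mixture quantiles; classes are ordered from the barren
  # core outward so built-up/bare concentrate centrally while the global
  # class proportions stay at the mixture exactly
  f_lc <- gaussian_field(nr, nc, recipe$corr_len)
  if (recipe$core_gradient != 0) {
    rr <- (seq_len(nr) - (nr + 1) / 2) / (nr / 2)
    cc <- (seq_len(nc) - (nc + 1) / 2) / (nc / 2)
    radial <- sqrt(outer(rr^2, cc^2, `+`))
    f_lc <- f_lc + recipe$core_gradient * radial
  }
  core_first <- c("built_up", "bare_sparse", "snow_ice", "moss_lichen",
                  "grassland", "shrubland", "cropland", "herbaceous_wetland",
                  "mangroves", "trees", "open_water")
  mix <- recipe$mixture[recipe$mixture > 0]
  mix <- mix[order(match(names(mix), core_first))]
  qs <- stats::quantile(f_lc, cumsum(mix), names = FALSE)
  qs[length(qs)] <- Inf
  cls <- findInterval(f_lc, c(-Inf, qs[-length(qs)]))
  codes <- unname(scheme$class_codes[names(mix)])
  lc <- matrix(codes[cls], nr, nc)

  # stamped contiguous water bodies
  if (recipe$n_water_bodies > 0) {
    rad_cells <- recipe$water_body_radius_m / cs
    margin <- ceiling(rad_cells) + 1
    for (k in seq_len(recipe$n_water_bodies)) {
      ctr <- c(sample(margin:(nr - margin), 1), sample(margin:(nc - margin), 1))
      cells <- disk_cells(nr, nc, ctr, rad_cells)
      lc[cbind(cells$i, cells$j)] <- scheme$water_code
    }
  }

  # clear-sky NDVI: class mean + correlated noise
  code_mean <- recipe$ndvi_class_mean[match(lc, scheme$class_codes[names(recipe$ndvi_class_mean)])]
  v_clear <- clamp(matrix(code_mean, nr, nc) +
                     recipe$ndvi_sd * gaussian_field(nr, nc, recipe$corr_len / 3))

  # per-date bands: seasonal depression + cloud dropouts
  clouds <- vector("list", recipe$n_dates)
  bands <- vector("list", recipe$n_dates)
  for (d in seq_len(recipe$n_dates)) {
    clouds[[d]] <- matrix(stats::runif(nr * nc) < recipe$cloud_prob, nr, nc)
    v_d <- v_clear - recipe$seasonal_depression[d] -
      ifelse(clouds[[d]], recipe$cloud_depression, 0)
    bands[[d]] <- bands_from_ndvi(clamp(v_d), cs, recipe$origin, recipe$crs_tag,
                                  date_tag = sprintf("date_%02d", d))
  }

  # irregular boundary at 100 m, expanded block-wise to 10 m
  nr1 <- nr %/% 10L; nc1 <- nc %/% 10L
  rr <- (seq_len(nr1) - (nr1 + 1) / 2) / (nr1 / 2)
  cc <- (seq_len(nc1) - (nc1 + 1) / 2) / (nc1 / 2)
  radial <- 1 - sqrt(outer(rr^2, cc^2, `+`))
  score <- radial + recipe$boundary_irregularity * gaussian_field(nr1, nc1, recipe$corr_len / 5 + 2)
  cut <- stats::quantile(score, 1 - recipe$boundary_fraction, names = FALSE)
  mask1 <- (score >= cut) + 0
  if (!any(mask1 == 1)) mask1[ceiling(nr1 / 2), ceiling(nc1 / 2)] <- 1
  mask10 <- mask1[rep(seq_len(nr1), each = 10L), rep(seq_len(nc1), each = 10L)]

  # population at 100 m: built-up concentration + lognormal noise, in-city only
  built10 <- (lc == scheme$class_codes[["built_up"]]) + 0
  built1 <- block_aggregate(mk(built10), 10, "mean")$values
  w <- (built1 + 0.01)^recipe$builtup_concentration *
    exp(stats::rnorm(nr1 * nc1, 0, recipe$pop_noise_sd))
  w <- matrix(w, nr1, nc1) * mask1
  pop1 <- if (sum(w) > 0) recipe$population_total * w / sum(w) else w

  in10 <- mask10 == 1
  ground_truth <- list(
    clear_ndvi = mk(v_clear),
    clouds = clouds,
    green_fraction = mean(lc[in10] %in% scheme$green_codes),
    natural_fraction = mean(lc[in10] %in% c(scheme$green_codes, scheme$water_code)),
    class_ndvi_mean = recipe$ndvi_class_mean,
    ndvi_sd = recipe$ndvi_sd
  )

  g100 <- function(v) ugrid(v, cs * 10, recipe$origin, recipe$crs_tag)
  structure(
    list(landcover = mk(lc), bands = bands, population = g100(pop1),
         mask_10m = mk(mask10), mask_100m = g100(mask1),
         recipe = recipe, ground_truth = ground_truth),
    class = "city_bundle"
  )
}

#' @export
print.city_bundle <- function(x, ...) {
  cat(sprintf("<city_bundle> %d x %d cells at %g m, %d date(s), seed %d\n",
              x$recipe$shape[1], x$recipe$shape[2], x$recipe$cell_size,
              x$recipe$n_dates, x$recipe$seed))
  cat(sprintf("  true green fraction %.3f, natural %.3f\n",
              x$ground_truth$green_fraction, x$ground_truth$natural_fraction))
  invisible(x)
}

#' Stamp an analytic geometry into a synthetic city
#'
#' Overwrites the landcover (and, consistently, every date's reflectance
#' bands) in a disk or strip of a given area with a single class, producing
#' fixtures whose patch areas and access geometry are known analytically.
#' The stamped region contains exactly `round(size_m2 / cell_area)` cells —
#' the nearest cells to `location` for a disk, a one-cell-high run for a
#' strip — is contiguous, cloud-free, and carries the class-mean NDVI with no
#' noise.
#'
#' @param bundle A `city_bundle` from [generate_city()].
#' @param shape `"disk"` or `"strip"`.
#' @param class Landcover class name (e.g. `"trees"`).
#' @param size_m2 Stamped area in square metres.
#' @param location `(row, col)` centre (disk) or left end (strip) in 10 m
#'   cells.
#' @return The modified `city_bundle`, ground truth updated.
#' @export
stamp_geometry <- function(bundle, shape = c("disk", "strip"), class,
                           size_m2, location) {
  stopifnot(inherits(bundle, "city_bundle"))
  shape <- match.arg(shape)
  recipe <- bundle$recipe
  scheme <- recipe$scheme
  if (!class %in% names(scheme$class_codes)) {
    stop("unknown landcover class: ", class, call. = FALSE)
  }
  cs <- recipe$cell_size
  n_cells <- max(1L, round(size_m2 / cs^2))
  nr <- recipe$shape[1]; nc <- recipe$shape[2]

  if (shape == "disk") {
    # exactly n_cells nearest cells to the centre (ties broken by scan order)
    r <- ceiling(sqrt(n_cells / pi)) + 2L
    rows <- (location[1] - r):(location[1] + r)
    cols <- (location[2] - r):(location[2] + r)
    if (min(rows) < 1 || max(rows) > nr || min(cols) < 1 || max(cols) > nc) {
      stop("geometry out of bounds", call. = FALSE)
    }
    idx <- expand.grid(i = rows, j = cols)
    d2 <- (idx$i - location[1])^2 + (idx$j - location[2])^2
    idx <- idx[order(d2), , drop = FALSE][seq_len(n_cells), ]
  } else {
    if (location[1] < 1 || location[1] > nr ||
        location[2] < 1 || location[2] + n_cells - 1 > nc) {
      stop("geometry out of bounds", call. = FALSE)
    }
    idx <- data.frame(i = location[1], j = location[2] + seq_len(n_cells) - 1)
  }
  cells <- cbind(idx$i, idx$j)

  bundle$landcover$values[cells] <- scheme$class_codes[[class]]
  v_stamp <- clamp(recipe$ndvi_class_mean[[class]])
  gt <- bundle$ground_truth
  gt$clear_ndvi$values[cells] <- v_stamp
  for (d in seq_along(bundle$bands)) {
    gt$clouds[[d]][cells] <- FALSE
    v_d <- clamp(v_stamp - recipe$seasonal_depression[d])
    bundle$bands[[d]]$nir$values[cells] <- (1 + v_d) / 2
    bundle$bands[[d]]$vis$values[cells] <- (1 - v_d) / 2
  }
  lc <- bundle$landcover$values
  in10 <- bundle$mask_10m$values == 1
  gt$green_fraction <- mean(lc[in10] %in% scheme$green_codes)
  gt$natural_fraction <- mean(lc[in10] %in% c(scheme$green_codes, scheme$water_code))
  bundle$ground_truth <- gt
  bundle
}
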