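#' Pipeline run configuration
#'
#' Bundles every input and tunable of a single-city run. Exactly one of
#' `recipe` (synthetic inputs) or `paths` (rasters on disk) must be given.
#' `paths` is a list with `landcover`, `nir` and `vis` (character vectors,
#' one path per date), `mask` (10 m city mask) and optionally `population`
#' (100 m). All rasters are Esri ASCII grids (see [read_raster()]).
#'
#' @param recipe A [city_recipe()], or `NULL`.
#' @param paths Named list of input raster paths, or `NULL`.
#' @param out_dir Output directory for intermediates and reports.
#' @param min_patch_m2 Minimum natural-space patch area (default 5,000 m2).
#' @param buffer_m Access buffer radius (default 1,000 m).
#' @param qtc_range Quality Total Cover target range (default 0.30-0.40).
#' @param esd_threshold Equitable Spatial Distribution population share
#'   (default 0.70).
#' @param threshold_level Green-area share whose predicted NDVI becomes the
#'   "green pixel" threshold for the NDVI-based access layer; one of 0.75,
#'   0.90, 1.00 (default 0.75, the level with the best access-model fit).
#' @param connectivity Patch connectivity, 4 or 8 (default 8).
#' @param qtc_direction,esd_direction Regression directions, see
#'   [convert_qtc()] and [convert_esd()].
#' @param scheme A [worldcover_scheme()].
#' @param write_intermediates Write the composite, masks and access layers as
#'   rasters under `out_dir` (default TRUE).
#' @return A `run_config` object.
#' @export
run_config <- function(recipe = NULL, paths = NULL, out_dir = tempfile("city_run_"),
                       min_patch_m2 = 5000, buffer_m = 1000,
                       qtc_range = c(0.30, 0.40), esd_threshold = 0.70,
                       threshold_level = 0.75, connectivity = 8,
                       qtc_direction = "ndvi_on_green",
                       esd_direction = "ndvi_on_lc",
                       scheme = worldcover_scheme(),
                       write_intermediates = TRUE) {
  if (is.null(recipe) == is.null(paths)) {
    stop("exactly one of `recipe` or `paths` must be given", call. = FALSE)
  }
  if (!is.null(paths)) {
    need <- c("landcover", "nir", "vis", "mask")
    if (!all(need %in% names(paths))) {
      stop("`paths` needs: ", paste(need, collapse = ", "), call. = FALSE)
    }
    if (length(paths$nir) != length(paths$vis)) {
      stop("`paths$nir` and `paths$vis` must pair up per date", call. = FALSE)
    }
  }
  if (!threshold_level %in% c(0.75, 0.90, 1.00)) {
    stop("`threshold_level` must be one of 0.75, 0.90, 1.00", call. = FALSE)
  }
  stopifnot(min_patch_m2 > 0, buffer_m > 0, connectivity %in% c(4, 8),
            length(qtc_range) == 2L, qtc_range[1] <= qtc_range[2],
            esd_threshold >= 0, esd_threshold <= 1)
  structure(
    list(recipe = recipe, paths = paths, out_dir = out_dir,
         min_patch_m2 = min_patch_m2, buffer_m = buffer_m,
         qtc_range = qtc_range, esd_threshold = esd_threshold,
         threshold_level = threshold_level, connectivity = connectivity,
         qtc_direction = qtc_direction, esd_direction = esd_direction,
         scheme = scheme, write_intermediates = write_intermediates),
    class = "run_config"
  )
}

stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
  })
  message(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
  res
}

load_inputs <- function(config) {
  if (!is.null(config$recipe)) {
    bundle <- generate_city(config$recipe)
    return(list(landcover = bundle$landcover, bands = bundle$bands,
                population = bundle$population, mask_10m = bundle$mask_10m,
                mask_100m = bundle$mask_100m))
  }
  p <- config$paths
  landcover <- read_raster(p$landcover)
  bands <- Map(function(n, v, d) band_pair(read_raster(n), read_raster(v), d),
               p$nir, p$vis, seq_along(p$nir))
  mask_10m <- read_raster(p$mask)
  mask_100m <- block_aggregate(mask_10m, 10, "max")
  population <- if (!is.null(p$population)) read_raster(p$population) else NULL
  list(landcover = landcover, bands = unname(bands), population = population,
       mask_10m = mask_10m, mask_100m = mask_100m)
}

#' Run the full target-evaluation pipeline for one city
#'
#' Executes, in order: greenest-pixel NDVI compositing; landcover
#' classification into green and natural masks; natural-space NDVI fusion;
#' 100 m area-weighted aggregation; patch filtering and buffer access on the
#' landcover natural mask; city summary and target evaluation; the Quality
#' Total Cover regression and its NDVI predictions; NDVI thresholding at the
#' selected prediction and the NDVI-based access layer; and the Equitable
#' Spatial Distribution regression. Patch filtering and buffering run on the
#' full raster (natural space just outside the boundary can serve residents
#' near the edge); the city mask applies only when summarising.
#'
#' Deterministic for a fixed config and seed. Intermediate rasters and
#' `report.json` / `report.csv` are written under `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return A `city_report`: list with `metrics`, `targets`, `qtc`, `esd`,
#'   `ndvi_threshold`, and `provenance` (config hash, seed, package version).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- stage("load-inputs", load_inputs(config))
  scheme <- config$scheme

  ndvi <- stage("ndvi-composite",
                greenest_composite(lapply(inputs$bands, compute_ndvi)))
  green <- stage("classify-green", classify_green(inputs$landcover, scheme))
  natural <- stage("classify-natural", classify_natural(inputs$landcover, scheme))
  natural_ndvi <- stage("fuse-natural-ndvi",
                        fuse_natural_ndvi(ndvi, inputs$landcover, scheme))

  agg <- function(g) block_aggregate(g, 10, "mean")
  ndvi_100 <- stage("aggregate-100m", agg(ndvi))
  natural_ndvi_100 <- agg(natural_ndvi)
  green_frac_100 <- agg(green)
  natural_frac_100 <- agg(natural)

  lc_flags <- stage("landcover-access", {
    kept <- filter_small_patches(natural, config$min_patch_m2, config$connectivity)
    buffer_access(kept, config$buffer_m, config$min_patch_m2)
  })
  lc_access_100 <- access_fraction_100m(lc_flags)

  metrics <- stage("summarize-city",
                   summarize_city(ndvi_100, natural_ndvi_100, green_frac_100,
                                  natural_frac_100, lc_access_100,
                                  inputs$population, inputs$mask_100m))
  targets <- evaluate_targets(metrics, config$qtc_range, config$esd_threshold)

  # a city with no variation in green fraction (fully green or fully built)
  # cannot be converted; metrics and target evaluation remain valid
  qtc <- tryCatch(
    stage("convert-qtc",
          convert_qtc(green_frac_100, ndvi_100, inputs$mask_100m,
                      direction = config$qtc_direction)),
    error = function(e) {
      warning("target conversion skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    }
  )

  esd <- NULL
  ndvi_access_100 <- NULL
  t_green <- NA_real_
  if (!is.null(qtc)) {
    t_green <- qtc$predictions$ndvi[qtc$predictions$green_fraction == config$threshold_level]
    ndvi_flags <- stage("ndvi-access", {
      nat_t <- threshold_natural(natural_ndvi, clamp(t_green))
      kept_t <- filter_small_patches(nat_t, config$min_patch_m2, config$connectivity)
      buffer_access(kept_t, config$buffer_m, config$min_patch_m2)
    })
    ndvi_access_100 <- access_fraction_100m(ndvi_flags)
    esd <- tryCatch(
      stage("convert-esd",
            convert_esd(lc_access_100, ndvi_access_100, inputs$mask_100m,
                        level = config$esd_threshold,
                        direction = config$esd_direction)),
      error = function(e) {
        warning("access conversion skipped: ", conditionMessage(e), call. = FALSE)
        NULL
      }
    )
  }

  na_fit <- tibble::tibble(r.squared = NA_real_, rmse = NA_real_, nobs = NA_integer_)
  report <- structure(
    list(metrics = metrics, targets = targets,
         qtc = if (!is.null(qtc)) {
           list(fit = glance(qtc$fit), predictions = qtc$predictions,
                direction = qtc$direction)
         } else {
           list(fit = na_fit,
                predictions = tibble::tibble(green_fraction = c(0.30, 0.40, 0.75, 0.90, 1.00),
                                             ndvi = NA_real_),
                direction = config$qtc_direction)
         },
         esd = if (!is.null(esd)) {
           list(fit = glance(esd$fit), equivalent_at_level = esd$equivalent_at_level,
                level = esd$level, direction = esd$direction)
         } else {
           list(fit = na_fit, equivalent_at_level = NA_real_,
                level = config$esd_threshold, direction = config$esd_direction)
         },
         ndvi_threshold = list(level = config$threshold_level, value = t_green),
         provenance = list(
           config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
           seed = if (!is.null(config$recipe)) config$recipe$seed else NA,
           package_version = as.character(utils::packageVersion("urbannature")))),
    class = "city_report"
  )

  stage("write-outputs", {
    if (config$write_intermediates) {
      out <- function(g, n) write_raster(g, file.path(config$out_dir, n))
      out(ndvi, "ndvi_composite_10m.asc")
      out(green, "green_10m.asc")
      out(natural, "natural_10m.asc")
      out(natural_ndvi, "natural_ndvi_10m.asc")
      out(green_frac_100, "green_fraction_100m.asc")
      out(lc_access_100, "access_landcover_100m.asc")
      if (!is.null(ndvi_access_100)) out(ndvi_access_100, "access_ndvi_100m.asc")
    }
    write_report(report, config$out_dir)
  })
  report
}

report_row <- function(report) {
  tibble::tibble(
    report$metrics, report$targets,
    qtc_r2 = report$qtc$fit$r.squared, qtc_rmse = report$qtc$fit$rmse,
    ndvi_at_30 = report$qtc$predictions$ndvi[report$qtc$predictions$green_fraction == 0.30],
    ndvi_at_40 = report$qtc$predictions$ndvi[report$qtc$predictions$green_fraction == 0.40],
    ndvi_threshold = report$ndvi_threshold$value,
    threshold_level = report$ndvi_threshold$level,
    esd_r2 = report$esd$fit$r.squared, esd_rmse = report$esd$fit$rmse,
    esd_equivalent_at_70 = report$esd$equivalent_at_level
  )
}

write_report <- function(report, out_dir) {
  json <- unclass(report)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  utils::write.csv(report_row(report), file.path(out_dir, "report.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.city_report <- function(x, ...) {
  cat("<city_report>\n")
  cat(sprintf("  mean NDVI %.3f (natural %.3f); green fraction %.3f (natural %.3f)\n",
              x$metrics$mean_ndvi, x$metrics$mean_natural_ndvi,
              x$metrics$green_fraction, x$metrics$natural_fraction))
  cat(sprintf("  population access share %.3f over %d cells\n",
              x$metrics$access_fraction_pop, x$metrics$n_cells))
  cat(sprintf("  QTC pass at 30%%/40%%: %s/%s; ESD pass: %s\n",
              x$targets$qtc_pass_30, x$targets$qtc_pass_40, x$targets$esd_pass))
  cat(sprintf("  NDVI at 30%%/40%% green: %.3f/%.3f (R2 %.3f, RMSE %.3f)\n",
              x$qtc$predictions$ndvi[1], x$qtc$predictions$ndvi[2],
              x$qtc$fit$r.squared, x$qtc$fit$rmse))
  cat(sprintf("  NDVI threshold (at %.2f green): %.3f; ESD equivalent at %.2f: %.3f (R2 %.3f)\n",
              x$ndvi_threshold$level, x$ndvi_threshold$value,
              x$esd$level, x$esd$equivalent_at_level, x$esd$fit$r.squared))
  invisible(x)
}
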