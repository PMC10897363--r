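small_recipe <- function(...) {
  city_recipe(shape = c(100, 100), seed = 7, n_water_bodies = 1,
              water_body_radius_m = 60, ...)
}

test_that("the generator is deterministic for a fixed seed", {
  a <- generate_city(small_recipe())
  b <- generate_city(small_recipe())
  expect_identical(a$landcover$values, b$landcover$values)
  expect_identical(a$population$values, b$population$values)
  expect_identical(a$mask_100m$values, b$mask_100m$values)
  for (d in seq_along(a$bands)) {
    expect_identical(a$bands[[d]]$nir$values, b$bands[[d]]$nir$values)
  }
  c2 <- generate_city(city_recipe(shape = c(100, 100), seed = 8,
                                  n_water_bodies = 1, water_body_radius_m = 60))
  expect_false(identical(a$landcover$values, c2$landcover$values))
})

test_that("a degenerate all-trees mixture yields a fully green city", {
  mix <- c(trees = 1, shrubland = 0, grassland = 0, cropland = 0, built_up = 0,
           bare_sparse = 0, snow_ice = 0, open_water = 0,
           herbaceous_wetland = 0, mangroves = 0, moss_lichen = 0)
  bundle <- generate_city(city_recipe(shape = c(50, 50), seed = 1, mixture = mix,
                                      n_water_bodies = 0))
  expect_true(all(bundle$landcover$values == 10))
  expect_equal(bundle$ground_truth$green_fraction, 1)
})

test_that("band synthesis inverts to the target NDVI exactly on clear cells", {
  bundle <- generate_city(small_recipe())
  recipe <- bundle$recipe
  for (d in seq_along(bundle$bands)) {
    ndvi <- compute_ndvi(bundle$bands[[d]])
    clear <- !bundle$ground_truth$clouds[[d]]
    target <- pmin(pmax(bundle$ground_truth$clear_ndvi$values -
                          recipe$seasonal_depression[d], -1), 1)
    expect_lt(max(abs(ndvi$values[clear] - target[clear])), 1e-12)
    expect_true(all(ndvi$values >= -1 & ndvi$values <= 1))
    expect_true(all(bundle$bands[[d]]$nir$values >= 0))
    expect_true(all(bundle$bands[[d]]$vis$values >= 0))
  }
})

test_that("the composite equals the clear-sky field wherever the peak date is clear", {
  bundle <- generate_city(small_recipe(n_dates = 3, cloud_prob = 0.3))
  comp <- greenest_composite(lapply(bundle$bands, compute_ndvi))
  peak <- which.min(bundle$recipe$seasonal_depression)
  clear_at_peak <- !bundle$ground_truth$clouds[[peak]]
  expect_lt(max(abs(comp$values[clear_at_peak] -
                      bundle$ground_truth$clear_ndvi$values[clear_at_peak])), 1e-12)
  # compositing can only remove seasonal/cloud depression, never exceed clear sky
  expect_true(all(comp$values <= bundle$ground_truth$clear_ndvi$values + 1e-12))
})

test_that("empirical class frequencies follow the mixture proportions", {
  recipe <- city_recipe(shape = c(400, 400), seed = 5, n_water_bodies = 0)
  bundle <- generate_city(recipe)
  scheme <- recipe$scheme
  freq <- table(factor(bundle$landcover$values, levels = scheme$class_codes)) / 400^2
  for (cls in names(recipe$mixture)) {
    expect_equal(unname(freq[[as.character(scheme$class_codes[[cls]])]]),
                 unname(recipe$mixture[[cls]]), tolerance = 0.02)
  }
})

test_that("water bodies are stamped as contiguous blobs", {
  bundle <- generate_city(small_recipe())
  water <- ugrid((bundle$landcover$values == 80) + 0, cell_size = 10)
  ps <- label_patches(water, 8)
  expect_gte(ps$n_patches, 1L)
  expect_gte(max(ps$areas_m2), pi * 60^2 * 0.8)  # at least one blob near the stamp size
})

test_that("population is confined to the city and sums to the recipe total", {
  bundle <- generate_city(small_recipe(population_total = 250000))
  pop <- bundle$population$values
  expect_equal(sum(pop), 250000, tolerance = 1e-9)
  expect_true(all(pop[bundle$mask_100m$values == 0] == 0))
  expect_true(all(pop >= 0))
})

test_that("the recipe validates mixtures, dates and water-body geometry", {
  expect_error(city_recipe(mixture = c(trees = 1.2, built_up = -0.2)), "negative")
  expect_error(city_recipe(shape = c(55, 100)), "multiples of 10")
  expect_error(city_recipe(n_dates = 2, seasonal_depression = c(0, 0.1, 0.2)),
               "per date")
  expect_error(city_recipe(shape = c(100, 100), water_body_radius_m = 5000),
               "too small")
})

test_that("stamped patches control patch-filter survival exactly", {
  base <- city_recipe(shape = c(100, 100), seed = 3, n_water_bodies = 0,
                      mixture = c(trees = 0, shrubland = 0, grassland = 0,
                                  cropland = 0, built_up = 1, bare_sparse = 0,
                                  snow_ice = 0, open_water = 0,
                                  herbaceous_wetland = 0, mangroves = 0,
                                  moss_lichen = 0))
  bundle <- generate_city(base)

  with_disk <- stamp_geometry(bundle, "disk", "trees", 5000, c(50, 50))
  natural <- classify_natural(with_disk$landcover)
  kept <- filter_small_patches(natural, 5000)
  expect_equal(label_patches(kept)$n_patches, 1L)
  expect_equal(sum(kept$values), 50)

  with_small <- stamp_geometry(bundle, "disk", "trees", 4900, c(50, 50))
  kept2 <- filter_small_patches(classify_natural(with_small$landcover), 5000)
  expect_equal(label_patches(kept2)$n_patches, 0L)
  expect_equal(sum(kept2$values), 0)

  expect_error(stamp_geometry(bundle, "disk", "trees", 5000, c(2, 2)),
               "out of bounds")
  expect_error(stamp_geometry(bundle, "disk", "lawn", 5000, c(50, 50)),
               "unknown landcover class")
})

test_that("stamping keeps bands consistent with the stamped class NDVI", {
  bundle <- generate_city(small_recipe())
  stamped <- stamp_geometry(bundle, "strip", "trees", 2000, c(30, 20))
  cells <- cbind(30, 20:39)
  for (d in seq_along(stamped$bands)) {
    ndvi <- compute_ndvi(stamped$bands[[d]])
    expected <- min(max(0.75 - stamped$recipe$seasonal_depression[d], -1), 1)
    expect_equal(unname(ndvi$values[cells]), rep(expected, 20), tolerance = 1e-12)
  }
  expect_true(all(stamped$landcover$values[cells] == 10))
})
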