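test_that("raster files round-trip float and categorical grids exactly", {
  dir <- withr::local_tempdir()
  set.seed(11)
  g_float <- ugrid(matrix(rnorm(12), 3, 4), cell_size = 10,
                   origin = c(500, 1200), crs_tag = "utm-zone-18n")
  path <- file.path(dir, "float.asc")
  write_raster(g_float, path)
  back <- read_raster(path)
  expect_identical(back$values, g_float$values)
  expect_equal(back$cell_size, 10)
  expect_equal(back$origin, c(500, 1200))
  expect_identical(back$crs_tag, "utm-zone-18n")

  g_cat <- ugrid(matrix(c(10, 20, 80, 95, 100, 50), 2, 3), cell_size = 10)
  p2 <- file.path(dir, "cat.asc")
  write_raster(g_cat, p2)
  expect_identical(read_raster(p2)$values, g_cat$values)
})

test_that("nodata tags propagate through file I/O", {
  dir <- withr::local_tempdir()
  m <- matrix(1:9 + 0, 3, 3)
  m[2, 2] <- NA
  g <- ugrid(m, cell_size = 10, nodata = 255)
  path <- file.path(dir, "nd.asc")
  write_raster(g, path)
  raw <- readLines(path)
  expect_match(raw[6], "NODATA_value 255")
  expect_match(raw[8], "255")   # row 2 carries the sentinel
  back <- read_raster(path)
  expect_equal(sum(is.na(back$values)), 1L)
  expect_true(is.na(back$values[2, 2]))
})

test_that("unreadable or unwritable rasters are rejected with clear errors", {
  dir <- withr::local_tempdir()
  txt <- file.path(dir, "not_a_raster.txt")
  writeLines(c("hello", "world"), txt)
  expect_error(read_raster(txt), "unreadable raster")
  expect_error(read_raster(file.path(dir, "missing.asc")), "unreadable raster")
  g <- ugrid(matrix(1, 2, 2), cell_size = 10)
  expect_error(write_raster(g, file.path(dir, "no_such_dir", "x.asc")),
               "directory does not exist")
})

test_that("geographic-degree CRS tags are rejected", {
  dir <- withr::local_tempdir()
  g <- ugrid(matrix(1, 2, 2), cell_size = 10, crs_tag = "EPSG:4326 degree lonlat")
  path <- file.path(dir, "geo.asc")
  write_raster(g, path)
  expect_error(read_raster(path), "projected metre CRS")
})

test_that("block aggregation computes area-weighted means over valid cells", {
  set.seed(7)
  m <- matrix(0, 10, 10)
  m[sample(100, 30)] <- 1
  coarse <- block_aggregate(ugrid(m, cell_size = 10), 10, "mean")
  expect_equal(dim(coarse$values), c(1L, 1L))
  expect_equal(coarse$values[1, 1], 0.30)
  expect_equal(coarse$cell_size, 100)

  all_na <- block_aggregate(ugrid(matrix(NA_real_, 10, 10), cell_size = 10), 10, "mean")
  expect_true(is.na(all_na$values[1, 1]))

  # 50 valid cells, 20 ones -> mean over valid only = 0.40
  m2 <- matrix(NA_real_, 10, 10)
  m2[1:50] <- c(rep(1, 20), rep(0, 30))
  expect_equal(block_aggregate(ugrid(m2, cell_size = 10), 10, "mean")$values[1, 1], 0.40)
})

test_that("block aggregation preserves the global mean and value bounds", {
  set.seed(21)
  for (dims in list(c(40, 60), c(30, 30))) {
    g <- ugrid(matrix(runif(prod(dims)), dims[1], dims[2]), cell_size = 10)
    cm <- block_aggregate(g, 10, "mean")
    expect_equal(mean(cm$values), mean(g$values), tolerance = 1e-12)
    expect_true(all(cm$values >= min(g$values) & cm$values <= max(g$values)))
    cx <- block_aggregate(g, 10, "max")
    expect_true(all(cx$values <= max(g$values)))
    expect_equal(max(cx$values), max(g$values))
  }
})

test_that("partial edge blocks aggregate over the cells that exist", {
  g <- ugrid(matrix(1, 15, 23), cell_size = 10)
  cm <- block_aggregate(g, 10, "mean")
  expect_equal(dim(cm$values), c(2L, 3L))
  expect_true(all(cm$values == 1))
  expect_error(block_aggregate(g, 0), "positive integer")
})

test_that("masked_cells returns valid in-mask values in row-major order", {
  g <- ugrid(matrix(c(1, 3, 2, NA), 2, 2), cell_size = 100)
  mask <- ugrid(matrix(c(1, 1, 0, 1), 2, 2), cell_size = 100)
  expect_equal(masked_cells(g, mask), c(1, 3))

  all_on <- all_true_mask(g)
  expect_equal(masked_cells(g, all_on), c(1, 2, 3))
  none <- ugrid(matrix(0, 2, 2), cell_size = 100)
  expect_length(masked_cells(g, none), 0)

  other <- ugrid(matrix(1, 2, 2), cell_size = 10)
  expect_error(masked_cells(g, other), "misaligned")
})

test_that("grid alignment requires cell size, shape, origin and CRS to match", {
  a <- ugrid(matrix(1, 3, 3), cell_size = 10, origin = c(0, 0))
  expect_true(grids_aligned(a, a))
  expect_false(grids_aligned(a, ugrid(matrix(1, 3, 3), cell_size = 100)))
  expect_false(grids_aligned(a, ugrid(matrix(1, 3, 4), cell_size = 10)))
  expect_false(grids_aligned(a, ugrid(matrix(1, 3, 3), cell_size = 10, origin = c(50, 0))))
  expect_false(grids_aligned(a, ugrid(matrix(1, 3, 3), cell_size = 10, crs_tag = "other")))
})
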