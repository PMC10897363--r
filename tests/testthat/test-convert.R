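test_that("a perfect line is recovered exactly", {
  fit <- fit_ols(c(0, 1, 2), c(0, 1, 2))
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r2, 1)
  expect_equal(fit$rmse, 0, tolerance = 1e-12)
})

test_that("a constant response reports r2 = 0 with a warning", {
  expect_warning(fit <- fit_ols(c(0, 1, 2), c(1, 1, 1)), "constant response")
  expect_equal(fit$slope, 0, tolerance = 1e-12)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r2, 0)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_ols(c(1, 1, 1), c(1, 2, 3)), "degenerate predictor")
  expect_error(fit_ols(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_ols(1:3, 1:4), "equal length")
})

test_that("coefficients match the normal-equation oracle on random data", {
  set.seed(43)
  for (trial in 1:20) {
    n <- sample(50:300, 1)
    x <- runif(n)
    y <- rnorm(n, 0.2 + 1.5 * x, 0.3)
    fit <- fit_ols(x, y)
    ora <- oracle_ols(x, y)
    expect_equal(fit$intercept, ora$intercept, tolerance = 1e-10)
    expect_equal(fit$slope, ora$slope, tolerance = 1e-10)
    expect_equal(fit$r2, ora$r2, tolerance = 1e-10)
    expect_equal(fit$rmse, ora$rmse, tolerance = 1e-10)
    expect_equal(fit$r2, cor(x, y)^2, tolerance = 1e-10)
  }
})

test_that("the fitted line minimises the residual sum of squares", {
  set.seed(47)
  x <- runif(100); y <- rnorm(100, 1 + 2 * x, 0.5)
  fit <- fit_ols(x, y)
  ss <- function(a, b) sum((y - a - b * x)^2)
  base <- ss(fit$intercept, fit$slope)
  for (da in c(-1e-3, 1e-3)) for (db in c(-1e-3, 0, 1e-3)) {
    if (da == 0 && db == 0) next
    expect_gte(ss(fit$intercept + da, fit$slope + db), base)
  }
})

test_that("rmse denominator is switchable between n and n - 2", {
  set.seed(53)
  x <- runif(30); y <- rnorm(30, x, 0.2)
  f_n <- fit_ols(x, y)
  f_df <- fit_ols(x, y, rmse_denominator = "n-2")
  expect_equal(f_df$rmse, f_n$rmse * sqrt(30 / 28))
})

test_that("tidy and glance summarise a fit", {
  set.seed(59)
  fit <- fit_ols(runif(40), rnorm(40))
  td <- generics::tidy(fit)
  expect_equal(td$term, c("(Intercept)", "x"))
  expect_equal(td$estimate, c(fit$intercept, fit$slope))
  gl <- generics::glance(fit)
  expect_named(gl, c("r.squared", "rmse", "nobs"))
  expect_equal(gl$nobs, 40L)
})

test_that("predict_at evaluates the line and warns outside the NDVI range", {
  fit <- structure(list(intercept = 0.3, slope = 0.5), class = "ols_fit")
  expect_equal(predict_at(fit, 0.30), 0.45)
  expect_equal(predict_at(fit, 0), 0.3)
  expect_equal(predict_at(fit, 1), 0.8)
  expect_warning(predict_at(fit, 5), "outside")
})

test_that("the Quality Total Cover conversion recovers a constructed line", {
  set.seed(101)
  nr <- 20; nc <- 20
  frac <- matrix(runif(nr * nc), nr, nc)
  ndvi <- 0.1 + 0.5 * frac
  gf <- ugrid(frac, cell_size = 100)
  gn <- ugrid(ndvi, cell_size = 100)
  mask <- all_true_mask(gf)
  conv <- convert_qtc(gf, gn, mask)
  expect_equal(conv$fit$r2, 1, tolerance = 1e-12)
  expect_equal(conv$predictions$ndvi[conv$predictions$green_fraction == 0.30],
               0.25, tolerance = 1e-10)
  # linearity: prediction difference equals slope times the level difference
  p <- conv$predictions
  expect_equal(p$ndvi[p$green_fraction == 0.40] - p$ndvi[p$green_fraction == 0.30],
               conv$fit$slope * 0.1, tolerance = 1e-12)
})

test_that("the conversion tolerates noise at scale", {
  set.seed(61)
  nr <- 100; nc <- 100
  frac <- matrix(runif(nr * nc), nr, nc)
  ndvi <- 0.1 + 0.5 * frac + rnorm(nr * nc, 0, 0.05)
  conv <- convert_qtc(ugrid(frac, cell_size = 100), ugrid(ndvi, cell_size = 100),
                      all_true_mask(ugrid(frac, cell_size = 100)))
  pred30 <- conv$predictions$ndvi[conv$predictions$green_fraction == 0.30]
  expect_equal(pred30, 0.25, tolerance = 0.01)
  expect_equal(conv$fit$r2, cor(as.vector(frac), as.vector(ndvi))^2,
               tolerance = 1e-10)
})

test_that("a fully green city is rejected as degenerate with guidance", {
  gf <- ugrid(matrix(1, 5, 5), cell_size = 100)
  gn <- ugrid(matrix(runif(25), 5, 5), cell_size = 100)
  expect_error(convert_qtc(gf, gn, all_true_mask(gf)), "no variation")
})

test_that("the access conversion matches identity and scaled relations", {
  set.seed(67)
  acc <- matrix(runif(100), 10, 10)
  g_lc <- ugrid(acc, cell_size = 100)
  mask <- all_true_mask(g_lc)

  ident <- convert_esd(g_lc, g_lc, mask)
  expect_equal(ident$fit$slope, 1, tolerance = 1e-10)
  expect_equal(ident$fit$intercept, 0, tolerance = 1e-10)
  expect_equal(ident$equivalent_at_level, 0.70, tolerance = 1e-10)

  g_nd <- ugrid(0.9 * acc, cell_size = 100)
  scaled <- convert_esd(g_lc, g_nd, mask)
  expect_equal(scaled$equivalent_at_level, 0.63, tolerance = 1e-10)
})

test_that("access conversion coefficients match the oracle on a synthetic city", {
  set.seed(71)
  n <- 500
  lc <- runif(n)
  nd <- pmin(1, pmax(0, 0.05 + 0.85 * lc + rnorm(n, 0, 0.1)))
  g_lc <- ugrid(matrix(lc, 20, 25), cell_size = 100)
  g_nd <- ugrid(matrix(nd, 20, 25), cell_size = 100)
  conv <- convert_esd(g_lc, g_nd, all_true_mask(g_lc))
  ora <- oracle_ols(lc, nd)
  expect_equal(conv$fit$intercept, ora$intercept, tolerance = 1e-10)
  expect_equal(conv$fit$slope, ora$slope, tolerance = 1e-10)
})

test_that("the direction switch is the only behavioural difference", {
  set.seed(73)
  frac <- matrix(runif(400), 20, 20)
  ndvi <- 0.1 + 0.5 * frac + rnorm(400, 0, 0.02)
  gf <- ugrid(frac, cell_size = 100); gn <- ugrid(ndvi, cell_size = 100)
  mask <- all_true_mask(gf)
  fwd <- convert_qtc(gf, gn, mask, direction = "ndvi_on_green")
  rev <- convert_qtc(gf, gn, mask, direction = "green_on_ndvi")
  # transposed fit regresses frac on ndvi; its fitted slope is not 1/slope,
  # but both directions share R2 (same squared correlation)
  expect_equal(fwd$fit$r2, rev$fit$r2, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(fwd$predictions$ndvi, rev$predictions$ndvi)))
})
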