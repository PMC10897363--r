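#' Simple per-city ordinary least squares fit
#'
#' Wraps [stats::lm()] for the single-predictor regressions used to convert
#' area- and access-based targets to the NDVI scale, keeping only the
#' quantities the conversion needs: intercept, slope, n, R-squared and RMSE.
#' RMSE is the plain root mean square of the residuals, `sqrt(SS_res / n)`
#' ("predicted values differ from actual values by RMSE" reading); set
#' `rmse_denominator = "n-2"` for the residual-degrees-of-freedom version.
#' A constant response (SS_tot = 0) yields `r2 = 0` with a warning.
#'
#' @param x Predictor values.
#' @param y Response values.
#' @param rmse_denominator `"n"` (default) or `"n-2"`.
#' @return An `ols_fit` object with fields `intercept`, `slope`, `n`, `r2`,
#'   `rmse`, plus the underlying `lm` fit.
#' @export
fit_ols <- function(x, y, rmse_denominator = c("n", "n-2")) {
  rmse_denominator <- match.arg(rmse_denominator)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations", call. = FALSE)
  if (diff(range(x)) == 0) stop("degenerate predictor: x is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warning("constant response: R-squared reported as 0", call. = FALSE)
    r2 <- 0
  } else {
    r2 <- 1 - ss_res / ss_tot
  }
  denom <- if (rmse_denominator == "n") n else n - 2L
  structure(
    list(intercept = unname(stats::coef(fit)[1]),
         slope = unname(stats::coef(fit)[2]),
         n = n, r2 = r2, rmse = sqrt(ss_res / denom),
         rmse_denominator = rmse_denominator, lm = fit),
    class = "ols_fit"
  )
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("<ols_fit> y = %.4f + %.4f x  (n = %d, R2 = %.3f, RMSE = %.4f)\n",
              x$intercept, x$slope, x$n, x$r2, x$rmse))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.ols_fit <- function(x, ...) {
  s <- summary(x$lm)$coefficients
  tibble::tibble(
    term = c("(Intercept)", "x"),
    estimate = c(x$intercept, x$slope),
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @exportS3Method generics::glance
glance.ols_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, rmse = x$rmse, nobs = x$n)
}

#' Predict the response at a predictor value
#'
#' Plain linear evaluation `intercept + slope * x0`. Predictions are never
#' clamped; an NDVI prediction outside \[-1, 1\] is returned as-is with a
#' warning.
#'
#' @param fit An [fit_ols()] object.
#' @param x0 Predictor value(s).
#' @return Predicted response value(s).
#' @export
predict_at <- function(fit, x0) {
  stopifnot(inherits(fit, "ols_fit"))
  pred <- fit$intercept + fit$slope * x0
  if (any(pred < -1 | pred > 1)) {
    warning("prediction outside [-1, 1]; reported unclamped", call. = FALSE)
  }
  pred
}

#' Convert the Quality Total Cover target to the NDVI scale
#'
#' Regresses, over the 100 m cells inside the city, the cell mean NDVI on
#' the cell green-area fraction, then predicts the NDVI level equivalent to a
#' given green-area share. Predictions at 0.30 and 0.40 are the NDVI
#' equivalents of the target range; predictions at 0.75, 0.90 and 1.00 are
#' candidate "green pixel" thresholds for the NDVI-based access layer.
#'
#' The default direction takes NDVI as the response, which is the direction
#' every prediction uses (an NDVI level given a green-area share);
#' `direction = "green_on_ndvi"` fits the transposed model for comparison.
#'
#' @param green_frac_100m 100 m green-fraction [ugrid].
#' @param ndvi_100m Aligned 100 m mean-NDVI [ugrid].
#' @param mask Aligned 100 m city mask [ugrid].
#' @param levels Green-area shares at which to predict NDVI.
#' @param direction `"ndvi_on_green"` (default) or `"green_on_ndvi"`.
#' @return A `qtc_conversion`: list with the `ols_fit` and a tibble
#'   `predictions` (`green_fraction`, `ndvi`).
#' @export
convert_qtc <- function(green_frac_100m, ndvi_100m, mask,
                        levels = c(0.30, 0.40, 0.75, 0.90, 1.00),
                        direction = c("ndvi_on_green", "green_on_ndvi")) {
  direction <- match.arg(direction)
  xy <- masked_pair(green_frac_100m, ndvi_100m, mask)
  frac <- xy$a
  ndvi <- xy$b
  fit <- tryCatch(
    if (direction == "ndvi_on_green") fit_ols(frac, ndvi) else fit_ols(ndvi, frac),
    error = function(e) {
      stop("Quality Total Cover regression failed (", conditionMessage(e),
           "); a city with no variation in green fraction cannot be converted",
           call. = FALSE)
    }
  )
  preds <- if (direction == "ndvi_on_green") {
    predict_at(fit, levels)
  } else {
    # literal transposed reading: invert the fitted line to get NDVI at a level
    (levels - fit$intercept) / fit$slope
  }
  structure(
    list(fit = fit, direction = direction,
         predictions = tibble::tibble(green_fraction = levels, ndvi = preds)),
    class = "qtc_conversion"
  )
}

#' @export
print.qtc_conversion <- function(x, ...) {
  cat("<qtc_conversion> direction:", x$direction, "\n")
  print(x$fit)
  print(x$predictions)
  invisible(x)
}

#' Convert the Equitable Spatial Distribution target to the NDVI scale
#'
#' Relates the two 100 m access-fraction layers — landcover-derived and
#' NDVI-threshold-derived — by OLS over the city cells, and predicts the
#' NDVI-based access level equivalent to the target share (default 0.70) of
#' landcover-based access. The default direction takes the NDVI-based layer
#' as the response (landcover natural space as the predictor of the
#' NDVI-based proximity measure); `direction = "lc_on_ndvi"` fits the
#' transposed model.
#'
#' @param lc_access_100m 100 m access-fraction [ugrid] built from the
#'   landcover natural-space mask.
#' @param ndvi_access_100m Aligned 100 m access-fraction [ugrid] built from
#'   the thresholded natural-space NDVI layer.
#' @param mask Aligned 100 m city mask [ugrid].
#' @param level Landcover access share at which to predict (default 0.70).
#' @param direction `"ndvi_on_lc"` (default) or `"lc_on_ndvi"`.
#' @return An `esd_conversion`: list with the `ols_fit`, the `level` and the
#'   prediction `equivalent_at_level`.
#' @export
convert_esd <- function(lc_access_100m, ndvi_access_100m, mask, level = 0.70,
                        direction = c("ndvi_on_lc", "lc_on_ndvi")) {
  direction <- match.arg(direction)
  xy <- masked_pair(lc_access_100m, ndvi_access_100m, mask)
  lc <- xy$a
  nd <- xy$b
  fit <- tryCatch(
    if (direction == "ndvi_on_lc") fit_ols(lc, nd) else fit_ols(nd, lc),
    error = function(e) {
      stop("Equitable Spatial Distribution regression failed (",
           conditionMessage(e), ")", call. = FALSE)
    }
  )
  pred <- if (direction == "ndvi_on_lc") predict_at(fit, level)
          else (level - fit$intercept) / fit$slope
  structure(
    list(fit = fit, direction = direction, level = level,
         equivalent_at_level = pred),
    class = "esd_conversion"
  )
}

#' @export
print.esd_conversion <- function(x, ...) {
  cat("<esd_conversion> direction:", x$direction, "\n")
  print(x$fit)
  cat(sprintf("  equivalent at %.2f: %.4f\n", x$level, x$equivalent_at_level))
  invisible(x)
}
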