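#' Fit a length-length allometric regression
#'
#' Ordinary least squares of one linear measurement on another (e.g.
#' total humerus length on distal-half length, or body length on
#' humerus length).  Axes are untransformed by default; `log = TRUE`
#' fits the log-log (power-law) form instead.
#'
#' @param x,y equal-length positive numeric vectors (`n >= 3`).
#' @param log fit `log(y) ~ log(x)`.
#' @param xlab,ylab,xunit,yunit optional labels/units stored with the
#'   model.
#' @return An object of class `allometric_model`: `slope`, `intercept`,
#'   `sigma` (residual standard deviation), `n`, standard errors, the
#'   underlying `lm` fit, labels and units.
#' @examples
#' m <- fit_allometry(1:5 * 100, 100 + 1.1 * (1:5 * 100))
#' predict(m, 723)
#' @export
fit_allometry <- function(x, y, log = FALSE, xlab = "x", ylab = "y",
                          xunit = "mm", yunit = "mm") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3L)
    stop("need at least 3 observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x <= 0) || any(y <= 0))
    stop("lengths must be positive and finite", call. = FALSE)
  if (var(x) <= .Machine$double.eps * mean(x)^2)
    stop("zero predictor variance: cannot fit a slope", call. = FALSE)
  if (log) { x <- base::log(x); y <- base::log(y) }
  fit <- lm(y ~ x, data = data.frame(x = x, y = y))
  # exact (sigma = 0) calibration data are legitimate here; silence the
  # "essentially perfect fit" advisory from summary.lm
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 sigma = sm$sigma,
                 slope_se = sm$coefficients[2, 2],
                 intercept_se = sm$coefficients[1, 2],
                 n = length(x), log = log, fit = fit,
                 xlab = xlab, ylab = ylab, xunit = xunit, yunit = yunit),
            class = "allometric_model")
}

#' @export
print.allometric_model <- function(x, ...) {
  cat(sprintf(
    "<allometric_model: %s = %.4g + %.4g * %s%s (n = %d, sigma = %.4g)>\n",
    x$ylab, x$intercept, x$slope, x$xlab,
    if (x$log) " [log-log]" else "", x$n, x$sigma))
  invisible(x)
}

#' Predict from an allometric model
#'
#' @param object an [fit_allometry()] model.
#' @param x0 positive predictor value(s) on the original scale.
#' @param interval add a 95% prediction interval.
#' @param level interval coverage.
#' @param ... unused.
#' @return Numeric vector of point estimates, or a data frame with
#'   `fit`, `lwr`, `upr` when `interval = TRUE`; always on the original
#'   response scale.
#' @export
predict.allometric_model <- function(object, x0, interval = FALSE,
                                     level = 0.95, ...) {
  if (any(x0 <= 0)) stop("x0 must be positive", call. = FALSE)
  nd <- data.frame(x = if (object$log) base::log(x0) else x0)
  if (interval) {
    p <- predict(object$fit, newdata = nd, interval = "prediction",
                 level = level)
    p <- as.data.frame(p)
    if (object$log) p[] <- lapply(p, exp)
    p
  } else {
    p <- unname(predict(object$fit, newdata = nd))
    if (object$log) exp(p) else p
  }
}

#' Estimate total body length from humerus length
#'
#' Linear prediction from a humerus (mm) to body length model, with the
#' result converted to meters when the model's response unit is mm.
#'
#' @param humerus_mm positive humerus length(s) in mm.
#' @param model_body an [fit_allometry()] model whose predictor is
#'   humerus length in mm; its `yunit` ("m" or "mm") sets the
#'   conversion.
#' @return Body length estimate(s) in meters (unrounded).
#' @export
estimate_body_length <- function(humerus_mm, model_body) {
  if (any(humerus_mm <= 0))
    stop("humerus length must be positive", call. = FALSE)
  stopifnot(inherits(model_body, "allometric_model"))
  est <- predict(model_body, humerus_mm)
  if (identical(model_body$yunit, "mm")) est / 1000 else est
}
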