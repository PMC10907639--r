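#' Fit a power law y = a * x^b by least squares in log10 space
#'
#' Ordinary least squares on `(log10 x, log10 y)`, the standard allometric
#' convention. With `fixed_exponent` given, only the prefactor is fitted
#' (the line's slope is imposed) and the coefficient of determination is
#' computed as `1 - SS_res / SS_tot` against the mean of `log10 y` in the
#' same space -- it can then be negative, and is never larger than the free
#' fit's R^2 (the free fit nests the fixed one).
#'
#' @param x,y positive numeric vectors of equal length.
#' @param fixed_exponent optional scalar; when supplied the exponent is
#'   imposed and only the prefactor is estimated.
#' @return An object of class `power_law_fit`: list with `exponent`,
#'   `log10_prefactor`, `r2`, `n`, `exponent_fixed`, and the fitting data
#'   (`log10_x`, `log10_y`) for methods.
#' @seealso [allometry_suite()], [fit_responses()]
#' @examples
#' fit <- fit_power_law(c(1, 2, 4), 2 * c(1, 2, 4)^2)
#' coef(fit)
#' predict(fit, newdata = 3)
#' @export
fit_power_law <- function(x, y, fixed_exponent = NULL) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  bad <- which(!is.finite(x) | x <= 0 | !is.finite(y) | y <= 0)
  if (length(bad)) {
    stop("power-law fit requires strictly positive values; offending ",
         "index(es): ", paste(utils::head(bad, 5L), collapse = ", "),
         call. = FALSE)
  }
  n <- length(x)
  fixed <- !is.null(fixed_exponent)
  if (fixed) {
    stopifnot(is.numeric(fixed_exponent), length(fixed_exponent) == 1L,
              is.finite(fixed_exponent))
    if (n < 2L) stop("need n >= 2 for a fixed-exponent fit", call. = FALSE)
  } else if (n < 3L) {
    stop("need n >= 3 for a free-exponent fit", call. = FALSE)
  }
  lx <- log10(x)
  ly <- log10(y)
  if (!fixed && stats::sd(lx) == 0) {
    stop("degenerate predictor: all x equal on the log scale", call. = FALSE)
  }
  if (fixed) {
    b <- fixed_exponent
    a <- mean(ly - b * lx) # LS prefactor given the imposed slope
  } else {
    cf <- stats::lm.fit(cbind(1, lx), ly)$coefficients
    a <- cf[[1L]]
    b <- cf[[2L]]
  }
  res <- ly - (a + b * lx)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot == 0) {
    if (sum(res^2) <= 1e-24) 1 else -Inf
  } else {
    1 - sum(res^2) / ss_tot
  }
  structure(list(
    exponent = unname(b),
    log10_prefactor = unname(a),
    r2 = r2,
    n = n,
    exponent_fixed = fixed,
    log10_x = lx,
    log10_y = ly
  ), class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Power-law fit%s: y ~ x^%.*f, R^2 = %.*f (n = %d)\n",
              if (x$exponent_fixed) " (fixed exponent)" else "",
              digits, x$exponent, digits, x$r2, x$n))
  invisible(x)
}

#' @export
summary.power_law_fit <- function(object, ...) {
  cat(sprintf(
    "Power-law fit in log10-log10 space (%s exponent)\n",
    if (object$exponent_fixed) "imposed" else "free"))
  cat(sprintf("  exponent        : %.6g\n", object$exponent))
  cat(sprintf("  prefactor       : %.6g  (log10: %.6g)\n",
              10^object$log10_prefactor, object$log10_prefactor))
  cat(sprintf("  R^2 (log space) : %.4f\n", object$r2))
  cat(sprintf("  n               : %d\n", object$n))
  invisible(object)
}

#' @export
coef.power_law_fit <- function(object, ...) {
  c(log10_prefactor = object$log10_prefactor, exponent = object$exponent)
}

#' Predict from a power-law fit on the natural scale
#'
#' @param object a `power_law_fit`.
#' @param newdata positive numeric vector of predictor values; defaults to
#'   the fitting data.
#' @param ... unused.
#' @return Predicted `y` values, `10^a * newdata^b`.
#' @export
predict.power_law_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- 10^object$log10_x
  stopifnot(is.numeric(newdata), all(newdata > 0))
  10^(object$log10_prefactor) * newdata^object$exponent
}

#' @export
residuals.power_law_fit <- function(object, ...) {
  object$log10_y - (object$log10_prefactor +
                      object$exponent * object$log10_x)
}

#' Log-log scatter plot of a power-law fit
#'
#' @param x a `power_law_fit`.
#' @param xlab,ylab axis labels.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.power_law_fit <- function(x, xlab = "log10 x", ylab = "log10 y", ...) {
  graphics::plot(x$log10_x, x$log10_y, xlab = xlab, ylab = ylab, ...)
  graphics::abline(a = x$log10_prefactor, b = x$exponent, col = "red3")
  invisible(x)
}
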