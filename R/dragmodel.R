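#' Fit the interspecific drag model and estimate C_D
#'
#' Regresses the lumped drag force `F_D = rho V_d^2 A |cos theta|` (with
#' the 1/2 C_D absorbed into the slope) on seed weight `m g` across a
#' population. At terminal descent `m g = (1/2) C_D F_D / (C_D/2)`...
#' i.e. `F_D = (2 / C_D) m g`, so the drag coefficient is recovered as
#' `C_D = 2 / slope`. The intercept is retained as a diagnostic: species
#' that are over- or under-weighted for their area pull it away from zero.
#'
#' Each wind-tunnel point is typically the mean of three replicates;
#' by default replicates are averaged per specimen before fitting
#' (`per_replicate = TRUE` fits every observation).
#'
#' @param forces data.frame from [force_table()] (needs `specimen_id`,
#'   `f_d_n`, `weight_n`).
#' @param through_origin force a zero intercept.
#' @param per_replicate fit per-replicate observations instead of specimen
#'   means.
#' @return An object of class `drag_model_fit`: list with `slope`,
#'   `intercept` (N), `r2`, `C_D = 2/slope`, `n`, and the fitted points
#'   (`weight_n`, `f_d_n`).
#' @examples
#' pop <- generate_population(generator_config(n_specimens = 40, seed = 7))
#' fit_drag_model(force_table(pop$morphology, pop$dynamics))
#' @export
fit_drag_model <- function(forces, through_origin = FALSE,
                           per_replicate = FALSE) {
  stopifnot(is.data.frame(forces))
  need <- c("specimen_id", "f_d_n", "weight_n")
  .check_schema(forces, need, "forces")
  if (!per_replicate) {
    agg <- stats::aggregate(forces[c("f_d_n", "weight_n")],
                            by = list(specimen_id = forces$specimen_id),
                            FUN = mean)
  } else {
    agg <- forces[c("specimen_id", "f_d_n", "weight_n")]
  }
  if (nrow(agg) < 3L) stop("need >= 3 records", call. = FALSE)
  x <- agg$weight_n
  y <- agg$f_d_n
  if (stats::sd(x) == 0) {
    stop("singular fit: all weights identical", call. = FALSE)
  }
  if (through_origin) {
    slope <- sum(x * y) / sum(x * x)
    intercept <- 0
    fitted <- slope * x
  } else {
    cf <- stats::lm.fit(cbind(1, x), y)$coefficients
    intercept <- cf[[1L]]
    slope <- cf[[2L]]
    fitted <- intercept + slope * x
  }
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum((y - fitted)^2) / ss_tot
  if (slope <= 0) {
    warning("non-physical fit: slope <= 0, C_D undefined/negative")
  }
  structure(list(
    slope = unname(slope),
    intercept = unname(intercept),
    r2 = r2,
    C_D = 2 / unname(slope),
    n = nrow(agg),
    weight_n = x,
    f_d_n = y,
    through_origin = through_origin
  ), class = "drag_model_fit")
}

#' @export
print.drag_model_fit <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Drag-model fit: F_D = %.4g + %.4g * mg, R^2 = %.*f (n = %d)\n",
    x$intercept, x$slope, digits, x$r2, x$n))
  cat(sprintf("  implied drag coefficient C_D = 2/slope = %.*f\n",
              digits, x$C_D))
  invisible(x)
}

#' @export
summary.drag_model_fit <- function(object, ...) {
  print(object, digits = 4)
  cat(sprintf("  intercept (N)   : %.4g%s\n", object$intercept,
              if (object$through_origin) " (constrained)" else ""))
  cat("  A nonzero intercept flags over/under-weighted species.\n")
  invisible(object)
}

#' @export
coef.drag_model_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope, C_D = object$C_D)
}

#' @export
predict.drag_model_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$weight_n
  object$intercept + object$slope * newdata
}

#' @export
plot.drag_model_fit <- function(x, xlab = "weight mg (N)",
                                ylab = "F_D (N)", ...) {
  graphics::plot(x$weight_n, x$f_d_n, xlab = xlab, ylab = ylab, ...)
  graphics::abline(a = x$intercept, b = x$slope, col = "red3")
  invisible(x)
}

#' Compare the wing-loading and drag-model descriptions of descent
#'
#' Computes (i) the linear-space R^2 of `V_d^2` against wing loading
#' `m g / A` and (ii) the R^2 of the coning-angle drag fit (`F_D` vs
#' `m g`, via [fit_drag_model()]), on the same specimens, and reports the
#' difference. The drag model folds the coning angle into the projected
#' area, which is what lets a single fit unify species; wing loading omits
#' it.
#'
#' @param morphology,dynamics the joined population tables (field units).
#' @param constants a [samara_constants()] object.
#' @param ... passed to [fit_drag_model()].
#' @return Object of class `model_comparison`: list with `r2_wing_loading`,
#'   `r2_drag_model`, `delta_r2`, `n`.
#' @examples
#' pop <- generate_population(generator_config(n_specimens = 40, seed = 7))
#' compare_models(pop$morphology, pop$dynamics)
#' @export
compare_models <- function(morphology, dynamics,
                           constants = samara_constants(), ...) {
  ft <- force_table(morphology, dynamics, constants = constants)
  if (length(unique(ft$specimen_id)) < 3L) {
    stop("need >= 3 joined specimens", call. = FALSE)
  }
  agg <- stats::aggregate(
    ft[c("v_d_m_s", "wing_loading_n_m2")],
    by = list(specimen_id = ft$specimen_id), FUN = mean)
  v2 <- agg$v_d_m_s^2
  wl <- agg$wing_loading_n_m2
  r2_wl <- if (stats::sd(wl) == 0 || stats::sd(v2) == 0) 0 else
    stats::cor(v2, wl)^2
  drag <- fit_drag_model(ft, ...)
  structure(list(
    r2_wing_loading = r2_wl,
    r2_drag_model = drag$r2,
    delta_r2 = drag$r2 - r2_wl,
    n = nrow(agg),
    drag_fit = drag
  ), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, digits = 3, ...) {
  cat("Descent-model comparison (specimen means):\n")
  cat(sprintf("  V_d^2 ~ mg/A (wing loading) : R^2 = %.*f\n",
              digits, x$r2_wing_loading))
  cat(sprintf("  F_D ~ mg (drag model)       : R^2 = %.*f\n",
              digits, x$r2_drag_model))
  cat(sprintf("  difference                  : %.*f (n = %d)\n",
              digits, x$delta_r2, x$n))
  invisible(x)
}
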