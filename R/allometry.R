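#' Allometric scaling suite for a samara population
#'
#' Two-dimensionally allometric organisms satisfy `A ~ L^2` and `m ~ L^3`
#' for a characteristic length `L`, hence for samaras
#' `A ~ m^(2/3) ~ S^2 ~ c^2 ~ cS`. The suite fits, in log10-log10 space,
#' both a free-exponent and a fixed-exponent (allometric-prediction)
#' version of each of the four relations:
#' A vs m (fixed 2/3), A vs S (fixed 2), A vs c (fixed 2), and
#' A vs cS (fixed 1) -- eight [fit_power_law()] results in all.
#' Species whose nutlet mass is out of proportion to their wing (over- or
#' under-weighted species) stand out in the A-vs-m panel while remaining
#' on-trend geometrically.
#'
#' @param morphology morphology table in field units (mg, mm, cm^2);
#'   internally converted to SI before fitting, which changes prefactors
#'   but not exponents or R^2.
#' @return Object of class `allometry_suite`: named list of
#'   `power_law_fit` objects (`A_vs_m`, `A_vs_m_fixed`, `A_vs_S`,
#'   `A_vs_S_fixed`, `A_vs_c`, `A_vs_c_fixed`, `A_vs_cS`,
#'   `A_vs_cS_fixed`).
#' @examples
#' pop <- generate_population(generator_config(n_specimens = 40, seed = 3))
#' allometry_suite(pop$morphology)
#' @export
allometry_suite <- function(morphology) {
  .check_schema(morphology, .cols_morphology, "morphology")
  if (nrow(morphology) < 3L) stop("need >= 3 specimens", call. = FALSE)
  si <- to_si(morphology)
  A <- si$a_m2
  m <- si$m_kg
  S <- si$s_m
  cc <- si$c_m
  fits <- list(
    A_vs_m = fit_power_law(m, A),
    A_vs_m_fixed = fit_power_law(m, A, fixed_exponent = 2 / 3),
    A_vs_S = fit_power_law(S, A),
    A_vs_S_fixed = fit_power_law(S, A, fixed_exponent = 2),
    A_vs_c = fit_power_law(cc, A),
    A_vs_c_fixed = fit_power_law(cc, A, fixed_exponent = 2),
    A_vs_cS = fit_power_law(cc * S, A),
    A_vs_cS_fixed = fit_power_law(cc * S, A, fixed_exponent = 1)
  )
  structure(fits, class = "allometry_suite")
}

#' @export
print.allometry_suite <- function(x, digits = 2, ...) {
  lab <- c(A_vs_m = "A ~ m", A_vs_S = "A ~ S", A_vs_c = "A ~ c",
           A_vs_cS = "A ~ cS")
  cat("Allometric relations (log10-log10 OLS):\n")
  for (nm in names(lab)) {
    f <- x[[nm]]
    ff <- x[[paste0(nm, "_fixed")]]
    cat(sprintf("  %-7s free: exponent %.*f, R^2 = %.*f | fixed %.*g: R^2 = %.*f\n",
                lab[[nm]], digits, f$exponent, digits, f$r2,
                3, ff$exponent, digits, ff$r2))
  }
  invisible(x)
}

#' @export
as.data.frame.allometry_suite <- function(x, ...) {
  do.call(rbind, lapply(names(x), function(nm) {
    f <- x[[nm]]
    data.frame(name = nm, exponent = f$exponent,
               log10_prefactor = f$log10_prefactor, r2 = f$r2, n = f$n,
               exponent_fixed = f$exponent_fixed,
               stringsAsFactors = FALSE)
  }))
}
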