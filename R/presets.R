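#' Species presets for the synthetic samara generator
#'
#' The `"study"` set emulates an eight-species *Acer* population: chord
#' medians and chord-span ratios spread so that generated spans stay
#' inside 17.2-60.6 mm and areas inside 0.53-5.72 cm^2; published
#' chord-span ratios are used where available (A. ginnala 0.33,
#' A. floridanum 0.34, A. campestre 0.25). Weighting factors mark the two species whose nutlet
#' mass departs from the interspecific allometric trend: A. saccharum
#' overweighted (w = 1.45) and A. negundo underweighted (w = 0.60). Coning
#' angle means straddle 117.8 degrees (their across-species average).
#' Failure bounds encode the sustained-perturbation envelopes: A. negundo
#' autorotates for m/m0 in about (0.5, 2.25), A. macrophyllum fails by
#' m/m0 of about 1.3 but tolerates deep mass removal and (having the
#' largest wing) the deepest ablation, down to A/A0 of about 0.6.
#'
#' The `"isometric"` set is a single idealised species with weighting 1,
#' used for exact allometric closure: all geometric ratios are shared, so
#' a noise-free population satisfies A ~ m^(2/3) ~ S^2 ~ c^2 ~ cS exactly.
#'
#' The per-species mass coefficient `mass_coefficient` (mu in
#' m = w * mu * A^(3/2), kg/m^3) is filled in by
#' [calibrate_mass_coefficient()] so that the ensemble-mean descent
#' velocity at the default drag coefficient is `V_ref`.
#'
#' @param set `"study"` (8 species) or `"isometric"` (1 idealised species).
#' @param V_ref target ensemble-mean descent velocity, m/s, used to
#'   calibrate the mass coefficient.
#' @param C_D drag coefficient assumed in the calibration.
#' @param constants a [samara_constants()] object.
#' @return data.frame with one row per species and columns `species`,
#'   `chord_median_mm`, `chord_log10_sd`, `chord_span_ratio`,
#'   `area_shape_factor`, `mass_coefficient`, `weighting_factor`,
#'   `theta_mean_deg`, `theta_sd_deg`, `min_m_ratio`, `max_m_ratio`,
#'   `min_a_ratio`.
#' @examples
#' samara_presets()
#' @export
samara_presets <- function(set = c("study", "isometric"), V_ref = 0.83,
                           C_D = 5.99, constants = samara_constants()) {
  set <- match.arg(set)
  if (set == "study") {
    p <- data.frame(
      species = c("A. buergerianum", "A. rubrum", "A. ginnala",
                  "A. floridanum", "A. saccharum", "A. campestre",
                  "A. negundo", "A. macrophyllum"),
      chord_median_mm = c(7.7, 7.8, 9.2, 10.2, 9.9, 8.5, 10.4, 12.0),
      chord_log10_sd = rep(0.03, 8),
      chord_span_ratio = c(0.32, 0.30, 0.33, 0.34, 0.31, 0.25, 0.28, 0.30),
      area_shape_factor = c(0.64, 0.62, 0.55, 0.66, 0.63, 0.60, 0.58, 0.62),
      weighting_factor = c(1, 1, 1, 1, 1.45, 1, 0.60, 1),
      theta_mean_deg = c(112, 120, 108, 122, 130, 115, 110, 125),
      theta_sd_deg = rep(9, 8),
      min_m_ratio = c(0.40, 0.40, 0.40, 0.40, 0.35, 0.40, 0.50, 0.30),
      max_m_ratio = c(1.60, 1.50, 1.50, 1.50, 1.50, 1.60, 2.25, 1.30),
      min_a_ratio = c(0.80, 0.75, 0.75, 0.72, 0.72, 0.70, 0.68, 0.60),
      stringsAsFactors = FALSE
    )
  } else {
    p <- data.frame(
      species = "synthetic",
      chord_median_mm = 9.5,
      chord_log10_sd = 0.06,
      chord_span_ratio = 0.30,
      area_shape_factor = 0.62,
      weighting_factor = 1,
      theta_mean_deg = 117.8,
      theta_sd_deg = 9,
      min_m_ratio = 0.40,
      max_m_ratio = 1.60,
      min_a_ratio = 0.70,
      stringsAsFactors = FALSE
    )
  }
  p$mass_coefficient <- calibrate_mass_coefficient(
    p, V_ref = V_ref, C_D = C_D, constants = constants)
  .validate_presets(p)
  p
}

.validate_presets <- function(p) {
  stopifnot(is.data.frame(p), nrow(p) >= 1L)
  need <- c("species", "chord_median_mm", "chord_log10_sd",
            "chord_span_ratio", "area_shape_factor", "mass_coefficient",
            "weighting_factor", "theta_mean_deg", "theta_sd_deg",
            "min_m_ratio", "max_m_ratio", "min_a_ratio")
  miss <- setdiff(need, names(p))
  if (length(miss)) {
    stop("preset table missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  checks <- list(
    chord_median_mm = p$chord_median_mm > 0,
    chord_log10_sd = p$chord_log10_sd >= 0,
    chord_span_ratio = p$chord_span_ratio > 0 & p$chord_span_ratio <= 1,
    area_shape_factor = p$area_shape_factor > 0 & p$area_shape_factor <= 1,
    mass_coefficient = p$mass_coefficient > 0,
    weighting_factor = p$weighting_factor > 0,
    theta_mean_deg = p$theta_mean_deg > 91 & p$theta_mean_deg < 179,
    theta_sd_deg = p$theta_sd_deg >= 0,
    min_m_ratio = p$min_m_ratio > 0 & p$min_m_ratio < 1,
    max_m_ratio = p$max_m_ratio >= 1,
    min_a_ratio = p$min_a_ratio > 0 & p$min_a_ratio <= 1
  )
  for (nm in names(checks)) {
    if (!all(checks[[nm]])) {
      stop("invalid preset field '", nm, "' for species ",
           paste(p$species[!checks[[nm]]], collapse = ", "), call. = FALSE)
    }
  }
  invisible(p)
}

#' Mass-coefficient calibration from the preset ensemble
#'
#' Under the force balance, a specimen's terminal velocity is
#' `V = sqrt(2 g w mu sqrt(A) / (C_D rho |cos theta|))` once
#' `m = w mu A^(3/2)` is substituted. The expected species factor
#' `J_s = sqrt(w_s) E[A^(1/4)] E[|cos theta|^(-1/2)]` is evaluated per
#' preset -- the angle expectation by quadrature over the truncated Normal
#' coning-angle distribution (91-179 degrees), the area moment in closed
#' form from the lognormal chord -- and `mean(V) = V_ref` is solved for
#' the mass coefficient:
#' `mu = C_D rho V_ref^2 / (2 g mean(J)^2)`.
#' The calibration is deterministic in the presets, so the generator's
#' conditions are fixed before any data are drawn.
#'
#' @param presets preset table (without or with a `mass_coefficient`
#'   column; it is not used).
#' @param V_ref target ensemble-mean descent velocity, m/s.
#' @param C_D drag coefficient.
#' @param constants a [samara_constants()] object.
#' @return Scalar mu, kg/m^3.
#' @export
calibrate_mass_coefficient <- function(presets, V_ref = 0.83, C_D = 5.99,
                                       constants = samara_constants()) {
  c_m <- presets$chord_median_mm * 1e-3
  S_m <- c_m / presets$chord_span_ratio
  A_med <- presets$area_shape_factor * c_m * S_m
  # E[A^(1/4)] for A = A_med * 10^(2 Z sigma_c), Z ~ N(0,1)
  e_a4 <- A_med^0.25 * exp((0.5 * presets$chord_log10_sd * log(10))^2 / 2)
  e_cos <- mapply(function(mu, sd) {
    if (sd == 0) return(abs(cos(deg2rad(mu)))^-0.5)
    z <- (stats::pnorm(179, mu, sd) - stats::pnorm(91, mu, sd))
    stats::integrate(function(th) {
      abs(cos(deg2rad(th)))^-0.5 * stats::dnorm(th, mu, sd) / z
    }, 91, 179, rel.tol = 1e-8)$value
  }, presets$theta_mean_deg, presets$theta_sd_deg)
  J <- sqrt(presets$weighting_factor) * e_a4 * e_cos
  C_D * constants$rho_air * V_ref^2 / (2 * constants$g * mean(J)^2)
}

#' Generator configuration
#'
#' Bundles the knobs of the synthetic generator. The seed is mandatory:
#' every generated dataset is a pure function of its configuration, with
#' no implicit entropy.
#'
#' Default response exponents are the pooled reduced-variable fits of the
#' perturbation experiments: descent velocity, rotation rate and coning
#' angle scale with reduced mass as `(m/m0)^0.12`, `(m/m0)^0.70` and
#' `(m/m0)^-0.48`, and with reduced area as `(A/A0)^-0.79`, `(A/A0)^0.03`
#' and `(A/A0)^-0.38`.
#'
#' @param n_specimens number of specimens to generate (spread round-robin
#'   across the preset species).
#' @param replicates flight replicates per specimen (default 3).
#' @param C_D_true drag coefficient used in the force balance
#'   (default 5.99).
#' @param noise_sd_V multiplicative lognormal sd on descent velocity.
#' @param noise_sd_dynamics multiplicative lognormal sd on omega and theta
#'   in perturbation responses (and on omega in populations).
#' @param response_exponents named list with elements `V_vs_m`,
#'   `omega_vs_m`, `theta_vs_m`, `V_vs_A`, `omega_vs_A`, `theta_vs_A`.
#' @param phi_mean,phi_sd distribution (degrees) of the 0.75-span angle of
#'   attack used to back out omega from `V_d` and span.
#' @param seed integer seed (required).
#' @return list of class `generator_config`.
#' @examples
#' generator_config(n_specimens = 16, seed = 1)
#' @export
generator_config <- function(n_specimens = 160, replicates = 3,
                             C_D_true = 5.99, noise_sd_V = 0.05,
                             noise_sd_dynamics = 0.05,
                             response_exponents = list(
                               V_vs_m = 0.12, omega_vs_m = 0.70,
                               theta_vs_m = -0.48, V_vs_A = -0.79,
                               omega_vs_A = 0.03, theta_vs_A = -0.38),
                             phi_mean = 42.5, phi_sd = 3.2,
                             seed = NULL) {
  if (is.null(seed)) {
    stop("a seed is required: generated data must be reproducible ",
         "(no implicit entropy)", call. = FALSE)
  }
  stopifnot(n_specimens >= 1, replicates >= 1, C_D_true > 0,
            noise_sd_V >= 0, noise_sd_dynamics >= 0, phi_sd >= 0,
            phi_mean > 0, phi_mean < 90)
  need <- c("V_vs_m", "omega_vs_m", "theta_vs_m", "V_vs_A", "omega_vs_A",
            "theta_vs_A")
  miss <- setdiff(need, names(response_exponents))
  if (length(miss)) {
    stop("response_exponents missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    n_specimens = as.integer(n_specimens),
    replicates = as.integer(replicates),
    C_D_true = C_D_true,
    noise_sd_V = noise_sd_V,
    noise_sd_dynamics = noise_sd_dynamics,
    response_exponents = response_exponents[need],
    phi_mean = phi_mean,
    phi_sd = phi_sd,
    seed = as.integer(seed)
  ), class = "generator_config")
}
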