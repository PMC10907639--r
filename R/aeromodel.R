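#' Wing loading
#'
#' Weight per unit plan area, `m g / A` (N/m^2). The classical predictor of
#' descent speed for autorotating seeds: a free-falling blunt body at
#' terminal velocity satisfies `V_d^2 ~ m g / A`. It ignores the coning
#' angle and so compares wing shapes across species only weakly; see
#' [compare_models()].
#'
#' @param m mass, kg (vectorised).
#' @param A plan-view area, m^2.
#' @param constants a [samara_constants()] object.
#' @return Wing loading in N/m^2.
#' @examples
#' wing_loading(1.2e-5, 2.5e-4)
#' @export
wing_loading <- function(m, A, constants = samara_constants()) {
  if (any(!is.finite(A) | A <= 0)) stop("A must be positive", call. = FALSE)
  if (any(!is.finite(m) | m <= 0)) stop("m must be positive", call. = FALSE)
  m * constants$g / A
}

#' Coning-angle-projected drag force
#'
#' The lumped vertical aerodynamic force on an autorotating samara,
#' `rho * V_d^2 * A * |cos(theta)|`. Form drag and lift both oppose
#' descent; projecting the plan area through the coning angle theta folds
#' the two into a single term. `A |cos theta|` is the area the seed
#' presents to the vertical flow.
#'
#' Nutlet-down autorotation gives coning angles beyond 90 degrees, where
#' `cos` is negative; only its magnitude is physical here, so the default
#' convention takes `|cos theta|`. Set
#' `projection = "sin"` if angles were recorded from the rotor plane
#' rather than from the descent axis.
#'
#' @param V_d descent velocity, m/s (vectorised).
#' @param A plan-view area, m^2.
#' @param theta coning angle in degrees, measured from the descent (spin)
#'   axis; must lie in (0, 180).
#' @param constants a [samara_constants()] object.
#' @param projection projection convention, `"abs_cos"` (default) or
#'   `"sin"`.
#' @return Force in N.
#' @examples
#' drag_force(0.83, 2.5e-4, 117.8)
#' @export
drag_force <- function(V_d, A, theta, constants = samara_constants(),
                       projection = c("abs_cos", "sin")) {
  projection <- match.arg(projection)
  if (any(!is.finite(theta) | theta <= 0 | theta >= 180)) {
    stop("theta must lie strictly inside (0, 180) degrees", call. = FALSE)
  }
  if (any(!is.finite(A) | A <= 0)) stop("A must be positive", call. = FALSE)
  if (any(!is.finite(V_d) | V_d < 0)) {
    stop("V_d must be non-negative", call. = FALSE)
  }
  proj <- switch(projection,
                 abs_cos = abs(cos(deg2rad(theta))),
                 sin = sin(deg2rad(theta)))
  constants$rho_air * V_d^2 * A * proj
}

#' Equilibrium descent velocity from the vertical force balance
#'
#' Inverts the force balance `m g = (1/2) C_D rho V_d^2 A |cos theta|`
#' for the terminal descent velocity:
#' `V_d = sqrt(2 m g / (C_D rho A |cos theta|))`.
#'
#' @param m mass, kg (vectorised).
#' @param A plan-view area, m^2.
#' @param theta coning angle, degrees in (0, 180), excluding 90 (at 90
#'   degrees the projected area vanishes and no equilibrium exists).
#' @param C_D drag coefficient (dimensionless, > 0).
#' @param constants a [samara_constants()] object.
#' @param projection see [drag_force()].
#' @return Descent velocity, m/s.
#' @examples
#' velocity_from_balance(1.2e-5, 2.5e-4, 117.8, C_D = 5.99)
#' @export
velocity_from_balance <- function(m, A, theta, C_D,
                                  constants = samara_constants(),
                                  projection = c("abs_cos", "sin")) {
  projection <- match.arg(projection)
  if (any(!is.finite(m) | m <= 0)) stop("m must be positive", call. = FALSE)
  if (any(!is.finite(A) | A <= 0)) stop("A must be positive", call. = FALSE)
  if (any(!is.finite(C_D) | C_D <= 0)) {
    stop("C_D must be positive", call. = FALSE)
  }
  if (any(!is.finite(theta) | theta <= 0 | theta >= 180)) {
    stop("theta must lie strictly inside (0, 180) degrees", call. = FALSE)
  }
  proj <- switch(projection,
                 abs_cos = abs(cos(deg2rad(theta))),
                 sin = sin(deg2rad(theta)))
  if (any(proj < 1e-12)) {
    stop("no equilibrium: projected area vanishes (theta = 90 degrees ",
         "under the |cos| convention)", call. = FALSE)
  }
  sqrt(2 * m * constants$g / (C_D * constants$rho_air * A * proj))
}

#' Blade angle of attack at the three-quarter-span station
#'
#' The effective pitch of an autorotating blade varies along its length,
#' so it is tabulated at 0.75 span from the nutlet tip:
#' `phi = arctan(V_d / (0.75 S omega))`, reported in degrees.
#'
#' @param V_d descent velocity, m/s (vectorised).
#' @param S span, m (> 0).
#' @param omega angular velocity, rad/s (> 0).
#' @return Angle of attack in degrees, in \[0, 90) (0 only when `V_d = 0`).
#' @examples
#' angle_of_attack(0.83, 0.0606, 18.8)
#' @export
angle_of_attack <- function(V_d, S, omega) {
  if (any(!is.finite(S) | S <= 0)) stop("S must be positive", call. = FALSE)
  if (any(!is.finite(omega) | omega <= 0)) {
    stop("omega must be positive", call. = FALSE)
  }
  if (any(!is.finite(V_d) | V_d < 0)) {
    stop("V_d must be non-negative", call. = FALSE)
  }
  rad2deg(atan(V_d / (0.75 * S * omega)))
}

#' Centrifugal force at the centroid path
#'
#' `F_c = m omega^2 r_c`, with `r_c` the radius of the circle traced by
#' the samara centroid about the spin axis. No universal convention fixes
#' that radius; the package default places the spin axis at the nutlet end
#' and the centroid at one quarter span (`r_c = 0.25 S`, the complement of
#' the 0.75-span blade station), which at least makes comparisons across
#' specimens internally consistent. Pass `r_c` explicitly to use another
#' convention.
#'
#' @param m mass, kg (vectorised).
#' @param omega angular velocity, rad/s (>= 0).
#' @param r_c centroid-path radius, m (>= 0).
#' @return Force in N.
#' @examples
#' centrifugal_force(1.2e-5, 18.8, r_c = 0.01)
#' @export
centrifugal_force <- function(m, omega, r_c) {
  if (any(!is.finite(m) | m < 0)) stop("m must be >= 0", call. = FALSE)
  if (any(!is.finite(omega) | omega < 0)) {
    stop("omega must be >= 0", call. = FALSE)
  }
  if (any(!is.finite(r_c) | r_c < 0)) stop("r_c must be >= 0", call. = FALSE)
  m * omega^2 * r_c
}

#' Assemble per-observation force records
#'
#' Joins a morphology table to a dynamics table on `specimen_id` and
#' computes, per flight replicate: the lumped drag force, weight,
#' centrifugal force (under the configured centroid-radius convention),
#' wing loading, and the 0.75-span angle of attack.
#'
#' @param morphology data.frame in the morphology CSV dialect (field
#'   units; see [read_morphology()]).
#' @param dynamics data.frame in the dynamics CSV dialect.
#' @param constants a [samara_constants()] object.
#' @param projection see [drag_force()].
#' @param r_c_fraction centroid-path radius as a fraction of span
#'   (default 0.25).
#' @return data.frame with columns `specimen_id`, `species`, `replicate`,
#'   `f_d_n`, `weight_n`, `f_c_n`, `wing_loading_n_m2`, `phi_deg`, plus the
#'   SI morphology and the raw dynamics columns.
#' @examples
#' pop <- generate_population(generator_config(n_specimens = 8, seed = 1))
#' head(force_table(pop$morphology, pop$dynamics))
#' @export
force_table <- function(morphology, dynamics,
                        constants = samara_constants(),
                        projection = c("abs_cos", "sin"),
                        r_c_fraction = 0.25) {
  projection <- match.arg(projection)
  .check_schema(morphology, .cols_morphology, "morphology")
  .check_schema(dynamics, .cols_dynamics, "dynamics")
  m_si <- to_si(morphology)
  df <- merge(m_si, dynamics, by = "specimen_id")
  if (!nrow(df)) stop("no specimen_id overlap between tables", call. = FALSE)
  df$f_d_n <- drag_force(df$v_d_m_s, df$a_m2, df$theta_deg,
                         constants = constants, projection = projection)
  df$weight_n <- df$m_kg * constants$g
  df$f_c_n <- centrifugal_force(df$m_kg, df$omega_rad_s,
                                r_c_fraction * df$s_m)
  df$wing_loading_n_m2 <- wing_loading(df$m_kg, df$a_m2,
                                       constants = constants)
  df$phi_deg <- angle_of_attack(df$v_d_m_s, df$s_m, df$omega_rad_s)
  df[order(df$specimen_id, df$replicate), ]
}
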