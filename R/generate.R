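# rnorm truncated to (lo, hi) by resampling; degenerate sd returns the
# clamped mean
.rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (all(sd == 0)) return(pmin(pmax(mean, lo), hi))
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:100) {
    bad <- x <= lo | x >= hi
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), if (length(mean) > 1) mean[bad] else
      mean, if (length(sd) > 1) sd[bad] else sd)
  }
  pmin(pmax(x, lo + 1e-9), hi - 1e-9)
}

.lognoise <- function(n, sd) {
  if (sd == 0) rep(1, n) else exp(stats::rnorm(n, 0, sd))
}

#' Generate a synthetic samara population
#'
#' Draws specimens round-robin across the preset species. Per specimen:
#' chord is lognormal about the species median; span follows from the
#' chord-span ratio; plan area is `A = k c S` with the species' shape
#' factor; mass follows the allometric model `m = w mu A^(3/2)` with the
#' calibrated mass coefficient and the species weighting factor. Per
#' replicate: the coning angle is Normal about the species mean (clipped
#' to nutlet-down flight, 91-179 degrees), descent velocity comes from the
#' force balance at `C_D_true` times multiplicative lognormal noise, and
#' the rotation rate is backed out of a drawn 0.75-span angle of attack
#' (`omega = V_d / (0.75 S tan phi)`) times noise, so generated
#' populations carry the tight angle-of-attack band characteristic of
#' autorotating samaras by construction.
#'
#' The same configuration (including seed) always produces bit-identical
#' tables.
#'
#' @param config a [generator_config()] (seed mandatory).
#' @param presets a preset table from [samara_presets()].
#' @param constants a [samara_constants()] object.
#' @return list of class `samara_population` with elements `morphology`
#'   (morphology CSV dialect), `dynamics` (dynamics dialect), and `truth`
#'   (list of all generating parameters, for recovery tests).
#' @examples
#' pop <- generate_population(generator_config(n_specimens = 16, seed = 42))
#' head(pop$morphology)
#' @export
generate_population <- function(config, presets = samara_presets(),
                                constants = samara_constants()) {
  stopifnot(inherits(config, "generator_config"))
  .validate_presets(presets)
  set.seed(config$seed)
  n <- config$n_specimens
  sp_idx <- rep(seq_len(nrow(presets)), length.out = n)
  sp_idx <- sp_idx[order(sp_idx)]
  p <- presets[sp_idx, ]
  code <- gsub("[^A-Za-z]", "", substr(gsub("^A\\. ", "", p$species), 1, 3))
  within_i <- stats::ave(seq_len(n), sp_idx, FUN = seq_along)
  id <- sprintf("%s_%03d", tolower(code), within_i)

  c_mm <- p$chord_median_mm * 10^stats::rnorm(n, 0, p$chord_log10_sd)
  s_mm <- c_mm / p$chord_span_ratio
  a_cm2 <- p$area_shape_factor * c_mm * s_mm / 100
  m_mg <- p$weighting_factor * p$mass_coefficient * (a_cm2 * 1e-4)^1.5 * 1e6

  morph <- data.frame(specimen_id = id, species = p$species,
                      mass_mg = m_mg, span_mm = s_mm, chord_mm = c_mm,
                      area_cm2 = a_cm2, stringsAsFactors = FALSE)

  reps <- config$replicates
  ridx <- rep(seq_len(n), each = reps)
  theta <- .rnorm_trunc(n * reps, p$theta_mean_deg[ridx],
                        p$theta_sd_deg[ridx], 91, 179)
  v_d <- velocity_from_balance(m_mg[ridx] * 1e-6, a_cm2[ridx] * 1e-4,
                               theta, config$C_D_true,
                               constants = constants) *
    .lognoise(n * reps, config$noise_sd_V)
  phi <- .rnorm_trunc(n * reps, config$phi_mean, config$phi_sd, 1, 89)
  omega <- v_d / (0.75 * s_mm[ridx] * 1e-3 * tan(deg2rad(phi))) *
    .lognoise(n * reps, config$noise_sd_dynamics)

  dyn <- data.frame(specimen_id = id[ridx],
                    replicate = rep(seq_len(reps), times = n),
                    v_d_m_s = v_d, omega_rad_s = omega, theta_deg = theta,
                    stringsAsFactors = FALSE)

  structure(list(
    morphology = morph,
    dynamics = dyn,
    truth = list(config = config, presets = presets,
                 constants = constants, C_D_true = config$C_D_true)
  ), class = "samara_population")
}

#' @export
print.samara_population <- function(x, ...) {
  cat("Synthetic samara population:", nrow(x$morphology), "specimens,",
      length(unique(x$morphology$species)), "species,",
      nrow(x$dynamics), "flight records\n")
  cat(sprintf("  generated at C_D = %.3g, seed = %d\n",
              x$truth$C_D_true, x$truth$config$seed))
  invisible(x)
}

#' Generate a perturbation series for one specimen
#'
#' Emulates mass-alteration (wax addition / nutlet shaving) and
#' trailing-edge ablation experiments. Each level's dynamics are the
#' specimen baseline scaled by the configured power-law responses of the
#' driving ratio, times multiplicative lognormal noise, with
#' `replicates` rows per level. Levels outside the species' sustained
#' envelope -- and levels whose scaled coning angle would leave (0, 180)
#' degrees, i.e. the cone flattening past the rotor plane -- are flagged
#' `failed` with missing dynamics (no stable autorotation).
#'
#' Bookkeeping of the non-driving ratio follows the experimental
#' procedure: wax addition also grows area slightly
#' (`A/A0 = min(1.05, 1 + 0.04 (m/m0 - 1))`), mass subtraction leaves
#' area untouched, and trailing-edge ablation removes a little mass
#' (`m/m0 = max(0.96, 1 - 0.1 (1 - A/A0))`).
#'
#' @param morph_row single-row morphology data.frame for the specimen.
#' @param baseline named list or vector with the unaltered `v_d`, `omega`,
#'   `theta` (typically replicate means from a generated population).
#' @param kind one of `"mass_add"`, `"mass_sub"`, `"ablation"`.
#' @param levels vector of driving ratios (m/m0 for mass kinds, A/A0 for
#'   ablation). Level 0 (ratio 1, the unaltered state) is always included
#'   and need not be listed.
#' @param config a [generator_config()] supplying response exponents,
#'   noise and replicates. The caller controls the random state (this
#'   function does not reseed), so series for several specimens can be
#'   drawn from one stream.
#' @param preset single-row preset for the specimen's species (failure
#'   bounds).
#' @return data.frame in the perturbation CSV dialect.
#' @seealso [generate_perturbation_study()] for the full multi-species
#'   design.
#' @export
generate_perturbation_series <- function(morph_row, baseline,
                                         kind = c("mass_add", "mass_sub",
                                                  "ablation"),
                                         levels, config, preset) {
  kind <- match.arg(kind)
  stopifnot(inherits(config, "generator_config"),
            is.data.frame(morph_row), nrow(morph_row) == 1L,
            is.data.frame(preset), nrow(preset) == 1L)
  baseline <- as.list(baseline)
  stopifnot(all(c("v_d", "omega", "theta") %in% names(baseline)))
  if (any(!is.finite(levels) | levels <= 0)) {
    stop("levels must be positive ratios", call. = FALSE)
  }
  if (kind == "mass_add" && any(levels < 1)) {
    stop("kind/driver mismatch: mass_add requires m/m0 >= 1", call. = FALSE)
  }
  if (kind == "mass_sub" && any(levels > 1)) {
    stop("kind/driver mismatch: mass_sub requires m/m0 <= 1", call. = FALSE)
  }
  if (kind == "ablation" && any(levels > 1)) {
    stop("kind/driver mismatch: ablation requires A/A0 <= 1", call. = FALSE)
  }
  levels <- c(1, levels[levels != 1])
  ex <- config$response_exponents
  if (kind == "ablation") {
    e <- c(ex$V_vs_A, ex$omega_vs_A, ex$theta_vs_A)
    a_ratio <- levels
    m_ratio <- pmax(0.96, 1 - 0.1 * (1 - a_ratio))
    failed <- a_ratio < preset$min_a_ratio
  } else {
    e <- c(ex$V_vs_m, ex$omega_vs_m, ex$theta_vs_m)
    m_ratio <- levels
    a_ratio <- if (kind == "mass_add") {
      pmin(1.05, 1 + 0.04 * (m_ratio - 1))
    } else rep(1, length(levels))
    failed <- m_ratio < preset$min_m_ratio | m_ratio > preset$max_m_ratio
  }
  driver <- levels
  theta_new <- baseline$theta * driver^e[3]
  failed <- failed | theta_new >= 179.9 | theta_new <= 0.1
  reps <- config$replicates
  nl <- length(levels)
  li <- rep(seq_len(nl), each = reps)
  out <- data.frame(
    specimen_id = morph_row$specimen_id,
    species = morph_row$species,
    kind = kind,
    level_index = rep(seq_len(nl) - 1L, each = reps),
    m_ratio = m_ratio[li],
    a_ratio = a_ratio[li],
    replicate = rep(seq_len(reps), times = nl),
    v_d_m_s = baseline$v_d * driver[li]^e[1] *
      .lognoise(nl * reps, config$noise_sd_V),
    omega_rad_s = baseline$omega * driver[li]^e[2] *
      .lognoise(nl * reps, config$noise_sd_dynamics),
    theta_deg = theta_new[li] * .lognoise(nl * reps,
                                          config$noise_sd_dynamics),
    failed = failed[li],
    stringsAsFactors = FALSE
  )
  out$v_d_m_s[out$failed] <- NA_real_
  out$omega_rad_s[out$failed] <- NA_real_
  out$theta_deg[out$failed] <- NA_real_
  out
}

#' Generate the full perturbation study design
#'
#' Reproduces the experimental layout: mass alteration on four species --
#' the overweighted (A. saccharum) and underweighted (A. negundo)
#' species plus the largest (A. macrophyllum) and smallest
#' (A. buergerianum) -- with `n_per_species` specimens each, and
#' trailing-edge ablation on the same specimens. Baselines are replicate
#' means from a generated population restricted to those species.
#'
#' @param population a `samara_population` (must contain the target
#'   species).
#' @param config a [generator_config()]; its seed fixes the series noise.
#' @param species character vector of species to perturb; defaults to the
#'   four mass-augmentation species.
#' @param n_per_species specimens per species (default 3).
#' @param mass_levels driving m/m0 levels (default 0.5-2.0).
#' @param ablation_levels driving A/A0 levels (default 0.65-1.0).
#' @return list with data.frames `mass` and `ablation` in the perturbation
#'   CSV dialect.
#' @examples
#' cfg <- generator_config(n_specimens = 40, seed = 9)
#' pop <- generate_population(cfg)
#' study <- generate_perturbation_study(pop, cfg)
#' head(study$mass)
#' @export
generate_perturbation_study <- function(population, config,
                                        species = c("A. saccharum",
                                                    "A. negundo",
                                                    "A. macrophyllum",
                                                    "A. buergerianum"),
                                        n_per_species = 3,
                                        mass_levels = c(0.5, 0.75, 1.25,
                                                        1.5, 2.0),
                                        ablation_levels = c(0.65, 0.75,
                                                            0.85, 0.95)) {
  stopifnot(inherits(population, "samara_population"))
  presets <- population$truth$presets
  morph <- population$morphology
  dyn <- population$dynamics
  set.seed(config$seed + 1L)
  mass_out <- list()
  abl_out <- list()
  for (sp in species) {
    rows <- which(morph$species == sp)
    if (!length(rows)) {
      stop("population has no specimens of ", sp, call. = FALSE)
    }
    rows <- utils::head(rows, n_per_species)
    preset <- presets[presets$species == sp, , drop = FALSE]
    for (r in rows) {
      mr <- morph[r, , drop = FALSE]
      d <- dyn[dyn$specimen_id == mr$specimen_id, ]
      base <- list(v_d = mean(d$v_d_m_s), omega = mean(d$omega_rad_s),
                   theta = mean(d$theta_deg))
      add <- generate_perturbation_series(
        mr, base, "mass_add", mass_levels[mass_levels > 1], config, preset)
      sub <- generate_perturbation_series(
        mr, base, "mass_sub", mass_levels[mass_levels < 1], config, preset)
      # one shared baseline: drop the duplicate level-0 rows of the
      # subtraction branch and renumber its levels after the addition's
      sub <- sub[sub$level_index > 0L, ]
      if (nrow(sub)) {
        sub$level_index <- sub$level_index + max(add$level_index)
      }
      mass_out[[length(mass_out) + 1L]] <- rbind(add, sub)
      abl_out[[length(abl_out) + 1L]] <- generate_perturbation_series(
        mr, base, "ablation", ablation_levels, config, preset)
    }
  }
  list(mass = do.call(rbind, mass_out), ablation = do.call(rbind, abl_out))
}
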