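.run_config_defaults <- function() {
  list(
    seed = NULL,
    n_specimens = 160L,
    replicates = 3L,
    C_D_true = 5.99,
    noise_sd_V = 0.05,
    noise_sd_dynamics = 0.05,
    response_exponents = list(V_vs_m = 0.12, omega_vs_m = 0.70,
                              theta_vs_m = -0.48, V_vs_A = -0.79,
                              omega_vs_A = 0.03, theta_vs_A = -0.38),
    phi_mean = 42.5,
    phi_sd = 3.2,
    g = 9.81,
    rho_air = 1.23,
    projection = "abs_cos",
    through_origin = FALSE,
    r_c_fraction = 0.25,
    preset_set = "study",
    log_level = "info"
  )
}

#' Resolve a pipeline run configuration
#'
#' Reads a YAML file (or takes a named list), validates it against the
#' known keys, and fills unset keys from the defaults. Unknown keys are
#' rejected rather than ignored, so typos cannot silently change a run.
#' Every simulate/analyze run writes its fully-resolved configuration
#' next to its outputs; feeding that sidecar back reproduces the run.
#'
#' @param x path to a YAML file, a named list, or `NULL` (defaults only).
#' @return named list of class `run_config` with all keys resolved.
#' @export
run_config <- function(x = NULL) {
  defaults <- .run_config_defaults()
  user <- if (is.null(x)) list() else if (is.character(x)) {
    yaml::read_yaml(x)
  } else if (is.list(x)) x else {
    stop("x must be a YAML path or a named list", call. = FALSE)
  }
  if (inherits(x, "run_config")) return(x)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, user)
  structure(cfg, class = "run_config")
}

.cfg_generator <- function(cfg) {
  generator_config(
    n_specimens = cfg$n_specimens, replicates = cfg$replicates,
    C_D_true = cfg$C_D_true, noise_sd_V = cfg$noise_sd_V,
    noise_sd_dynamics = cfg$noise_sd_dynamics,
    response_exponents = cfg$response_exponents,
    phi_mean = cfg$phi_mean, phi_sd = cfg$phi_sd, seed = cfg$seed)
}

.cfg_constants <- function(cfg) samara_constants(cfg$g, cfg$rho_air)

.log <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(...)
}

.write_resolved <- function(cfg, out_dir) {
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "run_config.yaml"))
}

#' Simulate a population and perturbation study to disk
#'
#' Generates the synthetic population and the four-species perturbation
#' study under the resolved configuration and writes `population.csv`,
#' `dynamics.csv`, `perturbation_mass.csv`, `perturbation_ablation.csv`,
#' the ground-truth parameters (`truth.json`) and the resolved
#' configuration (`run_config.yaml`) into `out_dir`. Identical
#' configurations produce identical files.
#'
#' @param config anything [run_config()] accepts; `seed` must be set.
#' @param out_dir output directory (created if needed).
#' @param force overwrite existing outputs.
#' @return Invisibly, the list of written paths.
#' @export
samara_simulate <- function(config, out_dir, force = FALSE) {
  cfg <- run_config(config)
  if (is.null(cfg$seed)) {
    stop("refusing to simulate without a seed (set `seed:` in the config)",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("population.csv", "dynamics.csv",
                                "perturbation_mass.csv",
                                "perturbation_ablation.csv", "truth.json"))
  if (!force && any(file.exists(paths))) {
    stop("outputs already exist in ", out_dir, " (use force = TRUE)",
         call. = FALSE)
  }
  gen <- .cfg_generator(cfg)
  presets <- samara_presets(cfg$preset_set)
  pop <- generate_population(gen, presets = presets,
                             constants = .cfg_constants(cfg))
  study <- generate_perturbation_study(pop, gen)
  write_samara_csv(pop$morphology, paths[1])
  write_samara_csv(pop$dynamics, paths[2])
  write_samara_csv(study$mass, paths[3])
  write_samara_csv(study$ablation, paths[4])
  truth <- list(C_D_true = gen$C_D_true,
                response_exponents = gen$response_exponents,
                mass_coefficient = presets$mass_coefficient[1],
                seed = gen$seed)
  jsonlite::write_json(truth, paths[5], auto_unbox = TRUE, digits = NA)
  .write_resolved(cfg, out_dir)
  .log(cfg, "simulated ", nrow(pop$morphology), " specimens into ", out_dir)
  invisible(c(paths, file.path(out_dir, "run_config.yaml")))
}

#' Measure every silhouette image in a directory
#'
#' Segments and measures each PNG/TIFF in `image_dir`, writing one
#' morphology CSV (specimen ids from file name stems; mass left `NA` --
#' images carry no mass information) and a JSON audit sidecar per image
#' holding the span endpoints' 0-based pixel coordinates.
#'
#' @param image_dir directory of images.
#' @param scale mm per pixel of the images.
#' @param out_csv path of the morphology CSV to write.
#' @param config optional [run_config()] (logging only).
#' @return Invisibly, a list with `n_measured`, `n_failed`, `failed`
#'   (file names); unreadable or unsegmentable files are skipped with a
#'   warning.
#' @export
samara_measure <- function(image_dir, scale, out_csv,
                           config = run_config()) {
  cfg <- run_config(config)
  files <- list.files(image_dir, pattern = "\\.(png|tif|tiff)$",
                      ignore.case = TRUE, full.names = TRUE)
  rows <- list()
  failed <- character(0)
  for (f in files) {
    res <- tryCatch({
      s <- segment_silhouette(read_silhouette(f), scale = scale)
      meas <- measure_silhouette(s)
      sidecar <- sub("\\.[^.]+$", ".measure.json", f)
      jsonlite::write_json(
        list(file = basename(f),
             span_endpoints_rowcol_0based = meas$endpoints,
             span_mm = meas$span_mm, chord_mm = meas$chord_mm,
             area_cm2 = meas$area_cm2, pixel_count = meas$pixel_count),
        sidecar, auto_unbox = TRUE, digits = NA)
      data.frame(specimen_id = sub("\\.[^.]+$", "", basename(f)),
                 species = "unknown", mass_mg = NA_real_,
                 span_mm = meas$span_mm, chord_mm = meas$chord_mm,
                 area_cm2 = meas$area_cm2, stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("skipping ", basename(f), ": ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) failed <- c(failed, basename(f)) else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(specimen_id = character(0), species = character(0),
               mass_mg = numeric(0), span_mm = numeric(0),
               chord_mm = numeric(0), area_cm2 = numeric(0))
  if (!nrow(out)) warning("no images measured from ", image_dir)
  write_samara_csv(out, out_csv)
  .log(cfg, "measured ", nrow(out), " image(s), ", length(failed),
       " failure(s)")
  invisible(list(n_measured = nrow(out), n_failed = length(failed),
                 failed = failed))
}

#' Run the full descent analysis and write fits + report
#'
#' Reads the population (and optionally perturbation) CSVs, validates the
#' morphology, fits the coning-angle drag model, compares it with wing
#' loading, runs the allometry suite, fits the reduced-variable
#' perturbation responses and the robustness summary, and writes
#' `fits.json` plus a human-readable `report.txt` (sections for absent
#' inputs are marked absent rather than dropped) and the resolved
#' configuration.
#'
#' @param population_csv morphology CSV path.
#' @param dynamics_csv dynamics CSV path.
#' @param out_dir output directory.
#' @param perturbation_mass_csv,perturbation_ablation_csv optional
#'   perturbation CSV paths.
#' @param config anything [run_config()] accepts.
#' @return Invisibly, the list of fitted objects.
#' @export
samara_analyze <- function(population_csv, dynamics_csv, out_dir,
                           perturbation_mass_csv = NULL,
                           perturbation_ablation_csv = NULL,
                           config = run_config()) {
  cfg <- run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  constants <- .cfg_constants(cfg)
  morph <- read_morphology(population_csv)
  dyn <- read_dynamics(dynamics_csv)
  val <- validate_population(morph)
  ft <- force_table(morph, dyn, constants = constants,
                    projection = cfg$projection,
                    r_c_fraction = cfg$r_c_fraction)
  drag <- fit_drag_model(ft, through_origin = cfg$through_origin)
  cmp <- compare_models(morph, dyn, constants = constants,
                        through_origin = cfg$through_origin)
  allo <- allometry_suite(morph)

  fits <- list(
    validation = list(n_records = val$n_records, n_passing = val$n_passing),
    drag_model = list(slope = drag$slope, intercept = drag$intercept,
                      r2 = drag$r2, C_D = drag$C_D, n = drag$n),
    model_comparison = list(r2_wing_loading = cmp$r2_wing_loading,
                            r2_drag_model = cmp$r2_drag_model,
                            delta_r2 = cmp$delta_r2),
    allometry = as.data.frame(allo)
  )

  resp_mass <- resp_abl <- robust <- NULL
  if (!is.null(perturbation_mass_csv)) {
    pert_m <- reduce_perturbation(read_perturbation(perturbation_mass_csv))
    resp_mass <- fit_responses(pert_m, driver = "m_ratio")
    all_pert <- pert_m
    if (!is.null(perturbation_ablation_csv)) {
      pert_a <- reduce_perturbation(
        read_perturbation(perturbation_ablation_csv))
      resp_abl <- fit_responses(pert_a, driver = "a_ratio")
      all_pert <- rbind(pert_m, pert_a)
    }
    robust <- robustness_summary(all_pert, resp_mass)
    as_json <- function(rf) lapply(rf, function(e) {
      list(response = e$response, driver = e$driver,
           exponent = e$fit$exponent, r2 = e$fit$r2, n = e$fit$n)
    })
    fits$mass_response <- as_json(resp_mass)
    if (!is.null(resp_abl)) fits$ablation_response <- as_json(resp_abl)
    fits$robustness <- robust
  }
  jsonlite::write_json(fits, file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  rep_path <- file.path(out_dir, "report.txt")
  con <- file(rep_path, "w")
  on.exit(close(con), add = TRUE)
  wline <- function(...) writeLines(paste0(...), con)
  wline("Samara descent analysis")
  wline("=======================")
  wline(sprintf("Population: %d records, %d passing validation",
                val$n_records, val$n_passing))
  wline("")
  wline("Drag model (F_D = rho V^2 A |cos theta| vs mg):")
  wline(sprintf("  C_D = %.3f, R^2 = %.3f (n = %d)", drag$C_D, drag$r2,
                drag$n))
  wline("")
  wline("Model comparison:")
  wline(sprintf("  wing loading R^2 = %.3f | drag model R^2 = %.3f",
                cmp$r2_wing_loading, cmp$r2_drag_model))
  wline("")
  wline("Allometry (free fits):")
  for (nm in c("A_vs_m", "A_vs_S", "A_vs_c", "A_vs_cS")) {
    f <- allo[[nm]]
    wline(sprintf("  %s: A ~ x^%.2f, R^2 = %.2f",
                  sub("_vs_", " vs ", nm), f$exponent, f$r2))
  }
  wline("")
  if (is.null(resp_mass)) {
    wline("Mass response: [absent - no perturbation input]")
  } else {
    wline("Mass response (reduced variables):")
    for (k in names(resp_mass)) {
      wline(sprintf("  %s ~ (m/m0)^%+.2f, R^2 = %.2f", k,
                    resp_mass[[k]]$fit$exponent, resp_mass[[k]]$fit$r2))
    }
  }
  if (is.null(resp_abl)) {
    wline("Ablation response: [absent - no perturbation input]")
  } else {
    wline("Ablation response (reduced variables):")
    for (k in names(resp_abl)) {
      wline(sprintf("  %s ~ (A/A0)^%+.2f, R^2 = %.2f", k,
                    resp_abl[[k]]$fit$exponent, resp_abl[[k]]$fit$r2))
    }
  }
  if (!is.null(robust)) {
    wline("")
    wline("Robustness summary:")
    for (i in seq_len(nrow(robust))) {
      wline(sprintf(
        "  %s: m/m0 sustained %.2f-%.2f, A/A0 down to %.2f, dV at 2x mass = %.1f%%",
        robust$species[i], robust$min_m_ratio_sustained[i],
        robust$max_m_ratio_sustained[i], robust$min_a_ratio_sustained[i],
        100 * robust$predicted_V_change_at_double_mass[i]))
    }
  }
  .write_resolved(cfg, out_dir)
  .log(cfg, "analysis written to ", out_dir)
  invisible(list(validation = val, drag = drag, comparison = cmp,
                 allometry = allo, mass_response = resp_mass,
                 ablation_response = resp_abl, robustness = robust))
}
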