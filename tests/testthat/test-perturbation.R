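# a small deterministic perturbation table built through the generator
make_series <- function(kind = "mass_add", levels = c(1.25, 1.5, 2),
                        seed = 1, noise = 0, exponents = NULL) {
  cfg <- if (is.null(exponents)) quiet_config(n = 8, seed = seed) else
    quiet_config(n = 8, seed = seed, response_exponents = exponents)
  if (noise > 0) {
    cfg <- generator_config(n_specimens = 8, seed = seed,
                            noise_sd_V = noise, noise_sd_dynamics = noise,
                            response_exponents = cfg$response_exponents)
  }
  pop <- generate_population(cfg)
  presets <- pop$truth$presets
  out <- list()
  set.seed(seed + 1000)
  for (id in unique(pop$morphology$specimen_id)[1:3]) {
    mr <- pop$morphology[pop$morphology$specimen_id == id, ]
    d <- pop$dynamics[pop$dynamics$specimen_id == id, ]
    base <- list(v_d = mean(d$v_d_m_s), omega = mean(d$omega_rad_s),
                 theta = mean(d$theta_deg))
    preset <- presets[presets$species == mr$species, ]
    out[[id]] <- generate_perturbation_series(mr, base, kind, levels, cfg,
                                              preset)
  }
  do.call(rbind, out)
}

test_that("reduction divides by the unaltered baseline", {
  ser <- make_series()
  red <- reduce_perturbation(ser)
  base <- red[red$level_index == 0L, ]
  expect_equal(base$v_ratio, rep(1, nrow(base)))
  expect_equal(base$omega_ratio, rep(1, nrow(base)))
  lvl <- red[abs(red$m_ratio - 1.5) < 1e-12 & !red$failed, ]
  expect_gt(nrow(lvl), 0)
  expect_equal(lvl$v_ratio, rep(1.5^0.12, nrow(lvl)), tolerance = 1e-10)
  expect_equal(lvl$omega_ratio, rep(1.5^0.70, nrow(lvl)), tolerance = 1e-10)
  expect_equal(lvl$theta_ratio, rep(1.5^-0.48, nrow(lvl)),
               tolerance = 1e-10)
})

test_that("reduction is idempotent and fails without a baseline", {
  ser <- make_series()
  red <- reduce_perturbation(ser)
  expect_identical(reduce_perturbation(red), red)
  orphan <- ser[ser$level_index > 0L, ]
  expect_error(reduce_perturbation(orphan), orphan$specimen_id[1])
})

test_that("noise-free response fits recover the configured exponents", {
  red_m <- reduce_perturbation(make_series("mass_add",
                                           levels = c(1.1, 1.25, 1.4)))
  fits <- fit_responses(red_m, driver = "m_ratio")
  expect_equal(fits$v_ratio$fit$exponent, 0.12, tolerance = 1e-8)
  expect_equal(fits$omega_ratio$fit$exponent, 0.70, tolerance = 1e-8)
  expect_equal(fits$theta_ratio$fit$exponent, -0.48, tolerance = 1e-8)
  expect_equal(fits$v_ratio$fit$r2, 1, tolerance = 1e-9)

  red_a <- reduce_perturbation(make_series("ablation",
                                           levels = c(0.8, 0.9, 0.95)))
  fits_a <- fit_responses(red_a, driver = "a_ratio")
  expect_equal(fits_a$v_ratio$fit$exponent, -0.79, tolerance = 1e-8)
  expect_equal(fits_a$omega_ratio$fit$exponent, 0.03, tolerance = 1e-8)
  expect_equal(fits_a$theta_ratio$fit$exponent, -0.38, tolerance = 1e-8)
})

test_that("noise-free recovery is exact for arbitrary exponents in [-1, 1]", {
  set.seed(31)
  for (i in 1:5) {
    ex <- as.list(runif(6, -1, 1))
    names(ex) <- c("V_vs_m", "omega_vs_m", "theta_vs_m", "V_vs_A",
                   "omega_vs_A", "theta_vs_A")
    ex$theta_vs_m <- runif(1, -0.3, 0.3) # keep theta inside (0, 180)
    red <- reduce_perturbation(
      make_series("mass_add", levels = c(1.2, 1.35, 1.5), exponents = ex,
                  seed = i))
    fits <- fit_responses(red, driver = "m_ratio")
    expect_equal(fits$v_ratio$fit$exponent, ex$V_vs_m, tolerance = 1e-8)
    expect_equal(fits$omega_ratio$fit$exponent, ex$omega_vs_m,
                 tolerance = 1e-8)
    expect_equal(fits$theta_ratio$fit$exponent, ex$theta_vs_m,
                 tolerance = 1e-8)
  }
})

test_that("a degenerate driver is rejected", {
  ser <- make_series(levels = numeric(0)) # baseline only
  red <- reduce_perturbation(ser)
  expect_error(fit_responses(red, driver = "m_ratio"), "degenerate driver")
})

test_that("failed records are excluded from fits but bound the summary", {
  cfg <- generator_config(n_specimens = 40, seed = 12)
  pop <- generate_population(cfg)
  # push A. negundo past its sustained envelope (0.5 <~ m/m0 <~ 2.25)
  mr <- pop$morphology[pop$morphology$species == "A. negundo", ][1, ]
  d <- pop$dynamics[pop$dynamics$specimen_id == mr$specimen_id, ]
  base <- list(v_d = mean(d$v_d_m_s), omega = mean(d$omega_rad_s),
               theta = mean(d$theta_deg))
  preset <- samara_presets()[samara_presets()$species == "A. negundo", ]
  set.seed(1)
  ser <- generate_perturbation_series(
    mr, base, "mass_add", c(1.25, 1.5, 2, 2.25, 2.5), quiet_config(seed = 1),
    preset)
  expect_true(all(ser$failed[ser$m_ratio > 2.25]))
  expect_true(all(is.na(ser$v_d_m_s[ser$failed])))
  red <- reduce_perturbation(ser)
  fits <- fit_responses(red, driver = "m_ratio")
  expect_equal(fits$v_ratio$fit$exponent, 0.12, tolerance = 1e-8)
  rob <- robustness_summary(red, fits)
  expect_equal(rob$max_m_ratio_sustained, 2.25)
})

test_that("robustness prediction at doubled mass follows 2^b - 1", {
  red <- reduce_perturbation(make_series("mass_add",
                                         levels = c(1.25, 1.5, 2)))
  fits <- fit_responses(red, driver = "m_ratio")
  rob <- robustness_summary(red, fits)
  expect_equal(unique(rob$predicted_V_change_at_double_mass), 2^0.12 - 1,
               tolerance = 1e-8)
  expect_lt(unique(rob$predicted_V_change_at_double_mass), 0.15)
  # the fixed-area force-balance exponent 0.5 would breach the bound
  expect_gt(2^0.5 - 1, 0.15)
})

test_that("altered specimens obey wing loading better than the population", {
  for (seed in c(2, 5)) {
    cfg <- generator_config(n_specimens = 80, seed = seed)
    pop <- generate_population(cfg)
    study <- generate_perturbation_study(pop, cfg)
    chk <- wing_loading_check(study$mass, pop$morphology, pop$dynamics)
    expect_gt(chk$r2_within_mean, chk$r2_across)
    expect_gt(chk$r2_within_mean, 0.6)
  }
})

test_that("wing-loading check rejects degenerate series", {
  cfg <- generator_config(n_specimens = 8, seed = 3)
  pop <- generate_population(cfg)
  ser <- make_series(levels = numeric(0), seed = 3) # constant everything
  expect_error(
    wing_loading_check(ser, pop$morphology, pop$dynamics), "singular")
})
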