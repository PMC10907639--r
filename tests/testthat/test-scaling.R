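test_that("an exact power law is recovered exactly", {
  fit <- fit_power_law(c(1, 2, 4), 2 * c(1, 2, 4)^2)
  expect_equal(fit$exponent, 2, tolerance = 1e-12)
  expect_equal(fit$log10_prefactor, log10(2), tolerance = 1e-12)
  expect_equal(fit$r2, 1)
  expect_false(fit$exponent_fixed)
  expect_equal(unname(predict(fit, newdata = 3)), 18, tolerance = 1e-10)
})

test_that("free fits equal the normal-equations oracle to 1e-10", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(3:50, 1)
    x <- 10^runif(n, -1, 2)
    y <- 10^(runif(1, -2, 2) + runif(1, -2, 2) * log10(x) +
               rnorm(n, 0, 0.3))
    fit <- fit_power_law(x, y)
    X <- cbind(1, log10(x))
    beta <- solve(t(X) %*% X, t(X) %*% log10(y))
    expect_equal(fit$log10_prefactor, beta[1, 1], tolerance = 1e-10)
    expect_equal(fit$exponent, beta[2, 1], tolerance = 1e-10)
  }
})

test_that("fixed-exponent fits estimate only the prefactor and nest", {
  set.seed(22)
  for (i in 1:20) {
    n <- sample(4:40, 1)
    x <- 10^runif(n, 0, 2)
    y <- 10^(0.3 + 0.52 * log10(x) + rnorm(n, 0, 0.15))
    free <- fit_power_law(x, y)
    fixed <- fit_power_law(x, y, fixed_exponent = 2 / 3)
    # least-squares prefactor given the imposed slope
    expect_equal(fixed$log10_prefactor,
                 mean(log10(y) - (2 / 3) * log10(x)), tolerance = 1e-12)
    expect_true(fixed$exponent_fixed)
    expect_lte(fixed$r2, free$r2)
  }
  # data generated at exponent 0.52: the imposed 2/3 must fit worse
  set.seed(23)
  x <- 10^runif(60, 0, 2)
  y <- 10^(0.1 + 0.52 * log10(x) + rnorm(60, 0, 0.1))
  expect_lt(fit_power_law(x, y, fixed_exponent = 2 / 3)$r2,
            fit_power_law(x, y)$r2)
})

test_that("power-law fit rejects bad inputs informatively", {
  expect_error(fit_power_law(c(1, 2, -3), c(1, 2, 3)), "3")
  expect_error(fit_power_law(c(1, 2), c(1, 2)), "n >= 3")
  expect_error(fit_power_law(c(2, 2, 2), c(1, 2, 3)), "degenerate")
  expect_silent(fit_power_law(c(1, 2), c(1, 2), fixed_exponent = 1))
})

test_that("noisy exponent recovery is unbiased over seeded replicates", {
  b <- numeric(200)
  for (s in 1:200) {
    set.seed(s)
    x <- 10^runif(30, 0, 1.5)
    y <- 10^(0.2 + 0.7 * log10(x) + rnorm(30, 0, 0.1))
    b[s] <- fit_power_law(x, y)$exponent
  }
  se_mean <- sd(b) / sqrt(length(b))
  expect_lt(abs(mean(b) - 0.7), 2 * se_mean)
})

test_that("drag-model fit recovers any true C_D exactly on exact data", {
  pop <- generate_population(quiet_config(n = 24, seed = 4))
  for (cd in c(1, 5.99, 20)) {
    cfg <- quiet_config(n = 24, seed = 4, C_D_true = cd)
    p <- generate_population(cfg)
    fit <- fit_drag_model(force_table(p$morphology, p$dynamics))
    expect_equal(fit$C_D, cd, tolerance = 1e-8)
    expect_equal(fit$r2, 1, tolerance = 1e-10)
    expect_equal(fit$intercept, 0, tolerance = 1e-12)
  }
})

test_that("drag-model slope equals y/x for exact points through origin", {
  forces <- data.frame(specimen_id = c("a", "b", "c"),
                       weight_n = c(1e-4, 2e-4, 3e-4),
                       f_d_n = c(4e-5, 8e-5, 1.2e-4))
  fit <- fit_drag_model(forces)
  expect_equal(fit$slope, 0.4, tolerance = 1e-12)
  expect_equal(fit$C_D, 5, tolerance = 1e-12)
  expect_error(fit_drag_model(transform(forces, weight_n = 2e-4)),
               "singular")
})

test_that("noisy C_D recovery stays within half a unit at n = 160", {
  cfg <- generator_config(n_specimens = 160, seed = 1234)
  pop <- generate_population(cfg)
  fit <- fit_drag_model(force_table(pop$morphology, pop$dynamics))
  expect_lt(abs(fit$C_D - 5.99), 0.5)
  # replicate-level fitting gives a compatible answer
  fit_r <- fit_drag_model(force_table(pop$morphology, pop$dynamics),
                          per_replicate = TRUE)
  expect_lt(abs(fit_r$C_D - fit$C_D), 0.3)
})

test_that("isometric noise-free population is exactly allometric", {
  pop <- generate_population(quiet_config(n = 60, seed = 3),
                             presets = samara_presets("isometric"))
  suite <- allometry_suite(pop$morphology)
  expect_equal(suite$A_vs_m$exponent, 2 / 3, tolerance = 1e-10)
  expect_equal(suite$A_vs_S$exponent, 2, tolerance = 1e-10)
  expect_equal(suite$A_vs_c$exponent, 2, tolerance = 1e-10)
  expect_equal(suite$A_vs_cS$exponent, 1, tolerance = 1e-10)
  for (nm in names(suite)) expect_equal(suite[[nm]]$r2, 1, tolerance = 1e-9)
})

test_that("default interspecific population shows the expected allometry", {
  pop <- generate_population(generator_config(n_specimens = 160, seed = 42))
  suite <- allometry_suite(pop$morphology)
  expect_lt(abs(suite$A_vs_c$exponent - 2), 0.15)
  expect_lt(abs(suite$A_vs_cS$exponent - 1), 0.10)
  expect_gte(suite$A_vs_m$r2, suite$A_vs_m_fixed$r2)
})

test_that("over/under-weighted species pull A~m off the isometric slope", {
  presets <- samara_presets()
  neutral <- presets
  neutral$weighting_factor <- 1
  cfg <- generator_config(n_specimens = 160, seed = 10)
  dev_with <- abs(allometry_suite(
    generate_population(cfg, presets = presets)$morphology
  )$A_vs_m$exponent - 2 / 3)
  dev_without <- abs(allometry_suite(
    generate_population(cfg, presets = neutral)$morphology
  )$A_vs_m$exponent - 2 / 3)
  expect_gt(dev_with, dev_without)
})

test_that("the drag model out-correlates wing loading when theta varies", {
  for (seed in c(1, 2, 3)) {
    pop <- generate_population(generator_config(n_specimens = 80,
                                                seed = seed))
    cmp <- compare_models(pop$morphology, pop$dynamics)
    expect_gt(cmp$r2_drag_model, cmp$r2_wing_loading)
    expect_gt(cmp$delta_r2, 0)
  }
})

test_that("with constant theta and C_D the two models coincide", {
  presets <- samara_presets("isometric")
  presets$theta_sd_deg <- 0
  pop <- generate_population(quiet_config(n = 30, seed = 6),
                             presets = presets)
  cmp <- compare_models(pop$morphology, pop$dynamics)
  expect_equal(cmp$r2_wing_loading, 1, tolerance = 1e-9)
  expect_equal(cmp$r2_drag_model, 1, tolerance = 1e-9)
  expect_equal(cmp$delta_r2, 0, tolerance = 1e-9)
})

test_that("shuffling descent velocities destroys the descent signal", {
  pop <- generate_population(generator_config(n_specimens = 80, seed = 8))
  dyn <- pop$dynamics
  set.seed(99)
  dyn$v_d_m_s <- sample(dyn$v_d_m_s)
  cmp <- compare_models(pop$morphology, dyn)
  cmp0 <- compare_models(pop$morphology, pop$dynamics)
  expect_lt(cmp$r2_wing_loading, 0.2)
  # the drag R^2 collapses too, though a residual correlation remains
  # because projected area and weight stay allometrically linked
  expect_lt(cmp$r2_drag_model, cmp0$r2_drag_model - 0.3)
})
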