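spr_ladder <- c(50, 11, 4.5, 1.8, 0.3) * 1e-6

test_that("the 1:1 Langmuir forward model matches hand-evaluated responses", {
  # at C = KD the plateau is half of Rmax
  KD <- 1e-6; ka <- 1e3; kd <- ka * KD
  expect_equal(model_sensorgram(ka, kd, 100, KD, 1e6, t_a = 2e6), 50,
               tolerance = 1e-6)
  expect_equal(model_sensorgram(1e3, 1e-3, 100, 1e-5, 0), 0)
  # frozen hand evaluation: kobs = 0.011, Req = 1000/11
  expect_equal(model_sensorgram(1e3, 1e-3, 100, 1e-5, 120),
               (1000 / 11) * (1 - exp(-0.011 * 120)), tolerance = 1e-12)
  expect_equal(model_sensorgram(1e3, 1e-3, 100, 1e-5, 120), 66.6241,
               tolerance = 1e-4)
  # dissociation is a pure exponential from R(t_a)
  r <- model_sensorgram(1e3, 1e-3, 100, 1e-5, c(120, 420))
  expect_equal(r[2], r[1] * exp(-1e-3 * 300), tolerance = 1e-12)
})

test_that("global kinetic fits recover noiseless truth to high precision", {
  sg <- gen_sensorgrams(8.72e2, 1.01e-3, 100, concentrations = spr_ladder,
                        noise_sd = 0, seed = 1)
  fit <- fit_kinetic_1to1(sg)
  expect_lt(abs(fit$ka - 8.72e2) / 8.72e2, 1e-6)
  expect_lt(abs(fit$kd - 1.01e-3) / 1.01e-3, 1e-6)
  expect_equal(fit$KD, 1.158e-6, tolerance = 1e-3)
  # internal consistency to machine precision
  expect_equal(fit$KD * fit$ka, fit$kd, tolerance = 1e-14)
  expect_equal(fit$kobs, fit$ka * sort(spr_ladder) + fit$kd)
})

test_that("kinetic fits under noise recover rates within fitted error", {
  sg <- gen_sensorgrams(8.72e2, 1.01e-3, 100, concentrations = spr_ladder,
                        noise_sd = 1, dt = 2, seed = 42)
  fit <- fit_kinetic_1to1(sg)
  expect_lt(abs(fit$ka - 8.72e2), 3 * fit$ka_err + 1e-9)
  expect_lt(abs(fit$kd - 1.01e-3), 3 * fit$kd_err + 1e-12)
})

test_that("degenerate kinetic designs are flagged, not silently fit", {
  # no dissociation decay
  times <- seq(0, 720, by = 2)
  sg0 <- do.call(rbind, lapply(spr_ladder, function(cc)
    data.frame(conc = cc, time = times,
               response = model_sensorgram(872, 0, 100, cc, times, 120))))
  fit0 <- fit_kinetic_1to1(sg0)
  expect_lt(fit0$kd, 1e-8)
  expect_false(is.na(fit0$warning))
  # all concentrations far above KD
  sg_sat <- gen_sensorgrams(1e5, 1e-4, 100, concentrations = spr_ladder,
                            noise_sd = 0, seed = 1)
  expect_false(is.na(fit_kinetic_1to1(sg_sat)$warning))
  expect_error(fit_kinetic_1to1(gen_sensorgrams(872, 1e-3, 100,
                                                concentrations = 1e-6,
                                                seed = 1)),
               ">= 2 concentrations")
})

test_that("steady-state fits invert exact equilibrium responses", {
  KD <- 2e-6; rmax <- 100
  concs <- c(KD, 2 * KD, 10 * KD)
  data <- do.call(rbind, lapply(concs, function(cc)
    data.frame(conc = cc, time = 100:120,
               response = rmax * cc / (cc + KD))))
  fit <- fit_steady_state(data, t_a = 120, plateau_window = 20)
  expect_equal(fit$KD, KD, tolerance = 1e-8)
  expect_equal(fit$rmax, rmax, tolerance = 1e-8)

  one <- data[data$conc == concs[1], ]
  expect_error(fit_steady_state(one, t_a = 120), ">= 2")

  # association long enough to plateau at every rung recovers a
  # micromolar-regime truth within 1%
  sg <- gen_sensorgrams(1e4, 5.7e-2, 100, concentrations = spr_ladder,
                        t_a = 600, t_d = 900, noise_sd = 0, seed = 3)
  fit2 <- fit_steady_state(sg, t_a = 600)
  expect_lt(abs(fit2$KD - 5.7e-6) / 5.7e-6, 0.01)

  # curves that never plateau are excluded with a warning
  slow <- gen_sensorgrams(872, 1.01e-3, 100, concentrations = spr_ladder,
                          t_a = 120, t_d = 720, noise_sd = 0, seed = 4)
  expect_warning(try(fit_steady_state(slow, t_a = 120), silent = TRUE),
                 "excluded")
})

test_that("depletion-corrected fraction bound follows the exact quadratic", {
  # saturation
  expect_gt(fraction_bound(1e-3, 10e-9, 1e-6), 0.999)
  # frozen hand evaluation of the quadratic at L0 = 10 nM, KD = 1 uM
  expect_equal(fraction_bound(1e-6, 10e-9, 1e-6), 0.49875, tolerance = 1e-5)
  # bounded in [0, 1] over random valid inputs
  set.seed(8)
  fb <- fraction_bound(10^runif(500, -9, -3), 10^runif(500, -9, -6),
                       10^runif(500, -8, -4))
  expect_true(all(fb >= 0 & fb <= 1))
  # no-depletion limit: hyperbolic isotherm
  kd <- 1e-6; t0 <- 10^seq(-8, -4, length.out = 20)
  expect_equal(fraction_bound(t0, kd / 1e4, kd), t0 / (t0 + kd),
               tolerance = 1e-3)
})

test_that("isotherm fits recover KD from a 16-point two-fold ladder", {
  iso <- gen_isotherm(13.1e-6, noise_sd = 0, seed = 2)
  expect_equal(nrow(iso), 16L)
  expect_equal(iso$titrant_M[1], 42.5e-6)
  fit <- fit_equilibrium_isotherm(iso$titrant_M, iso$signal)
  expect_lt(abs(fit$KD - 13.1e-6) / 13.1e-6, 0.01)
  expect_false(fit$low_confidence)
  expect_true(all(diff(fit$fb[order(iso$titrant_M)]) >= 0))

  flat <- gen_isotherm(13.1e-6, s_free = 800, s_bound = 800.5, noise_sd = 1,
                       seed = 5)
  fit_flat <- fit_equilibrium_isotherm(flat$titrant_M, flat$signal)
  expect_true(fit_flat$low_confidence)

  expect_error(fit_equilibrium_isotherm(c(1e-6, 2e-6), c(1, 2)), ">= 8")
})

test_that("KD = kd/ka reproduces the reported dissociation constants", {
  expect_lt(abs(kd_from_rates(8.72e2, 10.10e-4) - 1.18e-6), 0.14e-6)
  expect_lt(abs(kd_from_rates(6.06e2, 9.96e-4) - 1.67e-6), 0.21e-6)
  expect_equal(kd_from_rates(8.72e2, 0), 0)
  expect_error(kd_from_rates(0, 1e-3), "positive")
})

test_that("kinetic and steady-state routes agree on KD for noiseless
           full-plateau data", {
  ka <- 5e3; kd <- 1e-2; KD <- kd / ka
  sg <- gen_sensorgrams(ka, kd, 100, concentrations = spr_ladder,
                        t_a = 600, t_d = 900, noise_sd = 0, seed = 6)
  kin <- fit_kinetic_1to1(sg, t_a = 600)
  ss <- fit_steady_state(sg, t_a = 600)
  expect_lt(abs(kin$KD - ss$KD) / KD, 0.01)
  expect_lt(abs(kin$KD - KD) / KD, 1e-4)
})
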