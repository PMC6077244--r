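test_that("airway fitting requires a breath-hold and a populated window", {
  m0 <- breath_maneuver(121, 121, 726, ambient_ppb = 130)
  e <- run_maneuver(default_grid, params_avg, m0)
  expect_error(fit_airway(e, m0, default_grid, params_avg), "breath-hold")
  mbh <- breath_maneuver(121, 121, 726, hold_s = 10, ambient_ppb = 130)
  ebh <- run_maneuver(default_grid, params_avg, mbh)
  expect_error(fit_airway(ebh, mbh, default_grid, params_avg,
                          window_s = 0.001), "no samples")
})

test_that("noise-free self-fits are fixed points", {
  mbh <- breath_maneuver(121, 121, 726, hold_s = 10, ambient_ppb = 130)
  clean <- run_maneuver(default_grid, params_avg, mbh)
  s1 <- fit_airway(clean, mbh, default_grid, params_avg)
  expect_equal(s1$params$J_aw, params_avg$J_aw, tolerance = 0.01)
  expect_lt(s1$rms, 0.5)
  s2 <- fit_alveolar(clean, mbh, default_grid, params_avg)
  expect_equal(s2$params$J_A, params_avg$J_A, tolerance = 0.005)
  expect_equal(s2$params$D_A, params_avg$D_A, tolerance = 0.005)
  expect_lt(s2$rms, 1e-5)
})

test_that("stage-1 recovers the airway flux from noisy breath-hold data", {
  mbh <- breath_maneuver(121, 121, 726, hold_s = 10, ambient_ppb = 130)
  start <- exchange_params(500, 1.6, params_avg$J_A, params_avg$D_A)
  errs <- vapply(1:5, function(s) {
    syn <- synthetic_expirogram(params_avg, mbh, default_grid,
                                sensor_model(), seed = 100 + s)
    f <- fit_airway(syn, mbh, default_grid, start)
    abs(f$params$J_aw - 220) / 220
  }, numeric(1))
  expect_lt(median(errs), 0.15)
})

test_that("alveolar refinement recovers noisy parameters within 5%", {
  m <- breath_maneuver(121, 121, 726, ambient_ppb = 130)
  truth <- params_row_b
  syn <- synthetic_expirogram(truth, m, default_grid, sensor_model(),
                              seed = 7)
  start <- exchange_params(220, 1.6, 2.2e7, 8500)
  f <- fit_alveolar(syn, m, default_grid, start)
  expect_lt(abs(f$params$J_A - truth$J_A) / truth$J_A, 0.05)
  expect_lt(abs(f$params$D_A - truth$D_A) / truth$D_A, 0.05)
})

test_that("equal equilibria with different capacities give different slopes", {
  # same J_A/D_A ratio, different D_A: the phase III slope separates them
  m <- breath_maneuver(121, 121, 726, ambient_ppb = 130)
  pa <- exchange_params(220, 1.6, 1.76e7, 7400)
  pb <- exchange_params(220, 1.6, 0.88e7, 3700)
  ea <- run_maneuver(default_grid, pa, m)
  eb <- run_maneuver(default_grid, pb, m)
  sa <- segment_phases(ea, default_grid)
  sb <- segment_phases(eb, default_grid)
  expect_gt(abs(sa$phase3_slope - sb$phase3_slope) /
              abs(sa$phase3_slope), 0.1)
  # and the phase-III objective separates the two parameter sets
  fa <- fit_alveolar(ea, m, default_grid, pa)
  expect_lt(fa$rms, 1e-4)
  start_b <- exchange_params(220, 1.6, 0.88e7, 3700)
  rms_wrong <- tmad:::.rms(tmad:::.sim_at(start_b, m, default_grid, 0.01,
                                          ea$time_s) - ea$co_ppb)
  expect_gt(rms_wrong, 100)
})

test_that("joint refinement respects its mask and flags weak problems", {
  m <- breath_maneuver(121, 121, 726, ambient_ppb = 130)
  e <- run_maneuver(default_grid, params_avg, m)
  # empty mask: nothing happens
  r0 <- least_squares_refine(e, m, default_grid, params_avg,
                             free = character(0))
  expect_identical(r0$params, params_avg)
  expect_identical(r0$iterations, 0L)
  expect_error(least_squares_refine(e, m, default_grid, params_avg,
                                    free = "Q"), "unknown")
  # all four free on a single no-hold expirogram: airway identifiability
  # is flagged
  r4 <- least_squares_refine(e, m, default_grid, params_avg,
                             free = c("J_aw", "D_aw", "J_A", "D_A"))
  expect_true(any(grepl("weakly identifiable", r4$diagnostics)))
})

test_that("three-flow joint fit pins the alveolar parameters tightly", {
  efrs <- c(54, 103, 217)
  mans <- lapply(efrs, function(E)
    breath_maneuver(127, E, 800, ambient_ppb = 125))
  syn <- lapply(seq_along(mans), function(i)
    synthetic_expirogram(params_avg, mans[[i]], default_grid,
                         sensor_model(), seed = 200 + i))
  start <- exchange_params(220, 1.6, 2.41e7, 7764)
  r <- least_squares_refine(syn, mans, default_grid, start,
                            free = c("J_A", "D_A"))
  expect_lt(abs(r$params$J_A - params_avg$J_A) / params_avg$J_A, 0.02)
  expect_lt(abs(r$params$D_A - params_avg$D_A) / params_avg$D_A, 0.02)
  expect_lt(r$condition_number, 1e4)
})

test_that("the top-level estimator runs two-stage and exposes methods", {
  mbh <- breath_maneuver(121, 121, 726, hold_s = 10, ambient_ppb = 130)
  syn <- synthetic_expirogram(params_avg, mbh, default_grid,
                              sensor_model(), seed = 11)
  fit <- tmad_fit(syn, mbh, default_grid,
                  init = exchange_params(500, 1.6, 2.41e7, 7764))
  cf <- coef(fit)
  expect_named(cf, c("J_aw", "D_aw", "J_A", "D_A"))
  expect_lt(abs(cf[["J_A"]] - params_avg$J_A) / params_avg$J_A, 0.02)
  expect_lt(abs(cf[["D_A"]] - params_avg$D_A) / params_avg$D_A, 0.05)
  expect_lt(abs(cf[["J_aw"]] - 220) / 220, 0.3)
  # residuals are noise-sized
  expect_lt(sd(residuals(fit)), 4)
  # predict simulates an expirogram at the fitted parameters
  pe <- predict(fit)
  expect_s3_class(pe, "expirogram")
  # simulate round-trips through the synthetic generator, deterministically
  s1 <- simulate(fit, seed = 3)
  s2 <- simulate(fit, seed = 3)
  expect_identical(s1[[1]]$co_ppb, s2[[1]]$co_ppb)
  expect_output(print(fit), "Trumpet-model fit")
})
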