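test_that("maneuver inputs are validated", {
  expect_error(breath_maneuver(0, 100, 700), "positive")
  expect_error(breath_maneuver(100, 100, -5), "positive")
  expect_error(breath_maneuver(100, 100, 700, hold_s = -1), ">= 0")
  expect_error(run_maneuver(default_grid, params_row_b,
                            breath_maneuver(2e5, 2e5, 700), dt = 0.01),
               "time step")
})

test_that("expirogram bookkeeping: volumes, times, final volume", {
  e <- run_maneuver(default_grid, params_row_b, maneuver_row_b)
  expect_true(all(diff(e$time_s) > 0))
  expect_true(all(diff(e$volume_ml) > 0))
  expect_true(all(e$co_ppb >= 0))
  # final exhaled volume within one time-step increment of the target
  expect_lt(abs(max(e$volume_ml) - 726), 121 * 0.01 + 1e-9)
})

test_that("zero sources and zero ambient give an identically zero profile", {
  p0 <- exchange_params(0, 0, 0, 0, D_gas = 0.21)
  m <- breath_maneuver(121, 121, 726, ambient_ppb = 0)
  e <- run_maneuver(default_grid, p0, m)
  expect_true(all(e$co_ppb == 0))
  e2 <- run_no_axial_diffusion(default_grid, p0, m)
  expect_true(all(e2$co_ppb == 0))
})

test_that("all reservoirs at the same level give a flat expirogram", {
  # lung gas, airway tissue, alveolar blood and ambient all at `level`:
  # the profile must stay there
  level <- 1800
  p <- equilibrium_params(level)
  m <- breath_maneuver(121, 121, 726, hold_s = 5, ambient_ppb = level)
  e <- run_maneuver(default_grid, p, m,
                    initial = rep(level, length(default_grid$z)))
  expect_true(all(abs(e$co_ppb - level) / level < 0.001))
})

test_that("end-tidal stays strictly below the alveolar equilibrium", {
  C_A <- params_avg$J_A / params_avg$D_A
  for (efr in c(30, 121, 220)) {
    m <- breath_maneuver(127, efr, 800, ambient_ppb = 125)
    expect_lt(end_tidal(run_maneuver(default_grid, params_avg, m)), C_A)
  }
  # even after a 20-s breath-hold
  mbh <- breath_maneuver(127, 121, 800, hold_s = 20, ambient_ppb = 125)
  expect_lt(end_tidal(run_maneuver(default_grid, params_avg, mbh)), C_A)
})

test_that("breath-holding enriches the earliest exhaled gas", {
  m0 <- breath_maneuver(121, 121, 726, ambient_ppb = 130)
  m20 <- breath_maneuver(121, 121, 726, hold_s = 20, ambient_ppb = 130)
  e0 <- run_maneuver(default_grid, params_row_b, m0)
  e20 <- run_maneuver(default_grid, params_row_b, m20)
  first02 <- function(e) mean(e$co_ppb[e$time_s <= 0.2])
  expect_gt(first02(e20), first02(e0))
  # and every sample of the first 0.2 s is raised
  expect_true(all(e20$co_ppb[e20$time_s <= 0.2] >
                    e0$co_ppb[e0$time_s <= 0.2]))
})

test_that("axial diffusion matters in phase III and the switch is consistent", {
  m <- breath_maneuver(121, 121, 726, ambient_ppb = 130)
  eon <- run_maneuver(default_grid, params_row_b, m)
  eoff <- run_no_axial_diffusion(default_grid, params_row_b, m)
  ph3 <- eon$volume_ml > 300
  expect_gt(max(abs(eon$co_ppb[ph3] - eoff$co_ppb[ph3])), 50)
  # D_gas = 0 in the parameters is the same model as the disabled flag
  p0 <- exchange_params(220, 1.6, 1.76e7, 7400, D_gas = 0)
  e0 <- run_maneuver(default_grid, p0, m)
  expect_equal(eoff$co_ppb, e0$co_ppb, tolerance = 1e-12)
})

test_that("the engine is species-agnostic and reproduces NO behaviour", {
  no <- no_exchange_params()
  m <- breath_maneuver(200, 200, 1400, ambient_ppb = 0)
  e <- run_maneuver(default_grid, no, m)
  C_A <- no$J_A / no$D_A # 2.48 ppb
  # without breath-hold the plateau reflects alveolar NO plus the airway
  # flux picked up in transit (~J_aw/EFR), and stays below that bound
  expect_lt(end_tidal(e), C_A + no$J_aw / 200)
  expect_gt(end_tidal(e), 0.5 * C_A)
  # after 20 s of breath-holding, airway NO builds up toward the tissue
  # level and the profile peaks in phase I
  m20 <- breath_maneuver(200, 200, 1400, hold_s = 20, ambient_ppb = 0)
  e20 <- run_maneuver(default_grid, no, m20)
  ph1 <- e20$volume_ml <= default_grid$dead_space_ml
  expect_gt(max(e20$co_ppb[ph1]), end_tidal(e20))
  expect_gt(max(e20$co_ppb[ph1]), 10 * C_A)
})

test_that("snapshots record the axial field at requested times", {
  m <- breath_maneuver(121, 121, 726, hold_s = 2, ambient_ppb = 130)
  e <- run_maneuver(default_grid, params_row_b, m,
                    snapshot_times = c(3, 7, 9))
  sn <- attr(e, "snapshots")
  expect_equal(sn$time_s, c(3, 7, 9))
  expect_equal(sn$phase, c("inhale", "hold", "exhale"))
  expect_equal(dim(sn$C), c(273, 3))
  # distal concentration grows monotonically across the snapshots
  distal <- sn$C[273, ]
  expect_true(all(diff(distal) > 0))
})

test_that("steady cycling raises the single-cycle end-tidal value", {
  e1 <- run_maneuver(default_grid, params_row_b, maneuver_row_b)
  es <- run_maneuver(default_grid, params_row_b, maneuver_row_b,
                     initial = "steady")
  expect_gt(end_tidal(es), end_tidal(e1))
  C_A <- params_row_b$J_A / params_row_b$D_A
  expect_lt(end_tidal(es), C_A)
})

test_that("a measured flow trace drives the phases", {
  tr <- data.frame(time_s = c(0, 6, 6.01, 8, 8.01, 14),
                   flow_ml_s = c(121, 121, 0, 0, -121, -121))
  m <- breath_maneuver(121, 121, 726, hold_s = 2, ambient_ppb = 130,
                       flow_trace = tr)
  e <- run_maneuver(default_grid, params_row_b, m)
  m2 <- breath_maneuver(121, 121, 726, hold_s = 2, ambient_ppb = 130)
  e2 <- run_maneuver(default_grid, params_row_b, m2)
  expect_equal(nrow(e), nrow(e2), tolerance = 2)
  expect_equal(end_tidal(e), end_tidal(e2), tolerance = 0.01)
})
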