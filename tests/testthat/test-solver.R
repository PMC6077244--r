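test_that("tridiagonal solve matches a dense solver on random systems", {
  set.seed(42)
  for (n in c(2, 5, 20)) {
    lo <- c(0, runif(n - 1, -1, 1))
    up <- c(runif(n - 1, -1, 1), 0)
    di <- 2 + abs(lo) + abs(up) + runif(n) # diagonally dominant
    rhs <- runif(n, -5, 5)
    A <- diag(di)
    A[cbind(2:n, 1:(n - 1))] <- lo[-1]
    A[cbind(1:(n - 1), 2:n)] <- up[-n]
    x <- solve_tridiagonal(lo, di, up, rhs)
    expect_equal(x, solve(A, rhs), tolerance = 1e-10)
    expect_lt(max(abs(A %*% x - rhs)) / max(abs(rhs)), 1e-10)
  }
  # identity system returns the right-hand side
  expect_equal(solve_tridiagonal(rep(0, 4), rep(1, 4), rep(0, 4), 1:4),
               as.numeric(1:4))
  expect_error(solve_tridiagonal(c(0, 0), c(0, 1), c(0, 0), c(1, 1)),
               "pivot")
})

test_that("assembled 273-node system is solved to tight residual", {
  g <- default_grid
  state <- runif(length(g$z), 0, 2000)
  sys <- tmad_assemble(g, params_row_b, state, flow = -121, dt = 0.01,
                       ambient = 130)
  x <- solve_tridiagonal(sys$lower, sys$diag, sys$upper, sys$rhs)
  n <- length(x)
  Ax <- sys$diag * x + sys$upper * c(x[-1], 0) + sys$lower * c(0, x[-n])
  expect_lt(max(abs(Ax - sys$rhs)) / max(abs(sys$rhs)), 1e-10)
  # backward Euler with upwinding keeps the matrix diagonally dominant
  expect_true(all(sys$diag >= abs(sys$lower) + abs(sys$upper)))
})

test_that("no flow, no diffusion, no sources gives an identity update", {
  g <- toy_grid
  p0 <- exchange_params(0, 0, 0, 0, D_gas = 0)
  C <- runif(length(g$z), 0, 100)
  st <- tmad_step(g, p0, C, flow = 0, dt = 0.01, mouth_dirichlet = FALSE)
  expect_equal(st$state, C, tolerance = 1e-13)
})

test_that("uniform concentration is invariant under advection and diffusion", {
  g <- default_grid
  p0 <- exchange_params(0, 0, 0, 0, D_gas = 0.21)
  C <- rep(1234, length(g$z))
  for (flow in c(-200, 0, 150)) {
    st <- tmad_step(g, p0, C, flow = flow, dt = 0.01,
                    mouth_dirichlet = flow > 0, ambient = 1234)
    expect_equal(st$state, C, tolerance = 1e-12)
  }
})

test_that("a two-node closed system follows the scalar implicit update", {
  # flow 0, no diffusion: each node is an independent scalar
  # v (C' - C)/dt = dz * w * (J - D C')  =>  C' = (vC/dt + dz w J)/(v/dt + dz w D)
  n <- 2; dz <- 0.5
  g <- toy_grid
  g$z <- g$z[1:2]; g$A_aw <- c(3, 4); g$A_alv <- c(0, 6)
  g$capacity <- g$A_aw + g$A_alv
  g$w_alv <- c(0, 2); g$w_aw <- c(2, 0); g$A_face <- 3.5
  p <- exchange_params(100, 2, 5000, 10, D_gas = 0)
  C0 <- c(0, 0); dt <- 0.05
  st <- tmad_step(g, p, C0, flow = 0, dt = dt, mouth_dirichlet = FALSE)
  v <- g$capacity * dz
  hand <- (v * C0 / dt + dz * (g$w_aw * p$J_aw + g$w_alv * p$J_A)) /
    (v / dt + dz * (g$w_aw * p$D_aw + g$w_alv * p$D_A))
  expect_equal(st$state, hand, tolerance = 1e-12)
})

test_that("closed-boundary diffusion conserves total content to roundoff", {
  g <- toy_grid
  p0 <- exchange_params(0, 0, 0, 0, D_gas = 0.3)
  C <- c(10, 0, 0, 5, 0, 0, 0, 40, 0, 0)
  m0 <- lung_content(g, C)
  for (k in 1:1000) {
    C <- tmad_step(g, p0, C, flow = 0, dt = 0.05,
                   mouth_dirichlet = FALSE)$state
  }
  expect_lt(abs(lung_content(g, C) - m0) / m0, 1e-6)
  # and diffusion homogenized the field
  expect_lt(diff(range(C)) / mean(C), 0.05)
})

test_that("equilibrium state is a fixed point of the solver", {
  g <- default_grid
  level <- 1500
  p <- equilibrium_params(level)
  C <- rep(level, length(g$z))
  st <- C
  for (k in 1:50) st <- tmad_step(g, p, st, flow = 0, dt = 0.01,
                                  mouth_dirichlet = FALSE)$state
  expect_lt(max(abs(st - level)), 1e-9)
})

test_that("long closed integration approaches the compartment equilibria", {
  g <- default_grid
  p <- params_row_b # C_A 2378, C_tiss 137.5
  C <- rep(0, length(g$z))
  out <- tmad:::.tmad_run(g, p, C, flow = rep(0, 6000),
                          dirichlet = rep(0L, 6000),
                          ambient = rep(0, 6000), dt = 0.01)
  C <- out$state
  C_A <- p$J_A / p$D_A
  # alveolar-dominated nodes reach the alveolar equilibrium within 1%
  alv <- which(g$w_alv * p$D_A > 10 * g$w_aw * p$D_aw & g$w_alv > 0)
  expect_true(all(abs(C[alv] - C_A) / C_A < 0.01))
  # airway nodes sit between the tissue and alveolar levels (axial
  # diffusion couples them to the alveolar reservoir)
  aw <- which(g$w_alv == 0)
  expect_true(all(C[aw] > 0.5 * min(p$J_aw / p$D_aw, C_A)))
  expect_true(all(C[aw] < C_A * 1.001))
})

test_that("implicit solution matches a fine-step explicit reference", {
  g <- toy_grid
  p <- exchange_params(50, 1, 2000, 8, D_gas = 0.25)
  C0 <- rep(0, 10)
  t_end <- 1
  ref <- explicit_reference(g, p, C0, flow = 5, dt = 1e-5,
                            nsteps = t_end / 1e-5, ambient = 100)
  out <- tmad:::.tmad_run(g, p, C0, flow = rep(5, 1000),
                          dirichlet = rep(1L, 1000),
                          ambient = rep(100, 1000), dt = 1e-3)
  expect_lt(max(abs(out$state - ref)) / max(ref), 0.005)
})

test_that("implicit stepping is stable for large time steps", {
  g <- default_grid
  m <- breath_maneuver(220, 220, 800, ambient_ppb = 130)
  for (dt in c(0.01, 0.1, 1)) {
    e <- run_maneuver(g, params_avg, m, dt = dt)
    expect_true(all(is.finite(e$co_ppb)))
    expect_true(all(e$co_ppb >= 0))
    expect_lt(max(e$co_ppb), 1e5)
  }
})

test_that("refining dt and dz changes the end-tidal value by < 1%", {
  et <- function(g, dt) end_tidal(run_maneuver(g, params_row_b,
                                               maneuver_row_b, dt = dt))
  g1 <- default_grid
  expect_lt(abs(et(g1, 0.005) - et(g1, 0.01)) / et(g1, 0.01), 0.005)
  g2 <- trumpet_grid(dz = 0.05)
  expect_lt(abs(et(g2, 0.01) - et(g1, 0.01)) / et(g1, 0.01), 0.01)
})

test_that("genuinely negative states are reported, tiny ones clipped", {
  g <- toy_grid
  p0 <- exchange_params(0, 0, 0, 0, D_gas = 0)
  # a forced negative through an impossible ambient
  expect_error(tmad_step(g, p0, rep(-1, 10), flow = 0, dt = 0.01,
                         mouth_dirichlet = FALSE),
               "negative concentration")
})
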