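## Shared fixtures: default grid (built once; construction is cheap but used
## everywhere), reference parameter sets, and a small hand-made grid plus an
## independent explicit integrator used as a solver oracle.

default_grid <- trumpet_grid()

params_row_b <- exchange_params(220, 1.6, 1.76e7, 7400)
params_avg <- exchange_params(220, 1.6, 1.82e7, 7767)

maneuver_row_b <- breath_maneuver(ifr = 121, efr = 121, v_in = 726,
                                  ambient_ppb = 130)

## A 10-node toy trumpet: mildly varying areas, alveolar storage on the last
## three nodes.  All fields the solver consumes, none derived from the
## production grid builder.
toy_grid <- local({
  n <- 10
  dz <- 0.5
  z <- seq(0, by = dz, length.out = n)
  A_aw <- seq(2, 20, length.out = n)
  w_alv <- c(rep(0, 7), 1, 2, 3)
  w_alv <- w_alv / sum(w_alv * dz)
  A_alv <- 50 * w_alv
  att <- 1 - w_alv / max(w_alv)
  w_aw <- att / sum(att * dz)
  g <- list(z = z, dz = dz, A_aw = A_aw, A_alv = A_alv,
            capacity = A_aw + A_alv, N_alv = w_alv * 1e6,
            N_max_eff = max(w_alv) * 1e6, w_aw = w_aw, w_alv = w_alv,
            A_face = 0.5 * (A_aw[-1] + A_aw[-n]),
            airway_volume_ml = sum(A_aw * dz),
            capacity_ml = sum((A_aw + A_alv) * dz),
            dead_space_ml = sum(A_aw[w_alv == 0] * dz),
            anatomy = anatomical_constants())
  class(g) <- "trumpet_grid"
  g
})

## Independent explicit (forward-Euler) integrator for the same mass
## balance, written directly from the continuous equation: used to verify
## the implicit solver, never sharing its code path.
explicit_reference <- function(grid, params, C, flow, dt, nsteps,
                               ambient = 0, dirichlet = flow > 0,
                               axial_diffusion = TRUE) {
  n <- length(C)
  dz <- grid$dz
  Dg <- if (axial_diffusion) params$D_gas else 0
  Af <- grid$A_face
  for (k in seq_len(nsteps)) {
    dC <- numeric(n)
    # diffusion: conservative flux differences, no flux at outer faces
    flux <- Dg * Af * diff(C) / dz           # n-1 face fluxes
    dC <- dC + c(flux, 0) - c(0, flux)       # per-node net inflow * dz
    # advection, upwind in flow direction (non-conservative V dC/dz * dz)
    if (flow > 0) dC[-1] <- dC[-1] - flow * diff(C)
    if (flow < 0) dC[-n] <- dC[-n] - flow * diff(C)
    # sources
    dC <- dC + dz * (grid$w_aw * (params$J_aw - params$D_aw * C) +
                       grid$w_alv * (params$J_A - params$D_A * C))
    C <- C + dt * dC / (grid$capacity * dz)
    if (dirichlet) C[1] <- ambient
  }
  C
}

## Equal-equilibrium parameter set: every reservoir (airway tissue,
## alveolar, ambient) sits at `level` ppb.
equilibrium_params <- function(level, D_aw = 1.6, D_A = 7400,
                               D_gas = 0.21) {
  exchange_params(J_aw = level * D_aw, D_aw = D_aw, J_A = level * D_A,
                  D_A = D_A, D_gas = D_gas)
}
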