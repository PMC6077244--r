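#' Describe a breathing maneuver
#'
#' A single breathing cycle: inhalation at `ifr` until `v_in` ml are
#' inspired, an optional breath-hold, and exhalation at `efr` until `v_ex`
#' ml are expired.  Ambient air at `ambient_ppb` is inhaled.  A measured
#' flow trace (data frame with `time_s` and `flow_ml_s`, positive during
#' inhalation, negative during exhalation, ~0 during holds) may be supplied
#' instead of constant flows and is interpolated onto solver time steps.
#'
#' @param ifr inhalation flow rate (ml/s).
#' @param efr exhalation flow rate (ml/s).
#' @param v_in inhaled volume (ml).
#' @param v_ex exhaled volume (ml), default `v_in`.
#' @param hold_s breath-hold duration (s), default 0.
#' @param ambient_ppb inhaled ambient concentration (ppb).
#' @param flow_trace optional measured flow trace (see above).
#' @return A list of class `"breath_maneuver"`.
#' @examples
#' breath_maneuver(ifr = 121, efr = 121, v_in = 726, ambient_ppb = 130)
#' @export
breath_maneuver <- function(ifr, efr, v_in, v_ex = v_in, hold_s = 0,
                            ambient_ppb = 0, flow_trace = NULL) {
  if (ifr <= 0 || efr <= 0) .tmad_stop("flow rates must be positive")
  if (v_in <= 0 || v_ex <= 0) .tmad_stop("volumes must be positive")
  if (hold_s < 0) .tmad_stop("breath-hold duration must be >= 0")
  if (ambient_ppb < 0) .tmad_stop("ambient concentration must be >= 0")
  if (!is.null(flow_trace)) {
    if (!all(c("time_s", "flow_ml_s") %in% names(flow_trace)))
      .tmad_stop("flow_trace needs columns time_s and flow_ml_s")
    if (any(diff(flow_trace$time_s) <= 0))
      .tmad_stop("flow_trace times must be strictly increasing")
  }
  m <- list(ifr = ifr, efr = efr, v_in = v_in, v_ex = v_ex, hold_s = hold_s,
            ambient = ambient_ppb, flow_trace = flow_trace)
  class(m) <- "breath_maneuver"
  m
}

#' @export
print.breath_maneuver <- function(x, ...) {
  cat(sprintf(
    "Breath maneuver: inhale %g ml at %g ml/s, hold %g s, exhale %g ml at %g ml/s; ambient %g ppb%s\n",
    x$v_in, x$ifr, x$hold_s, x$v_ex, x$efr, x$ambient,
    if (!is.null(x$flow_trace)) " (measured flow trace)" else ""))
  invisible(x)
}

## Per-step flow schedule: list(flow, dirichlet, ambient, exhale_idx, times)
.maneuver_schedule <- function(maneuver, dt) {
  if (!is.null(maneuver$flow_trace)) {
    tr <- maneuver$flow_trace
    times <- seq(0, max(tr$time_s), by = dt)[-1]
    flow <- approx(tr$time_s, tr$flow_ml_s, xout = times, rule = 2)$y
    dirichlet <- as.integer(flow > 0)
    exhale <- flow < 0
  } else {
    n_in <- round(maneuver$v_in / maneuver$ifr / dt)
    n_hold <- round(maneuver$hold_s / dt)
    n_ex <- round(maneuver$v_ex / maneuver$efr / dt)
    if (n_in < 1 || n_ex < 1)
      .tmad_stop("phase duration shorter than one time step")
    flow <- c(rep(maneuver$ifr, n_in), rep(0, n_hold),
              rep(-maneuver$efr, n_ex))
    dirichlet <- c(rep(1L, n_in), rep(0L, n_hold + n_ex))
    exhale <- c(rep(FALSE, n_in + n_hold), rep(TRUE, n_ex))
    times <- dt * seq_along(flow)
  }
  list(flow = flow, dirichlet = dirichlet,
       ambient = rep(maneuver$ambient, length(flow)),
       exhale = exhale, times = times)
}

.new_expirogram <- function(time_s, volume_ml, co_ppb, maneuver, params,
                            extra = list()) {
  x <- data.frame(time_s = time_s, volume_ml = volume_ml, co_ppb = co_ppb)
  attr(x, "maneuver") <- maneuver
  attr(x, "params") <- params
  for (nm in names(extra)) attr(x, nm) <- extra[[nm]]
  class(x) <- c("expirogram", "data.frame")
  x
}

#' Simulate a full breathing maneuver
#'
#' Drives the implicit solver through inhalation (mouth pinned to ambient),
#' optional breath-hold and exhalation (zero-gradient mouth), starting from
#' a gas-free respiratory tract (or the steady cycling state), and records
#' the mouth concentration at every exhalation time step together with
#' optional axial snapshots.
#'
#' @param grid [trumpet_grid()].
#' @param params [exchange_params()].
#' @param maneuver [breath_maneuver()].
#' @param dt time step (s), default 0.01.
#' @param snapshot_times times (s from simulation start) at which to record
#'   the full axial concentration field.
#' @param axial_diffusion include gas-phase axial diffusion (default TRUE).
#' @param initial `"zero"` (default) starts from zero concentration;
#'   `"steady"` repeats the cycle until the end-tidal value changes by less
#'   than 0.5% between cycles (at most `max_cycles`); or a numeric vector
#'   giving the initial state.
#' @param max_cycles cycle cap for `initial = "steady"`.
#' @return An object of class `"expirogram"`: data frame with `time_s`
#'   (from exhalation start), `volume_ml` (exhaled volume) and `co_ppb`
#'   (mouth concentration), with the maneuver, parameters, snapshots and
#'   final state attached as attributes.
#' @examples
#' g <- trumpet_grid()
#' p <- exchange_params(220, 1.6, 1.76e7, 7400)
#' m <- breath_maneuver(121, 121, 726, ambient_ppb = 130)
#' e <- run_maneuver(g, p, m)
#' end_tidal(e)
#' @export
run_maneuver <- function(grid, params, maneuver, dt = 0.01,
                         snapshot_times = NULL, axial_diffusion = TRUE,
                         initial = "zero", max_cycles = 20) {
  stopifnot(inherits(grid, "trumpet_grid"),
            inherits(params, "exchange_params"),
            inherits(maneuver, "breath_maneuver"))
  sch <- .maneuver_schedule(maneuver, dt)
  n <- length(grid$z)
  state <- if (is.numeric(initial)) {
    if (length(initial) != n) .tmad_stop("initial state has wrong length")
    initial
  } else rep(0, n)
  if (identical(initial, "steady")) {
    et_prev <- NULL
    for (cyc in seq_len(max_cycles)) {
      out <- .tmad_run(grid, params, state, sch$flow, sch$dirichlet,
                       sch$ambient, dt, axial_diffusion)
      state <- out$state
      co <- out$mouth[sch$exhale]
      et <- mean(co[seq(max(1, floor(0.95 * length(co))), length(co))])
      if (!is.null(et_prev) && abs(et - et_prev) <= 0.005 * max(et, 1e-12))
        break
      et_prev <- et
    }
    state_start <- state # converged pre-breath state feeds the final run
  } else {
    state_start <- state
  }
  snap_at <- integer(0)
  if (!is.null(snapshot_times)) {
    snap_at <- sort(unique(pmin(pmax(round(snapshot_times / dt), 1),
                                length(sch$flow))))
  }
  out <- .tmad_run(grid, params, state_start, sch$flow, sch$dirichlet,
                   sch$ambient, dt, axial_diffusion, snap_at = snap_at)
  ex <- which(sch$exhale)
  t_ex <- dt * seq_along(ex) # schedule is uniform in dt; avoids fp drift
  vol <- cumsum(-sch$flow[ex] * dt)
  snaps <- NULL
  if (length(snap_at)) {
    phase <- ifelse(sch$flow[snap_at] > 0, "inhale",
                    ifelse(sch$flow[snap_at] < 0, "exhale", "hold"))
    snaps <- list(time_s = snap_at * dt, phase = phase,
                  z_cm = grid$z, C = out$snapshots)
  }
  .new_expirogram(t_ex, vol, out$mouth[ex], maneuver, params,
                  extra = list(snapshots = snaps, final_state = out$state,
                               dt = dt, n_clipped = out$n_clipped,
                               axial_diffusion = axial_diffusion))
}

#' Simulate a maneuver without axial diffusion
#'
#' Identical to [run_maneuver()] with the gas-phase axial-diffusion term
#' switched off; used to assess the role of axial diffusion in shaping the
#' expirogram.
#'
#' @inheritParams run_maneuver
#' @return An `"expirogram"` object.
#' @export
run_no_axial_diffusion <- function(grid, params, maneuver, dt = 0.01,
                                   snapshot_times = NULL, initial = "zero",
                                   max_cycles = 20) {
  run_maneuver(grid, params, maneuver, dt = dt,
               snapshot_times = snapshot_times, axial_diffusion = FALSE,
               initial = initial, max_cycles = max_cycles)
}

#' @export
print.expirogram <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Expirogram (%s): %d samples, %.2f s, %.0f ml exhaled\n",
              if (!is.null(p)) p$species else "?", nrow(x),
              max(x$time_s), max(x$volume_ml)))
  cat(sprintf("  end-tidal %.4g ppb (final 5%% of volume)\n", end_tidal(x)))
  invisible(x)
}

#' @describeIn run_maneuver plot method: concentration against exhaled
#'   volume.
#' @param x,y,... plot arguments.
#' @export
plot.expirogram <- function(x, y = NULL,
                            xlab = "exhaled volume (ml)",
                            ylab = "concentration (ppb)", type = "l", ...) {
  plot(x$volume_ml, x$co_ppb, xlab = xlab, ylab = ylab, type = type, ...)
  invisible(x)
}

#' Summarize an expirogram
#'
#' Computes the derived quantities of a single-exhalation profile:
#' end-tidal concentration, elimination rate, exhalation-phase boundaries
#' and phase III slope, plus the equilibrium (alveolar and airway tissue)
#' concentrations implied by the exchange parameters used.
#'
#' @param object an `"expirogram"`.
#' @param grid [trumpet_grid()] used for the dead-space volume; defaults to
#'   the default grid.
#' @param window end-tidal window as a fraction of exhaled volume.
#' @param ... unused.
#' @return A list of class `"expirogram_summary"`.
#' @export
summary.expirogram <- function(object, grid = NULL, window = 0.05, ...) {
  p <- attr(object, "params")
  m <- attr(object, "maneuver")
  if (is.null(grid)) grid <- trumpet_grid()
  ph <- segment_phases(object, grid)
  et <- end_tidal(object, window)
  out <- list(end_tidal = et,
              elimination_rate = if (!is.null(m))
                elimination_rate(et, m$efr) else NA_real_,
              phases = ph,
              C_A = if (!is.null(p) && p$D_A > 0) p$J_A / p$D_A else NA_real_,
              C_tiss = if (!is.null(p) && p$D_aw > 0)
                p$J_aw / p$D_aw else NA_real_,
              window = window)
  class(out) <- "expirogram_summary"
  out
}

#' @export
print.expirogram_summary <- function(x, ...) {
  cat(sprintf("End-tidal: %.4g ppb (final %.0f%% of volume); elimination rate %.4g pl/s\n",
              x$end_tidal, 100 * x$window, x$elimination_rate))
  cat(sprintf("Phases: I up to %.0f ml, II up to %.0f ml, III slope %.3g ppb/ml\n",
              x$phases$phase1_end_ml, x$phases$phase2_end_ml,
              x$phases$phase3_slope))
  if (is.finite(x$C_A))
    cat(sprintf("Equilibria: alveolar %.4g ppb, airway tissue %.4g ppb\n",
                x$C_A, x$C_tiss))
  invisible(x)
}
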