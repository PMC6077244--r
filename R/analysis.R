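#' End-tidal concentration
#'
#' Mean mouth concentration over the final fraction (`window`, default 5%)
#' of the exhaled volume.  With `window = 0` the single final sample is
#' returned (the mouth concentration at the end of exhalation).
#'
#' @param x an `"expirogram"` (or data frame with `volume_ml`, `co_ppb`).
#' @param window fraction of exhaled volume to average over.
#' @return End-tidal concentration (ppb).
#' @examples
#' e <- data.frame(time_s = 1:4, volume_ml = 1:4 * 100,
#'                 co_ppb = c(0, 1000, 2000, 2000))
#' end_tidal(e, window = 0.25)
#' @export
end_tidal <- function(x, window = 0.05) {
  if (is.null(x) || nrow(x) == 0) .tmad_stop("empty expirogram")
  if (window <= 0) return(x$co_ppb[nrow(x)])
  vmax <- max(x$volume_ml)
  mean(x$co_ppb[x$volume_ml >= (1 - window) * vmax])
}

#' Elimination rate
#'
#' The net output of the gas: end-tidal concentration times exhalation flow
#' rate.  With concentrations in ppb and flows in ml/s the product is
#' numerically the elimination rate in pl/s (1 ppb ml/s = 1 pl/s).
#'
#' @param end_tidal end-tidal concentration (ppb).
#' @param efr exhalation flow rate (ml/s).
#' @return Elimination rate (pl/s).
#' @examples
#' elimination_rate(2000, 100) # 2e5 pl/s
#' @export
elimination_rate <- function(end_tidal, efr) {
  if (any(end_tidal < 0) || any(efr < 0))
    .tmad_stop("end_tidal and efr must be >= 0")
  end_tidal * efr
}

#' Segment the three exhalation phases
#'
#' Phase I is the dead-space gas: exhaled volume up to the
#' conducting-airway volume of the grid.  Phase II is the airway-alveolar
#' transition, ending where the profile first reaches 95% of its
#' plateau-trend value (a least-squares line over the final third of
#' exhaled volume, which also provides the phase III slope).  The remainder
#' is the alveolar plateau, phase III.
#'
#' @param x an `"expirogram"`.
#' @param grid [trumpet_grid()] providing the dead-space volume.
#' @param plateau_fraction threshold on the plateau trend (default 0.95).
#' @return List with `phase1_end_ml`, `phase2_end_ml`, `phase3_slope`
#'   (ppb/ml) and `phase3_level` (mean phase III concentration).  If the
#'   exhaled volume does not exceed the dead space, phases II/III are `NA`
#'   and `incomplete` is `TRUE`.
#' @export
segment_phases <- function(x, grid = trumpet_grid(),
                           plateau_fraction = 0.95) {
  if (is.null(x) || nrow(x) == 0) .tmad_stop("empty expirogram")
  ds <- grid$dead_space_ml
  vmax <- max(x$volume_ml)
  if (vmax <= ds)
    return(list(phase1_end_ml = vmax, phase2_end_ml = NA_real_,
                phase3_slope = NA_real_, phase3_level = NA_real_,
                incomplete = TRUE))
  last3 <- x$volume_ml >= (2 / 3) * vmax
  fit <- lm(co_ppb ~ volume_ml, data = x[last3, , drop = FALSE])
  trend <- predict(fit, newdata = x)
  beyond <- x$volume_ml > ds & x$co_ppb >= plateau_fraction * trend
  p2 <- if (any(beyond)) x$volume_ml[which(beyond)[1]] else vmax
  list(phase1_end_ml = ds, phase2_end_ml = max(p2, ds),
       phase3_slope = unname(coef(fit)[2]),
       phase3_level = mean(x$co_ppb[last3]), incomplete = FALSE)
}

#' Sweep the exhalation flow rate
#'
#' Runs one maneuver per exhalation flow rate at fixed inhalation flow and
#' volume and collects end-tidal concentration and elimination rate.  The
#' defaults mirror the flow-dependence study: inhalation at 127 ml/s,
#' inhaled/exhaled volume 800 ml (the volume range of the subject whose
#' measurements the sweep is compared against) and ambient CO 125 ppb.
#'
#' @param grid [trumpet_grid()].
#' @param params [exchange_params()].
#' @param efr_values exhalation flow rates (ml/s) to sweep.
#' @param ifr inhalation flow rate (ml/s).
#' @param volume inhaled/exhaled volume (ml).
#' @param ambient_ppb inhaled concentration (ppb).
#' @param hold_s breath-hold (s), default 0.
#' @param dt solver time step (s).
#' @param window end-tidal window (fraction of exhaled volume).
#' @return A data frame of class `"tmad_sweep"` with columns `efr_ml_s`,
#'   `end_tidal_ppb`, `elimination_pl_s`; the alveolar equilibrium
#'   `J_A/D_A` is attached as attribute `"C_A"`.
#' @examples
#' \donttest{
#' g <- trumpet_grid()
#' p <- exchange_params(220, 1.6, 1.82e7, 7767)
#' sw <- flow_sweep(g, p, efr_values = c(50, 121, 204))
#' }
#' @export
flow_sweep <- function(grid, params, efr_values = seq(20, 250, length.out = 20),
                       ifr = 127, volume = 800, ambient_ppb = 125,
                       hold_s = 0, dt = 0.01, window = 0.05) {
  if (any(efr_values <= 0)) .tmad_stop("EFR values must be positive")
  et <- vapply(efr_values, function(efr) {
    m <- breath_maneuver(ifr, efr, volume, hold_s = hold_s,
                         ambient_ppb = ambient_ppb)
    end_tidal(run_maneuver(grid, params, m, dt = dt), window)
  }, numeric(1))
  out <- data.frame(efr_ml_s = efr_values, end_tidal_ppb = et,
                    elimination_pl_s = elimination_rate(et, efr_values))
  attr(out, "C_A") <- equilibrium_concentration(params$J_A, params$D_A)
  class(out) <- c("tmad_sweep", "data.frame")
  out
}

#' @export
plot.tmad_sweep <- function(x, y = NULL, ...) {
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  plot(x$efr_ml_s, x$end_tidal_ppb, type = "b", xlab = "EFR (ml/s)",
       ylab = "end-tidal (ppb)", ...)
  abline(h = attr(x, "C_A"), lty = 2)
  plot(x$efr_ml_s, x$elimination_pl_s, type = "b", xlab = "EFR (ml/s)",
       ylab = "elimination rate (pl/s)", ...)
  invisible(x)
}

#' Parametric sensitivity of the expirogram shape
#'
#' Re-simulates a maneuver under separate (or combined) perturbations of
#' the four exchange parameters and reports, for each, the change in
#' end-tidal concentration, phase III slope and the mean of the first
#' 0.2 s of exhalation (the airway-sensitive window) relative to the
#' unperturbed profile.
#'
#' @param grid [trumpet_grid()].
#' @param params base [exchange_params()].
#' @param perturbations named list; each element is a named numeric vector
#'   of multipliers applied to a subset of `J_aw`, `D_aw`, `J_A`, `D_A`,
#'   e.g. `list(high_JA = c(J_A = 1.5))`.
#' @param maneuver [breath_maneuver()].
#' @param dt solver time step (s).
#' @param early_s width of the early-exhalation window (s).
#' @return List of class `"tmad_sensitivity"` with the base expirogram,
#'   one expirogram per perturbation, and a `contrasts` data frame.
#' @export
sensitivity_study <- function(grid, params, perturbations, maneuver,
                              dt = 0.01, early_s = 0.2) {
  stopifnot(is.list(perturbations))
  base <- run_maneuver(grid, params, maneuver, dt = dt)
  sb <- segment_phases(base, grid)
  early <- function(e) mean(e$co_ppb[e$time_s <= early_s])
  runs <- list(); contrasts <- NULL
  for (nm in names(perturbations)) {
    mult <- perturbations[[nm]]
    bad <- setdiff(names(mult), c("J_aw", "D_aw", "J_A", "D_A"))
    if (length(bad))
      .tmad_stop("unknown parameters in perturbation '", nm, "': ",
                 paste(bad, collapse = ", "))
    p <- params
    for (f in names(mult)) p[[f]] <- p[[f]] * mult[[f]]
    p <- exchange_params(p$J_aw, p$D_aw, p$J_A, p$D_A, p$D_gas, p$species)
    e <- run_maneuver(grid, p, maneuver, dt = dt)
    s <- segment_phases(e, grid)
    runs[[nm]] <- e
    contrasts <- rbind(contrasts, data.frame(
      perturbation = nm,
      d_end_tidal_ppb = end_tidal(e) - end_tidal(base),
      d_phase3_slope = s$phase3_slope - sb$phase3_slope,
      d_early_ppb = early(e) - early(base)))
  }
  out <- list(base = base, runs = runs, contrasts = contrasts)
  class(out) <- "tmad_sensitivity"
  out
}

#' @export
print.tmad_sensitivity <- function(x, ...) {
  cat("Expirogram sensitivity study (", length(x$runs), "perturbations )\n")
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}
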