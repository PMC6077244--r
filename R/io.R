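#' Read an expirogram from delimited text
#'
#' Comma-separated file with header columns `time_s`, `co_ppb`,
#' `flow_ml_s` (exhalation flow, ml/s) and optionally `co2_pct`.
#' Times must be strictly increasing; malformed rows are reported with
#' their line numbers.
#'
#' @param path file path.
#' @return An `"expirogram"` data frame (exhaled volume integrated from the
#'   flow column; `co2_pct` carried through if present).
#' @export
read_expirogram <- function(path) {
  tab <- read.csv(path)
  need <- c("time_s", "co_ppb", "flow_ml_s")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    .tmad_stop("missing columns in ", path, ": ", paste(miss, collapse = ", "))
  num_bad <- which(!stats::complete.cases(tab[need]) |
                     Reduce(`|`, lapply(tab[need], function(x) !is.finite(x))))
  if (length(num_bad))
    .tmad_stop("malformed rows (file line ",
               paste(num_bad + 1, collapse = ", "), ") in ", path)
  bad <- which(diff(tab$time_s) <= 0)
  if (length(bad))
    .tmad_stop("time not strictly increasing at file line ", bad[1] + 2,
               " of ", path)
  if (any(tab$co_ppb < 0))
    .tmad_stop("negative concentrations in ", path)
  dtv <- diff(c(0, tab$time_s))
  vol <- cumsum(abs(tab$flow_ml_s) * dtv)
  e <- .new_expirogram(tab$time_s, vol, tab$co_ppb, maneuver = NULL,
                       params = NULL)
  e$flow_ml_s <- tab$flow_ml_s
  if ("co2_pct" %in% names(tab)) e$co2_pct <- tab$co2_pct
  e
}

#' Write an expirogram to delimited text
#'
#' Writes `time_s`, `co_ppb`, `flow_ml_s` (and `co2_pct` if present) as a
#' comma-separated file with full double precision, so that a
#' write-then-read round trip is lossless.
#'
#' @param x an `"expirogram"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expirogram <- function(x, path) {
  m <- attr(x, "maneuver")
  flow <- if ("flow_ml_s" %in% names(x)) x$flow_ml_s
          else if (!is.null(m)) rep(-m$efr, nrow(x))
          else c(-diff(c(0, x$volume_ml)) / diff(c(0, x$time_s)))
  out <- data.frame(time_s = format(x$time_s, digits = 15, trim = TRUE),
                    co_ppb = format(x$co_ppb, digits = 15, trim = TRUE),
                    flow_ml_s = format(flow, digits = 15, trim = TRUE))
  if ("co2_pct" %in% names(x))
    out$co2_pct <- format(x$co2_pct, digits = 15, trim = TRUE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Describe the breath-gas sensor
#'
#' Measurement model of the real-time analyzer used to turn clean
#' simulations into realistic synthetic data: regular sampling every
#' `interval_s` seconds, additive Gaussian noise (`noise_sd_ppb`, the
#' instrument precision), optional flow jitter and start/end flow ramps.
#'
#' @param interval_s acquisition interval (s), default 0.14.
#' @param noise_sd_ppb concentration noise SD (ppb), default 2.
#' @param flow_jitter_sd_ml_s SD of flow fluctuations (ml/s), default 0.
#' @param ramp_s duration of the start/end exhalation-flow transients (s),
#'   default 0.
#' @return A list of class `"sensor_model"`.
#' @export
sensor_model <- function(interval_s = 0.14, noise_sd_ppb = 2,
                         flow_jitter_sd_ml_s = 0, ramp_s = 0) {
  s <- list(interval = interval_s, noise_sd = noise_sd_ppb,
            flow_jitter_sd = flow_jitter_sd_ml_s, ramp = ramp_s)
  if (any(unlist(s) < 0)) .tmad_stop("sensor parameters must be >= 0")
  if (s$interval <= 0) .tmad_stop("sampling interval must be > 0")
  class(s) <- "sensor_model"
  s
}

#' Generate a synthetic measured expirogram
#'
#' Simulates the maneuver with [run_maneuver()], resamples the exhalation
#' to the sensor's acquisition interval, and adds seeded Gaussian
#' concentration noise (plus optional flow jitter and start/end flow
#' ramps).  Deterministic for a given seed; the global RNG state is left
#' untouched.
#'
#' @param params [exchange_params()].
#' @param maneuver [breath_maneuver()].
#' @param grid [trumpet_grid()].
#' @param sensor [sensor_model()].
#' @param seed integer seed.
#' @param dt solver time step (s).
#' @return An `"expirogram"` with a `flow_ml_s` column; the noise-free
#'   resampled profile is attached as attribute `"clean_ppb"`.
#' @export
synthetic_expirogram <- function(params, maneuver, grid,
                                 sensor = sensor_model(), seed = 1,
                                 dt = 0.01) {
  e <- run_maneuver(grid, params, maneuver, dt = dt)
  times <- seq(sensor$interval, max(e$time_s), by = sensor$interval)
  if (!length(times)) times <- max(e$time_s)
  clean <- approx(e$time_s, e$co_ppb, xout = times, rule = 2)$y
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  set.seed(seed)
  co <- pmax(clean + rnorm(length(times), 0, sensor$noise_sd), 0)
  flow <- rep(maneuver$efr, length(times))
  if (sensor$ramp > 0) {
    ramp_up <- pmin(times / sensor$ramp, 1)
    ramp_dn <- pmin((max(times) - times) / sensor$ramp, 1)
    flow <- flow * pmin(ramp_up, ramp_dn)
  }
  if (sensor$flow_jitter_sd > 0)
    flow <- pmax(flow + rnorm(length(times), 0, sensor$flow_jitter_sd), 0)
  vol <- approx(e$time_s, e$volume_ml, xout = times, rule = 2)$y
  out <- .new_expirogram(times, vol, co, maneuver, params,
                         extra = list(clean_ppb = clean, sensor = sensor,
                                      seed = seed))
  out$flow_ml_s <- -flow
  out
}

## ---- configuration -------------------------------------------------------

.config_keys <- list(
  top = c("species", "anatomy", "tissue_blood", "exchange", "maneuver",
          "numerics", "sensor", "seed"),
  anatomy = c("L_cm", "z1_cm", "A_c1_cm2", "m", "A_cA_cm2", "N_t", "N_max",
              "V_total_ml"),
  tissue_blood = c("A_M_aw_cm2", "dx_aw_um", "A_M_A_cm2", "dx_A_um",
                   "K_CO_cm2_min_atm", "COHb_pct", "mcapO2Hb_pct",
                   "mcapPO2_mmHg", "M", "airway_blood_fraction"),
  exchange = c("J_aw_pl_s", "D_aw_pl_s_ppb", "J_A_pl_s", "D_A_pl_s_ppb",
               "D_gas_cm2_s"),
  maneuver = c("ifr_ml_s", "efr_ml_s", "v_in_ml", "v_ex_ml", "hold_s",
               "ambient_ppb"),
  numerics = c("dz_cm", "dt_s", "axial_diffusion"),
  sensor = c("interval_s", "noise_sd_ppb", "flow_jitter_sd_ml_s", "ramp_s"))

.check_keys <- function(x, section) {
  extra <- setdiff(names(x), .config_keys[[section]])
  if (length(extra))
    .tmad_stop("unknown key(s) in config section '", section, "': ",
               paste(extra, collapse = ", "))
}

#' Read and validate a run configuration
#'
#' JSON configuration with sections `anatomy`, `tissue_blood` (or a direct
#' `exchange` parameter block), `maneuver`, `numerics`, `sensor`, plus
#' `species` ("co"/"no") and `seed`.  All keys are validated before any
#' simulation; unknown keys are rejected.  See
#' `system.file("extdata", "config_example.json", package = "tmad")`.
#'
#' @param path JSON file.
#' @return A list with constructed objects: `anatomy`, `grid_args`,
#'   `params`, `maneuver`, `numerics`, `sensor`, `species`, `seed`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  .check_keys(cfg, "top")
  species <- toupper(cfg$species %||% "CO")
  anat_args <- cfg$anatomy %||% list()
  .check_keys(anat_args, "anatomy")
  anatomy <- do.call(anatomical_constants, as.list(anat_args))
  numer <- cfg$numerics %||% list()
  .check_keys(numer, "numerics")
  numerics <- list(dz = numer$dz_cm %||% 0.1, dt = numer$dt_s %||% 0.01,
                   axial_diffusion = numer$axial_diffusion %||% TRUE)
  if (!is.null(cfg$exchange)) {
    ex <- cfg$exchange
    .check_keys(ex, "exchange")
    params <- exchange_params(ex$J_aw_pl_s, ex$D_aw_pl_s_ppb, ex$J_A_pl_s,
                              ex$D_A_pl_s_ppb,
                              ex$D_gas_cm2_s %||%
                                if (species == "NO") 0.23 else 0.21,
                              species = species)
  } else {
    tb <- cfg$tissue_blood %||% list()
    .check_keys(tb, "tissue_blood")
    tbp <- do.call(tissue_blood_params, tb)
    params <- if (species == "NO") no_exchange_params()
              else estimate_exchange(tbp)
  }
  man <- NULL
  if (!is.null(cfg$maneuver)) {
    mv <- cfg$maneuver
    .check_keys(mv, "maneuver")
    man <- breath_maneuver(ifr = mv$ifr_ml_s, efr = mv$efr_ml_s,
                           v_in = mv$v_in_ml,
                           v_ex = mv$v_ex_ml %||% mv$v_in_ml,
                           hold_s = mv$hold_s %||% 0,
                           ambient_ppb = mv$ambient_ppb %||% 0)
  }
  sn <- cfg$sensor %||% list()
  .check_keys(sn, "sensor")
  sensor <- sensor_model(interval_s = sn$interval_s %||% 0.14,
                         noise_sd_ppb = sn$noise_sd_ppb %||% 2,
                         flow_jitter_sd_ml_s = sn$flow_jitter_sd_ml_s %||% 0,
                         ramp_s = sn$ramp_s %||% 0)
  list(species = species, anatomy = anatomy, params = params,
       maneuver = man, numerics = numerics, sensor = sensor,
       seed = cfg$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## anatomical_constants takes *_cm style names already; map config keys
## (identical names) straight through.
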