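## Simulated mouth concentration at the sample times of a measured
## expirogram (linear interpolation from the solver's exhalation series).
.sim_at <- function(params, maneuver, grid, dt, times) {
  e <- run_maneuver(grid, params, maneuver, dt = dt)
  approx(e$time_s, e$co_ppb, xout = times, rule = 2)$y
}

.default_bounds <- function(init) {
  list(J_aw = c(0, 5000), D_aw = c(0.1, 20),
       J_A = c(0.5, 1.5) * init$J_A, D_A = c(0.5, 1.5) * init$D_A)
}

.replace_params <- function(params, values) {
  p <- params
  for (nm in names(values)) p[[nm]] <- unname(values[[nm]])
  exchange_params(p$J_aw, p$D_aw, p$J_A, p$D_A, p$D_gas, p$species)
}

.rms <- function(x) sqrt(mean(x^2))

#' Fit the airway parameters to the start of a breath-hold exhalation
#'
#' During a breath-hold the gas residing in the conducting airways
#' equilibrates toward the airway tissue level `J_aw/D_aw`, so the first
#' fraction of a second of the subsequent exhalation is the
#' airway-sensitive window.  This stage minimizes the RMS mismatch between
#' simulated and measured mouth concentration over that window, varying
#' `J_aw` (and optionally `D_aw`).  Without a breath-hold the sensitivity
#' to the airway parameters is too low and the procedure refuses to run.
#'
#' @param expirogram measured (or synthetic) `"expirogram"`-like data frame
#'   with `time_s` (from exhalation start) and `co_ppb`.
#' @param maneuver the [breath_maneuver()] that produced it (must include a
#'   breath-hold).
#' @param grid [trumpet_grid()].
#' @param init starting [exchange_params()].
#' @param window_s fit window from exhalation start (s), default 0.2.
#' @param fit_D_aw also vary the airway diffusing capacity? Default FALSE
#'   (held at its initial value).
#' @param dt solver time step (s).
#' @param bounds list of per-parameter `c(lo, hi)` bounds.
#' @return List with updated `params`, `rms` (ppb) over the window, and
#'   `n_window` (samples used).
#' @export
fit_airway <- function(expirogram, maneuver, grid, init, window_s = 0.2,
                       fit_D_aw = FALSE, dt = 0.01,
                       bounds = .default_bounds(init)) {
  if (maneuver$hold_s <= 0)
    .tmad_stop("airway fitting requires a breath-hold maneuver ",
               "(sensitivity to the airway parameters is too low otherwise)")
  idx <- which(expirogram$time_s <= window_s)
  if (!length(idx))
    .tmad_stop("fit window of ", window_s, " s contains no samples")
  times <- expirogram$time_s[idx]
  meas <- expirogram$co_ppb[idx]
  obj1 <- function(J_aw)
    .rms(.sim_at(.replace_params(init, c(J_aw = J_aw)), maneuver, grid, dt,
                 times) - meas)
  if (!fit_D_aw) {
    opt <- optimize(obj1, interval = bounds$J_aw, tol = 0.5)
    params <- .replace_params(init, c(J_aw = opt$minimum))
    return(list(params = params, rms = opt$objective, n_window = length(idx)))
  }
  obj2 <- function(th) {
    if (th[1] < bounds$J_aw[1] || th[1] > bounds$J_aw[2] ||
        th[2] < bounds$D_aw[1] || th[2] > bounds$D_aw[2])
      return(1e9 + sum(abs(th)))
    .rms(.sim_at(.replace_params(init, c(J_aw = th[1], D_aw = th[2])),
                 maneuver, grid, dt, times) - meas)
  }
  opt <- optim(c(init$J_aw, init$D_aw), obj2, method = "Nelder-Mead",
               control = list(reltol = 1e-6, maxit = 200))
  params <- .replace_params(init, c(J_aw = opt$par[1], D_aw = opt$par[2]))
  list(params = params, rms = opt$value, n_window = length(idx))
}

#' Refine the alveolar parameters against exhalation phase III
#'
#' Minimizes the RMS mismatch over phase III of the expirogram (level and
#' slope of the alveolar plateau), varying the alveolar maximum flux and
#' diffusing capacity within bounds around the initial estimates.  Uses a
#' derivative-free bounded Nelder-Mead search.
#'
#' @inheritParams fit_airway
#' @param expirograms one expirogram or a list of them.
#' @param maneuvers matching [breath_maneuver()] (or list).
#' @return List with updated `params`, `rms` (ppb) over the pooled phase
#'   III samples, optimizer `iterations` and `convergence` code.
#' @export
fit_alveolar <- function(expirograms, maneuvers, grid, init, dt = 0.01,
                         bounds = .default_bounds(init)) {
  if (inherits(expirograms, "data.frame")) expirograms <- list(expirograms)
  if (inherits(maneuvers, "breath_maneuver")) maneuvers <- list(maneuvers)
  stopifnot(length(expirograms) == length(maneuvers))
  masks <- lapply(expirograms, function(e) {
    ph <- segment_phases(e, grid)
    if (isTRUE(ph$incomplete) || !is.finite(ph$phase2_end_ml))
      .tmad_stop("expirogram has no phase III (exhaled volume below dead space)")
    which(e$volume_ml >= ph$phase2_end_ml)
  })
  if (any(vapply(masks, length, integer(1)) == 0))
    .tmad_stop("expirogram has an empty phase III window")
  obj <- function(th) {
    if (th[1] < bounds$J_A[1] || th[1] > bounds$J_A[2] ||
        th[2] < bounds$D_A[1] || th[2] > bounds$D_A[2])
      return(1e9 + sum(abs(th)))
    p <- .replace_params(init, c(J_A = th[1], D_A = th[2]))
    res <- unlist(lapply(seq_along(expirograms), function(i) {
      .sim_at(p, maneuvers[[i]], grid, dt,
              expirograms[[i]]$time_s[masks[[i]]]) -
        expirograms[[i]]$co_ppb[masks[[i]]]
    }))
    .rms(res)
  }
  sc <- c(init$J_A, init$D_A)
  opt <- optim(sc, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-8, maxit = 400,
                              parscale = pmax(sc, 1)))
  list(params = .replace_params(init, c(J_A = opt$par[1], D_A = opt$par[2])),
       rms = opt$value, iterations = opt$counts[["function"]],
       convergence = opt$convergence)
}

#' Joint bounded least-squares refinement of exchange parameters
#'
#' General machinery: minimizes the pooled RMS between simulated and
#' measured expirograms over any subset of the four exchange parameters,
#' across one or several maneuvers, with a derivative-free bounded
#' Nelder-Mead search (optionally multi-start, seeded).
#'
#' @inheritParams fit_alveolar
#' @param free character vector of parameters to vary, a subset of
#'   `c("J_aw", "D_aw", "J_A", "D_A")`; empty returns the input unchanged.
#' @param n_starts number of optimizer starts (>1 jitters the start point
#'   within bounds, deterministically per `seed`).
#' @param seed seed for the multi-start jitter.
#' @param windows optional list of index vectors restricting the samples
#'   used per expirogram (default: all samples).
#' @return A list of class `"tmad_refine"`: `params`, `rms`, `iterations`,
#'   `convergence`, `free`, and `diagnostics` (identifiability notes and
#'   the condition number of the residual Jacobian at the solution).
#' @export
least_squares_refine <- function(expirograms, maneuvers, grid, init,
                                 free = c("J_A", "D_A"), dt = 0.01,
                                 bounds = .default_bounds(init),
                                 n_starts = 1, seed = 1, windows = NULL) {
  if (inherits(expirograms, "data.frame")) expirograms <- list(expirograms)
  if (inherits(maneuvers, "breath_maneuver")) maneuvers <- list(maneuvers)
  stopifnot(length(expirograms) == length(maneuvers))
  all_par <- c("J_aw", "D_aw", "J_A", "D_A")
  bad <- setdiff(free, all_par)
  if (length(bad)) .tmad_stop("unknown parameters: ", paste(bad, collapse = ", "))
  diagnostics <- character(0)
  if (length(free) == 0)
    return(structure(list(params = init, rms = NA_real_, iterations = 0L,
                          convergence = 0L, free = free,
                          diagnostics = diagnostics),
                     class = "tmad_refine"))
  if (is.null(windows))
    windows <- lapply(expirograms, function(e) seq_len(nrow(e)))
  holds <- vapply(maneuvers, function(m) m$hold_s, numeric(1))
  if (any(c("J_aw", "D_aw") %in% free) && all(holds == 0))
    diagnostics <- c(diagnostics,
                     paste("airway parameters are weakly identifiable",
                           "without a breath-hold maneuver"))
  resid_fun <- function(vals) {
    p <- .replace_params(init, vals)
    unlist(lapply(seq_along(expirograms), function(i) {
      w <- windows[[i]]
      .sim_at(p, maneuvers[[i]], grid, dt, expirograms[[i]]$time_s[w]) -
        expirograms[[i]]$co_ppb[w]
    }))
  }
  obj <- function(th) {
    names(th) <- free
    for (nm in free)
      if (th[nm] < bounds[[nm]][1] || th[nm] > bounds[[nm]][2])
        return(1e9 + sum(abs(th)))
    .rms(resid_fun(th))
  }
  start0 <- vapply(free, function(nm) init[[nm]], numeric(1))
  starts <- list(start0)
  if (n_starts > 1) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    for (k in seq_len(n_starts - 1))
      starts[[k + 1]] <- vapply(free, function(nm)
        runif(1, max(bounds[[nm]][1], 0.6 * init[[nm]]),
              min(bounds[[nm]][2], 1.4 * init[[nm]] + 1e-12)), numeric(1))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  best <- NULL
  iter <- 0L
  for (st in starts) {
    opt <- if (length(free) == 1) {
      o <- optimize(function(v) obj(setNames(v, free)),
                    interval = bounds[[free]], tol = 1e-4 *
                      max(abs(start0), 1))
      list(par = o$minimum, value = o$objective, counts = c(`function` = NA),
           convergence = 0L)
    } else {
      optim(st, obj, method = "Nelder-Mead",
            control = list(reltol = 1e-8, maxit = 500,
                           parscale = pmax(abs(start0), 1)))
    }
    iter <- iter + ifelse(is.na(opt$counts[["function"]]), 0L,
                          opt$counts[["function"]])
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  sol <- setNames(as.numeric(best$par), free)
  # identifiability: condition number of the residual Jacobian at the fit
  J <- vapply(free, function(nm) {
    h <- max(abs(sol[nm]), 1) * 1e-2
    v1 <- sol; v1[nm] <- sol[nm] + h
    (resid_fun(v1) - resid_fun(sol)) / h
  }, numeric(sum(vapply(windows, length, integer(1)))))
  J <- matrix(J, ncol = length(free))
  sv <- svd(sweep(J, 2, pmax(abs(sol), 1), "*"))$d
  condn <- if (min(sv) > 0) max(sv) / min(sv) else Inf
  if (condn > 1e4)
    diagnostics <- c(diagnostics, sprintf(
      "ill-conditioned fit (Jacobian condition number %.3g); parameter combination under-determined by the data",
      condn))
  structure(list(params = .replace_params(init, sol), rms = best$value,
                 iterations = iter, convergence = best$convergence,
                 free = free, condition_number = condn,
                 diagnostics = diagnostics),
            class = "tmad_refine")
}

#' Fit trumpet-model exchange parameters to expirograms
#'
#' The top-level estimator.  The default `"two_stage"` method mirrors the
#' staged procedure used with breath-hold data: first the airway maximum
#' flux is determined from the earliest samples (default first 0.2 s) of a
#' breath-hold exhalation, where the exhaled gas resided in the conducting
#' airways; then the alveolar parameters are refined against the phase III
#' plateau of all supplied expirograms.  `method = "joint"` instead runs a
#' single bounded least-squares over the parameters in `free` across all
#' expirograms ([least_squares_refine()]).
#'
#' @param data an `"expirogram"` (measured, [read_expirogram()], or
#'   synthetic) or a list of them.
#' @param maneuvers matching [breath_maneuver()] or list of them.
#' @param grid [trumpet_grid()].
#' @param init starting [exchange_params()]; defaults to the healthy
#'   non-smoker estimate ([estimate_exchange()]).
#' @param method `"two_stage"` (default) or `"joint"`.
#' @param free for `"joint"`: parameters to vary.
#' @param fit_D_aw for `"two_stage"`: also vary `D_aw` in stage 1.
#' @param airway_window_s stage-1 window (s from exhalation start).
#' @param dt solver time step (s).
#' @param n_starts,seed multi-start control for `"joint"`.
#' @return An object of class `"tmad_fit"` with methods [coef()],
#'   [predict()], [residuals()], [simulate()], `print()`, `summary()` and
#'   `plot()`.
#' @examples
#' \donttest{
#' g <- trumpet_grid()
#' truth <- exchange_params(220, 1.6, 1.82e7, 7767)
#' m <- breath_maneuver(121, 121, 726, hold_s = 10, ambient_ppb = 130)
#' e <- synthetic_expirogram(truth, m, g, seed = 1)
#' fit <- tmad_fit(e, m, g)
#' coef(fit)
#' }
#' @export
tmad_fit <- function(data, maneuvers, grid = trumpet_grid(),
                     init = estimate_exchange(),
                     method = c("two_stage", "joint"),
                     free = c("J_A", "D_A"), fit_D_aw = FALSE,
                     airway_window_s = 0.2, dt = 0.01, n_starts = 1,
                     seed = 1) {
  method <- match.arg(method)
  if (inherits(data, "data.frame")) data <- list(data)
  if (inherits(maneuvers, "breath_maneuver")) maneuvers <- list(maneuvers)
  stopifnot(length(data) == length(maneuvers), length(data) >= 1)
  stages <- list()
  diagnostics <- character(0)
  params <- init
  if (method == "two_stage") {
    holds <- vapply(maneuvers, function(m) m$hold_s, numeric(1))
    bh <- which(holds > 0)
    if (!length(bh))
      diagnostics <- c(diagnostics,
                       "no breath-hold expirogram: airway parameters kept at their initial estimates")
    # two alternating passes: the airway window also feels the alveolar
    # level (axial diffusion), so stage 1 is repeated once the alveolar
    # parameters have been refined
    for (pass in 1:2) {
      if (length(bh)) {
        s1 <- fit_airway(data[[bh[1]]], maneuvers[[bh[1]]], grid, params,
                         window_s = airway_window_s, fit_D_aw = fit_D_aw,
                         dt = dt)
        params <- s1$params
        stages$airway <- s1
      }
      s2 <- fit_alveolar(data, maneuvers, grid, params, dt = dt)
      params <- s2$params
      stages$alveolar <- s2
      if (!length(bh)) break
    }
  } else {
    ref <- least_squares_refine(data, maneuvers, grid, params, free = free,
                                dt = dt, n_starts = n_starts, seed = seed)
    params <- ref$params
    stages$joint <- ref
    diagnostics <- c(diagnostics, ref$diagnostics)
  }
  fitted <- lapply(seq_along(data), function(i)
    .sim_at(params, maneuvers[[i]], grid, dt, data[[i]]$time_s))
  resid <- lapply(seq_along(data), function(i)
    data[[i]]$co_ppb - fitted[[i]])
  out <- list(params = params, init = init, stages = stages,
              method = method, data = data, maneuvers = maneuvers,
              grid = grid, dt = dt, fitted = fitted, residuals = resid,
              rms = .rms(unlist(resid)), diagnostics = diagnostics,
              call = match.call())
  class(out) <- "tmad_fit"
  out
}

#' @export
coef.tmad_fit <- function(object, ...) {
  with(object$params, c(J_aw = J_aw, D_aw = D_aw, J_A = J_A, D_A = D_A))
}

#' @export
print.tmad_fit <- function(x, ...) {
  cat("Trumpet-model fit (", x$method, ", ", length(x$data),
      " expirogram(s) )\n", sep = "")
  print(signif(coef(x), 4))
  cat(sprintf("overall RMS %.3g ppb; alveolar C_A = %.4g ppb, airway C_tiss = %.4g ppb\n",
              x$rms, x$params$J_A / x$params$D_A,
              x$params$J_aw / x$params$D_aw))
  for (d in x$diagnostics) cat("note:", d, "\n")
  invisible(x)
}

#' @export
summary.tmad_fit <- function(object, ...) {
  cat("Call: "); print(object$call)
  print(object)
  if (!is.null(object$stages$airway))
    cat(sprintf("stage 1 (airway, first %d samples): RMS %.3g ppb\n",
                object$stages$airway$n_window, object$stages$airway$rms))
  if (!is.null(object$stages$alveolar))
    cat(sprintf("stage 2 (alveolar, phase III): RMS %.3g ppb in %d evaluations\n",
                object$stages$alveolar$rms,
                object$stages$alveolar$iterations))
  if (!is.null(object$stages$joint))
    cat(sprintf("joint fit over {%s}: RMS %.3g ppb, condition number %.3g\n",
                paste(object$stages$joint$free, collapse = ", "),
                object$stages$joint$rms,
                object$stages$joint$condition_number))
  invisible(object)
}

#' @describeIn tmad_fit simulate an expirogram at the fitted parameters for
#'   a new maneuver (default: the first fitted maneuver).
#' @param object a `"tmad_fit"`.
#' @param newdata a [breath_maneuver()].
#' @param ... unused.
#' @export
predict.tmad_fit <- function(object, newdata = NULL, ...) {
  m <- if (is.null(newdata)) object$maneuvers[[1]] else newdata
  run_maneuver(object$grid, object$params, m, dt = object$dt)
}

#' @export
residuals.tmad_fit <- function(object, ...) {
  if (length(object$residuals) == 1) object$residuals[[1]]
  else object$residuals
}

#' @describeIn tmad_fit generate noisy synthetic expirograms at the fitted
#'   parameters (one per fitted maneuver per replicate).
#' @param nsim number of replicates.
#' @param seed RNG seed.
#' @param sensor [sensor_model()] describing the measurement process.
#' @export
simulate.tmad_fit <- function(object, nsim = 1, seed = NULL,
                              sensor = sensor_model(), ...) {
  if (is.null(seed)) seed <- 1
  out <- list()
  k <- 0
  for (r in seq_len(nsim))
    for (i in seq_along(object$maneuvers)) {
      k <- k + 1
      out[[k]] <- synthetic_expirogram(object$params,
                                       object$maneuvers[[i]], object$grid,
                                       sensor, seed = seed + 1000 * (r - 1) + i,
                                       dt = object$dt)
    }
  out
}

#' @export
plot.tmad_fit <- function(x, y = NULL, which = 1, ...) {
  e <- x$data[[which]]
  plot(e$volume_ml, e$co_ppb, pch = 1, col = "grey40",
       xlab = "exhaled volume (ml)", ylab = "concentration (ppb)", ...)
  lines(e$volume_ml, x$fitted[[which]], lwd = 2)
  legend("bottomright", c("data", "fit"), pch = c(1, NA), lty = c(NA, 1),
         col = c("grey40", "black"), bty = "n")
  invisible(x)
}
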