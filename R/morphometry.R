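#' Anatomical constants of the trumpet lung model
#'
#' The one-dimensional "trumpet" representation of the symmetric (Weibel)
#' airway tree places the mouth at axial position `z = 0` and the distal end
#' of the alveolar region at `z = L`.  The conducting airways (generations
#' 0--16) occupy `[0, L - z1]`; the alveolar region (generations 17--23) the
#' final `z1` centimetres.  Defaults are the rescaled morphometric values
#' used throughout the package.
#'
#' @param L_cm total trumpet length (cm).
#' @param z1_cm length of the alveolar region (cm).
#' @param A_c1_cm2 airway cross-sectional area at generation 17 (cm^2).
#' @param m power-law exponent of the conducting-airway area profile.
#' @param A_cA_cm2 total alveolar cross-sectional area (cm^2).
#' @param N_t total number of alveoli.
#' @param N_max maximum number of alveoli at any axial position (metadata;
#'   the solver uses the maximum of the discretized distribution, see
#'   [trumpet_grid()]).
#' @param V_total_ml total airspace volume (ml) of the rescaled airway-tree
#'   geometry (metadata; see [trumpet_grid()] for how the alveolar storage
#'   term is scaled).
#' @return A list of class `"tmad_anatomy"`.
#' @examples
#' anatomical_constants()
#' @export
anatomical_constants <- function(L_cm = 27.2, z1_cm = 0.6, A_c1_cm2 = 217,
                                 m = 2, A_cA_cm2 = 39444, N_t = 480e6,
                                 N_max = 263.3e6, V_total_ml = 3700) {
  a <- list(L = L_cm, z1 = z1_cm, A_c1 = A_c1_cm2, m = m, A_cA = A_cA_cm2,
            N_t = N_t, N_max = N_max, V_total = V_total_ml)
  bad <- names(a)[!vapply(a, function(x) is.numeric(x) && length(x) == 1 &&
                            is.finite(x) && x > 0, logical(1))]
  if (length(bad))
    .tmad_stop("anatomical constants must be positive scalars: ",
               paste(bad, collapse = ", "))
  if (a$z1 >= a$L) .tmad_stop("alveolar-region length z1 must be < L")
  class(a) <- "tmad_anatomy"
  a
}

#' @export
print.tmad_anatomy <- function(x, ...) {
  cat("Trumpet anatomy: L =", x$L, "cm, alveolar region =", x$z1,
      "cm, A_c1 =", x$A_c1, "cm2, A_cA =", x$A_cA, "cm2\n")
  cat("  alveoli: N_t =", format(x$N_t, big.mark = ","),
      " N_max =", format(x$N_max, big.mark = ","), "\n")
  invisible(x)
}

#' Per-generation morphometric table
#'
#' Reads the bundled (or a user-supplied) per-generation table: generation
#' index 0--23, cumulative axial position (cm), airway cross-sectional area
#' (cm^2) and the fraction of all alveoli in that generation (non-zero for
#' generations 17--23 only).  Conducting-airway areas are the power-law
#' model values; areas and alveoli fractions in the alveolar region are
#' rescaled morphometric data.  The exact rescaled per-generation alveoli
#' fractions are not tabulated in the primary sources; the bundled values
#' are an approximation that increases monotonically to a generation-23
#' fraction of `N_max / N_t` and may be edited by the user.
#'
#' @param path CSV file with columns `generation`, `position_cm`,
#'   `area_cm2`, `alveoli_fraction`.  Default: the bundled table.
#' @param anatomy [anatomical_constants()] used for validation.
#' @return A `data.frame` with the four columns above.
#' @examples
#' head(generation_table())
#' @export
generation_table <- function(path = system.file("extdata",
                                                "weibel_generations.csv",
                                                package = "tmad"),
                             anatomy = anatomical_constants()) {
  tab <- read.csv(path)
  need <- c("generation", "position_cm", "area_cm2", "alveoli_fraction")
  if (!all(need %in% names(tab)))
    .tmad_stop("generation table needs columns: ", paste(need, collapse = ", "))
  if (any(diff(tab$position_cm) <= 0))
    .tmad_stop("generation positions must be strictly increasing")
  if (any(tab$area_cm2 <= 0)) .tmad_stop("generation areas must be positive")
  if (abs(tab$position_cm[nrow(tab)] - anatomy$L) > 1e-6)
    .tmad_stop("final generation position must equal L = ", anatomy$L, " cm")
  fsum <- sum(tab$alveoli_fraction)
  if (abs(fsum - 1) > 1e-6)
    .tmad_stop("alveoli fractions must sum to 1 (got ", format(fsum), ")")
  tab
}

#' Conducting-airway cross-sectional area
#'
#' Power-law area profile of the conducting airways,
#' `A(z) = A_c1 * ((L - z)/z1)^(-m)`, valid from the mouth (`z = 0`) up to
#' generation 17 (`z = L - z1`).  The area increases monotonically toward
#' the lung periphery.
#'
#' @param z axial position(s), cm from the mouth.
#' @param anatomy [anatomical_constants()].
#' @return Airway cross-sectional area (cm^2) at `z`.
#' @examples
#' airway_cross_section(26.6) # 217 cm2 at generation 17
#' @export
airway_cross_section <- function(z, anatomy = anatomical_constants()) {
  if (any(z < -1e-9 | z > anatomy$L - anatomy$z1 + 1e-9))
    .tmad_stop("z must lie in [0, L - z1] = [0, ",
               anatomy$L - anatomy$z1, "] cm")
  anatomy$A_c1 * ((anatomy$L - z) / anatomy$z1)^(-anatomy$m)
}

#' Volume of the conducting airways
#'
#' Closed-form integral of the power-law area profile over `[0, L - z1]`:
#' `A_c1 * z1 * (1 - z1/L)` for exponent `m = 2`, the anatomical dead-space
#' volume of the model (about 127 ml with default constants).
#'
#' @param anatomy [anatomical_constants()].
#' @return Volume in ml.
#' @examples
#' conducting_airway_volume() # ~127 ml
#' @export
conducting_airway_volume <- function(anatomy = anatomical_constants()) {
  if (anatomy$m != 2) {
    # general m: A_c1 z1 / (m-1) * (1 - (z1/L)^(m-1))
    return(anatomy$A_c1 * anatomy$z1 / (anatomy$m - 1) *
             (1 - (anatomy$z1 / anatomy$L)^(anatomy$m - 1)))
  }
  anatomy$A_c1 * anatomy$z1 * (1 - anatomy$z1 / anatomy$L)
}

#' Axial distribution of alveoli
#'
#' Interpolates the per-generation alveoli fractions onto axial positions
#' and scales the resulting density so that it integrates (node-centred, at
#' spacing `dz`) to exactly `N_t` alveoli.  The density is zero in the
#' conducting airways.
#'
#' @param z axial node positions (cm), equally spaced by `dz`.
#' @param dz node spacing (cm).
#' @param anatomy [anatomical_constants()].
#' @param gen_table [generation_table()].
#' @return A list with `N_alv` (alveoli per cm at each node), `N_max_eff`
#'   (maximum of `N_alv`) and `w_alv` (`N_alv / N_t`, integrating to 1).
#' @examples
#' z <- seq(0, 27.2, by = 0.1)
#' p <- alveolar_profile(z, 0.1)
#' sum(p$N_alv * 0.1) # 480e6
#' @export
alveolar_profile <- function(z, dz, anatomy = anatomical_constants(),
                             gen_table = generation_table(anatomy = anatomy)) {
  alv <- gen_table$alveoli_fraction > 0
  if (!any(alv)) .tmad_stop("generation table has no alveolated generations")
  gz <- gen_table$position_cm[alv]
  dens <- rep(0, length(z))
  if (sum(alv) == 1) {
    # single alveolated generation: all mass on the nearest node
    dens[which.min(abs(z - gz))] <- 1
  } else {
    gap <- mean(diff(gz))
    in_alv <- z > min(gz) - 1e-9
    dens[in_alv] <- approx(gz, gen_table$alveoli_fraction[alv] / gap,
                           xout = pmin(z[in_alv], max(gz)), rule = 2)$y
  }
  tot <- sum(dens * dz)
  if (tot <= 0) .tmad_stop("no grid nodes fall in the alveolar region")
  w_alv <- dens / tot
  N_alv <- w_alv * anatomy$N_t
  list(N_alv = N_alv, N_max_eff = max(N_alv), w_alv = w_alv)
}

#' Discretize the trumpet geometry onto a uniform axial grid
#'
#' Builds the node-centred geometry the solver works on: airway and
#' alveolar cross-sections, alveolar density and the normalized axial
#' source weights for the airway and alveolar exchange terms.
#'
#' Conducting-airway areas come from the power law
#' ([airway_cross_section()]); beyond generation 17 the rescaled
#' per-generation areas are interpolated directly.  The airway source
#' weight is uniform per unit axial length, attenuated by
#' `1 - N_alv(z)/N_max` where alveoli displace airway tissue; the alveolar
#' source weight is `N_alv(z)/N_t`.  Both integrate to one so that the
#' configured total fluxes and diffusing capacities are conserved.
#'
#' The alveolar storage (capacity) term is `A_cA * N_alv(z)/N_t` per unit
#' length, the literal storage coefficient of the mass-balance equation.
#' Its axial integral, `A_cA` x 1 cm (about 39.4 l), acts as the effective
#' alveolar gas-exchange reservoir and sets the alveolar equilibration time
#' constant `A_cA / D_A` of a few seconds -- the value that reproduces the
#' published expirograms.  Pass `total_capacity_ml` to instead rescale the
#' alveolar term so that the total grid capacity equals a prescribed
#' physical airspace volume (e.g. 3700 ml); this makes alveolar
#' equilibration essentially instantaneous and is provided for comparison
#' only.
#'
#' @param dz grid spacing (cm), default 0.1.
#' @param anatomy [anatomical_constants()].
#' @param gen_table [generation_table()].
#' @param total_capacity_ml optional total capacity (ml) to rescale the
#'   alveolar storage term to; `NULL` (default) keeps the literal `A_cA`
#'   scaling.
#' @return An object of class `"trumpet_grid"`: list with node positions
#'   `z`, spacing `dz`, areas `A_aw` and `A_alv`, capacity `capacity`
#'   (`A_aw + A_alv`), alveolar density `N_alv`, source weights `w_aw` and
#'   `w_alv`, face-averaged airway areas `A_face`, and summary volumes.
#' @examples
#' g <- trumpet_grid()
#' length(g$z) # 273 nodes at dz = 0.1
#' @export
trumpet_grid <- function(dz = 0.1, anatomy = anatomical_constants(),
                         gen_table = generation_table(anatomy = anatomy),
                         total_capacity_ml = NULL) {
  if (dz <= 0) .tmad_stop("dz must be positive")
  if (dz > anatomy$z1 + 1e-9)
    .tmad_stop("dz must not exceed the alveolar-region length z1 = ",
               anatomy$z1, " cm (no node would fall in the alveolar region)")
  n_sec <- round(anatomy$L / dz)
  if (abs(n_sec * dz - anatomy$L) > 0.5 * dz)
    .tmad_stop("dz must divide the trumpet length L to within one node")
  z <- seq(0, by = dz, length.out = n_sec + 1)
  z[length(z)] <- anatomy$L
  cond <- z <= anatomy$L - anatomy$z1 + 1e-9
  A_aw <- numeric(length(z))
  A_aw[cond] <- airway_cross_section(z[cond], anatomy)
  gz <- gen_table$position_cm
  A_aw[!cond] <- approx(gz, gen_table$area_cm2, xout = z[!cond], rule = 2)$y
  prof <- alveolar_profile(z, dz, anatomy, gen_table)
  att <- 1 - prof$N_alv / prof$N_max_eff
  w_aw <- att / sum(att * dz)
  aw_vol <- sum((A_aw[-1] + A_aw[-length(A_aw)]) / 2 * dz) # trapezoid
  A_alv <- anatomy$A_cA * prof$w_alv
  if (!is.null(total_capacity_ml)) {
    if (total_capacity_ml <= aw_vol)
      .tmad_stop("total_capacity_ml must exceed the airway volume of ",
                 round(aw_vol), " ml")
    A_alv <- (total_capacity_ml - aw_vol) * prof$w_alv
  }
  capacity <- A_aw + A_alv
  g <- list(z = z, dz = dz, A_aw = A_aw, A_alv = A_alv, capacity = capacity,
            N_alv = prof$N_alv, N_max_eff = prof$N_max_eff,
            w_aw = w_aw, w_alv = prof$w_alv,
            A_face = 0.5 * (A_aw[-1] + A_aw[-length(A_aw)]),
            airway_volume_ml = aw_vol,
            capacity_ml = aw_vol + sum(A_alv * dz),
            dead_space_ml = conducting_airway_volume(anatomy),
            anatomy = anatomy)
  class(g) <- "trumpet_grid"
  g
}

#' @export
print.trumpet_grid <- function(x, ...) {
  cat("Trumpet grid:", length(x$z), "nodes, dz =", x$dz, "cm, L =",
      x$anatomy$L, "cm\n")
  cat("  airway volume", round(x$airway_volume_ml, 1),
      "ml (dead space", round(x$dead_space_ml, 1),
      "ml); total storage capacity", round(x$capacity_ml), "ml\n")
  cat("  alveolar nodes:", sum(x$w_alv > 0), " max N_alv =",
      format(signif(x$N_max_eff, 4)), "per cm\n")
  invisible(x)
}
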