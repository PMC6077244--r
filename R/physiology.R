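#' Tissue, blood and membrane parameters for CO exchange
#'
#' Healthy non-smoker reference values used for the initial estimation of
#' the four gas-exchange parameters.  Airway and alveolar membranes are
#' characterized by their area and thickness; blood by carboxyhemoglobin,
#' mean capillary oxyhemoglobin and oxygen tension, and the Haldane
#' equilibrium constant for CO--O2 competition on hemoglobin.
#'
#' @param A_M_aw_cm2 airway membrane area (cm^2).
#' @param dx_aw_um airway tissue thickness (micrometre).
#' @param A_M_A_cm2 alveolar membrane area (cm^2).
#' @param dx_A_um alveolar membrane thickness (micrometre).
#' @param K_CO_cm2_min_atm CO permeation coefficient of lung tissue at
#'   37 C (cm^2 min^-1 atm^-1).
#' @param COHb_pct carboxyhemoglobin (% saturation).
#' @param mcapO2Hb_pct mean capillary oxyhemoglobin (% saturation).
#' @param mcapPO2_mmHg mean capillary O2 partial pressure (mmHg).
#' @param M Haldane equilibrium constant (dimensionless).
#' @param airway_blood_fraction ratio of airway-proximal to pulmonary blood
#'   volume (the bronchial circulation carries roughly a tenth of the
#'   pulmonary blood flow).
#' @return A list of class `"tissue_blood_params"`.
#' @examples
#' tissue_blood_params()
#' @export
tissue_blood_params <- function(A_M_aw_cm2 = 9100, dx_aw_um = 20,
                                A_M_A_cm2 = 1.30e6, dx_A_um = 0.6,
                                K_CO_cm2_min_atm = 2.15e-5,
                                COHb_pct = 0.56, mcapO2Hb_pct = 97,
                                mcapPO2_mmHg = 90, M = 220,
                                airway_blood_fraction = 0.1) {
  p <- list(A_M_aw = A_M_aw_cm2, dx_aw = dx_aw_um, A_M_A = A_M_A_cm2,
            dx_A = dx_A_um, K_CO = K_CO_cm2_min_atm, COHb = COHb_pct,
            mcapO2Hb = mcapO2Hb_pct, mcapPO2 = mcapPO2_mmHg, M = M,
            airway_blood_fraction = airway_blood_fraction)
  bad <- names(p)[!vapply(p, function(x) is.numeric(x) && length(x) == 1 &&
                            is.finite(x) && x > 0, logical(1))]
  if (length(bad))
    .tmad_stop("tissue/blood parameters must be positive scalars: ",
               paste(bad, collapse = ", "))
  if (p$COHb > 100 || p$mcapO2Hb > 100)
    .tmad_stop("saturations are percentages in (0, 100]")
  class(p) <- "tissue_blood_params"
  p
}

#' Membrane diffusing capacity from morphometry
#'
#' Fick's-law diffusing capacity of a planar tissue membrane,
#' `D = A_M * K / dx`, converted to the model's working units
#' (pl s^-1 ppb^-1, with partial pressures as ppb mole fractions at
#' 1 atm).  The conversion constant is derived from first principles:
#' 1 cm^3 min^-1 atm^-1 corresponds to 1/60 pl s^-1 ppb^-1 in these units
#' (minute to second, atm to 1e9 ppb, cm^3 CO to 1e9 pl in the model's
#' flux bookkeeping), with the thickness converted from micrometres to cm.
#'
#' @param A_M membrane area (cm^2).
#' @param K permeation coefficient (cm^2 min^-1 atm^-1).
#' @param dx_um membrane thickness (micrometre).
#' @return Diffusing capacity in pl s^-1 ppb^-1.
#' @examples
#' diffusing_capacity(1.30e6, 2.15e-5, 0.6) # alveolar, ~7,760
#' diffusing_capacity(9100, 2.15e-5, 20)    # airway, ~1.6
#' @export
diffusing_capacity <- function(A_M, K, dx_um) {
  if (any(dx_um <= 0)) .tmad_stop("invalid membrane thickness (must be > 0)")
  if (any(A_M <= 0) || any(K <= 0))
    .tmad_stop("membrane area and permeation coefficient must be > 0")
  A_M * K / (dx_um * 1e-4) / 60
}

#' Mean capillary CO tension from the Haldane relation
#'
#' CO competes with O2 for hemoglobin; at equilibrium
#' `PCO = COHb * PO2 / (O2Hb * M)`.  The mmHg result is expressed as a ppb
#' mole fraction at 1 atm = 760 mmHg, i.e. multiplied by 1e9/760.
#'
#' @param COHb carboxyhemoglobin (% saturation).
#' @param mcapPO2 mean capillary O2 tension (mmHg).
#' @param mcapO2Hb mean capillary oxyhemoglobin (% saturation).
#' @param M Haldane equilibrium constant.
#' @return Mean capillary CO tension (ppb).
#' @examples
#' haldane_mcap_pco(0.56, 90, 97, 220) # ~3,100 ppb
#' @export
haldane_mcap_pco <- function(COHb, mcapPO2, mcapO2Hb, M) {
  if (any(mcapO2Hb <= 0) || any(M <= 0))
    .tmad_stop("mcapO2Hb and M must be > 0")
  if (any(COHb < 0) || any(mcapPO2 < 0))
    .tmad_stop("COHb and mcapPO2 must be >= 0")
  1e9 / 760 * COHb * mcapPO2 / (mcapO2Hb * M)
}

#' Maximum trans-membrane flux
#'
#' The flux across a membrane when the gas-phase concentration is zero:
#' `J = fraction * D * PCO`.  For the airway compartment the blood volume
#' in proximity of the airway wall is about a tenth of the pulmonary blood
#' volume, expressed by `blood_fraction`.
#'
#' @param D diffusing capacity (pl s^-1 ppb^-1).
#' @param mcapPCO capillary CO tension (ppb).
#' @param blood_fraction fraction of pulmonary blood volume feeding the
#'   membrane (default 1).
#' @return Maximum flux (pl/s).
#' @examples
#' max_flux(7764, 3108)      # alveolar, ~2.4e7 pl/s
#' max_flux(1.63, 3108, 0.1) # airway, ~500 pl/s
#' @export
max_flux <- function(D, mcapPCO, blood_fraction = 1) {
  if (any(D < 0) || any(mcapPCO < 0) || any(blood_fraction < 0))
    .tmad_stop("max_flux inputs must be non-negative")
  blood_fraction * D * mcapPCO
}

#' Gas-exchange parameter set
#'
#' The four parameters governing gas exchange in the trumpet model -- total
#' maximum flux and diffusing capacity for the airway and alveolar
#' compartments -- plus the gas-phase molecular diffusivity of the species.
#'
#' @param J_aw total maximum airway flux (pl/s).
#' @param D_aw total airway diffusing capacity (pl s^-1 ppb^-1).
#' @param J_A total maximum alveolar flux (pl/s).
#' @param D_A total alveolar diffusing capacity (pl s^-1 ppb^-1).
#' @param D_gas gas-phase molecular diffusivity in air (cm^2/s); 0.21 for
#'   CO, 0.23 for NO.
#' @param species label carried through outputs ("CO" or "NO" or other).
#' @return A list of class `"exchange_params"`.
#' @examples
#' exchange_params(220, 1.6, 1.76e7, 7400)
#' @export
exchange_params <- function(J_aw, D_aw, J_A, D_A, D_gas = 0.21,
                            species = "CO") {
  p <- list(J_aw = J_aw, D_aw = D_aw, J_A = J_A, D_A = D_A, D_gas = D_gas,
            species = species)
  num <- p[c("J_aw", "D_aw", "J_A", "D_A", "D_gas")]
  bad <- names(num)[!vapply(num, function(x) is.numeric(x) &&
                              length(x) == 1 && is.finite(x) && x >= 0,
                            logical(1))]
  if (length(bad))
    .tmad_stop("exchange parameters must be non-negative scalars: ",
               paste(bad, collapse = ", "))
  class(p) <- "exchange_params"
  p
}

#' @export
print.exchange_params <- function(x, ...) {
  cat(x$species, "exchange parameters:\n")
  cat(sprintf("  airway:   J_aw = %s pl/s, D_aw = %s pl.s-1.ppb-1 (C_tiss = %s ppb)\n",
              signif(x$J_aw, 4), signif(x$D_aw, 4),
              if (x$D_aw > 0) signif(x$J_aw / x$D_aw, 4) else NA))
  cat(sprintf("  alveolar: J_A  = %s pl/s, D_A  = %s pl.s-1.ppb-1 (C_A = %s ppb)\n",
              signif(x$J_A, 4), signif(x$D_A, 4),
              if (x$D_A > 0) signif(x$J_A / x$D_A, 4) else NA))
  cat("  gas-phase diffusivity:", x$D_gas, "cm2/s\n")
  invisible(x)
}

#' Estimate exchange parameters from tissue and blood data
#'
#' Composes the morphometric diffusing capacities, the Haldane capillary CO
#' tension and the maximum-flux relation into the four model parameters:
#' `D_A` and `D_aw` from membrane area/thickness, `J_A = D_A * PCO`, and
#' `J_aw = airway_blood_fraction * D_aw * PCO`.
#'
#' @param params [tissue_blood_params()].
#' @param D_gas gas-phase diffusivity (cm^2/s), default CO.
#' @return An [exchange_params()] object; the estimated capillary CO
#'   tension is attached as attribute `"mcapPCO"`.
#' @examples
#' estimate_exchange() # healthy non-smoker defaults
#' @export
estimate_exchange <- function(params = tissue_blood_params(), D_gas = 0.21) {
  D_A <- diffusing_capacity(params$A_M_A, params$K_CO, params$dx_A)
  D_aw <- diffusing_capacity(params$A_M_aw, params$K_CO, params$dx_aw)
  pco <- haldane_mcap_pco(params$COHb, params$mcapPO2, params$mcapO2Hb,
                          params$M)
  out <- exchange_params(J_aw = max_flux(D_aw, pco,
                                         params$airway_blood_fraction),
                         D_aw = D_aw,
                         J_A = max_flux(D_A, pco),
                         D_A = D_A, D_gas = D_gas, species = "CO")
  attr(out, "mcapPCO") <- pco
  out
}

#' Reference NO exchange parameters
#'
#' The nitric-oxide parameter set commonly used with trumpet-type models
#' (airway flux 640 pl/s, airway diffusing capacity 4.2, alveolar flux
#' 3,638 pl/s, alveolar diffusing capacity 1,467), with the NO gas-phase
#' diffusivity of 0.23 cm^2/s.
#'
#' @return An [exchange_params()] object for NO.
#' @examples
#' no_exchange_params()
#' @export
no_exchange_params <- function() {
  exchange_params(J_aw = 640, D_aw = 4.2, J_A = 3638, D_A = 1467,
                  D_gas = 0.23, species = "NO")
}

#' Equilibrium concentration of a compartment
#'
#' The ratio of maximum flux to diffusing capacity is the gas-phase
#' concentration at which net exchange vanishes: the airway tissue level
#' `J_aw/D_aw` or the alveolar level `J_A/D_A`.
#'
#' @param J maximum flux (pl/s).
#' @param D diffusing capacity (pl s^-1 ppb^-1).
#' @return Equilibrium concentration (ppb).
#' @examples
#' equilibrium_concentration(2.05e7, 8800) # 2,330 ppb
#' @export
equilibrium_concentration <- function(J, D) {
  if (any(D <= 0))
    .tmad_stop("undefined equilibrium: diffusing capacity must be > 0")
  if (any(J < 0)) .tmad_stop("maximum flux must be >= 0")
  J / D
}

#' Fitted subject parameters and respiratory data
#'
#' The bundled per-maneuver parameter sets and breath-sampling data for the
#' two healthy non-smoking subjects (exchange parameters, end-tidal and
#' alveolar CO, flow rates, volumes, end-tidal CO2 and ambient CO;
#' `hold_s` marks breath-hold maneuvers).
#'
#' @return A `data.frame`, one row per maneuver.
#' @examples
#' subject_parameters()
#' @export
subject_parameters <- function() {
  read.csv(system.file("extdata", "subject_parameters.csv", package = "tmad"))
}
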