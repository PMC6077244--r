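#' Solve a tridiagonal linear system
#'
#' Thomas-algorithm solve of `A x = rhs` where `A` has bands
#' `lower` (sub-diagonal, first element unused), `diag` and `upper`
#' (super-diagonal, last element unused).  The systems assembled by the
#' trumpet solver are strictly diagonally dominant, for which the algorithm
#' is stable without pivoting.
#'
#' @param lower,diag,upper band vectors, all of length `n`.
#' @param rhs right-hand side, length `n`.
#' @return Solution vector of length `n`.
#' @examples
#' solve_tridiagonal(c(0, -1), c(2, 2), c(-1, 0), c(1, 1))
#' @export
solve_tridiagonal <- function(lower, diag, upper, rhs) {
  cpp_thomas(as.numeric(lower), as.numeric(diag), as.numeric(upper),
             as.numeric(rhs))
}

## Normalize exchange params + optional switches into the flat argument set
## the C++ core takes.
.solver_params <- function(params, axial_diffusion = TRUE) {
  stopifnot(inherits(params, "exchange_params"))
  list(J_aw = params$J_aw, D_aw = params$D_aw, J_A = params$J_A,
       D_A = params$D_A, D_gas = if (axial_diffusion) params$D_gas else 0)
}

#' Assemble the implicit system for one time step
#'
#' Builds the tridiagonal backward-Euler system for the mass balance on a
#' trumpet grid: storage `capacity * dC/dt`, sign-upwinded advection at
#' volumetric flow `flow`, conservative-flux axial diffusion through the
#' airway cross-section, and the airway/alveolar source-sink terms, all
#' taken at the new time level.  Boundary handling: the mouth row is a
#' Dirichlet row at `ambient` when `mouth_dirichlet` is `TRUE`
#' (inhalation); otherwise boundary nodes are finite-volume rows with no
#' flux through the outer face (zero diffusive gradient) and advective
#' outflow through the open end.
#'
#' @param grid [trumpet_grid()].
#' @param params [exchange_params()].
#' @param state concentration vector (ppb), one value per grid node.
#' @param flow signed volumetric flow (ml/s): positive mouth-to-distal
#'   (inhalation), negative during exhalation.
#' @param dt time step (s).
#' @param mouth_dirichlet pin the mouth node to `ambient`?
#' @param ambient ambient concentration (ppb) for the Dirichlet row.
#' @param axial_diffusion include the axial-diffusion term?
#' @return List with `lower`, `diag`, `upper`, `rhs`.
#' @export
tmad_assemble <- function(grid, params, state, flow, dt,
                          mouth_dirichlet = flow > 0, ambient = 0,
                          axial_diffusion = TRUE) {
  stopifnot(inherits(grid, "trumpet_grid"))
  if (length(state) != length(grid$z))
    .tmad_stop("state length must equal the node count")
  if (any(grid$capacity <= 0)) .tmad_stop("zero capacity node in grid")
  p <- .solver_params(params, axial_diffusion)
  cpp_tmad_assemble(as.numeric(state), grid$capacity, grid$A_face,
                    grid$w_aw, grid$w_alv, grid$dz, dt, flow,
                    as.integer(mouth_dirichlet), ambient,
                    p$J_aw, p$D_aw, p$J_A, p$D_A, p$D_gas)
}

#' Advance the lung state by one implicit time step
#'
#' One backward-Euler step of the trumpet mass balance (assembly +
#' tridiagonal solve); see [tmad_assemble()] for the discretization.  Tiny
#' negative concentrations (down to `-neg_tol`) are clipped to zero; larger
#' violations raise an error since the implicit upwind scheme is
#' positivity-preserving and a real violation indicates a defect.
#'
#' @inheritParams tmad_assemble
#' @param neg_tol clip tolerance (ppb), default `1e-9`.
#' @return List with `state` (new concentration vector) and `mouth`
#'   (mouth-node concentration after the step).
#' @examples
#' g <- trumpet_grid()
#' p <- exchange_params(220, 1.6, 1.76e7, 7400)
#' st <- tmad_step(g, p, rep(0, length(g$z)), flow = 121, dt = 0.01,
#'                 ambient = 130)
#' @export
tmad_step <- function(grid, params, state, flow, dt,
                      mouth_dirichlet = flow > 0, ambient = 0,
                      axial_diffusion = TRUE, neg_tol = 1e-9) {
  stopifnot(inherits(grid, "trumpet_grid"))
  if (length(state) != length(grid$z))
    .tmad_stop("state length must equal the node count")
  p <- .solver_params(params, axial_diffusion)
  out <- cpp_tmad_run(as.numeric(state), grid$capacity, grid$A_face,
                      grid$w_aw, grid$w_alv, grid$dz, dt,
                      flow = flow, dirichlet = as.integer(mouth_dirichlet),
                      ambient = ambient, J_aw = p$J_aw, D_aw = p$D_aw,
                      J_A = p$J_A, D_A = p$D_A, D_gas = p$D_gas,
                      snap_at = integer(0), neg_tol = neg_tol)
  list(state = out$state, mouth = out$mouth[1])
}

## Internal multi-step driver used by the maneuver engine.
.tmad_run <- function(grid, params, state, flow, dirichlet, ambient, dt,
                      axial_diffusion = TRUE, snap_at = integer(0),
                      neg_tol = 1e-9) {
  p <- .solver_params(params, axial_diffusion)
  cpp_tmad_run(as.numeric(state), grid$capacity, grid$A_face, grid$w_aw,
               grid$w_alv, grid$dz, dt, flow = as.numeric(flow),
               dirichlet = as.integer(dirichlet),
               ambient = as.numeric(ambient), J_aw = p$J_aw, D_aw = p$D_aw,
               J_A = p$J_A, D_A = p$D_A, D_gas = p$D_gas,
               snap_at = as.integer(snap_at), neg_tol = neg_tol)
}

#' Total gas content of a lung state
#'
#' Node-centred integral `sum(capacity * C * dz)` in ppb ml -- the quantity
#' conserved by advection and axial diffusion when sources and boundary
#' fluxes vanish.
#'
#' @param grid [trumpet_grid()].
#' @param state concentration vector (ppb).
#' @return Content in ppb ml (equivalently pl of gas).
#' @export
lung_content <- function(grid, state) {
  sum(grid$capacity * state * grid$dz)
}
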