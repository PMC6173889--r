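#' Fluid phase properties
#'
#' One incompressible species of the homogeneous mixture: phase 1 is the
#' transferred medium loaded in the catheter, phase 2 the uterine fluid
#' (glycerin-like, `rho = 1259.9` kg/m^3, `mu = 0.799` Pa.s).
#'
#' @param density density (kg/m^3), > 0.
#' @param viscosity dynamic viscosity (Pa.s), > 0.
#' @return an object of class `et_phase`.
#' @export
fluid_phase <- function(density, viscosity) {
  stopifnot(is.numeric(density), is.numeric(viscosity),
            length(density) == 1, length(viscosity) == 1,
            is.finite(density), is.finite(viscosity),
            density > 0, viscosity > 0)
  structure(list(density = density, viscosity = viscosity),
            class = "et_phase")
}

#' Uterine fluid reference phase
#' @return `fluid_phase(1259.9, 0.799)`.
#' @export
uterine_fluid <- function() fluid_phase(1259.9, 0.799)

#' Mixture density and viscosity
#'
#' Linear volume-fraction blends of the two phases:
#' `rho_m = alpha*rho1 + (1-alpha)*rho2` and likewise for `mu_m`.
#'
#' @param alpha volume fraction of the transferred medium, in `[0, 1]`
#'   (vectorized).
#' @param phase1,phase2 [fluid_phase()] objects for the transferred medium
#'   and the uterine fluid.
#' @return list with numeric `rho` and `mu` of the same shape as `alpha`.
#' @export
mixture_properties <- function(alpha, phase1, phase2) {
  if (any(alpha < 0 | alpha > 1, na.rm = TRUE)) {
    stop("alpha must lie in [0, 1]")
  }
  list(rho = alpha * phase1$density + (1 - alpha) * phase2$density,
       mu = alpha * phase1$viscosity + (1 - alpha) * phase2$viscosity)
}

#' Mean injection speed through the catheter bore
#'
#' The injection velocity is constant during injection and follows from the
#' transferred volume, the injection time and the circular bore area:
#' `U = V / (t_inj * pi * r_c^2)`.
#'
#' @param injected_volume transferred volume (microlitres); may be 0.
#' @param injection_time injection duration (s), > 0.
#' @param inner_radius catheter bore radius (mm), > 0.
#' @return mean speed in mm/s.
#' @export
inlet_velocity <- function(injected_volume, injection_time, inner_radius) {
  stopifnot(injected_volume >= 0, injection_time > 0, inner_radius > 0)
  # 1 uL = 1 mm^3
  injected_volume / (injection_time * pi * inner_radius^2)
}

#' Solver settings
#'
#' Time step and SIMPLE iteration controls. The default time step is 1e-4 s
#' and fields are recorded every 100 steps; the desk-scale profiles in
#' [resolution_profile()] relax the step under the first-order implicit
#' scheme.
#'
#' @param dt time step (s).
#' @param relax_u,relax_p under-relaxation factors for momentum and pressure.
#' @param tol_rel inner-iteration convergence tolerance on the summed
#'   continuity imbalance, relative to the driving boundary flux.
#' @param max_iter maximum SIMPLE inner iterations per step.
#' @param snapshot_every snapshot cadence in steps.
#' @return an object of class `et_settings`.
#' @export
solver_settings <- function(dt = 1e-4, relax_u = 0.7, relax_p = 0.3,
                            tol_rel = 1e-6, max_iter = 60L,
                            snapshot_every = 100L) {
  stopifnot(dt > 0, tol_rel > 0, relax_u > 0, relax_u <= 1,
            relax_p > 0, relax_p <= 1, max_iter >= 1)
  structure(list(dt = dt, relax_u = relax_u, relax_p = relax_p,
                 tol_rel = tol_rel, max_iter = as.integer(max_iter),
                 snapshot_every = as.integer(snapshot_every)),
            class = "et_settings")
}
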