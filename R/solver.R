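#' @importFrom Matrix sparseMatrix solve Cholesky forceSymmetric
NULL

# accumulate val into a length-n vector by integer index (duplicates sum);
# used on cold paths -- hot paths use the precomputed sparse operators
accum <- function(idx, val, n) {
  res <- numeric(n)
  if (length(idx)) {
    rs <- rowsum(val, idx)
    res[as.integer(rownames(rs))] <- rs[, 1]
  }
  res
}

# fill the shared sparsity template with off-diagonal (4 per interior face)
# and diagonal values
fill_matrix <- function(faces, off, diagv) {
  A <- faces$tmpl
  A@x <- as.numeric(faces$Sasm %*% c(off, diagv))
  A
}

#' Initialize a flow field
#'
#' Quiescent field at `t = 0` with a prescribed volume-fraction distribution
#' (catheter bore filled with transferred medium, cavity with uterine fluid,
#' in the transfer scenarios).
#'
#' @param mesh an `et_mesh`.
#' @param fluid logical fluid mask.
#' @param alpha0 initial volume fraction: a scalar or an `nx x ny` matrix.
#' @return an object of class `et_field` with cell-centered `u`, `v` (m/s),
#'   `p` (Pa gauge), `alpha`, time `t` and face-flux caches.
#' @export
flow_init <- function(mesh, fluid, alpha0 = 0) {
  z <- matrix(0, mesh$nx, mesh$ny)
  a <- if (is.matrix(alpha0)) alpha0 else matrix(alpha0, mesh$nx, mesh$ny)
  a[!fluid] <- 0
  structure(list(t = 0, u = z, v = z, p = z, alpha = a,
                 Fi = NULL, Fb = NULL, clip = 0),
            class = "et_field")
}

# Green-Gauss cell gradient of a cell field phi (eq-indexed vector), given
# boundary-face values phib. Returns per-volume gradient components.
# In the axisymmetric metric the radial component carries the -phi*dx*dy
# identity correction so that a uniform field has zero gradient.
cell_gradient <- function(phi, phib, mesh, faces, Vc, dxdy) {
  it <- faces$interior; bd <- faces$boundary
  eo <- faces$eo; en <- faces$en
  phif <- it$w * phi[eo] + (1 - it$w) * phi[en]
  isx <- it$dir == 1L
  fx <- phif * it$A * isx
  fy <- phif * it$A * !isx
  nxf <- (bd$dir == 1L) * bd$sgn
  nyf <- (bd$dir == 2L) * bd$sgn
  gx <- as.numeric(faces$So %*% fx - faces$Sn %*% fx +
                     faces$Sc %*% (phib * bd$A * nxf))
  gy <- as.numeric(faces$So %*% fy - faces$Sn %*% fy +
                     faces$Sc %*% (phib * bd$A * nyf))
  if (mesh$metric == "axisymmetric") gy <- gy - phi * dxdy
  list(gx = gx / Vc, gy = gy / Vc)
}

#' Advance the mixture flow by one time step
#'
#' One first-order implicit step of the variable-density, variable-viscosity
#' momentum equations with first-order upwind convection, iterated with
#' SIMPLE pressure correction on a colocated grid (Rhie-Chow momentum
#' interpolation) until the summed continuity imbalance falls below
#' `settings$tol_rel` times the driving boundary flux. The stress divergence
#' is the standard variable-viscosity form `div(mu (grad u + grad u^T))`,
#' with the transposed part treated explicitly (lagged over the step).
#' Matrix coefficients are assembled and factorized once per step (Picard
#' linearization about the step start); inner iterations update only
#' right-hand sides, which keeps the cost per SIMPLE sweep at a few
#' triangular solves. The volume fraction is then advected implicitly
#' (monotone first-order upwind) with the divergence-consistent face fluxes
#' and clipped to `[0, 1]`.
#'
#' @param state an `et_field`.
#' @param mesh an `et_mesh`.
#' @param faces face structure from [build_faces()] for the current catheter
#'   position and boundary-condition phase.
#' @param phases list with components `phase1` (transferred medium) and
#'   `phase2` (uterine fluid), each a [fluid_phase()].
#' @param settings a [solver_settings()] object.
#' @param advect_alpha advance the volume fraction (disable for single-phase
#'   benchmarks).
#' @return the updated `et_field`; attribute `diag` carries `res` (final
#'   continuity imbalance, relative), `iters`, `p_inlet` (area-mean inlet
#'   gauge pressure, Pa, `NA` without an inlet), boundary volume and
#'   volume-fraction fluxes (per solver metric convention) and the clipping
#'   magnitude.
#' @export
advance_flow <- function(state, mesh, faces, phases, settings,
                         advect_alpha = TRUE) {
  it <- faces$interior; bd <- faces$boundary
  n <- faces$ncell
  eo <- faces$eo; en <- faces$en; ec <- faces$ec
  ord <- which(faces$eq > 0L)
  dt <- settings$dt
  axis <- mesh$metric == "axisymmetric"

  Vc <- mesh$V[ord]
  ij <- arrayInd(ord, c(mesh$nx, mesh$ny))
  dxdy <- mesh$dx[ij[, 1]] * mesh$dy[ij[, 2]]
  ycc <- mesh$yc[ij[, 2]]

  r1 <- phases$phase1$density; m1 <- phases$phase1$viscosity
  r2 <- phases$phase2$density; m2 <- phases$phase2$viscosity

  al0 <- state$alpha[ord]
  rho <- al0 * r1 + (1 - al0) * r2
  mu <- al0 * m1 + (1 - al0) * m2
  u <- state$u[ord]; v <- state$v[ord]; p <- state$p[ord]
  u0 <- u; v0 <- v

  w <- it$w
  isx <- it$dir == 1L
  bisx <- bd$dir == 1L
  mu_f <- w * mu[eo] + (1 - w) * mu[en]
  Dif <- mu_f * it$A / it$delta
  nxf <- bisx * bd$sgn
  nyf <- (!bisx) * bd$sgn
  is_in <- bd$type == FACE_INLET
  is_out <- bd$type == FACE_OUT
  is_sym <- bd$type == FACE_SYM
  presc <- bd$type == FACE_WALL | is_in
  iout <- which(is_out)
  bout_x <- bisx[iout]
  ec_out <- ec[iout]
  un_w <- bd$uwx * nxf + bd$uwy * nyf      # prescribed normal velocity
  Fb_presc <- ifelse(presc, un_w * bd$A, 0)
  Dw <- mu[ec] * bd$A / bd$dhalf
  rho_in <- bd$alpha_in * r1 + (1 - bd$alpha_in) * r2

  ref <- sum(abs(Fb_presc))
  if (ref < 1e-15) ref <- 1e-15

  # face volume fluxes carried between steps; rebuild if face set changed
  Fi <- state$Fi; Fb <- state$Fb
  if (is.null(Fi) || length(Fi) != length(it$A)) {
    ubar <- ifelse(isx, w * u[eo] + (1 - w) * u[en],
                   w * v[eo] + (1 - w) * v[en])
    Fi <- ubar * it$A
    Fb <- Fb_presc
    Fb[iout] <- ifelse(bout_x, u[ec_out], v[ec_out]) *
      bd$sgn[iout] * bd$A[iout]
  } else {
    Fb[presc] <- Fb_presc[presc]
  }

  aT <- rho * Vc / dt
  bTu <- aT * u0
  bTv <- aT * v0

  # explicit transposed-gradient stress source, lagged over the step;
  # at a symmetry face the normal velocity component vanishes while the
  # tangential one is zero-gradient
  gb_u <- ifelse(presc, bd$uwx, u[ec])
  gb_v <- ifelse(presc, bd$uwy, v[ec])
  gb_u[is_sym & bisx] <- 0
  gb_v[is_sym & !bisx] <- 0
  gu <- cell_gradient(u, gb_u, mesh, faces, Vc, dxdy)
  gv <- cell_gradient(v, gb_v, mesh, faces, Vc, dxdy)
  gvx_f <- w * gv$gx[eo] + (1 - w) * gv$gx[en]
  guy_f <- w * gu$gy[eo] + (1 - w) * gu$gy[en]
  tx_i <- ifelse(isx, mu_f * (u[en] - u[eo]) / it$delta, mu_f * gvx_f) * it$A
  ty_i <- ifelse(isx, mu_f * guy_f, mu_f * (v[en] - v[eo]) / it$delta) * it$A
  # normal-gradient part: prescribed walls carry the wall velocity, a
  # symmetry face carries zero normal velocity; cross-derivative part is
  # zero along walls and symmetry lines (velocity constant along the face)
  # and one-sided at outflows
  tx_b <- ifelse(bisx & presc, Dw * (bd$uwx - u[ec]),
                 ifelse(bisx & is_sym, -Dw * u[ec], 0)) +
    ifelse(!bisx & is_out, mu[ec] * gv$gx[ec] * bd$A * nyf, 0)
  ty_b <- ifelse(!bisx & presc, Dw * (bd$uwy - v[ec]),
                 ifelse(!bisx & is_sym, -Dw * v[ec], 0)) +
    ifelse(bisx & is_out, mu[ec] * gu$gy[ec] * bd$A * nxf, 0)
  Tx <- as.numeric(faces$So %*% tx_i - faces$Sn %*% tx_i +
                     faces$Sc %*% tx_b)
  Ty <- as.numeric(faces$So %*% ty_i - faces$Sn %*% ty_i +
                     faces$Sc %*% ty_b)

  axv <- if (axis) 2 * mu * Vc / ycc^2 else 0
  omu <- settings$relax_u

  # ---- coefficient assembly and factorization (frozen over the step) -----
  Fm <- ifelse(Fi >= 0, rho[eo], rho[en]) * Fi
  Fb[iout] <- ifelse(bout_x, u[ec_out], v[ec_out]) *
    bd$sgn[iout] * bd$A[iout]
  Fmb <- ifelse(Fb >= 0, rho[ec], rho_in) * Fb

  voo <- Dif + pmax(Fm, 0)
  vnn <- Dif + pmax(-Fm, 0)
  diag_int <- as.numeric(faces$So %*% voo + faces$Sn %*% vnn)

  db_u <- pmax(Fmb, 0) + ifelse(presc | (is_sym & bisx), Dw, 0)
  db_v <- pmax(Fmb, 0) + ifelse(presc | (is_sym & !bisx), Dw, 0)
  bb_u <- as.numeric(faces$Sc %*% ((pmax(-Fmb, 0) + presc * Dw) * bd$uwx))
  bb_v <- as.numeric(faces$Sc %*% ((pmax(-Fmb, 0) + presc * Dw) * bd$uwy))

  diag_u <- aT + diag_int + as.numeric(faces$Sc %*% db_u)
  diag_v <- aT + diag_int + as.numeric(faces$Sc %*% db_v) + axv

  off <- c(voo, -vnn, vnn, -voo)
  Au <- fill_matrix(faces, off, diag_u / omu - diag_int)
  Av <- fill_matrix(faces, off, diag_v / omu - diag_int)
  lu_u <- Matrix::lu(Au)
  lu_v <- Matrix::lu(Av)

  du <- Vc / (diag_u / omu)
  dv <- Vc / (diag_v / omu)
  d_f <- ifelse(isx, w * du[eo] + (1 - w) * du[en],
                w * dv[eo] + (1 - w) * dv[en])
  E_i <- d_f * it$A / it$delta
  E_b <- numeric(length(ec))
  E_b[iout] <- ifelse(bout_x, du[ec_out], dv[ec_out]) *
    bd$A[iout] / bd$dhalf[iout]
  acc_E <- as.numeric(faces$So %*% E_i + faces$Sn %*% E_i)
  diag_p <- acc_E + as.numeric(faces$Sc %*% E_b)
  if (!length(iout)) diag_p <- diag_p + max(diag_p) * 1e-10
  Ap <- fill_matrix(faces, c(E_i, -E_i, E_i, -E_i), diag_p - acc_E)
  ch_p <- Matrix::Cholesky(forceSymmetric(Ap), LDL = FALSE, perm = TRUE)

  relax_c <- (1 - omu) / omu

  res <- Inf; iters <- 0L
  for (k in seq_len(settings$max_iter)) {
    iters <- k
    pb <- p[ec]; pb[iout] <- 0
    gp <- cell_gradient(p, pb, mesh, faces, Vc, dxdy)

    bu <- bTu + Tx - gp$gx * Vc + bb_u + relax_c * diag_u * u
    bv <- bTv + Ty - gp$gy * Vc + bb_v + relax_c * diag_v * v
    us <- as.numeric(Matrix::solve(lu_u, bu))
    vs <- as.numeric(Matrix::solve(lu_v, bv))

    # Rhie-Chow face fluxes
    ubar <- ifelse(isx, w * us[eo] + (1 - w) * us[en],
                   w * vs[eo] + (1 - w) * vs[en])
    gpn_f <- ifelse(isx, w * gp$gx[eo] + (1 - w) * gp$gx[en],
                    w * gp$gy[eo] + (1 - w) * gp$gy[en])
    Fi <- (ubar - d_f * ((p[en] - p[eo]) / it$delta - gpn_f)) * it$A
    Fb <- Fb_presc
    Fb[iout] <- ifelse(bout_x, us[ec_out], vs[ec_out]) *
      bd$sgn[iout] * bd$A[iout]

    bp <- -as.numeric(faces$So %*% Fi - faces$Sn %*% Fi + faces$Sc %*% Fb)
    res <- sum(abs(bp)) / ref

    pc <- as.numeric(Matrix::solve(ch_p, bp, system = "A"))

    pcb <- pc[ec]; pcb[iout] <- 0
    gpc <- cell_gradient(pc, pcb, mesh, faces, Vc, dxdy)
    u <- us - du * gpc$gx
    v <- vs - dv * gpc$gy
    p <- p + settings$relax_p * pc
    Fi <- Fi + E_i * (pc[eo] - pc[en])
    Fb[iout] <- Fb[iout] + E_b[iout] * pc[ec_out]

    if (res < settings$tol_rel && k >= 2L) break
  }
  if (!is.finite(res)) {
    stop("flow solver diverged at t = ", state$t, " (residual not finite)")
  }

  p_inlet <- if (any(is_in)) {
    sum((p[ec] * bd$A)[is_in]) / sum(bd$A[is_in])
  } else NA_real_

  clip <- 0
  infl_a <- outfl_a <- 0
  infl_v <- sum(pmax(-Fb, 0)); outfl_v <- sum(pmax(Fb, 0))
  al <- al0
  if (advect_alpha) {
    Fip <- pmax(Fi, 0); Fim <- pmax(-Fi, 0)
    acc_F <- as.numeric(faces$So %*% Fip + faces$Sn %*% Fim)
    da <- Vc / dt + acc_F + as.numeric(faces$Sc %*% pmax(Fb, 0))
    ba <- Vc / dt * al0 +
      as.numeric(faces$Sc %*% (pmax(-Fb, 0) * bd$alpha_in))
    Aa <- fill_matrix(faces, c(Fip, -Fim, Fim, -Fip), da - acc_F)
    al <- as.numeric(Matrix::solve(Aa, ba))
    clip <- max(0, max(al) - 1, -min(al))
    al <- pmin(pmax(al, 0), 1)
    infl_a <- sum(pmax(-Fb, 0) * bd$alpha_in)
    outfl_a <- sum(pmax(Fb, 0) * al[ec])
  }

  state$u[ord] <- u; state$v[ord] <- v; state$p[ord] <- p
  state$alpha[ord] <- al
  state$Fi <- Fi; state$Fb <- Fb
  state$t <- state$t + dt
  state$clip <- max(state$clip, clip)
  attr(state, "diag") <- list(res = res, iters = iters, p_inlet = p_inlet,
                              influx_vol = infl_v, outflux_vol = outfl_v,
                              influx_alpha = infl_a, outflux_alpha = outfl_a,
                              clip = clip)
  state
}

#' Advect the volume fraction with a frozen velocity field
#'
#' Convenience wrapper advancing only the volume fraction (implicit upwind)
#' with the face fluxes stored in the field, for passive-scalar tests.
#'
#' @inheritParams advance_flow
#' @return updated `et_field`.
#' @export
advect_volume_fraction <- function(state, mesh, faces, settings) {
  bd <- faces$boundary
  n <- faces$ncell
  ord <- which(faces$eq > 0L)
  dt <- settings$dt
  Vc <- mesh$V[ord]
  al0 <- state$alpha[ord]
  Fi <- state$Fi; Fb <- state$Fb
  if (is.null(Fi)) stop("field carries no face fluxes; run advance_flow first")
  Fip <- pmax(Fi, 0); Fim <- pmax(-Fi, 0)
  acc_F <- as.numeric(faces$So %*% Fip + faces$Sn %*% Fim)
  da <- Vc / dt + acc_F + as.numeric(faces$Sc %*% pmax(Fb, 0))
  ba <- Vc / dt * al0 + as.numeric(faces$Sc %*% (pmax(-Fb, 0) * bd$alpha_in))
  Aa <- fill_matrix(faces, c(Fip, -Fim, Fim, -Fip), da - acc_F)
  al <- as.numeric(Matrix::solve(Aa, ba))
  state$clip <- max(state$clip, max(0, max(al) - 1, -min(al)))
  state$alpha[ord] <- pmin(pmax(al, 0), 1)
  state$t <- state$t + dt
  state
}
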