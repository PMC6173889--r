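#' Embryo parameters
#'
#' Embryos are inertial spheres: diameter 0.1 mm, density 1000 kg/m^3,
#' initially at rest 10 mm behind the catheter tip.
#'
#' @param radius embryo radius (mm, default 0.05).
#' @param density embryo density (kg/m^3, default 1000).
#' @param tip_distance initial axial distance from the catheter tip (mm,
#'   default 10).
#' @return an object of class `et_embryo`.
#' @export
embryo_params <- function(radius = 0.05, density = 1000, tip_distance = 10) {
  stopifnot(radius > 0, density > 0, tip_distance > 0)
  structure(list(radius = radius, density = density,
                 tip_distance = tip_distance),
            class = "et_embryo")
}

#' Equal-area initial radial offsets of the ten embryos
#'
#' The catheter cross-section is divided into ten equal-area zones (a center
#' circle and nine annuli) by circles of radius
#' `r_i = sqrt(i/10) * (r_c - r_e)`; each embryo center sits at the midpoint
#' of its zone along the radius, `y_i = (r_(i-1) + r_i)/2` with `r_0 = 0`, so
#' embryo 1 is closest to the axis and embryo 10 the farthest.
#'
#' @param r_c catheter bore radius (mm).
#' @param r_e embryo radius (mm), must satisfy `0 < r_e < r_c`.
#' @return numeric vector of 10 radial offsets (mm), increasing.
#' @export
initial_positions <- function(r_c, r_e) {
  if (!(r_e > 0 && r_e < r_c)) {
    stop("embryo radius must satisfy 0 < r_e < r_c")
  }
  r <- sqrt(seq_len(10) / 10) * (r_c - r_e)
  (c(0, r[1:9]) + r) / 2
}

#' Relative Reynolds number of an embryo
#'
#' `Re_r = 2 rho_m r_e |v_e - u_m| / mu_m`, based on the embryo diameter and
#' its slip velocity relative to the local mixture.
#'
#' @param rho_m,mu_m local mixture density (kg/m^3) and viscosity (Pa.s).
#' @param r_e embryo radius (m).
#' @param slip slip speed `|v_e - u_m|` (m/s), or the two velocity vectors
#'   via `v_e` and `u_m`.
#' @param v_e,u_m optional velocity vectors (m/s); used when `slip` is
#'   missing.
#' @return `Re_r >= 0` (vectorized over `slip`).
#' @export
relative_reynolds <- function(rho_m, mu_m, r_e, slip = NULL,
                              v_e = NULL, u_m = NULL) {
  stopifnot(all(mu_m > 0))
  if (is.null(slip)) slip <- sqrt(sum((v_e - u_m)^2))
  2 * rho_m * r_e * abs(slip) / mu_m
}

# Morsi-Alexander piecewise coefficients (a1, a2, a3) by Re band
morsi_alexander_table <- function() {
  data.frame(
    re_max = c(0.1, 1, 10, 100, 1000, 5000, 10000, Inf),
    a1 = c(0, 3.690, 1.222, 0.6167, 0.3644, 0.357, 0.46, 0.5191),
    a2 = c(24, 22.73, 29.1667, 46.5, 98.33, 148.62, -490.546, -1662.5),
    a3 = c(0, 0.0903, -3.8889, -116.67, -2778, -47500, 578700, 5416700))
}

#' Sphere drag coefficient (Morsi-Alexander)
#'
#' Piecewise empirical fit `C_D = a1 + a2/Re + a3/Re^2` with the published
#' band coefficients. At `Re = 0` the drag response is finite only through
#' the product `C_D * Re` (see [drag_response()]); here `Re = 0` returns
#' `Inf` consistently with the Stokes law `24/Re`.
#'
#' @param re_r relative Reynolds number(s), `>= 0`.
#' @return drag coefficient(s).
#' @export
drag_coefficient <- function(re_r) {
  stopifnot(all(re_r >= 0))
  tab <- morsi_alexander_table()
  band <- findInterval(re_r, c(0, tab$re_max), left.open = TRUE,
                       rightmost.closed = FALSE)
  band[re_r == 0] <- 1L
  band <- pmin(band, nrow(tab))
  a1 <- tab$a1[band]; a2 <- tab$a2[band]; a3 <- tab$a3[band]
  a1 + a2 / re_r + a3 / re_r^2
}

# C_D * Re, finite at Re = 0 (Stokes product 24)
drag_cd_re <- function(re_r) {
  out <- ifelse(re_r > 0, drag_coefficient(pmax(re_r, 1e-300)) * re_r, 24)
  out
}

#' Inverse drag relaxation rate
#'
#' The drag acceleration on an embryo is `beta * (u_m - v_e)`. Two forms are
#' selectable: `"standard"` uses `beta = 3 mu_m C_D Re_r / (16 rho_e r_e^2)`,
#' the conventional particle drag response whose Stokes limit is
#' `9 mu / (2 rho_e r_e^2)`; `"doubled"` uses the prefactor `3/8` (exactly
#' twice `"standard"`). For the transfer scenarios `beta * dt >> 1` in every
#' case, so the embryos relax to the local fluid velocity within a step and
#' delivery sites are insensitive to the choice; `"standard"` is the default.
#'
#' @param mu_m,rho_m local mixture viscosity (Pa.s) and density (kg/m^3).
#' @param slip slip speed (m/s).
#' @param embryo an [embryo_params()]; its radius is interpreted in mm and
#'   converted internally.
#' @param form `"standard"` or `"doubled"`.
#' @return relaxation rate `beta` (1/s).
#' @export
drag_response <- function(mu_m, rho_m, slip, embryo,
                          form = c("standard", "doubled")) {
  form <- match.arg(form)
  r_e <- embryo$radius * 1e-3
  re_r <- relative_reynolds(rho_m, mu_m, r_e, slip = slip)
  pref <- if (form == "standard") 3 / 16 else 3 / 8
  pref * mu_m * drag_cd_re(re_r) / (embryo$density * r_e^2)
}

#' Advance one embryo over a time step
#'
#' Velocity update by exact integration of the linear drag equation with the
#' local flow frozen over the step (`v_new = u + (v - u) exp(-beta dt)`),
#' which is the stable treatment of the stiff relaxation; position update by
#' the trapezoidal rule on the velocity.
#'
#' @param pos,vel position (m) and velocity (m/s), length-2 vectors.
#' @param flow list with local `u`, `v` (m/s), `rho`, `mu` of the mixture.
#' @param dt time step (s).
#' @param embryo an [embryo_params()].
#' @param form drag form, see [drag_response()].
#' @return list with `pos`, `vel`, `beta`.
#' @export
step_embryo <- function(pos, vel, flow, dt, embryo,
                        form = c("standard", "doubled")) {
  um <- c(flow$u, flow$v)
  slip <- sqrt(sum((vel - um)^2))
  beta <- drag_response(flow$mu, flow$rho, slip, embryo, form)
  f <- exp(-beta * dt)
  vnew <- um + (vel - um) * f
  list(pos = pos + dt / 2 * (vel + vnew), vel = vnew, beta = beta)
}

#' Track embryos through a prescribed flow
#'
#' Integrates the drag dynamics of independent embryos through a flow given
#' by a sampler function (no embryo-embryo or embryo-flow coupling). Mainly
#' used for verification against passive-tracer integrations; the scenario
#' runner tracks embryos inline with the solver using the same stepper.
#'
#' @param sampler function `(t, x, y)` returning list `u`, `v`, `rho`, `mu`
#'   at a point (SI units).
#' @param start matrix (n x 2) of start positions (m).
#' @param times strictly increasing time grid (s); embryos are stepped
#'   between consecutive entries.
#' @param embryo an [embryo_params()].
#' @param form drag form.
#' @return array `n x 2 x length(times)` of positions (m).
#' @export
track_all <- function(sampler, start, times, embryo,
                      form = c("standard", "doubled")) {
  form <- match.arg(form)
  n <- nrow(start)
  out <- array(NA_real_, c(n, 2, length(times)))
  pos <- start
  vel <- matrix(0, n, 2)
  out[, , 1] <- pos
  for (k in seq_along(times)[-1]) {
    dt <- times[k] - times[k - 1]
    for (e in seq_len(n)) {
      fl <- sampler(times[k - 1], pos[e, 1], pos[e, 2])
      st <- step_embryo(pos[e, ], vel[e, ], fl, dt, embryo, form)
      pos[e, ] <- st$pos; vel[e, ] <- st$vel
    }
    out[, , k] <- pos
  }
  out
}

#' Bilinear interpolation of a cell-centered field
#'
#' Samples a cell-centered matrix at arbitrary points by bilinear
#' interpolation between cell centers, weighting only fluid nodes (near
#' walls the value is effectively clamped to the nearest interior data, no
#' one-sided extrapolation). Coordinates are clamped to the cell-center
#' bounding box.
#'
#' @param mesh an `et_mesh`.
#' @param fluid logical fluid mask.
#' @param field `nx x ny` matrix.
#' @param x,y sample coordinates (m).
#' @return interpolated values (0 where no fluid node is available).
#' @export
interp_field <- function(mesh, fluid, field, x, y) {
  xc <- mesh$xc; yc <- mesh$yc
  x <- pmin(pmax(x, xc[1]), xc[mesh$nx])
  y <- pmin(pmax(y, yc[1]), yc[mesh$ny])
  i <- pmin(pmax(findInterval(x, xc), 1L), mesh$nx - 1L)
  j <- pmin(pmax(findInterval(y, yc), 1L), mesh$ny - 1L)
  tx <- (x - xc[i]) / (xc[i + 1L] - xc[i])
  ty <- (y - yc[j]) / (yc[j + 1L] - yc[j])
  w00 <- (1 - tx) * (1 - ty); w10 <- tx * (1 - ty)
  w01 <- (1 - tx) * ty; w11 <- tx * ty
  f00 <- fluid[cbind(i, j)]; f10 <- fluid[cbind(i + 1L, j)]
  f01 <- fluid[cbind(i, j + 1L)]; f11 <- fluid[cbind(i + 1L, j + 1L)]
  w00 <- w00 * f00; w10 <- w10 * f10; w01 <- w01 * f01; w11 <- w11 * f11
  wt <- w00 + w10 + w01 + w11
  val <- w00 * field[cbind(i, j)] + w10 * field[cbind(i + 1L, j)] +
    w01 * field[cbind(i, j + 1L)] + w11 * field[cbind(i + 1L, j + 1L)]
  ifelse(wt > 0, val / wt, 0)
}
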