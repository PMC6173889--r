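#' Rectilinear finite-volume mesh
#'
#' Builds a 2D rectilinear (tensor-product, possibly non-uniform) mesh from
#' breakpoint vectors. Coordinates are stored internally in metres; the
#' constructor accepts millimetres by default since all geometry in this
#' package is specified in mm.
#'
#' Two metrics are supported. `"planar"` treats the domain as a plane of unit
#' depth (cell volume `dx*dy`). `"axisymmetric"` treats `y` as the radial
#' coordinate about the `y = 0` axis and uses per-radian volumes and face
#' areas (`V = dx*dy*y_c`, exact for linear `r`), so that a swept volume is
#' `2*pi` times the per-radian budget. All internal budgets are consistent
#' within a metric; unit-bearing outputs document their convention.
#'
#' @param xb,yb strictly increasing breakpoint vectors.
#' @param metric `"planar"` (default) or `"axisymmetric"`.
#' @param unit unit of `xb`/`yb` (`"mm"` or `"m"`).
#' @return an object of class `et_mesh`: breakpoints, centers, spacings (m),
#'   cell count `nx`, `ny`, per-cell volume matrix `V`, and the metric.
#' @export
et_mesh <- function(xb, yb, metric = c("planar", "axisymmetric"),
                    unit = c("mm", "m")) {
  metric <- match.arg(metric)
  unit <- match.arg(unit)
  s <- if (unit == "mm") 1e-3 else 1
  xb <- as.numeric(xb) * s
  yb <- as.numeric(yb) * s
  if (any(diff(xb) <= 0) || any(diff(yb) <= 0)) {
    stop("mesh breakpoints must be strictly increasing")
  }
  nx <- length(xb) - 1L
  ny <- length(yb) - 1L
  xc <- (xb[-1] + xb[-(nx + 1L)]) / 2
  yc <- (yb[-1] + yb[-(ny + 1L)]) / 2
  dx <- diff(xb)
  dy <- diff(yb)
  ry <- if (metric == "axisymmetric") yc else rep(1, ny)
  V <- outer(dx, dy * ry)
  structure(list(xb = xb, yb = yb, xc = xc, yc = yc, dx = dx, dy = dy,
                 nx = nx, ny = ny, metric = metric, V = V),
            class = "et_mesh")
}

# geometric growth of cell widths from h0 (capped at hmax), rescaled so the
# breakpoints hit `to` exactly
grow_breaks <- function(from, to, h0, hmax, ratio = 1.35) {
  len <- to - from
  stopifnot(len > 0, h0 > 0)
  h <- min(h0, len)
  inc <- c()
  while (sum(inc) < len) {
    inc <- c(inc, h)
    h <- min(h * ratio, hmax)
  }
  inc <- inc * (len / sum(inc))
  from + cumsum(c(0, inc))
}

uniform_breaks <- function(from, to, h) {
  n <- max(1L, round((to - from) / h))
  seq(from, to, length.out = n + 1L)
}

#' Resolution and time-stepping profiles
#'
#' Named bundles of mesh resolution and solver time-stepping choices used by
#' the scenario runner. `"coarse"` is the desk-scale default used for the
#' reported results (about 2000 cells; injection time step 2.5e-3 s,
#' withdrawal 5e-3 s, both stable under the first-order implicit scheme);
#' `"mini"` is a reduced profile for fast checks; `"fine"` uses the full
#' 1e-4 s time step with a denser grid and is provided for users with
#' patience rather than used by default.
#'
#' @param name profile name.
#' @return a list of profile parameters.
#' @export
resolution_profile <- function(name = c("coarse", "mini", "fine")) {
  name <- match.arg(name)
  switch(name,
    coarse = list(name = "coarse", hx = 1.0, hx_fine = 0.5, fine_halo = 4,
                  bore_cells = 6L, wall_cells = 2L, hmax_gap = 0.35,
                  hmax_cavity = 1.6, ratio = 1.35,
                  dt_injection = 2.5e-3, dt_withdrawal = 5e-3,
                  snapshot_every = 4L, tol_rel = 1e-3,
                  max_iter = 30L, relax_u = 0.7, relax_p = 0.3),
    mini = list(name = "mini", hx = 2.0, hx_fine = 1.0, fine_halo = 4,
                bore_cells = 3L, wall_cells = 1L, hmax_gap = 0.7,
                hmax_cavity = 3.0, ratio = 1.5,
                dt_injection = 5e-3, dt_withdrawal = 1e-2,
                snapshot_every = 2L, tol_rel = 1e-3,
                max_iter = 30L, relax_u = 0.7, relax_p = 0.3),
    fine = list(name = "fine", hx = 0.5, hx_fine = 0.2, fine_halo = 4,
                 bore_cells = 10L, wall_cells = 3L, hmax_gap = 0.2,
                 hmax_cavity = 0.8, ratio = 1.2,
                 dt_injection = 1e-4, dt_withdrawal = 1e-4,
                 snapshot_every = 100L, tol_rel = 1e-6,
                 max_iter = 60L, relax_u = 0.7, relax_p = 0.3))
}

#' Mesh for the uterus + catheter half-domain
#'
#' Discretizes the half-domain of [uterus_geometry()] into a rectilinear mesh
#' with local refinement around the initial catheter tip position, breakpoints
#' aligned with the catheter bore and wall radii, the cervical half-width and
#' the tube-ostium band.
#'
#' @param geom an `et_geometry`.
#' @param profile a [resolution_profile()] list (or profile name).
#' @param metric mesh metric, see [et_mesh()].
#' @return an `et_mesh` with the geometry attached as attribute `geometry`.
#' @export
uterus_mesh <- function(geom, profile = resolution_profile("coarse"),
                        metric = c("planar", "axisymmetric")) {
  metric <- match.arg(metric)
  if (is.character(profile)) profile <- resolution_profile(profile)
  r_c <- geom$catheter_inner_diameter / 2
  r_o <- geom$catheter_outer_diameter / 2
  w2 <- geom$external_ostium_width / 2
  yb2 <- geom$cavity_base / 2
  tow <- geom$tube_ostium_width
  xf <- geom$x_fundus

  xa <- max(0, geom$tip_x - profile$fine_halo)
  xz <- min(xf, geom$tip_x + profile$fine_halo)
  xb <- unique(c(uniform_breaks(0, xa, profile$hx),
                 uniform_breaks(xa, xz, profile$hx_fine),
                 uniform_breaks(xz, xf, profile$hx)))

  h_wall <- (r_o - r_c) / profile$wall_cells
  yb <- unique(c(seq(0, r_c, length.out = profile$bore_cells + 1L),
                 seq(r_c, r_o, length.out = profile$wall_cells + 1L),
                 grow_breaks(r_o, w2, h_wall * profile$ratio,
                             profile$hmax_gap, profile$ratio),
                 grow_breaks(w2, yb2 - tow, profile$hmax_gap * profile$ratio,
                             profile$hmax_cavity, profile$ratio),
                 yb2))
  m <- et_mesh(xb, yb, metric = metric, unit = "mm")
  attr(m, "geometry") <- geom
  attr(m, "profile") <- profile
  m
}

#' Fluid/solid mask for a catheter position
#'
#' Stair-step blanking: a cell is solid if its center lies outside the domain
#' half-width profile or inside the catheter wall annulus for the current tip
#' position.
#'
#' @param mesh an `et_mesh` built by [uterus_mesh()].
#' @param geom an `et_geometry`.
#' @param tip_x catheter tip position (mm); `NULL` for the resting position.
#' @return logical `nx x ny` matrix, `TRUE` for fluid cells.
#' @export
mask_fluid <- function(mesh, geom, tip_x = NULL) {
  if (is.null(tip_x)) tip_x <- geom$tip_x
  xc <- mesh$xc * 1e3
  yc <- mesh$yc * 1e3
  r_c <- geom$catheter_inner_diameter / 2
  r_o <- geom$catheter_outer_diameter / 2
  inside <- outer(xc, yc, function(x, y) y < geom$half_width(x))
  wall_band <- yc > r_c & yc < r_o
  catheter <- outer(xc < tip_x, wall_band, "&")
  inside & !catheter
}

# face types used by the solver
FACE_WALL <- 1L
FACE_INLET <- 2L
FACE_OUT <- 3L
FACE_SYM <- 4L

#' Face connectivity for a masked mesh
#'
#' Enumerates interior faces (fluid-fluid) and boundary faces (fluid-solid or
#' fluid-domain edge) with their areas, center distances and boundary
#' conditions. Boundary conditions are assigned by two caller-supplied
#' vectorized classifiers, which makes the builder reusable for simple test
#' geometries as well as the uterus domain:
#'
#' * `edge_fun(x, y, nrm_x, nrm_y)` for domain-edge faces, given face
#'   midpoints (m) and outward normals; must return a list/data.frame with
#'   `type` (one of `"wall"`, `"inlet"`, `"outflow"`, `"symmetry"`) and
#'   `uwx`, `uwy` (prescribed face velocity, m/s; used by `"wall"` and
#'   `"inlet"`).
#' * `wall_fun(x, y, dir, sgn)` for internal fluid-solid faces, given the
#'   solid cell center, the face direction (1 = x-normal, 2 = y-normal) and
#'   the outward normal sign; must return `uwx`, `uwy` (the solid wall
#'   velocity at that face, m/s).
#'
#' @param mesh an `et_mesh`.
#' @param fluid logical fluid mask.
#' @param edge_fun,wall_fun boundary classifiers (see Details).
#' @return a list with `interior` and `boundary` face tables, the
#'   equation-index map `eq` (0 for solid cells), `ncell` (number of fluid
#'   cells), and precomputed sparse-assembly index vectors.
#' @keywords internal
#' @export
build_faces <- function(mesh, fluid, edge_fun, wall_fun = NULL) {
  nx <- mesh$nx; ny <- mesh$ny
  eq <- integer(nx * ny)
  eq[which(fluid)] <- seq_len(sum(fluid))
  ncell <- sum(fluid)
  axis <- mesh$metric == "axisymmetric"
  ryc <- if (axis) mesh$yc else rep(1, ny)
  ryb <- if (axis) mesh$yb else rep(1, ny + 1L)
  if (is.null(wall_fun)) {
    wall_fun <- function(x, y, dir, sgn) list(uwx = numeric(length(x)),
                                              uwy = numeric(length(x)))
  }
  cid <- function(i, j) i + (j - 1L) * nx

  int <- list(o = integer(0), n = integer(0), A = numeric(0),
              delta = numeric(0), w = numeric(0), dir = integer(0))
  bnd <- list(c = integer(0), A = numeric(0), dhalf = numeric(0),
              dir = integer(0), sgn = numeric(0), type = integer(0),
              uwx = numeric(0), uwy = numeric(0), alpha_in = numeric(0))
  push_int <- function(o, n, A, delta, w, dir) {
    int$o <<- c(int$o, o); int$n <<- c(int$n, n); int$A <<- c(int$A, A)
    int$delta <<- c(int$delta, delta); int$w <<- c(int$w, w)
    int$dir <<- c(int$dir, rep(dir, length(o)))
  }
  push_bnd <- function(c_, A, dhalf, dir, sgn, type, uwx, uwy,
                       alpha_in = 0) {
    k <- length(c_)
    bnd$c <<- c(bnd$c, c_); bnd$A <<- c(bnd$A, A)
    bnd$dhalf <<- c(bnd$dhalf, dhalf)
    bnd$dir <<- c(bnd$dir, rep(dir, k)); bnd$sgn <<- c(bnd$sgn, rep(sgn, k))
    bnd$type <<- c(bnd$type, rep_len(type, k))
    bnd$uwx <<- c(bnd$uwx, rep_len(uwx, k)); bnd$uwy <<- c(bnd$uwy, rep_len(uwy, k))
    bnd$alpha_in <<- c(bnd$alpha_in, rep_len(alpha_in, k))
  }
  type_code <- function(type) {
    m <- c(wall = FACE_WALL, inlet = FACE_INLET, outflow = FACE_OUT,
           symmetry = FACE_SYM)
    unname(m[type])
  }
  push_edge <- function(idx, i, j, A, dhalf, dir, sgn, nx_, ny_) {
    if (!length(idx)) return(invisible())
    i <- i[idx]; j <- j[idx]
    xf <- if (dir == 1L) mesh$xb[i + (sgn + 1L) / 2] else mesh$xc[i]
    yf <- if (dir == 2L) mesh$yb[j + (sgn + 1L) / 2] else mesh$yc[j]
    bc <- edge_fun(xf, yf, rep(nx_, length(i)), rep(ny_, length(i)))
    ain <- if (is.null(bc$alpha)) 0 else bc$alpha
    push_bnd(cid(i, j), A[idx], dhalf[idx], dir, sgn,
             type_code(bc$type), bc$uwx, bc$uwy, ain)
  }

  # ---- x-direction interior/internal-wall faces --------------------------
  if (nx > 1L) {
    g <- expand.grid(i = 1:(nx - 1L), j = 1:ny)
    i <- g$i; j <- g$j
    oF <- fluid[cbind(i, j)]; nF <- fluid[cbind(i + 1L, j)]
    A <- mesh$dy[j] * ryc[j]
    both <- which(oF & nF)
    if (length(both)) {
      push_int(cid(i, j)[both], cid(i + 1L, j)[both], A[both],
               (mesh$dx[i] + mesh$dx[i + 1L])[both] / 2,
               (mesh$dx[i + 1L] / (mesh$dx[i] + mesh$dx[i + 1L]))[both], 1L)
    }
    os <- which(oF & !nF)   # fluid west of solid: outward normal +x
    if (length(os)) {
      w <- wall_fun(mesh$xc[i + 1L][os], mesh$yc[j][os], 1L, +1)
      push_bnd(cid(i, j)[os], A[os], mesh$dx[i][os] / 2, 1L, +1,
               FACE_WALL, w$uwx, w$uwy)
    }
    so <- which(!oF & nF)   # fluid east of solid: outward normal -x
    if (length(so)) {
      w <- wall_fun(mesh$xc[i][so], mesh$yc[j][so], 1L, -1)
      push_bnd(cid(i + 1L, j)[so], A[so], mesh$dx[i + 1L][so] / 2, 1L, -1,
               FACE_WALL, w$uwx, w$uwy)
    }
  }
  # ---- y-direction interior/internal-wall faces --------------------------
  if (ny > 1L) {
    g <- expand.grid(i = 1:nx, j = 1:(ny - 1L))
    i <- g$i; j <- g$j
    oF <- fluid[cbind(i, j)]; nF <- fluid[cbind(i, j + 1L)]
    A <- mesh$dx[i] * ryb[j + 1L]
    both <- which(oF & nF)
    if (length(both)) {
      push_int(cid(i, j)[both], cid(i, j + 1L)[both], A[both],
               (mesh$dy[j] + mesh$dy[j + 1L])[both] / 2,
               (mesh$dy[j + 1L] / (mesh$dy[j] + mesh$dy[j + 1L]))[both], 2L)
    }
    os <- which(oF & !nF)
    if (length(os)) {
      w <- wall_fun(mesh$xc[i][os], mesh$yc[j + 1L][os], 2L, +1)
      push_bnd(cid(i, j)[os], A[os], mesh$dy[j][os] / 2, 2L, +1,
               FACE_WALL, w$uwx, w$uwy)
    }
    so <- which(!oF & nF)
    if (length(so)) {
      w <- wall_fun(mesh$xc[i][so], mesh$yc[j][so], 2L, -1)
      push_bnd(cid(i, j + 1L)[so], A[so], mesh$dy[j + 1L][so] / 2, 2L, -1,
               FACE_WALL, w$uwx, w$uwy)
    }
  }
  # ---- domain-edge faces -------------------------------------------------
  j <- 1:ny
  push_edge(which(fluid[1, ]), rep(1L, ny), j, mesh$dy * ryc,
            rep(mesh$dx[1] / 2, ny), 1L, -1L, -1, 0)
  push_edge(which(fluid[nx, ]), rep(nx, ny), j, mesh$dy * ryc,
            rep(mesh$dx[nx] / 2, ny), 1L, +1L, +1, 0)
  i <- 1:nx
  push_edge(which(fluid[, 1]), i, rep(1L, nx), mesh$dx * ryb[1],
            rep(mesh$dy[1] / 2, nx), 2L, -1L, 0, -1)
  push_edge(which(fluid[, ny]), i, rep(ny, nx), mesh$dx * ryb[ny + 1L],
            rep(mesh$dy[ny] / 2, nx), 2L, +1L, 0, +1)

  # sparse-assembly index maps (momentum/pressure share the structure)
  eo <- eq[int$o]; en <- eq[int$n]; ec <- eq[bnd$c]
  tri_i <- c(eo, eo, en, en); tri_j <- c(eo, en, en, eo)
  n <- ncell
  nint <- length(eo); nbnd <- length(ec)
  # accumulation operators: cell sums over interior-owner, interior-neighbor
  # and boundary faces as sparse matvecs
  So <- sparseMatrix(i = eo, j = seq_len(nint), x = 1, dims = c(n, nint))
  Sn <- sparseMatrix(i = en, j = seq_len(nint), x = 1, dims = c(n, nint))
  Sc <- sparseMatrix(i = ec, j = seq_len(nbnd), x = 1, dims = c(n, nbnd))
  # assembly template: triplets (tri + diagonal) -> nonzero slots of the
  # column-compressed pattern, so each iteration only fills @x
  ti <- c(tri_i, seq_len(n)); tj <- c(tri_j, seq_len(n))
  tmpl <- sparseMatrix(i = ti, j = tj, x = 0, dims = c(n, n))
  key <- (tj - 1) * n + ti
  pos <- match(key, sort(unique(key)))
  Sasm <- sparseMatrix(i = pos, j = seq_along(pos), x = 1,
                       dims = c(length(tmpl@x), length(pos)))
  list(interior = int, boundary = bnd, eq = eq, ncell = ncell,
       eo = eo, en = en, ec = ec, tri_i = tri_i, tri_j = tri_j,
       So = So, Sn = Sn, Sc = Sc, tmpl = tmpl, Sasm = Sasm)
}
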