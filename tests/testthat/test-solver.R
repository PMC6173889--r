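test_that("a quiescent closed field is an equilibrium of the flow step", {
  mesh <- et_mesh(seq(0, 10, 1), seq(0, 5, 1), metric = "planar")
  fluid <- matrix(TRUE, mesh$nx, mesh$ny)
  walls <- function(x, y, nx_, ny_) {
    list(type = rep("wall", length(x)), uwx = numeric(length(x)),
         uwy = numeric(length(x)))
  }
  faces <- build_faces(mesh, fluid, walls)
  st <- flow_init(mesh, fluid, 0.3)
  phases <- list(phase1 = fluid_phase(1000, 0.001), phase2 = uterine_fluid())
  set <- solver_settings(dt = 0.01, tol_rel = 1e-6, max_iter = 10)
  for (k in 1:3) st <- advance_flow(st, mesh, faces, phases, set)
  expect_lt(max(abs(st$u)), 1e-12)
  expect_lt(max(abs(st$v)), 1e-12)
  expect_equal(unique(as.vector(st$alpha)), 0.3)
})

test_that("axisymmetric metric reproduces pipe Poiseuille flow", {
  ch <- channel_setup(L_mm = 20, h_mm = 1, nxc = 40, nyc = 20,
                      metric = "axisymmetric")
  st <- run_to_steady(ch)
  icol <- round(0.8 * ch$mesh$nx)
  prof <- st$u[icol, ]
  R <- max(ch$mesh$yb)
  exact <- 2 * 0.01 * (1 - (ch$mesh$yc / R)^2)    # parabolic, peak 2x mean
  expect_lt(max(abs(prof - exact)) / max(exact), 0.03)
})

test_that("implicit upwind advection matches a 1D oracle and stays monotone", {
  # uniform plug flow between two symmetry (free-slip) planes
  nxc <- 40L
  mesh <- et_mesh(seq(0, 40, 1), seq(0, 2, 0.5), metric = "planar")
  fluid <- matrix(TRUE, mesh$nx, mesh$ny)
  U <- 0.02
  edge <- function(x, y, nx_, ny_) {
    k <- length(x)
    type <- rep("symmetry", k)
    uwx <- numeric(k)
    type[nx_ < 0] <- "inlet"; uwx[nx_ < 0] <- U
    type[nx_ > 0] <- "outflow"
    list(type = type, uwx = uwx, uwy = numeric(k), alpha = 1)
  }
  faces <- build_faces(mesh, fluid, edge)
  phases <- list(phase1 = fluid_phase(1000, 0.01),
                 phase2 = fluid_phase(1000, 0.01))
  st <- flow_init(mesh, fluid, 0)
  st$u[] <- U
  st$alpha[mesh$xc < 10e-3, ] <- 1                # sharp step at x = 10 mm
  dt <- 0.02                                      # CFL = U dt/dx = 0.4
  set <- solver_settings(dt = dt, tol_rel = 1e-8, max_iter = 40)
  nstep <- 10L
  for (k in seq_len(nstep)) st <- advance_flow(st, mesh, faces, phases, set)
  expect_lt(max(abs(st$u - U)), 1e-10)            # flow stays uniform plug

  # dense 1D implicit-upwind oracle with the same U, dx, dt
  a0 <- as.numeric(mesh$xc < 10e-3)
  dx <- mesh$dx[1]
  n <- mesh$nx
  A <- diag(1 + U * dt / dx, n)
  for (i in 2:n) A[i, i - 1] <- -U * dt / dx
  a <- a0
  for (k in seq_len(nstep)) {
    b <- a; b[1] <- b[1] + U * dt / dx * 1        # inlet alpha = 1
    a <- solve(A, b)
  }
  for (j in seq_len(mesh$ny)) {
    expect_equal(st$alpha[, j], a, tolerance = 1e-6)
  }
  expect_true(all(diff(st$alpha[, 1]) <= 1e-12))  # monotone, no new extrema
  expect_true(all(st$alpha >= 0 & st$alpha <= 1))
  # the half-value point has translated downstream at speed U
  f <- st$alpha[, 1]
  i0 <- max(which(f > 0.5))
  x_half <- mesh$xc[i0] + (f[i0] - 0.5) / (f[i0] - f[i0 + 1]) *
    (mesh$xc[i0 + 1] - mesh$xc[i0])
  expect_equal(x_half * 1e3, 10 + U * dt * nstep * 1e3, tolerance = 0.15)
})

test_that("the injection run is divergence-consistent and laminar", {
  r <- mini_injection_run(1)
  b <- r$budget
  # the impulsive start stops at the sweep cap; established flow converges
  expect_true(all(b$res[b$t > 0.1] < 2e-3))
  # bore Reynolds number of the reference case stays in the laminar regime
  u <- inlet_velocity(20, 1, 0.3) * 1e-3
  re <- 1000 * u * 6e-4 / 0.001
  expect_gt(re, 10); expect_lt(re, 100)
})
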