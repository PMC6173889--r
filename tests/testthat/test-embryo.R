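test_that("initial embryo layout divides the bore into equal-area zones", {
  y <- initial_positions(0.3, 0.05)
  expect_length(y, 10)
  r <- sqrt(1:10 / 10) * 0.25
  expect_equal(r[10], 0.25)                       # outermost circle
  expect_equal(y[1], sqrt(0.1) * 0.25 / 2)        # ~0.0395 mm
  expect_equal(y, (c(0, r[1:9]) + r) / 2)
  zones <- diff(c(0, r)^2) * pi                   # annulus areas
  expect_equal(zones, rep(pi * 0.25^2 / 10, 10))
  expect_true(all(diff(y) > 0))
  expect_error(initial_positions(0.3, 0.3), "r_c")
})

test_that("relative Reynolds number follows its definition", {
  expect_equal(relative_reynolds(1000, 0.001, 5e-5, slip = 0), 0)
  expect_equal(relative_reynolds(1000, 0.001, 5e-5, slip = 0.0707), 7.07)
  expect_equal(relative_reynolds(1000, 0.001, 1e-4, slip = 0.0707),
               2 * relative_reynolds(1000, 0.001, 5e-5, slip = 0.0707))
  expect_equal(relative_reynolds(1000, 0.001, 5e-5,
                                 v_e = c(0.1, 0), u_m = c(0.1, 0)), 0)
})

test_that("drag coefficient matches the Stokes law at low Re and is near-continuous", {
  expect_equal(drag_coefficient(0.05), 24 / 0.05)      # 480
  expect_equal(drag_coefficient(0.01), 2400)
  tab <- etflow:::morsi_alexander_table()
  cd <- function(row, re) tab$a1[row] + tab$a2[row] / re + tab$a3[row] / re^2
  for (row in 1:(nrow(tab) - 1)) {
    bp <- tab$re_max[row]
    jump <- abs(cd(row, bp) - cd(row + 1, bp)) / cd(row, bp)
    expect_lt(jump, 0.05)
  }
  # increasing Re spans every band without gaps
  re <- 10^seq(-3, 5, length.out = 200)
  expect_true(all(is.finite(drag_coefficient(re))))
})

test_that("drag response has the Stokes limit and a factor-2 form toggle", {
  em <- embryo_params()
  b_std <- drag_response(0.799, 1259.9, 0, em, "standard")
  b_pap <- drag_response(0.799, 1259.9, 0, em, "doubled")
  expect_equal(b_std, 9 * 0.799 / (2 * 1000 * (5e-5)^2))   # ~1.44e6 1/s
  expect_equal(b_pap / b_std, 2)
  # zero slip leaves the velocity unchanged whatever the form
  s <- step_embryo(c(0, 0), c(0.01, 0),
                   list(u = 0.01, v = 0, rho = 1000, mu = 0.001),
                   1e-4, em, "doubled")
  expect_equal(s$vel, c(0.01, 0))
  expect_equal(s$pos, c(0.01 * 1e-4, 0))                   # straight line
})

test_that("embryos reach the tracer limit when beta*dt is large", {
  em <- embryo_params()
  fl <- list(u = 0.05, v = 0.02, rho = 1259.9, mu = 0.799)
  s <- step_embryo(c(0, 0), c(0, 0), fl, 1e-4, em)
  expect_gt(s$beta * 1e-4, 10)
  slip <- sqrt(sum((s$vel - c(fl$u, fl$v))^2)) / sqrt(fl$u^2 + fl$v^2)
  expect_lt(slip, 1e-3)
})

test_that("delivery sites are insensitive to the drag-form toggle", {
  r_std <- mini_injection_run(1)
  r_pap <- mini_injection_run(1, drag_form = "doubled")
  a <- r_std$summary$per_embryo
  b <- r_pap$summary$per_embryo
  expect_lt(max(abs(a$axial - b$axial)), 0.5)     # well under one cell
  expect_lt(max(abs(a$radial - b$radial)), 0.5)
})

test_that("bilinear interpolation is exact for linear fields and clamps at walls", {
  mesh <- et_mesh(seq(0, 10, 1), seq(0, 5, 1), metric = "planar")
  fluid <- matrix(TRUE, mesh$nx, mesh$ny)
  f <- outer(mesh$xc, mesh$yc, function(x, y) 2 + 3 * x - 4 * y)
  xs <- c(2.3e-3, 7.1e-3); ys <- c(1.2e-3, 3.9e-3)
  expect_equal(interp_field(mesh, fluid, f, xs, ys), 2 + 3 * xs - 4 * ys)
  # a solid quadrant is excluded from the weights
  fluid[, 4:5] <- FALSE
  v <- interp_field(mesh, fluid, f, 5e-3, 3.4e-3)
  expect_equal(v, 2 + 3 * 5e-3 - 4 * 2.5e-3)      # clamped to nearest row
})
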