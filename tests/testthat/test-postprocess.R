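test_that("contour extraction handles trivial, step and disc fields", {
  mesh <- et_mesh(seq(0, 10, 0.5), seq(0, 10, 0.5), metric = "planar")
  ones <- matrix(1, mesh$nx, mesh$ny)
  expect_length(dispersion_contour(ones, mesh), 0)

  step <- outer(mesh$xc < 5e-3, rep(TRUE, mesh$ny)) * 1
  cs <- dispersion_contour(step, mesh)
  expect_gt(length(cs), 0)
  xs <- unlist(lapply(cs, `[[`, "x"))
  expect_true(all(abs(xs - 5) < 1e-9))            # midpoint of 1 -> 0 edge

  # disc of radius R at 20 cells per R: enclosed area within 2% of pi R^2
  R <- 5
  mesh2 <- et_mesh(seq(-7.5, 7.5, R / 20), seq(-7.5, 7.5, R / 20),
                   metric = "planar")
  disc <- outer(mesh2$xc, mesh2$yc,
                function(x, y) (x^2 + y^2 < (R * 1e-3)^2) * 1)
  cs2 <- dispersion_contour(disc, mesh2)
  expect_length(cs2, 1)
  expect_lt(abs(contour_area(cs2) - pi * R^2) / (pi * R^2), 0.02)
})

test_that("upstream/downstream classification uses the tip plane with a tie-break", {
  expect_identical(classify_region(70, 60), "downstream")
  expect_identical(classify_region(40, 60), "upstream")
  expect_identical(classify_region(60, 60), "upstream")  # boundary convention
})

test_that("transport distances are measured relative to the catheter tip", {
  traj <- data.frame(t = 1, id = 1:10,
                     x = c(64.41, rep(60, 9)),
                     y = c(3.27, seq(-1, 1, length.out = 9)),
                     status = "downstream")
  s <- transport_distances(traj, tip_x = 60, t_ref = 1)
  expect_equal(s$per_embryo$axial[1], 4.41)
  expect_equal(s$per_embryo$radial[1], 3.27)
  expect_identical(s$per_embryo$region[1], "downstream")
  # mirror symmetry: radial distances use the absolute offset
  traj2 <- traj; traj2$y <- -traj2$y
  s2 <- transport_distances(traj2, tip_x = 60, t_ref = 1)
  expect_equal(s2$mean_radial, s$mean_radial)
  expect_equal(s2$mean_axial, s$mean_axial)
})

test_that("driving force integrates the inlet pressure over the bore area", {
  fake <- structure(list(
    geometry = uterus_geometry(),
    budget = data.frame(t = c(0.5, 1), phase = "injection",
                        p_inlet = c(2000, 1000))), class = "et_run")
  f <- driving_force(fake)
  expect_equal(f$p_mean, 1500)
  expect_equal(f$force, 1500 * pi * (3e-4)^2)
  expect_equal(f$force_peak, 2000 * pi * (3e-4)^2)
  expect_equal(f$force_per_depth, 1500 * 6e-4)
  fake$budget$p_inlet <- 0
  expect_equal(driving_force(fake)$force, 0)
})

test_that("drag-back defaults to zero without a withdrawal phase", {
  r <- mini_injection_run(1)
  wd <- withdrawal_dragback(r)
  expect_equal(wd$dragback, 0)
  expect_identical(wd$n_entered_cervix, 0L)
})

test_that("summaries recomputed from the trajectory table match the stored ones", {
  r <- mini_injection_run(1)
  s1 <- r$summary
  s2 <- transport_distances(r$trajectories, tip_x = r$geometry$tip_x,
                            t_ref = r$config$injection_time)
  expect_equal(s2$per_embryo$axial, s1$per_embryo$axial)
  expect_equal(s2$per_embryo$radial, s1$per_embryo$radial)
  expect_equal(s2$mean_axial, s1$mean_axial)
})
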