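test_that("built-in cases reproduce the tabulated parameter settings", {
  c1 <- builtin_case(1)
  expect_equal(c1$phase1$viscosity, 0.001)
  expect_equal(c1$phase1$density, 1000)
  expect_equal(c1$injection_time, 1)
  expect_true(c1$withdrawal)                      # reference case
  c7 <- builtin_case(7)
  expect_equal(c7$phase1$viscosity, c7$phase2$viscosity)  # equal viscosity
  expect_equal(c7$phase1$density, c7$phase2$density)
  c9 <- builtin_case(9)
  expect_equal(c9$phase1$viscosity, 0.799)
  expect_equal(c9$injection_time, 15)
  expect_false(builtin_case(2)$withdrawal)
  expect_error(builtin_case(10), "1..9")
  tab <- builtin_case_table()
  expect_equal(tab$mu1,
               c(0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 0.799, 0.001, 0.799))
  expect_equal(tab$rho1,
               c(1000, 1001.3, 1002.9, 1016, 1032.2, 1162.5, 1259.9,
                 1000, 1259.9))
  expect_equal(c1$injected_volume, 20)            # same volume in all cases
})

test_that("runs are deterministic: identical configs give identical results", {
  cfg <- case_config(phase1 = fluid_phase(1000, 0.001), injection_time = 0.2,
                     profile = "mini")
  r1 <- run_case(cfg)
  r2 <- run_case(cfg)
  expect_identical(r1$trajectories, r2$trajectories)
  expect_identical(r1$final$alpha, r2$final$alpha)
  expect_identical(r1$summary$mean_axial, r2$summary$mean_axial)
})

test_that("embryos start on the catheter axis-parallel line 10 mm behind the tip", {
  r <- mini_injection_run(1)
  t0 <- r$trajectories[r$trajectories$t == 0, ]
  expect_equal(t0$x, rep(50, 10))                 # 60 - 10 mm
  expect_equal(t0$y, initial_positions(0.3, 0.05))
  expect_true(all(t0$status == "in_catheter"))
  # trajectories inside the bore stay parallel to the axis
  t1 <- traj_at(r$trajectories, 0.05)
  inside <- t1$x < 60 & t1$y < 0.3
  expect_gt(sum(inside), 0)
  expect_equal(t1$y[inside], t0$y[inside], tolerance = 1e-3)
})

test_that("delivery regions follow the viscosity contrast", {
  s1 <- coarse_full_run(1)$summary
  expect_gt(s1$n_upstream, 0)                     # low viscosity spreads back
  s7 <- coarse_full_run(7)$summary
  expect_equal(s7$n_downstream, 10L)              # equal viscosity: all ahead
})

test_that("translating withdrawal retracts the catheter and frees the mask", {
  cfg <- case_config(phase1 = fluid_phase(1000, 0.001), injection_time = 0.1,
                     withdrawal = TRUE, withdrawal_mode = "translating",
                     withdrawal_duration = 0.5, profile = "mini")
  r <- run_case(cfg)
  wb <- r$budget[r$budget$phase == "withdrawal", ]
  expect_true(all(diff(wb$tip_x) < 0))            # tip marches to the cervix
  expect_lt(wb$tip_x[nrow(wb)], 0)                # fully out at this speed
  cervix <- outer(r$mesh$xc * 1e3 > 0 & r$mesh$xc * 1e3 < 25,
                  r$mesh$yc * 1e3 < 2, "&")
  fl_end <- mask_fluid(r$mesh, r$geometry, wb$tip_x[nrow(wb)])
  expect_true(all(fl_end[cervix]))                # canal free of the catheter
  expect_true(is.finite(withdrawal_dragback(r, 0.1, 0.6)$dragback))
})

test_that("run artifacts export to plain-text files", {
  r <- mini_injection_run(1)
  dir <- withr::local_tempdir()
  export_run(r, dir)
  expect_true(file.exists(file.path(dir, "trajectories.csv")))
  expect_true(file.exists(file.path(dir, "summary.csv")))
  expect_true(file.exists(file.path(dir, "config.yml")))
  vtk <- list.files(dir, pattern = "\\.vtk$")
  expect_gt(length(vtk), 0)
  tr <- utils::read.csv(file.path(dir, "trajectories.csv"))
  expect_identical(nrow(tr), nrow(r$trajectories))
})
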