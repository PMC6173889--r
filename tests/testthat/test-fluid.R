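test_that("mixture properties blend linearly in the volume fraction", {
  p1 <- fluid_phase(1000, 0.001)
  p2 <- uterine_fluid()
  expect_equal(mixture_properties(1, p1, p2), list(rho = 1000, mu = 0.001))
  expect_equal(mixture_properties(0, p1, p2), list(rho = 1259.9, mu = 0.799))
  mid <- mixture_properties(0.5, p1, p2)
  expect_equal(mid$rho, 1129.95)
  expect_equal(mid$mu, 0.400)
  expect_error(mixture_properties(1.2, p1, p2), "alpha")
  expect_error(fluid_phase(-1, 0.1))
})

test_that("injection speed scales inversely with time and bore area", {
  u <- inlet_velocity(20, 1, 0.3)
  expect_equal(inlet_velocity(20, 2, 0.3), u / 2)
  expect_equal(inlet_velocity(20, 1, 0.6), u / 4)
  expect_error(inlet_velocity(20, 0, 0.3))
})

test_that("solver settings validate their controls", {
  s <- solver_settings()
  expect_equal(s$dt, 1e-4)
  expect_equal(s$snapshot_every, 100L)
  expect_error(solver_settings(dt = 0))
  expect_error(solver_settings(relax_u = 1.5))
})
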