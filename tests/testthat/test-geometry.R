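test_that("default geometry places the catheter tip and openings correctly", {
  g <- uterus_geometry()
  expect_equal(g$tip_x, 60)                       # 25 + 50 - 15
  expect_equal(g$x_fundus, 75)
  ost <- g$openings$tube_ostium
  expect_equal(ost$x, 75)
  expect_equal(ost$ymax - ost$ymin, 0.3)
  expect_equal(ost$ymax, 16)                      # lateral end of the base
  expect_equal(g$openings$inlet$ymax, 0.3)        # half of the 0.6 mm bore
  expect_equal(g$half_width(0), 2)                # cervical half-channel
  expect_equal(g$half_width(75), 16)
})

test_that("degenerate geometries are rejected with a message", {
  expect_error(uterus_geometry(tip_fundus_distance = 50), "apex")
  expect_error(uterus_geometry(cavity_height = -1), "positive")
  expect_error(uterus_geometry(catheter_outer_diameter = 0.5), "exceed")
})

test_that("catheter position follows the constant-speed withdrawal protocol", {
  g <- uterus_geometry()
  p0 <- catheter_position(0, g, t_inj = 1)
  expect_equal(p0$offset, 0)
  expect_equal(p0$wall_velocity, 0)
  ph <- catheter_position(1 + 2.5, g, t_inj = 1)
  expect_equal(ph$offset, 81 / 2)                 # half the travel
  expect_equal(ph$wall_velocity, -81 / 5)
  pe <- catheter_position(1 + 5, g, t_inj = 1)
  expect_lte(pe$tip_x, 0)                         # fully clear of the ostium
  expect_equal(catheter_position(3, g, t_inj = 1,
                                 withdrawal = FALSE)$offset, 0)
})

test_that("masked mesh area converges to the continuum half-domain area", {
  g <- uterus_geometry()
  area <- geometry_area(g)
  expect_equal(area, 450.25, tolerance = 1e-9)    # shoelace minus catheter
  err <- vapply(c(1, 2, 4), function(s) {
    p <- resolution_profile("mini")
    p$hx <- p$hx / s; p$hx_fine <- p$hx_fine / s
    p$hmax_gap <- p$hmax_gap / s; p$hmax_cavity <- p$hmax_cavity / s
    p$bore_cells <- as.integer(p$bore_cells * s)
    p$wall_cells <- as.integer(p$wall_cells * s)
    m <- uterus_mesh(g, p, "planar")
    fl <- mask_fluid(m, g)
    abs(sum(outer(m$dx, m$dy)[fl]) * 1e6 - area) / area
  }, numeric(1))
  expect_true(all(err < 0.05))
  # stair-step masking: error shrinks with refinement (individual levels can
  # benefit from fortuitous breakpoint alignment, so compare end points)
  expect_lt(err[3], err[1] / 2)
})

test_that("mask and boundary tags resolve the catheter and openings", {
  g <- uterus_geometry()
  m <- uterus_mesh(g, "mini", "planar")
  fl <- mask_fluid(m, g)
  expect_equal(m$yb[1], 0)                        # symmetry plane at y = 0
  band <- m$yc * 1e3 > 0.3 & m$yc * 1e3 < 0.4
  cath <- outer(m$xc * 1e3 < g$tip_x, band, "&")
  expect_false(any(fl & cath))                    # no fluid in the annulus
  u_in <- inlet_velocity(20, 1, 0.3) * 1e-3
  fc <- build_faces(m, fl,
                    etflow:::uterus_edge_bc(g, "planar", "injection", u_in,
                                            0, g$tip_x * 1e-3, "plug"),
                    etflow:::uterus_wall_bc(g, 0, g$tip_x * 1e-3))
  bd <- fc$boundary
  inlet <- bd$type == etflow:::FACE_INLET
  expect_equal(sum(bd$A[inlet]) * 1e3, 0.3, tolerance = 1e-9)
  expect_true(all(bd$type %in% 1:4))              # exhaustive tagging
  out_x <- m$xc[(bd$c[bd$type == etflow:::FACE_OUT] - 1L) %% m$nx + 1L]
  expect_true(all(out_x < 2e-3 | out_x > 73e-3))  # outflows only at ostia
})

test_that("displacing the tip by one cell pitch shifts the solid mask by one column", {
  g <- uterus_geometry()
  m <- uterus_mesh(g, "coarse", "planar")
  s1 <- !mask_fluid(m, g, 60)
  s2 <- !mask_fluid(m, g, 59.5)                   # one fine-pitch step back
  changed <- which(s1 != s2, arr.ind = TRUE)
  expect_gt(nrow(changed), 0)
  expect_equal(length(unique(changed[, 1])), 1L)  # a single column
  expect_equal(m$xc[unique(changed[, 1])] * 1e3, 59.75, tolerance = 1e-9)
})
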