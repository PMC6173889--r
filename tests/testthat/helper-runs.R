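# shared, lazily-computed simulation runs (the heavy fixtures); cached so
# that acceptance and module tests reuse the same deterministic results
the_cache <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (is.null(the_cache[[key]])) assign(key, maker(), envir = the_cache)
  get(key, envir = the_cache)
}

# injection-only run at the reduced (mini) resolution profile
mini_injection_run <- function(i, ...) {
  key <- paste0("mini_inj_", i, "_", paste(c(...), collapse = "_"))
  cached(key, function() {
    run_case(builtin_case(i, withdrawal = FALSE, profile = "mini", ...))
  })
}

# full injection + withdrawal run at the coarse (default) profile
coarse_full_run <- function(i) {
  cached(paste0("coarse_full_", i), function() {
    run_case(builtin_case(i, withdrawal = TRUE, profile = "coarse"))
  })
}

mini_trend_table <- function() {
  cached("mini_trend", function() {
    summarize_cases(lapply(1:7, mini_injection_run))
  })
}

# straight planar channel: half-channel of height h_mm with symmetry at
# y = 0, no-slip wall at y = h, plug inlet (speed u_in m/s) at x = 0 and a
# fixed-pressure outflow at x = L
channel_setup <- function(L_mm = 20, h_mm = 1, nxc = 40, nyc = 20,
                          u_in = 0.01, mu = 0.05, rho = 1000,
                          metric = "planar") {
  mesh <- et_mesh(seq(0, L_mm, length.out = nxc + 1),
                  seq(0, h_mm, length.out = nyc + 1),
                  metric = metric, unit = "mm")
  fluid <- matrix(TRUE, mesh$nx, mesh$ny)
  edge <- function(x, y, nx_, ny_) {
    k <- length(x)
    type <- rep("wall", k)
    uwx <- numeric(k); uwy <- numeric(k)
    type[nx_ < 0] <- "inlet"; uwx[nx_ < 0] <- u_in
    type[nx_ > 0] <- "outflow"
    type[ny_ < 0] <- "symmetry"
    list(type = type, uwx = uwx, uwy = uwy, alpha = 1)
  }
  list(mesh = mesh, fluid = fluid,
       faces = build_faces(mesh, fluid, edge),
       phases = list(phase1 = fluid_phase(rho, mu),
                     phase2 = fluid_phase(rho, mu)))
}

run_to_steady <- function(setup, dt = 0.05, nstep = 40, tol = 1e-4) {
  st <- flow_init(setup$mesh, setup$fluid, 1)
  set <- solver_settings(dt = dt, tol_rel = tol, max_iter = 80)
  for (i in seq_len(nstep)) {
    st <- advance_flow(st, setup$mesh, setup$faces, setup$phases, set,
                       advect_alpha = FALSE)
  }
  st
}
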