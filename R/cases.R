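#' Case configuration
#'
#' Bundles everything one simulation needs: the two fluid phases, injected
#' volume and time, withdrawal protocol, geometry, embryo parameters, drag
#' form, mesh/time-stepping profile and metric.
#'
#' @param phase1 transferred-medium [fluid_phase()].
#' @param injection_time injection duration (s).
#' @param phase2 uterine-fluid [fluid_phase()].
#' @param injected_volume transferred volume (microlitres).
#' @param withdrawal simulate the 5 s catheter withdrawal after injection.
#' @param withdrawal_duration withdrawal duration (s).
#' @param withdrawal_distance catheter travel during withdrawal (mm);
#'   defaults to `catheter_length_in_cavity + cervix_length`. Together with
#'   the duration it sets the withdrawal wall speed.
#' @param withdrawal_mode `"sliding"` (default) keeps the catheter geometry
#'   in place and imposes the withdrawal speed as a moving-wall velocity on
#'   the tip, inner and outer catheter walls for the whole withdrawal, the
#'   way a wall-velocity boundary condition on a static mesh behaves;
#'   `"translating"` physically retracts the catheter as a time-dependent
#'   solid mask, with the vacated volume accounted for through moving-wall
#'   normal fluxes. See the methods vignette for the trade-off.
#' @param geometry an [uterus_geometry()].
#' @param embryo an [embryo_params()].
#' @param drag_form `"standard"` or `"doubled"`, see [drag_response()].
#' @param inlet_profile `"plug"` or `"parabolic"` inlet velocity shape.
#' @param profile a [resolution_profile()] or its name.
#' @param metric mesh metric, see [et_mesh()].
#' @param case_index optional index label (1-9 for the built-in cases).
#' @return an object of class `et_case`.
#' @export
case_config <- function(phase1, injection_time,
                        phase2 = uterine_fluid(),
                        injected_volume = 20,
                        withdrawal = FALSE,
                        withdrawal_duration = 5,
                        withdrawal_distance = NULL,
                        withdrawal_mode = c("sliding", "translating"),
                        geometry = uterus_geometry(),
                        embryo = embryo_params(),
                        drag_form = c("standard", "doubled"),
                        inlet_profile = c("plug", "parabolic"),
                        profile = "coarse",
                        metric = c("planar", "axisymmetric"),
                        case_index = NA_integer_) {
  drag_form <- match.arg(drag_form)
  inlet_profile <- match.arg(inlet_profile)
  metric <- match.arg(metric)
  withdrawal_mode <- match.arg(withdrawal_mode)
  if (is.character(profile)) profile <- resolution_profile(profile)
  stopifnot(inherits(phase1, "et_phase"), inherits(phase2, "et_phase"),
            injection_time > 0, injected_volume >= 0)
  if (is.null(withdrawal_distance)) {
    withdrawal_distance <- geometry$catheter_length_in_cavity +
      geometry$cervix_length
  }
  if (embryo$radius >= geometry$catheter_inner_diameter / 2) {
    stop("embryo radius must be smaller than the catheter bore radius")
  }
  structure(list(case_index = case_index, phase1 = phase1, phase2 = phase2,
                 injected_volume = injected_volume,
                 injection_time = injection_time,
                 withdrawal = withdrawal,
                 withdrawal_duration = withdrawal_duration,
                 withdrawal_distance = withdrawal_distance,
                 withdrawal_mode = withdrawal_mode,
                 geometry = geometry, embryo = embryo,
                 drag_form = drag_form, inlet_profile = inlet_profile,
                 profile = profile, metric = metric),
            class = "et_case")
}

#' Table of the nine built-in case parameterizations
#'
#' Transferred-medium viscosity (Pa.s), density (kg/m^3), injection time (s)
#' and group label for the built-in cases of [builtin_case()].
#'
#' @return a data.frame with one row per case.
#' @export
builtin_case_table <- function() {
  data.frame(
    case = 1:9,
    mu1 = c(0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 0.799, 0.001, 0.799),
    rho1 = c(1000, 1001.3, 1002.9, 1016, 1032.2, 1162.5, 1259.9,
             1000, 1259.9),
    t_inj = c(1, 1, 1, 1, 1, 1, 1, 15, 15),
    group = c("reference", "low", "low", "low", "high", "high", "high",
              "slow", "slow"))
}

#' Built-in simulation cases
#'
#' The nine tabulated parameterizations: case 1 is the reference (normal
#' saline, fast 1 s injection), cases 2-7 increase the transferred-medium
#' viscosity up to the equal-viscosity case 7 (identical to the uterine
#' fluid), cases 8-9 repeat cases 1 and 7 with a slow 15 s injection. The
#' transferred volume is 20 microlitres in every case. Withdrawal defaults
#' to on for cases 1 and 7 only.
#'
#' @param i case index, 1 to 9.
#' @param withdrawal override the default withdrawal flag.
#' @param ... further arguments passed to [case_config()].
#' @return an `et_case`.
#' @export
builtin_case <- function(i, withdrawal = NULL, ...) {
  tab <- builtin_case_table()
  if (!(length(i) == 1 && i %in% tab$case)) {
    stop("case index must be one of 1..9")
  }
  r <- tab[tab$case == i, ]
  if (is.null(withdrawal)) withdrawal <- i %in% c(1L, 7L)
  case_config(phase1 = fluid_phase(r$rho1, r$mu1),
              injection_time = r$t_inj,
              withdrawal = withdrawal,
              case_index = as.integer(i), ...)
}

# inlet velocity shape across the bore: mean-preserving plug or parabolic
inlet_shape <- function(y, r_c, metric, profile) {
  if (profile == "plug") return(rep(1, length(y)))
  s <- 1 - (y / r_c)^2
  if (metric == "axisymmetric") 2 * s else 1.5 * s
}

# boundary classifier factory for the uterus domain edges; in sliding
# withdrawal the bore entrance is a closed stationary wall (the plunger face
# motion is normal to itself and carries no tangential velocity), in
# translating withdrawal it is a receding plunger with prescribed normal flux
uterus_edge_bc <- function(geom, metric, phase, u_in, u_w, tip_x,
                           inlet_profile, mode = "translating") {
  r_c <- geom$catheter_inner_diameter / 2 * 1e-3
  r_o <- geom$catheter_outer_diameter / 2 * 1e-3
  yb2 <- geom$cavity_base / 2 * 1e-3
  tow <- geom$tube_ostium_width * 1e-3
  xf <- geom$x_fundus * 1e-3
  function(x, y, nx_, ny_) {
    k <- length(x)
    type <- rep("wall", k)
    uwx <- numeric(k); uwy <- numeric(k); alpha <- numeric(k)
    left <- nx_ < 0
    right <- nx_ > 0
    bottom <- ny_ < 0
    type[bottom] <- "symmetry"
    cath <- tip_x > 0
    if (any(left)) {
      bore <- left & y < r_c
      if (!cath) {
        type[left] <- "outflow"
      } else {
        type[left & !bore] <- "outflow"
        if (phase == "injection") {
          type[bore] <- "inlet"
          uwx[bore] <- u_in * inlet_shape(y[bore], r_c, metric,
                                          inlet_profile)
          alpha[bore] <- 1
        } else if (phase == "withdrawal") {
          type[bore] <- "wall"
          uwx[bore] <- if (mode == "translating") u_w else 0
        } else {
          type[bore] <- "wall"   # closed bore, catheter at rest
        }
      }
    }
    if (any(right)) {
      ost <- right & y > (yb2 - tow) & y <= yb2 + 1e-12
      type[ost] <- "outflow"
    }
    list(type = type, uwx = uwx, uwy = uwy, alpha = alpha)
  }
}

# internal solid-wall classifier: catheter walls move during withdrawal.
# Sliding mode carries the wall velocity only on the axial (sliding) faces;
# the tip face motion would be normal to itself and is dropped, as a wall
# velocity on a static boundary acts tangentially. Translating mode keeps
# the normal component on tip faces, which is what accounts for the vacated
# volume of a physically retracting catheter.
uterus_wall_bc <- function(geom, u_w, tip_x, mode = "translating") {
  r_c <- geom$catheter_inner_diameter / 2 * 1e-3
  r_o <- geom$catheter_outer_diameter / 2 * 1e-3
  function(x, y, dir, sgn) {
    in_cath <- y > r_c & y < r_o & x < tip_x
    on <- in_cath & (mode == "translating" | dir == 2L)
    list(uwx = ifelse(on, u_w, 0), uwy = numeric(length(x)))
  }
}

# embryo status from position (m) and tip position (m)
embryo_status <- function(x, y, geom, tip_x) {
  r_c <- geom$catheter_inner_diameter / 2 * 1e-3
  xf <- geom$x_fundus * 1e-3
  yb2 <- geom$cavity_base / 2 * 1e-3
  tow <- geom$tube_ostium_width * 1e-3
  if (x < 0) return("exited_cervix")
  if (x >= xf - 1e-9 && y > (yb2 - tow)) return("exited_tube")
  if (tip_x > 0 && x <= tip_x && y < r_c) return("in_catheter")
  if (x > tip_x) "downstream" else "upstream"
}

# keep an embryo out of solid cells / outside walls; returns corrected
# position and whether a pushback occurred
embryo_pushback <- function(pos, geom, tip_x) {
  x <- pos[1]; y <- abs(pos[2])
  pushed <- FALSE
  r_c <- geom$catheter_inner_diameter / 2 * 1e-3
  r_o <- geom$catheter_outer_diameter / 2 * 1e-3
  eps <- 1e-6
  if (tip_x > 0 && x < tip_x && y > r_c && y < r_o) {
    y_new <- if (y - r_c < r_o - y) r_c - eps else r_o + eps
    y <- max(y_new, 0); pushed <- TRUE
  }
  yw <- geom$half_width(x * 1e3) * 1e-3
  if (x >= 0 && yw > 0 && y > yw - eps) {
    y <- yw - eps; pushed <- TRUE
  }
  xf <- geom$x_fundus * 1e-3
  if (x > xf) { x <- xf - eps; pushed <- TRUE }
  c(x, y, pushed)
}

#' Run one embryo-transfer simulation
#'
#' Simulates injection for `injection_time` (catheter at rest, constant
#' inlet velocity, bore initially filled with transferred medium, cavity
#' with uterine fluid, both at rest), then optionally the 5 s catheter
#' withdrawal (moving-wall catheter translating toward the cervix, bore
#' inlet closed). The ten embryos are tracked inline through the evolving
#' flow, independently of each other and without back-reaction on the flow.
#' Entirely deterministic for a given configuration.
#'
#' @param config an `et_case`.
#' @param store_fields `"final"` (default) keeps the fields at the end of
#'   injection and at the final time; `"cadence"` keeps every snapshot;
#'   `"none"` keeps only the final field.
#' @param verbose print progress lines.
#' @return an object of class `et_run`: the config, mesh, trajectory table
#'   (`t` s, positions mm, velocities mm/s, status), per-step budget log,
#'   stored fields, and the transport summary (see [transport_distances()]).
#' @export
run_case <- function(config, store_fields = c("final", "cadence", "none"),
                     verbose = FALSE) {
  store_fields <- match.arg(store_fields)
  geom <- config$geometry
  prof <- config$profile
  mesh <- uterus_mesh(geom, prof, config$metric)
  phases <- list(phase1 = config$phase1, phase2 = config$phase2)
  r_c <- geom$catheter_inner_diameter / 2
  u_in <- inlet_velocity(config$injected_volume, config$injection_time,
                         r_c) * 1e-3
  t_inj <- config$injection_time

  tip0 <- geom$tip_x * 1e-3
  fluid <- mask_fluid(mesh, geom, geom$tip_x)
  bore <- outer(mesh$xc < tip0, mesh$yc < r_c * 1e-3, "&") & fluid
  state <- flow_init(mesh, fluid, alpha0 = bore * 1)

  # embryos
  y0 <- initial_positions(r_c, config$embryo$radius) * 1e-3
  x0 <- (geom$tip_x - config$embryo$tip_distance) * 1e-3
  pos <- cbind(rep(x0, 10), y0)
  vel <- matrix(0, 10, 2)
  status <- rep("in_catheter", 10)
  pushbacks <- 0L

  traj <- list(); budget <- list(); fields <- list()
  record_traj <- function(t) {
    traj[[length(traj) + 1L]] <<- data.frame(
      t = t, id = 1:10, x = pos[, 1] * 1e3, y = pos[, 2] * 1e3,
      vx = vel[, 1] * 1e3, vy = vel[, 2] * 1e3, status = status)
  }
  step_embryos <- function(dt, tip_x) {
    rho_m <- state$alpha * config$phase1$density +
      (1 - state$alpha) * config$phase2$density
    mu_m <- state$alpha * config$phase1$viscosity +
      (1 - state$alpha) * config$phase2$viscosity
    for (e in 1:10) {
      if (status[e] %in% c("exited_cervix", "exited_tube")) next
      fl <- list(
        u = interp_field(mesh, fluid, state$u, pos[e, 1], pos[e, 2]),
        v = interp_field(mesh, fluid, state$v, pos[e, 1], pos[e, 2]),
        rho = interp_field(mesh, fluid, rho_m, pos[e, 1], pos[e, 2]),
        mu = interp_field(mesh, fluid, mu_m, pos[e, 1], pos[e, 2]))
      if (fl$mu <= 0) fl$mu <- config$phase2$viscosity
      if (fl$rho <= 0) fl$rho <- config$phase2$density
      st <- step_embryo(pos[e, ], vel[e, ], fl, dt, config$embryo,
                        config$drag_form)
      pb <- embryo_pushback(st$pos, geom, tip_x)
      if (pb[3] > 0) pushbacks <<- pushbacks + 1L
      pos[e, ] <<- pb[1:2]
      vel[e, ] <<- st$vel
      status[e] <<- embryo_status(pos[e, 1], pos[e, 2], geom, tip_x)
    }
  }
  log_budget <- function(t, dg, tip_x, phase) {
    budget[[length(budget) + 1L]] <<- data.frame(
      t = t, phase = phase, res = dg$res, iters = dg$iters,
      p_inlet = dg$p_inlet,
      influx_alpha = dg$influx_alpha, outflux_alpha = dg$outflux_alpha,
      alpha_volume = sum(state$alpha * mesh$V * fluid),
      clip = dg$clip, tip_x = tip_x * 1e3)
  }

  # ---- injection ---------------------------------------------------------
  settings <- solver_settings(dt = prof$dt_injection,
                              relax_u = prof$relax_u, relax_p = prof$relax_p,
                              tol_rel = prof$tol_rel,
                              max_iter = prof$max_iter,
                              snapshot_every = prof$snapshot_every)
  faces <- build_faces(
    mesh, fluid,
    uterus_edge_bc(geom, config$metric, "injection", u_in, 0, tip0,
                   config$inlet_profile),
    uterus_wall_bc(geom, 0, tip0))
  nstep <- max(1L, round(t_inj / settings$dt))
  record_traj(0)
  for (s in seq_len(nstep)) {
    state <- advance_flow(state, mesh, faces, phases, settings)
    dg <- attr(state, "diag")
    step_embryos(settings$dt, tip0)
    log_budget(state$t, dg, tip0, "injection")
    if (s %% settings$snapshot_every == 0L || s == nstep) {
      record_traj(state$t)
      if (store_fields == "cadence") {
        fields[[length(fields) + 1L]] <- list(t = state$t, field = state)
      }
    }
    if (verbose && s %% 50L == 0L) {
      message(sprintf("t=%.3f s res=%.2e iters=%d", state$t, dg$res,
                      dg$iters))
    }
  }
  end_inj <- state
  if (store_fields == "final") {
    fields[[length(fields) + 1L]] <- list(t = state$t, field = end_inj)
  }

  # ---- withdrawal --------------------------------------------------------
  exited_n <- 0L
  if (config$withdrawal) {
    u_w <- -(config$withdrawal_distance / config$withdrawal_duration) * 1e-3
    settings <- solver_settings(dt = prof$dt_withdrawal,
                                relax_u = prof$relax_u,
                                relax_p = prof$relax_p,
                                tol_rel = prof$tol_rel,
                                max_iter = prof$max_iter,
                                snapshot_every = prof$snapshot_every)
    nstep <- max(1L, round(config$withdrawal_duration / settings$dt))
    if (config$withdrawal_mode == "sliding") {
      faces <- build_faces(
        mesh, fluid,
        uterus_edge_bc(geom, config$metric, "withdrawal", 0, u_w, tip0,
                       config$inlet_profile, "sliding"),
        uterus_wall_bc(geom, u_w, tip0, "sliding"))
      for (s in seq_len(nstep)) {
        state <- advance_flow(state, mesh, faces, phases, settings)
        dg <- attr(state, "diag")
        step_embryos(settings$dt, tip0)
        log_budget(state$t, dg, tip0, "withdrawal")
        if (s %% settings$snapshot_every == 0L || s == nstep) {
          record_traj(state$t)
          if (store_fields == "cadence") {
            fields[[length(fields) + 1L]] <- list(t = state$t, field = state)
          }
        }
        if (verbose && s %% 100L == 0L) {
          message(sprintf("withdrawal t=%.3f s res=%.2e", state$t, dg$res))
        }
      }
    } else {
    fluid_prev <- fluid
    faces <- NULL
    for (s in seq_len(nstep)) {
      t_new <- t_inj + s * settings$dt
      cp <- catheter_position(t_new, geom, t_inj,
                              withdrawal = TRUE,
                              withdrawal_duration =
                                config$withdrawal_duration,
                              withdrawal_distance =
                                config$withdrawal_distance)
      tip_x <- cp$tip_x * 1e-3
      fluid <- mask_fluid(mesh, geom, cp$tip_x)
      if (is.null(faces) || !identical(fluid, fluid_prev)) {
        fresh <- which(fluid & !fluid_prev)
        for (k in fresh) {
          ij <- arrayInd(k, c(mesh$nx, mesh$ny))
          nb <- rbind(c(ij[1] - 1, ij[2]), c(ij[1] + 1, ij[2]),
                      c(ij[1], ij[2] - 1), c(ij[1], ij[2] + 1))
          nb <- nb[nb[, 1] >= 1 & nb[, 1] <= mesh$nx &
                     nb[, 2] >= 1 & nb[, 2] <= mesh$ny, , drop = FALSE]
          ok <- fluid_prev[nb]
          state$alpha[k] <- if (any(ok)) mean(state$alpha[nb[ok, ,
                                                             drop = FALSE]])
            else 0
          state$p[k] <- if (any(ok)) mean(state$p[nb[ok, , drop = FALSE]])
            else 0
          state$u[k] <- u_w * 1e0
          state$v[k] <- 0
        }
        solidified <- which(!fluid & fluid_prev)
        if (length(solidified)) {
          state$u[solidified] <- 0; state$v[solidified] <- 0
          state$alpha[solidified] <- 0
        }
        phase_lbl <- if (tip_x > 0) "withdrawal" else "free"
        faces <- build_faces(
          mesh, fluid,
          uterus_edge_bc(geom, config$metric, phase_lbl, 0, u_w, tip_x,
                         config$inlet_profile),
          uterus_wall_bc(geom, u_w, tip_x))
        state$Fi <- NULL
        fluid_prev <- fluid
      }
      state <- advance_flow(state, mesh, faces, phases, settings)
      dg <- attr(state, "diag")
      step_embryos(settings$dt, tip_x)
      log_budget(state$t, dg, tip_x, "withdrawal")
      if (s %% settings$snapshot_every == 0L || s == nstep) {
        record_traj(state$t)
        if (store_fields == "cadence") {
          fields[[length(fields) + 1L]] <- list(t = state$t, field = state)
        }
      }
      if (verbose && s %% 100L == 0L) {
        message(sprintf("withdrawal t=%.3f s tip=%.1f mm res=%.2e",
                        state$t, cp$tip_x, dg$res))
      }
    }
    }
    exited_n <- sum(status == "exited_cervix")
    if (store_fields != "cadence") {
      fields[[length(fields) + 1L]] <- list(t = state$t, field = state)
    }
  }

  traj <- do.call(rbind, traj)
  budget <- do.call(rbind, budget)
  run <- structure(list(config = config, mesh = mesh, geometry = geom,
                        trajectories = traj, budget = budget,
                        fields = fields, final = state,
                        end_of_injection = end_inj,
                        fluid_final = fluid,
                        pushbacks = pushbacks,
                        exited_cervix = exited_n),
                   class = "et_run")
  run$summary <- transport_distances(run)
  run
}

#' @export
print.et_run <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<et_run> case %s: mu1=%g Pa.s rho1=%g kg/m^3 t_inj=%g s%s\n",
              ifelse(is.na(cfg$case_index), "custom", cfg$case_index),
              cfg$phase1$viscosity, cfg$phase1$density, cfg$injection_time,
              if (cfg$withdrawal) " + withdrawal" else ""))
  s <- x$summary
  cat(sprintf("  mean axial %.2f mm, mean radial %.2f mm, force %.3g mN\n",
              s$mean_axial, s$mean_radial, s$driving_force * 1e3))
  invisible(x)
}
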