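#' Extract the volume-fraction contour
#'
#' Marching-squares style level-set extraction (linear interpolation along
#' cell-center edges) of the `alpha = level` contour, the dispersion-pattern
#' outline of the transferred medium.
#'
#' @param alpha `nx x ny` volume-fraction matrix.
#' @param mesh an `et_mesh`.
#' @param level contour level (default 0.5, equal parts of both fluids).
#' @return list of polylines, each a data.frame with `x`, `y` in mm; empty
#'   list when `alpha` never crosses the level.
#' @export
dispersion_contour <- function(alpha, mesh, level = 0.5) {
  if (min(alpha) >= level || max(alpha) <= level) return(list())
  cl <- grDevices::contourLines(x = mesh$xc * 1e3, y = mesh$yc * 1e3,
                                z = alpha, levels = level)
  lapply(cl, function(s) data.frame(x = s$x, y = s$y))
}

#' Area enclosed by closed contour polylines
#'
#' Shoelace area summed over the closed loops of a contour set (loops whose
#' ends coincide within a tolerance). Open polylines (contours cut by the
#' domain boundary) are closed by the straight segment between their ends.
#'
#' @param contours list of polylines from [dispersion_contour()].
#' @return total enclosed area (mm^2).
#' @export
contour_area <- function(contours) {
  sum(vapply(contours, function(s) {
    n <- nrow(s)
    if (n < 3) return(0)
    x <- s$x; y <- s$y
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }, numeric(1)))
}

#' Dispersion pattern of the transferred medium
#'
#' The region occupied by the transferred medium (`alpha > 0.5`), described
#' by its contour polylines, its sagittal area, the upstream-lobe area
#' (medium found on the cervix side of the catheter tip, outside the
#' catheter annulus) and a heuristic shape class: `"incomplete_ellipse"`
#' when upstream lobes hold more than 5 percent of the pattern area,
#' `"sector"` when they do not, `"other"` when the pattern is empty.
#'
#' @param run an `et_run`.
#' @param at `"end_of_injection"` or `"final"`.
#' @param level contour level.
#' @return an object of class `et_pattern`: `t`, `contours`, `area` (mm^2,
#'   sagittal cell-count area), `area_upstream`, `shape`.
#' @export
dispersion_pattern <- function(run, at = c("end_of_injection", "final"),
                               level = 0.5) {
  at <- match.arg(at)
  field <- if (at == "end_of_injection") run$end_of_injection else run$final
  mesh <- run$mesh
  geom <- run$geometry
  a <- field$alpha
  dxdy <- outer(mesh$dx, mesh$dy) * 1e6   # mm^2
  inside <- a > level
  area <- sum(dxdy[inside])
  tipm <- geom$tip_x * 1e-3
  r_o <- geom$catheter_outer_diameter / 2 * 1e-3
  up <- outer(mesh$xc < tipm, mesh$yc > r_o, "&")
  area_up <- sum(dxdy[inside & up])
  shape <- if (area <= 0) "other" else if (area_up / area > 0.05) {
    "incomplete_ellipse"
  } else "sector"
  structure(list(t = field$t, contours = dispersion_contour(a, mesh, level),
                 area = area, area_upstream = area_up, shape = shape),
            class = "et_pattern")
}

#' Upstream/downstream classification
#'
#' The cavity region between the catheter tip and the fundus is downstream,
#' the region between the tip and the external ostium upstream. A position
#' exactly at the tip plane counts as upstream (boundary convention).
#'
#' @param x axial position(s) (mm).
#' @param tip_x catheter tip position (mm).
#' @return character vector, `"downstream"` or `"upstream"`.
#' @export
classify_region <- function(x, tip_x) {
  ifelse(x > tip_x, "downstream", "upstream")
}

#' Trajectory snapshot nearest to a time
#'
#' Extracts the recorded embryo states at the snapshot time closest to
#' `t_ref`.
#'
#' @param traj trajectory data.frame (`t, id, x, y, vx, vy, status`).
#' @param t_ref requested time (s).
#' @return the rows of the nearest recorded snapshot.
#' @export
traj_at <- function(traj, t_ref) {
  tt <- unique(traj$t)
  t0 <- tt[which.min(abs(tt - t_ref))]
  traj[traj$t == t0, ]
}

#' Embryo transport distances and delivery summary
#'
#' Per-embryo and mean axial and radial transport distances relative to the
#' catheter tip, measured at the end of injection: axial
#' `x(t_ref) - tip_x` (positive toward the fundus), radial `|y(t_ref)|`;
#' plus the delivery region of each embryo and the injection driving force.
#'
#' @param x an `et_run`, or a trajectory data.frame with columns
#'   `t, id, x, y, status` (mm).
#' @param tip_x catheter tip position (mm); taken from the run geometry when
#'   `x` is an `et_run`.
#' @param t_ref reference time (s); defaults to the end of injection.
#' @param run optional `et_run` supplying the driving force when `x` is a
#'   bare trajectory table.
#' @return an object of class `et_summary`: data.frame `per_embryo`
#'   (id, axial, radial, region, status, exited flag), `mean_axial`,
#'   `mean_radial` (mm), `driving_force` and `driving_force_peak` (N),
#'   `p_inlet_mean` (Pa).
#' @export
transport_distances <- function(x, tip_x = NULL, t_ref = NULL, run = NULL) {
  if (inherits(x, "et_run")) {
    run <- x
    traj <- run$trajectories
    if (is.null(tip_x)) tip_x <- run$geometry$tip_x
    if (is.null(t_ref)) t_ref <- run$config$injection_time
  } else {
    traj <- x
    if (is.null(tip_x) || is.null(t_ref)) {
      stop("tip_x and t_ref are required with a bare trajectory table")
    }
  }
  snap <- traj_at(traj, t_ref)
  snap <- snap[order(snap$id), ]
  per <- data.frame(
    id = snap$id,
    axial = snap$x - tip_x,
    radial = abs(snap$y),
    region = classify_region(snap$x, tip_x),
    status = snap$status,
    exited = snap$status %in% c("exited_cervix", "exited_tube"))
  force <- if (!is.null(run)) driving_force(run) else
    list(force = NA_real_, force_peak = NA_real_, p_mean = NA_real_)
  structure(list(per_embryo = per,
                 mean_axial = mean(per$axial),
                 mean_radial = mean(per$radial),
                 n_upstream = sum(per$region == "upstream" & !per$exited),
                 n_downstream = sum(per$region == "downstream" & !per$exited),
                 driving_force = force$force,
                 driving_force_peak = force$force_peak,
                 p_inlet_mean = force$p_mean,
                 t_ref = t_ref, tip_x = tip_x),
            class = "et_summary")
}

#' @export
print.et_summary <- function(x, ...) {
  cat(sprintf(paste0("<et_summary> t_ref=%.3g s: mean axial %.2f mm, ",
                     "mean radial %.2f mm\n"),
              x$t_ref, x$mean_axial, x$mean_radial))
  cat(sprintf("  upstream %d, downstream %d, driving force %.4g N\n",
              x$n_upstream, x$n_downstream, x$driving_force))
  invisible(x)
}

#' Injection driving force
#'
#' The force driving the catheter load, obtained by integrating the inlet
#' gauge pressure over the bore area: the area-mean inlet pressure times the
#' circular bore area `pi r_c^2`. Reported as the time mean over the
#' injection interval (used for comparisons) and the peak; a per-unit-depth
#' planar variant (`p * 2 r_c`, N/m) is included for transparency.
#'
#' @param run an `et_run`.
#' @return list with `force` (N, time mean), `force_peak` (N), `p_mean`,
#'   `p_peak` (Pa), `force_per_depth` (N/m) and the per-step `series`
#'   data.frame (`t`, `p_inlet`, `force`).
#' @export
driving_force <- function(run) {
  b <- run$budget
  b <- b[b$phase == "injection" & is.finite(b$p_inlet), ]
  r_c <- run$geometry$catheter_inner_diameter / 2 * 1e-3
  area <- pi * r_c^2
  if (nrow(b) == 0) {
    return(list(force = NA_real_, force_peak = NA_real_, p_mean = NA_real_,
                p_peak = NA_real_, force_per_depth = NA_real_,
                series = NULL))
  }
  p_mean <- mean(b$p_inlet)
  p_peak <- max(b$p_inlet)
  list(force = p_mean * area, force_peak = p_peak * area,
       p_mean = p_mean, p_peak = p_peak,
       force_per_depth = p_mean * 2 * r_c,
       series = data.frame(t = b$t, p_inlet = b$p_inlet,
                           force = b$p_inlet * area))
}

#' Drag-back during catheter withdrawal
#'
#' Mean axial displacement of the embryos toward the cervix between the end
#' of injection and the end of withdrawal,
#' `mean(x(t_end_injection) - x(t_end_withdrawal))` (mm, positive toward
#' the cervix), with the count of embryos dragged out of the uterine cavity
#' into the cervix.
#'
#' @param run an `et_run`.
#' @param t_end_injection,t_end_withdrawal timestamps (s); default to the
#'   configured injection and withdrawal times.
#' @return list with `dragback` (mm), `per_embryo` (mm, length 10),
#'   `n_entered_cervix` (embryos ending in the cervical canal,
#'   `x < cervix_length`, i.e. dragged out of the uterine cavity) and
#'   `n_exited_cervix` (embryos leaving the domain through the external
#'   ostium, `x < 0`).
#' @export
withdrawal_dragback <- function(run, t_end_injection = NULL,
                                t_end_withdrawal = NULL) {
  cfg <- run$config
  if (is.null(t_end_injection)) t_end_injection <- cfg$injection_time
  if (is.null(t_end_withdrawal)) {
    t_end_withdrawal <- cfg$injection_time + cfg$withdrawal_duration
  }
  if (!cfg$withdrawal) {
    return(list(dragback = 0, per_embryo = rep(0, 10),
                n_entered_cervix = 0L, n_exited_cervix = 0L))
  }
  a <- traj_at(run$trajectories, t_end_injection)
  bb <- traj_at(run$trajectories, t_end_withdrawal)
  a <- a[order(a$id), ]; bb <- bb[order(bb$id), ]
  d <- a$x - bb$x
  list(dragback = mean(d), per_embryo = d,
       n_entered_cervix = sum(bb$x < run$geometry$cervix_length |
                                bb$status == "exited_cervix"),
       n_exited_cervix = sum(bb$status == "exited_cervix"))
}

#' Table-2-shaped summary across runs
#'
#' Collects per-case summaries into one table: case index, transferred
#' medium viscosity, injection speed, mean axial and radial transport
#' distances and driving force.
#'
#' @param runs list of `et_run` objects.
#' @return data.frame with one row per run.
#' @export
summarize_cases <- function(runs) {
  do.call(rbind, lapply(runs, function(r) {
    cfg <- r$config
    s <- r$summary
    data.frame(
      case = cfg$case_index,
      viscosity = cfg$phase1$viscosity,
      injection_speed = inlet_velocity(cfg$injected_volume,
                                       cfg$injection_time,
                                       cfg$geometry$catheter_inner_diameter / 2),
      mean_axial = s$mean_axial,
      mean_radial = s$mean_radial,
      driving_force_mN = s$driving_force * 1e3)
  }))
}
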