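#' Uterine cavity and catheter geometry
#'
#' Parameterizes the half-symmetric mid-sagittal model of an average-sized
#' uterine cavity: a triangular cavity (base across the fundus, apex joining
#' the cervical channel), the straight cervical channel, and a transfer
#' catheter lying along the symmetry midline. All lengths are in millimetres.
#'
#' The coordinate convention used throughout the package is: `x` axial,
#' increasing from the external ostium (`x = 0`) toward the fundus
#' (`x = cervix_length + cavity_height`); `y` radial, with `y = 0` on the
#' symmetry midline. The catheter tip sits at
#' `x = cervix_length + cavity_height - tip_fundus_distance`.
#'
#' @param cavity_base full width of the triangular cavity at the fundus (mm).
#' @param cavity_height axial extent of the cavity (mm).
#' @param cervix_length length of the cervical channel (mm).
#' @param external_ostium_width full width of the external ostium (mm); also
#'   taken as the uniform full width of the cervical channel.
#' @param tube_ostium_width width of each fallopian-tube ostium opening (mm).
#' @param catheter_inner_diameter,catheter_outer_diameter catheter bore and
#'   outer diameters (mm).
#' @param catheter_length_in_cavity nominal catheter length inside the uterus
#'   (mm); together with `cervix_length` it sets the default withdrawal
#'   distance.
#' @param tip_fundus_distance distance from the catheter tip to the fundus
#'   (mm); must be strictly less than `cavity_height`.
#'
#' @return An object of class `et_geometry`: the validated parameters plus
#'   derived quantities (`tip_x`, the domain half-width function, outline
#'   polygon and opening segments; see [build_geometry()]).
#' @export
uterus_geometry <- function(cavity_base = 32,
                            cavity_height = 50,
                            cervix_length = 25,
                            external_ostium_width = 4,
                            tube_ostium_width = 0.3,
                            catheter_inner_diameter = 0.6,
                            catheter_outer_diameter = 0.8,
                            catheter_length_in_cavity = 56,
                            tip_fundus_distance = 15) {
  p <- list(cavity_base = cavity_base, cavity_height = cavity_height,
            cervix_length = cervix_length,
            external_ostium_width = external_ostium_width,
            tube_ostium_width = tube_ostium_width,
            catheter_inner_diameter = catheter_inner_diameter,
            catheter_outer_diameter = catheter_outer_diameter,
            catheter_length_in_cavity = catheter_length_in_cavity,
            tip_fundus_distance = tip_fundus_distance)
  num <- vapply(p, function(v) is.numeric(v) && length(v) == 1 && is.finite(v),
                logical(1))
  if (!all(num)) {
    stop("all geometry parameters must be finite scalars: ",
         paste(names(p)[!num], collapse = ", "))
  }
  if (any(unlist(p) <= 0)) {
    stop("all geometry lengths must be strictly positive")
  }
  if (catheter_outer_diameter <= catheter_inner_diameter) {
    stop("catheter_outer_diameter must exceed catheter_inner_diameter")
  }
  if (tip_fundus_distance >= cavity_height) {
    stop("catheter tip would lie at or beyond the cavity apex: ",
         "tip_fundus_distance (", tip_fundus_distance,
         " mm) must be < cavity_height (", cavity_height, " mm)")
  }
  if (catheter_outer_diameter >= external_ostium_width) {
    stop("catheter does not fit through the external ostium")
  }
  if (tube_ostium_width >= cavity_base / 2) {
    stop("tube_ostium_width must be smaller than the half fundus base")
  }
  structure(build_geometry(p), class = "et_geometry")
}

#' Continuous half-domain description
#'
#' Derives the continuous computational half-domain from validated geometry
#' parameters: the outline polygon of the fluid region (cervical channel plus
#' half cavity), the catheter wall rectangle, the domain half-width profile
#' `Y(x)`, and the three opening segments (catheter-bore inlet and external
#' ostium on `x = 0`, fallopian-tube ostium on the fundus plane).
#'
#' The triangle apex joins the 4 mm-wide cervical channel, so the half-width
#' is the larger of the cervical half-width and the slanted-wall height:
#' `Y(x) = max(w_cx/2, s*(x - cervix_length))` with slope
#' `s = (cavity_base/2)/cavity_height`.
#'
#' @param params a named list (or `et_geometry`) of geometry parameters as in
#'   [uterus_geometry()].
#' @return a list with the input parameters plus `tip_x` (mm), `x_fundus`,
#'   `half_width(x)` (a function, mm), `outline` (data.frame of polygon
#'   vertices, mm), `catheter` (rectangle as `xmin/xmax/ymin/ymax`), and
#'   `openings` (list of `inlet`, `external_ostium`, `tube_ostium` segments).
#' @keywords internal
#' @export
build_geometry <- function(params) {
  p <- unclass(params)
  x_fundus <- p$cervix_length + p$cavity_height
  tip_x <- x_fundus - p$tip_fundus_distance
  if (tip_x <= p$cervix_length) {
    stop("catheter tip would lie at or beyond the cavity apex")
  }
  w2 <- p$external_ostium_width / 2
  slope <- (p$cavity_base / 2) / p$cavity_height
  x_join <- p$cervix_length + w2 / slope
  half_width <- function(x) pmax(w2, pmin(slope * (x - p$cervix_length),
                                          p$cavity_base / 2)) *
    as.numeric(x >= 0 & x <= x_fundus)
  yb2 <- p$cavity_base / 2
  outline <- data.frame(
    x = c(0, x_fundus, x_fundus, x_join, 0),
    y = c(0, 0, yb2, w2, w2))
  r_c <- p$catheter_inner_diameter / 2
  r_o <- p$catheter_outer_diameter / 2
  p$x_fundus <- x_fundus
  p$tip_x <- tip_x
  p$slope <- slope
  p$x_join <- x_join
  p$half_width <- half_width
  p$outline <- outline
  p$catheter <- list(xmin = 0, xmax = tip_x, ymin = r_c, ymax = r_o)
  p$openings <- list(
    inlet = list(x = 0, ymin = 0, ymax = r_c),
    external_ostium = list(x = 0, ymin = r_o, ymax = w2),
    tube_ostium = list(x = x_fundus, ymin = yb2 - p$tube_ostium_width,
                       ymax = yb2))
  p
}

#' Polygon area of the continuum fluid half-domain
#'
#' Shoelace area of the outline polygon minus the catheter wall rectangle
#' (mm^2); used as the reference in mesh-area checks.
#' @param geom an `et_geometry`.
#' @return area in mm^2.
#' @export
geometry_area <- function(geom) {
  x <- geom$outline$x; y <- geom$outline$y
  n <- length(x)
  xs <- c(x, x[1]); ys <- c(y, y[1])
  a <- abs(sum(xs[1:n] * ys[2:(n + 1)] - xs[2:(n + 1)] * ys[1:n])) / 2
  cat_a <- with(geom$catheter, (xmax - xmin) * (ymax - ymin))
  a - cat_a
}

#' Catheter position and wall velocity during withdrawal
#'
#' The catheter is stationary until the end of injection `t_inj`; during the
#' following `withdrawal_duration` (5 s) it translates toward the cervix at
#' constant speed over `withdrawal_distance`, so that its tip clears the
#' external ostium. The moving-wall speed applies to the tip, inner and outer
#' catheter walls.
#'
#' @param t time (s), from the start of injection.
#' @param geom an `et_geometry`.
#' @param t_inj injection duration (s).
#' @param withdrawal logical; if `FALSE` the catheter never moves.
#' @param withdrawal_duration duration of withdrawal (s, default 5).
#' @param withdrawal_distance total travel (mm); default
#'   `catheter_length_in_cavity + cervix_length` = 81 mm.
#' @return list with `offset` (mm, >= 0 toward the cervix), `wall_velocity`
#'   (mm/s, <= 0, the signed axial wall speed), and `tip_x` (mm, tip position;
#'   negative once the catheter has left the domain).
#' @export
catheter_position <- function(t, geom, t_inj,
                              withdrawal = TRUE,
                              withdrawal_duration = 5,
                              withdrawal_distance = NULL) {
  stopifnot(t >= 0)
  if (is.null(withdrawal_distance)) {
    withdrawal_distance <- geom$catheter_length_in_cavity + geom$cervix_length
  }
  speed <- withdrawal_distance / withdrawal_duration
  if (!withdrawal || t <= t_inj) {
    offset <- 0; w <- 0
  } else if (t <= t_inj + withdrawal_duration) {
    offset <- speed * (t - t_inj); w <- -speed
  } else {
    offset <- withdrawal_distance; w <- 0
  }
  list(offset = offset, wall_velocity = w, tip_x = geom$tip_x - offset)
}
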