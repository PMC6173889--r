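#' Write cell fields to a legacy-ASCII VTK rectilinear grid
#'
#' Minimal VTK (version 3.0, `DATASET RECTILINEAR_GRID`) writer for
#' inspecting fields in ParaView or similar. Cell-centered matrices are
#' written as `CELL_DATA` scalars; coordinates are in millimetres.
#'
#' @param mesh an `et_mesh`.
#' @param fields named list of `nx x ny` matrices.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_vtk_field <- function(mesh, fields, file) {
  con <- file(file, "w")
  on.exit(close(con))
  nx <- mesh$nx; ny <- mesh$ny
  writeLines(c("# vtk DataFile Version 3.0",
               "etflow field snapshot", "ASCII",
               "DATASET RECTILINEAR_GRID",
               sprintf("DIMENSIONS %d %d 1", nx + 1L, ny + 1L)), con)
  writeLines(sprintf("X_COORDINATES %d float", nx + 1L), con)
  writeLines(paste(format(mesh$xb * 1e3, digits = 8), collapse = " "), con)
  writeLines(sprintf("Y_COORDINATES %d float", ny + 1L), con)
  writeLines(paste(format(mesh$yb * 1e3, digits = 8), collapse = " "), con)
  writeLines("Z_COORDINATES 1 float", con)
  writeLines("0", con)
  writeLines(sprintf("CELL_DATA %d", nx * ny), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s float 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(paste(format(as.vector(fields[[nm]]), digits = 8),
                     collapse = " "), con)
  }
  invisible(file)
}

#' Export a run to a directory
#'
#' Writes the standard artifacts of one simulation: per-snapshot embryo
#' trajectories and the per-step budget log as CSV, the transport summary,
#' the dispersion-pattern contour polylines, and VTK snapshots of the stored
#' fields.
#'
#' @param run an `et_run`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$trajectories, file.path(dir, "trajectories.csv"),
                   row.names = FALSE)
  utils::write.csv(run$budget, file.path(dir, "budget.csv"),
                   row.names = FALSE)
  s <- run$summary
  utils::write.csv(s$per_embryo, file.path(dir, "embryos.csv"),
                   row.names = FALSE)
  utils::write.csv(summarize_cases(list(run)), file.path(dir, "summary.csv"),
                   row.names = FALSE)
  pat <- dispersion_pattern(run)
  if (length(pat$contours)) {
    poly <- do.call(rbind, lapply(seq_along(pat$contours), function(i) {
      cbind(piece = i, pat$contours[[i]])
    }))
    utils::write.csv(poly, file.path(dir, "dispersion_contour.csv"),
                     row.names = FALSE)
  }
  for (i in seq_along(run$fields)) {
    f <- run$fields[[i]]$field
    write_vtk_field(run$mesh,
                    list(alpha = f$alpha, u = f$u * 1e3, v = f$v * 1e3,
                         p = f$p),
                    file.path(dir, sprintf("field_t%07.3fs.vtk", f$t)))
  }
  cfg <- run$config
  writeLines(c(
    sprintf("case_index: %s", cfg$case_index),
    sprintf("mu1: %g", cfg$phase1$viscosity),
    sprintf("rho1: %g", cfg$phase1$density),
    sprintf("mu2: %g", cfg$phase2$viscosity),
    sprintf("rho2: %g", cfg$phase2$density),
    sprintf("injected_volume_uL: %g", cfg$injected_volume),
    sprintf("injection_time_s: %g", cfg$injection_time),
    sprintf("withdrawal: %s", cfg$withdrawal),
    sprintf("withdrawal_mode: %s", cfg$withdrawal_mode),
    sprintf("drag_form: %s", cfg$drag_form),
    sprintf("metric: %s", cfg$metric),
    sprintf("profile: %s", cfg$profile$name)),
    file.path(dir, "config.yml"))
  invisible(dir)
}
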