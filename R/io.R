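#' Default run configuration
#'
#' Reads the packaged default configuration (YAML): the reference material
#' parameters, head/pelvis diameters, levator shell calibration, trajectory
#' and solver settings.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  read_config(system.file("extdata", "default_config.yaml",
                          package = "levatorfem", mustWork = TRUE))
}

#' Read a run configuration file (YAML)
#' @param path file path.
#' @return nested configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop(errorCondition(sprintf("config file '%s' does not exist", path),
                        class = c("levatorfem_io_error", "error", "condition")))
  cfg <- yaml::read_yaml(path)
  for (block in c("material", "geometry", "trajectory"))
    if (is.null(cfg[[block]]))
      stop(errorCondition(sprintf("config lacks required block '%s'", block),
                          class = c("levatorfem_io_error", "error", "condition")))
  cfg
}

#' Write a run configuration file (YAML)
#' @param config nested configuration list.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.cfg_material <- function(cfg) {
  m <- cfg$material
  ogden_params(mu = as.numeric(m$mu), alpha = as.numeric(m$alpha),
               nu = if (is.null(m$poisson)) 0.499 else m$poisson,
               density = if (is.null(m$density_kg_l)) 1.06e-9
               else m$density_kg_l * 1e-9)
}

.cfg_geometry <- function(cfg) {
  g <- cfg$geometry
  head <- build_fetal_head(do.call(head_dimensions, g$head),
                           target_edge = g$head_mesh_edge %||% 4)
  pelvis <- build_pelvis(do.call(pelvis_dimensions, g$pelvis),
                         target_edge = g$pelvis_mesh_edge %||% 6)
  lev <- g$levator
  mesh <- build_levator(pelvis,
                        shell_thickness = lev$shell_thickness %||% 7,
                        hiatus_dims = c(lev$hiatus_width %||% 35,
                                        lev$hiatus_length %||% 55),
                        target_edge = lev$mesh_edge %||% 4)
  list(head = head, pelvis = pelvis, mesh = mesh)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.cfg_trajectory <- function(cfg, head = NULL) {
  tc <- do.call(trajectory_config, cfg$trajectory)
  build_trajectory(tc, head = head)
}

.cfg_solver <- function(cfg) {
  s <- cfg$solver %||% list()
  s$tether_stiffness <- NULL
  do.call(solver_settings, Filter(Negate(is.null), s))
}

.fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# ---- mesh / field writers ---------------------------------------------------

#' Write a tetrahedral mesh with fields as a legacy-ASCII VTK file
#'
#' Unstructured-grid export with optional cell data (e.g. von Mises stress,
#' region labels) and point data (e.g. displacements, node-set membership).
#'
#' @param path output file (.vtk).
#' @param nodes N x 3 coordinates.
#' @param tets M x 4 connectivity (1-based).
#' @param cell_data named list of numeric vectors (length M).
#' @param point_data named list of numeric vectors (length N) or N x 3
#'   matrices (written as vectors).
#' @return \code{path}, invisibly.
#' @export
write_vtk <- function(path, nodes, tets, cell_data = list(), point_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "levatorfem output", "ASCII",
               "DATASET UNSTRUCTURED_GRID"), con)
  writeLines(sprintf("POINTS %d double", nrow(nodes)), con)
  writeLines(apply(format(nodes, digits = 9, trim = TRUE, scientific = FALSE),
                   1, paste, collapse = " "), con)
  m <- nrow(tets)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  writeLines(apply(cbind(4L, tets - 1L), 1, paste, collapse = " "), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", m), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(format(as.numeric(cell_data[[nm]]), digits = 9, trim = TRUE), con)
    }
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nrow(nodes)), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(apply(format(v, digits = 9, trim = TRUE), 1, paste,
                         collapse = " "), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
        writeLines(format(as.numeric(v), digits = 9, trim = TRUE), con)
      }
    }
  }
  invisible(path)
}

#' Write a rigid triangle surface as Wavefront OBJ
#' @param surface a \code{rigid_surface} (written in its current pose).
#' @param path output file (.obj).
#' @return \code{path}, invisibly.
#' @export
write_obj <- function(surface, path) {
  v <- surface_nodes(surface)
  lines <- c(sprintf("v %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]),
             sprintf("f %d %d %d", surface$tris[, 1], surface$tris[, 2],
                     surface$tris[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Write a rigid triangle surface as ASCII STL
#' @inheritParams write_obj
#' @param path output file (.stl).
#' @return \code{path}, invisibly.
#' @export
write_stl <- function(surface, path) {
  v <- surface_nodes(surface)
  tr <- surface$tris
  a <- v[tr[, 1], , drop = FALSE]
  e1 <- v[tr[, 2], , drop = FALSE] - a
  e2 <- v[tr[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- n / pmax(sqrt(rowSums(n^2)), 1e-300)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", surface$role), con)
  for (t in seq_len(nrow(tr))) {
    writeLines(sprintf("  facet normal %.6e %.6e %.6e", n[t, 1], n[t, 2], n[t, 3]), con)
    writeLines("    outer loop", con)
    for (k in 1:3) {
      p <- v[tr[t, k], ]
      writeLines(sprintf("      vertex %.6e %.6e %.6e", p[1], p[2], p[3]), con)
    }
    writeLines(c("    endloop", "  endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", surface$role), con)
  invisible(path)
}

#' Export a head trajectory as CSV
#'
#' Columns: frame, time (s), station, translation (mm) and orientation
#' quaternion (w, x, y, z).
#'
#' @param trajectory a \code{head_trajectory}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  rows <- lapply(seq_along(trajectory$frames), function(i) {
    f <- trajectory$frames[[i]]
    q <- rot_to_quat(f$transform$R)
    data.frame(frame = i, time_s = f$time, station = f$station,
               tx = f$transform$t[1], ty = f$transform$t[2],
               tz = f$transform$t[3], qw = q[1], qx = q[2], qy = q[3], qz = q[4])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- pipeline runners -------------------------------------------------------

.stage_log <- function(log_path, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
  cat(line, "\n", file = log_path, append = TRUE, sep = "")
}

#' Fit Ogden parameters and write a parameter file + report
#'
#' With \code{data_file = NULL} a synthetic uniaxial test is generated from
#' the reference material and re-identified (the pipeline's self-check);
#' otherwise the CSV (columns \code{stretch,nominal_stress_mpa}) is fitted.
#'
#' @param data_file CSV path or NULL for synthetic data.
#' @param out_dir output directory (created if needed).
#' @param n_terms Ogden terms.
#' @param noise_sd synthetic noise level, MPa.
#' @param seed integer seed (restarts and synthetic noise).
#' @return the \code{ogden_fit}, invisibly.
#' @export
run_fit <- function(data_file = NULL, out_dir = "levatorfem_fit", n_terms = 2,
                    noise_sd = 0, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  data <- if (is.null(data_file))
    generate_uniaxial_data(lam_material(), noise_sd = noise_sd, seed = seed)
  else read_uniaxial_csv(data_file)
  fit <- fit_ogden(data, n_terms = n_terms, seed = seed)
  write_uniaxial_csv(data, file.path(out_dir, "uniaxial_data.csv"))
  p <- fit$params
  write_config(list(material = list(mu = p$mu, alpha = p$alpha,
                                    poisson = p$nu, K = p$K)),
               file.path(out_dir, "fitted_material.yaml"))
  jsonlite::write_json(
    list(sse_mpa2 = fit$sse, converged = fit$converged,
         n_restarts_used = fit$n_restarts_used,
         coefficients = as.list(coef(fit)),
         stability_margin = sum(p$mu * p$alpha),
         provenance = attr(data, "provenance"), seed = seed),
    file.path(out_dir, "fit_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(fit)
}

#' Build the default trajectory and write CSV + net-motion report
#'
#' @param config configuration list (see [default_config()]).
#' @param out_dir output directory.
#' @return the \code{head_trajectory}, invisibly.
#' @export
run_trajectory <- function(config = default_config(),
                           out_dir = "levatorfem_trajectory") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  head <- build_fetal_head(do.call(head_dimensions, config$geometry$head),
                           target_edge = config$geometry$head_mesh_edge %||% 4)
  traj <- .cfg_trajectory(config, head = head)
  write_trajectory_csv(traj, file.path(out_dir, "trajectory.csv"))
  ang <- decompose_net_rotation(traj)
  n <- length(traj$frames)
  report <- list(
    net_anterior_displacement_mm =
      traj$centroid_track[n, 2] - traj$centroid_track[1, 2],
    extension_deg = unname(ang["extension"]),
    internal_rotation_deg = unname(ang["internal_rotation"]),
    lateral_straightening_deg = unname(ang["lateral_straightening"]),
    n_frames = n,
    stations = range(vapply(traj$frames, `[[`, numeric(1), "station")))
  jsonlite::write_json(report, file.path(out_dir, "net_motion.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(traj)
}

#' Run the full delivery simulation pipeline
#'
#' Builds the synthetic anatomy, the cardinal-movements trajectory and the
#' boundary conditions from a configuration, runs the quasi-static solve,
#' and writes: the regional stress table (CSV), the elongation report
#' (JSON), a VTK time series of the deformed shell (every
#' \code{vtk_stride}-th frame), rigid surfaces (OBJ), the trajectory CSV, a
#' run manifest with a config hash, and a stage log. Deterministic given
#' the configuration.
#'
#' @param config configuration list (see [default_config()]).
#' @param out_dir output directory.
#' @param vtk_stride write every k-th frame as VTK (0 disables).
#' @param verbose print solver progress.
#' @return the \code{delivery_fem} result, invisibly (with the elongation
#'   report and summary table attached).
#' @export
run_simulation <- function(config = default_config(),
                           out_dir = "levatorfem_results",
                           vtk_stride = 10, verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  cat("", file = log_path)
  t0 <- proc.time()[3]
  stage <- function(name, expr) {
    ts <- proc.time()[3]
    val <- tryCatch(expr, error = function(e) {
      .stage_log(log_path, sprintf("stage '%s' FAILED: %s", name,
                                   conditionMessage(e)))
      stop(errorCondition(sprintf("stage '%s' failed: %s", name,
                                  conditionMessage(e)),
                          class = c("levatorfem_stage_error", "error",
                                    "condition"), stage = name))
    })
    .stage_log(log_path, sprintf("stage '%s' done in %.1f s", name,
                                 proc.time()[3] - ts))
    val
  }
  params <- stage("material", .cfg_material(config))
  geo <- stage("geometry", .cfg_geometry(config))
  traj <- stage("trajectory", .cfg_trajectory(config, head = geo$head))
  bcs <- stage("boundary_conditions",
               levator_boundary_conditions(
                 geo$mesh,
                 tether_stiffness = config$solver$tether_stiffness %||% 0.5))
  settings <- stage("solver_settings", .cfg_solver(config))
  fem <- stage("solve",
               solve_quasistatic(geo$mesh, params, bcs, traj,
                                 settings = settings, head = geo$head,
                                 verbose = verbose))
  tab <- stage("stress_table", summarize_run(fem))
  elong <- stage("elongation", elongation_report(fem))
  stage("export", {
    export_table(tab, file.path(out_dir, "stress_table.csv"))
    jsonlite::write_json(elong, file.path(out_dir, "elongation.json"),
                         auto_unbox = TRUE, digits = NA)
    write_trajectory_csv(traj, file.path(out_dir, "trajectory.csv"))
    write_obj(geo$head, file.path(out_dir, "head.obj"))
    write_obj(geo$pelvis, file.path(out_dir, "pelvis.obj"))
    if (vtk_stride > 0) {
      frames <- unique(c(seq(1, length(fem$states), by = vtk_stride),
                         length(fem$states)))
      for (fi in frames)
        write_vtk(file.path(out_dir, sprintf("levator_%03d.vtk", fi)),
                  geo$mesh$nodes + fem$states[[fi]]$displacements,
                  geo$mesh$tets,
                  cell_data = list(von_mises = fem$states[[fi]]$vm,
                                   region = as.integer(geo$mesh$region)),
                  point_data = list(
                    displacement = fem$states[[fi]]$displacements))
    }
    utils::write.csv(fem$diagnostics,
                     file.path(out_dir, "solver_diagnostics.csv"),
                     row.names = FALSE)
  })
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    config_hash = .fnv1a(as.character(cfg_json)),
    config = config,
    artifacts = sort(setdiff(list.files(out_dir), "manifest.json")),
    n_frames = length(fem$states),
    n_elements = nrow(geo$mesh$tets),
    elapsed_s = unname(proc.time()[3] - t0))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .stage_log(log_path, sprintf("run complete in %.1f s", manifest$elapsed_s))
  fem$table <- tab
  fem$elongation <- elong
  invisible(fem)
}
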