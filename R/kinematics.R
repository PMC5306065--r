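#' Rigid transform
#'
#' A proper rigid-body transform: rotation \code{R} (proper orthogonal,
#' checked to 1e-10) plus translation \code{t} in mm. Applied to row-wise
#' point matrices as \code{x R^T + t}.
#'
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation (mm).
#' @return an object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- unname(as.matrix(R)); t <- as.numeric(t)
  if (any(dim(R) != c(3, 3)) || length(t) != 3L || any(!is.finite(R)) || any(!is.finite(t)))
    stop(errorCondition("R must be 3x3 and t length 3, all finite",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  if (max(abs(crossprod(R) - diag(3))) > 1e-10 || abs(det(R) - 1) > 1e-10)
    stop(errorCondition("R is not proper orthogonal within 1e-10",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  structure(list(R = R, t = t), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid transform: t =", sprintf("%.3f", x$t), "mm\n")
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param tf a \code{rigid_transform}.
#' @param pts numeric 3-vector or N x 3 matrix of points (mm).
#' @return transformed points, same shape.
#' @export
apply_transform <- function(tf, pts) {
  if (is.null(dim(pts))) return(as.numeric(tf$R %*% pts + tf$t))
  sweep(pts %*% t(tf$R), 2, -tf$t)
}

#' Compose two rigid transforms (a then b)
#' @param a,b \code{rigid_transform}s; the result maps x to b(a(x)).
#' @return a \code{rigid_transform}.
#' @export
compose_transform <- function(a, b)
  rigid_transform(b$R %*% a$R, as.numeric(b$R %*% a$t + b$t))

# elementary rotations, angle in degrees
rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rot_to_quat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(max(R[i, i] - R[j, j] - R[k, k] + 1, 0)) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  q / sqrt(sum(q^2))
}

#' Cardinal-movements trajectory configuration
#'
#' Parameters of the prescribed fetal-head motion for the second stage of
#' labor. The world frame is x = maternal left, y = anterior, z = cranial,
#' with the interspinous plane at z = 0; stations are in cm of vertex
#' descent below that plane.
#'
#' The head starts at \code{start_station} in the left occiput anterior
#' (LOA) attitude, deviated \code{lateral_deviation_deg} to the right, and
#' descends along a circular curve-of-Carus arc of radius
#' \code{carus_radius} mm in the mediosagittal plane to \code{end_station}.
#' Internal rotation (about z, occiput from left-anterior to anterior) and
#' lateral straightening accrue linearly with descent and complete at
#' \code{rotation_complete_station}. Extension (\code{extension_deg} about
#' the lateral x axis) happens after the final descent station, hinging
#' about the inferior pubic margin (\code{extension_pivot_y},
#' \code{extension_pivot_z}) with a small caudal drift
#' (\code{extension_caudal_mm}) that keeps the vertex descent monotone.
#' The anterior translation budget is closed exactly so the head origin's
#' net anterior displacement equals \code{total_anterior_mm}.
#'
#' @param start_station,end_station descent schedule in stations (cm).
#' @param frames_per_station frames per station of descent.
#' @param carus_radius radius of the curve-of-Carus arc, mm.
#' @param total_anterior_mm net anterior (y) displacement of the head
#'   origin over the whole trajectory, mm.
#' @param extension_deg total extension angle, degrees.
#' @param lateral_deviation_deg initial rightward deviation that is
#'   straightened during descent, degrees.
#' @param internal_rotation_deg total internal rotation about z, degrees.
#' @param rotation_complete_station station at which internal rotation (and
#'   straightening) are complete.
#' @param extension_frames number of frames in the extension phase.
#' @param extension_caudal_mm additional caudal drift during extension, mm
#'   (keeps the vertex descent strictly monotone through the pivot sweep).
#' @param extension_pivot_y,extension_pivot_z mediosagittal position of the
#'   extension pivot, mm: the inferior margin of the pubic symphysis, under
#'   which the occiput hinges while the face sweeps over the perineum.
#' @param start_anterior_mm initial anterior (y) position of the head
#'   origin, mm.
#' @param vertex_local position of the vertex landmark in head-local
#'   coordinates, mm (overridden when a head surface is supplied to
#'   [build_trajectory()]).
#' @return an object of class \code{trajectory_config}.
#' @export
trajectory_config <- function(start_station = -3, end_station = 5,
                              frames_per_station = 5, carus_radius = 160,
                              total_anterior_mm = 100.0,
                              extension_deg = 80.25,
                              lateral_deviation_deg = 28.66,
                              internal_rotation_deg = 40.13,
                              rotation_complete_station = 3,
                              extension_frames = 10,
                              extension_caudal_mm = 8,
                              extension_pivot_y = 65,
                              extension_pivot_z = -35,
                              start_anterior_mm = 0,
                              vertex_local = c(0, 0, 47)) {
  cfg <- list(start_station = start_station, end_station = end_station,
              frames_per_station = frames_per_station,
              carus_radius = carus_radius,
              total_anterior_mm = total_anterior_mm,
              extension_deg = extension_deg,
              lateral_deviation_deg = lateral_deviation_deg,
              internal_rotation_deg = internal_rotation_deg,
              rotation_complete_station = rotation_complete_station,
              extension_frames = extension_frames,
              extension_caudal_mm = extension_caudal_mm,
              extension_pivot_y = extension_pivot_y,
              extension_pivot_z = extension_pivot_z,
              start_anterior_mm = start_anterior_mm,
              vertex_local = vertex_local)
  num <- vapply(cfg[!(names(cfg) %in% "vertex_local")], is.numeric, logical(1))
  if (!all(num) || any(!is.finite(unlist(cfg))))
    stop(errorCondition("trajectory config fields must be finite numerics",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  if (end_station <= start_station || frames_per_station < 1 || extension_frames < 1)
    stop(errorCondition("invalid station schedule",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  if (rotation_complete_station <= start_station ||
      rotation_complete_station > end_station)
    stop(errorCondition("rotation completion station must lie within the descent schedule",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  descent <- (end_station - start_station) * 10
  if (carus_radius < descent)
    stop(errorCondition("carus_radius must be at least the total descent depth",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  structure(cfg, class = "trajectory_config")
}

# initial head pose: vertex down (flexed, presenting), occiput rotated to the
# left-anterior azimuth, head deviated laterally to the right.  Chosen so that
# applying Rx(ext) Rz(rot) Ry(straighten) with the full configured angles
# returns the head to the straight, occiput-anterior, extended attitude.
.initial_head_rotation <- function(config) {
  rot_y(-config$lateral_deviation_deg) %*%
    rot_z(-config$internal_rotation_deg) %*% rot_x(180)
}

.relative_rotation <- function(e, r, s) rot_x(e) %*% rot_z(r) %*% rot_y(s)

#' Build the prescribed fetal-head trajectory
#'
#' Constructs the ordered sequence of rigid-body frames implementing the
#' cardinal movements of labor (descent along the curve of Carus, internal
#' rotation, lateral straightening, extension). Frame poses map head-local
#' coordinates to the world frame. There is no lateral (x) translation at
#' any frame.
#'
#' @param config a \code{trajectory_config}.
#' @param head optional \code{rigid_surface} fetal head; when given, its
#'   vertex landmark replaces \code{config$vertex_local}.
#' @return an object of class \code{head_trajectory}: a list with
#'   \code{frames} (each with \code{time}, \code{station},
#'   \code{transform}), \code{config}, and vertex/centroid tracks.
#' @export
build_trajectory <- function(config, head = NULL) {
  if (!inherits(config, "trajectory_config"))
    stop(errorCondition("config must be a trajectory_config",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  v_local <- if (!is.null(head)) head$landmarks["vertex", ] else config$vertex_local
  v_local <- as.numeric(v_local)

  n_desc <- (config$end_station - config$start_station) * config$frames_per_station
  depth <- (config$end_station - config$start_station) * 10
  Rarc <- config$carus_radius
  theta_d <- asin(depth / Rarc)
  R0 <- .initial_head_rotation(config)
  y0 <- config$start_anterior_mm

  frames <- vector("list", n_desc + 1 + config$extension_frames)
  rot_span <- config$rotation_complete_station - config$start_station
  for (k in 0:n_desc) {
    u <- k / n_desc
    phi <- u * theta_d
    cy <- y0 + Rarc * (1 - cos(phi))
    st_nom <- config$start_station + u * (config$end_station - config$start_station)
    w <- min(1, max(0, (st_nom - config$start_station) / rot_span))
    Rrel <- .relative_rotation(0, w * config$internal_rotation_deg,
                               w * config$lateral_deviation_deg)
    R <- Rrel %*% R0
    # the vertex z schedule is prescribed exactly: station st_nom in cm
    cz <- -st_nom * 10 - as.numeric(R %*% v_local)[3]
    frames[[k + 1]] <- list(time = k, transform = rigid_transform(R, c(0, cy, cz)))
  }
  # extension phase: the head hinges about the inferior pubic margin; the
  # residual anterior translation closes the configured net displacement
  tf_d <- frames[[n_desc + 1]]$transform
  c_d <- tf_d$t
  pivot <- c(0, config$extension_pivot_y, config$extension_pivot_z)
  arm <- c_d - pivot
  dy_arc <- c_d[2] - y0
  dy_rot <- as.numeric(rot_x(config$extension_deg) %*% arm)[2] - arm[2]
  dy_extra <- config$total_anterior_mm - dy_arc - dy_rot
  for (k in seq_len(config$extension_frames)) {
    u <- k / config$extension_frames
    e <- u * config$extension_deg
    Rrel <- .relative_rotation(e, config$internal_rotation_deg,
                               config$lateral_deviation_deg)
    drift <- c(0, u * dy_extra, -u * config$extension_caudal_mm)
    tr <- pivot + as.numeric(rot_x(e) %*% arm) + drift
    frames[[n_desc + 1 + k]] <- list(time = n_desc + k, transform =
                                       rigid_transform(Rrel %*% R0, tr))
  }

  vertex_track <- t(vapply(frames, function(f)
    apply_transform(f$transform, v_local), numeric(3)))
  centroid_track <- t(vapply(frames, function(f) f$transform$t, numeric(3)))
  for (i in seq_along(frames))
    frames[[i]]$station <- round(-vertex_track[i, 3] / 10)
  structure(list(frames = frames, config = config, vertex_local = v_local,
                 vertex_track = vertex_track, centroid_track = centroid_track),
            class = "head_trajectory")
}

#' @export
print.head_trajectory <- function(x, ...) {
  n <- length(x$frames)
  cat(sprintf("head trajectory: %d frames, stations %d to %d, net anterior %.2f mm\n",
              n, x$frames[[1]]$station, x$frames[[n]]$station,
              x$centroid_track[n, 2] - x$centroid_track[1, 2]))
  invisible(x)
}

#' @export
length.head_trajectory <- function(x) length(x$frames)

#' Obstetric station of a head pose
#'
#' Station is the signed distance, in cm (rounded to the 1-cm schedule), of
#' the head vertex below the interspinous plane carried by the pelvis:
#' negative above the plane, 0 at the plane.
#'
#' @param transform the head pose (\code{rigid_transform}) for one frame, or
#'   a trajectory frame list.
#' @param pelvis a \code{rigid_surface} pelvis carrying the interspinous
#'   plane (point + normal); defaults to the plane z = 0.
#' @param vertex_local vertex landmark in head-local coordinates.
#' @return integer station label.
#' @export
station_of <- function(transform, pelvis = NULL, vertex_local = c(0, 0, 47)) {
  if (is.list(transform) && !inherits(transform, "rigid_transform"))
    transform <- transform$transform
  v <- apply_transform(transform, as.numeric(vertex_local))
  if (!is.null(pelvis) && !is.null(pelvis$interspinous_plane)) {
    pl <- pelvis$interspinous_plane
    d <- sum((v - pl$point) * pl$normal)  # positive above the plane
  } else {
    d <- v[3]
  }
  as.integer(round(-d / 10))
}

#' Decompose the net head rotation into cardinal-movement angles
#'
#' Factors the net rotation from the first to the last frame as
#' \eqn{R = R_x(e) R_z(r) R_y(s)} (extension about the lateral x axis,
#' internal rotation about the craniocaudal z axis, lateral straightening
#' about the anterior y axis) and returns the three angles in degrees.
#' For trajectories built by [build_trajectory()] this reproduces the
#' configured angles exactly.
#'
#' @param trajectory a \code{head_trajectory} (needs at least 2 frames).
#' @return named numeric vector \code{c(extension, internal_rotation,
#'   lateral_straightening)}, degrees.
#' @export
decompose_net_rotation <- function(trajectory) {
  if (length(trajectory$frames) < 2L)
    stop(errorCondition("need at least two frames",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  Rf <- trajectory$frames[[1]]$transform$R
  Rl <- trajectory$frames[[length(trajectory$frames)]]$transform$R
  M <- Rl %*% t(Rf)
  cr <- sqrt(M[1, 1]^2 + M[1, 3]^2)
  if (cr < 1e-8) {
    e1 <- atan2(M[2, 3], M[3, 3]) * 180 / pi
    stop(errorCondition(
      sprintf(paste0("gimbal-degenerate decomposition (|cos r| ~ 0): ",
                     "solutions e+s = %.4f deg or e-s = %.4f deg with r = %.0f deg"),
              e1, -e1, 90 * sign(-M[1, 2])),
      class = c("levatorfem_ambiguity_error", "error", "condition")))
  }
  r <- atan2(-M[1, 2], cr)
  s <- atan2(M[1, 3], M[1, 1])
  e <- atan2(M[3, 2], M[2, 2])
  c(extension = e, internal_rotation = r, lateral_straightening = s) * 180 / pi
}
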