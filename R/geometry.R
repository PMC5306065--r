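#' Fetal head dimensions
#'
#' The four principal diameters of the fetal head (mm). Defaults are the
#' package's reference 50th-percentile term neonate: suboccipitobregmatic
#' 100.3, occipitofrontal 105.7, occipitomental 131.9, biparietal 93.7.
#'
#' @param suboccipitobregmatic,occipitofrontal,occipitomental,biparietal
#'   diameters in mm, all positive; the ordering occipitomental >=
#'   occipitofrontal >= suboccipitobregmatic is enforced.
#' @return an object of class \code{head_dimensions}.
#' @export
head_dimensions <- function(suboccipitobregmatic = 100.3,
                            occipitofrontal = 105.7,
                            occipitomental = 131.9,
                            biparietal = 93.7) {
  d <- c(suboccipitobregmatic = suboccipitobregmatic,
         occipitofrontal = occipitofrontal,
         occipitomental = occipitomental,
         biparietal = biparietal)
  if (any(!is.finite(d)) || any(d <= 0))
    stop(errorCondition("head dimensions must be positive",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  if (!(occipitomental >= occipitofrontal && occipitofrontal >= suboccipitobregmatic))
    stop(errorCondition(
      "need occipitomental >= occipitofrontal >= suboccipitobregmatic",
      class = c("levatorfem_invalid_input", "error", "condition")))
  structure(as.list(d), class = "head_dimensions")
}

#' Pelvis dimensions
#'
#' The four principal diameters of the bony pelvis (mm). Defaults are the
#' package's reference gynecoid pelvis: anteroposterior inlet 113.4,
#' anteroposterior outlet 145.1, transverse inlet 148.8, interspinous 146.7.
#'
#' @param inlet_ap,outlet_ap,transverse_inlet,interspinous diameters, mm.
#' @return an object of class \code{pelvis_dimensions}.
#' @export
pelvis_dimensions <- function(inlet_ap = 113.4, outlet_ap = 145.1,
                              transverse_inlet = 148.8, interspinous = 146.7) {
  d <- c(inlet_ap = inlet_ap, outlet_ap = outlet_ap,
         transverse_inlet = transverse_inlet, interspinous = interspinous)
  if (any(!is.finite(d)) || any(d <= 0))
    stop(errorCondition("pelvis dimensions must be positive",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  structure(as.list(d), class = "pelvis_dimensions")
}

.rigid_surface <- function(nodes, tris, landmarks, role,
                           pose = rigid_transform(), extra = list()) {
  obj <- c(list(nodes = nodes, tris = tris, landmarks = landmarks,
                role = role, pose = pose), extra)
  class(obj) <- "rigid_surface"
  obj
}

#' @export
print.rigid_surface <- function(x, ...) {
  cat(sprintf("rigid surface '%s': %d nodes, %d triangles, %d landmarks\n",
              x$role, nrow(x$nodes), nrow(x$tris), nrow(x$landmarks)))
  invisible(x)
}

#' Nodes of a rigid surface in its current pose
#' @param surface a \code{rigid_surface}.
#' @return N x 3 matrix of posed node coordinates (mm).
#' @export
surface_nodes <- function(surface) apply_transform(surface$pose, surface$nodes)

#' Re-pose a rigid surface
#' @param surface a \code{rigid_surface}.
#' @param tf a \code{rigid_transform}; replaces the current pose when
#'   \code{absolute = TRUE}, otherwise composes after it.
#' @param absolute replace instead of compose.
#' @return the surface with updated pose.
#' @export
set_pose <- function(surface, tf, absolute = TRUE) {
  surface$pose <- if (absolute) tf else compose_transform(surface$pose, tf)
  surface
}

# icosphere of unit radius, subdivided so edges are below edge_frac
.icosphere <- function(edge_frac) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  n_sub <- max(0L, ceiling(log2(1.0514 / edge_frac)))  # icosahedron edge/r
  for (s in seq_len(n_sub)) {
    mid_env <- new.env(hash = TRUE)
    verts <- v
    nf <- matrix(0L, 4 * nrow(f), 3)
    nv <- nrow(verts)
    vlist <- list(verts)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      m <- mid_env[[key]]
      if (!is.null(m)) return(m)
      nv <<- nv + 1L
      p <- (v[i, ] + v[j, ]) / 2
      vlist[[length(vlist) + 1L]] <<- p / sqrt(sum(p^2))
      mid_env[[key]] <- nv
      nv
    }
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[4 * k - 3, ] <- c(a, ab, ca)
      nf[4 * k - 2, ] <- c(b, bc, ab)
      nf[4 * k - 1, ] <- c(cc, ca, bc)
      nf[4 * k, ] <- c(ab, bc, ca)
    }
    v <- do.call(rbind, vlist)
    f <- nf
  }
  list(v = v, f = f)
}

# radius of an axis-aligned ellipsoid along unit direction u
.ellipsoid_radius <- function(u, semi) {
  1 / sqrt((u[1] / semi[1])^2 + (u[2] / semi[2])^2 + (u[3] / semi[3])^2)
}

#' Build the rigid fetal head surface
#'
#' Parametric ovoid whose landmark pairs reproduce the four principal head
#' diameters exactly. The shape is a base ellipsoid (biparietal width,
#' occipitofrontal length) with smooth radial Gaussian bumps solved so that
#' the suboccipitobregmatic and occipitomental landmark distances, and the
#' base landmark radii, are met simultaneously. Head-local axes: x ear to
#' ear, y toward the face, z toward the vertex; origin at the ellipsoid
#' centre (the head "origin" used for trajectory displacement bookkeeping).
#'
#' Landmarks carried: vertex, bregma, occiput, sinciput, mentum,
#' suboccipital, parietal_left, parietal_right.
#'
#' @param dims a \code{head_dimensions} object.
#' @param target_edge target triangle edge length, mm.
#' @return a \code{rigid_surface} with role "head".
#' @export
build_fetal_head <- function(dims = head_dimensions(), target_edge = 4) {
  if (!inherits(dims, "head_dimensions")) dims <- do.call(head_dimensions, dims)
  if (!is.numeric(target_edge) || target_edge <= 0)
    stop(errorCondition("target_edge must be positive",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  ax <- dims$biparietal / 2
  ay <- dims$occipitofrontal / 2
  az <- ax                      # roundish cranium height
  semi <- c(ax, ay, az)

  deg <- pi / 180
  d_breg <- c(0, sin(25 * deg), cos(25 * deg))        # near-vertex, anterior
  d_sub <- c(0, -cos(35 * deg), -sin(35 * deg))       # below occiput (nape)
  d_ment <- c(0, cos(55 * deg), -sin(55 * deg))       # chin, low anterior
  centers <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   d_breg, d_sub, d_ment)
  r_ell <- apply(centers, 1, .ellipsoid_radius, semi = semi)
  B0 <- r_ell[5] * d_breg
  O0 <- c(0, -ay, 0)
  # surface radii so the chord landmark distances are exact
  .chord_radius <- function(d, anchor, L) {
    b <- sum(d * anchor)
    disc <- b^2 - sum(anchor^2) + L^2
    if (disc <= 0)
      stop(errorCondition("inconsistent head dimensions (no real landmark radius)",
                          class = c("levatorfem_invalid_input", "error", "condition")))
    b + sqrt(disc)
  }
  targets <- c(ax, ax, ay, ay, r_ell[5],
               .chord_radius(d_sub, B0, dims$suboccipitobregmatic),
               .chord_radius(d_ment, O0, dims$occipitomental))
  w <- 25 * deg
  ang <- function(u, v) acos(pmin(1, pmax(-1, sum(u * v))))
  A <- outer(seq_len(7), seq_len(7), Vectorize(function(i, k)
    exp(-(ang(centers[i, ], centers[k, ]) / w)^2)))
  cf <- solve(A, targets - r_ell)

  rad <- function(u) {
    bump <- sum(cf * exp(-(apply(centers, 1, ang, v = u) / w)^2))
    .ellipsoid_radius(u, semi) + bump
  }
  ico <- .icosphere(target_edge / max(semi, targets))
  radii <- apply(ico$v, 1, rad)
  nodes <- ico$v * radii
  lm_dirs <- rbind(vertex = c(0, 0, 1), bregma = d_breg,
                   occiput = c(0, -1, 0), sinciput = c(0, 1, 0),
                   mentum = d_ment, suboccipital = d_sub,
                   parietal_left = c(1, 0, 0), parietal_right = c(-1, 0, 0))
  landmarks <- lm_dirs * apply(lm_dirs, 1, rad)
  .rigid_surface(nodes, ico$f, landmarks, role = "head",
                 extra = list(dims = dims,
                              centroid = c(0, 0, 0),
                              min_radius = min(radii)))
}

#' Build the rigid bony pelvis surface
#'
#' Parametric birth canal: elliptical inlet, interspinous and outlet rings
#' lofted along the craniocaudal axis. The interspinous plane is z = 0 (its
#' point and normal are carried on the surface for station bookkeeping); the
#' inlet lies 60 mm cranially, the outlet 50 mm caudally. Landmark pairs
#' reproduce the four configured diameters exactly.
#'
#' @param dims a \code{pelvis_dimensions} object.
#' @param target_edge target triangle edge length, mm.
#' @return a \code{rigid_surface} with role "pelvis".
#' @export
build_pelvis <- function(dims = pelvis_dimensions(), target_edge = 6) {
  if (!inherits(dims, "pelvis_dimensions")) dims <- do.call(pelvis_dimensions, dims)
  if (!is.numeric(target_edge) || target_edge <= 0)
    stop(errorCondition("target_edge must be positive",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  z_in <- 60; z_mid <- 0; z_out <- -50
  key_z <- c(z_in, z_mid, z_out)
  # semi-axes at the three key levels: x = transverse, y = anteroposterior
  sx <- c(dims$transverse_inlet / 2, dims$interspinous / 2, 110 / 2)
  sy <- c(dims$inlet_ap / 2,
          (dims$inlet_ap + dims$outlet_ap) / 4 + 10,  # midpelvis AP, smooth
          dims$outlet_ap / 2)
  zs <- seq(z_in, z_out, by = -target_edge)
  if (zs[length(zs)] != z_out) zs <- c(zs, z_out)
  fx <- stats::splinefun(key_z, sx, method = "natural")
  fy <- stats::splinefun(key_z, sy, method = "natural")
  n_ring <- max(16L, ceiling(2 * pi * max(sx, sy) / target_edge))
  th <- seq(0, 2 * pi, length.out = n_ring + 1)[-(n_ring + 1)]
  nodes <- do.call(rbind, lapply(zs, function(z)
    cbind(fx(z) * sin(th), fy(z) * cos(th), z)))
  tris <- list()
  for (i in seq_len(length(zs) - 1)) {
    base0 <- (i - 1) * n_ring; base1 <- i * n_ring
    for (j in seq_len(n_ring)) {
      jn <- j %% n_ring + 1
      # outward orientation (normals away from the canal axis)
      tris[[length(tris) + 1L]] <- c(base0 + j, base1 + j, base0 + jn)
      tris[[length(tris) + 1L]] <- c(base0 + jn, base1 + j, base1 + jn)
    }
  }
  landmarks <- rbind(inlet_anterior = c(0, sy[1], z_in),
                     inlet_posterior = c(0, -sy[1], z_in),
                     inlet_left = c(sx[1], 0, z_in),
                     inlet_right = c(-sx[1], 0, z_in),
                     spine_left = c(sx[2], 0, z_mid),
                     spine_right = c(-sx[2], 0, z_mid),
                     outlet_anterior = c(0, sy[3], z_out),
                     outlet_posterior = c(0, -sy[3], z_out))
  .rigid_surface(nodes, do.call(rbind, tris), landmarks, role = "pelvis",
                 extra = list(dims = dims,
                              interspinous_plane = list(point = c(0, 0, 0),
                                                        normal = c(0, 0, 1))))
}

#' Distance between two landmarks of a rigid surface
#'
#' Euclidean distance between named landmarks in the surface's current
#' pose; invariant under rigid re-posing.
#'
#' @param surface a \code{rigid_surface}.
#' @param landmark_a,landmark_b landmark names.
#' @return distance, mm.
#' @export
measure_landmark_distance <- function(surface, landmark_a, landmark_b) {
  lm <- surface$landmarks
  for (nm in c(landmark_a, landmark_b))
    if (!nm %in% rownames(lm))
      stop(errorCondition(sprintf("unknown landmark '%s'", nm),
                          class = c("levatorfem_lookup_error", "error", "condition")))
  pa <- apply_transform(surface$pose, lm[landmark_a, ])
  pb <- apply_transform(surface$pose, lm[landmark_b, ])
  sqrt(sum((pa - pb)^2))
}

#' Signed volumes of tetrahedral elements
#' @param nodes N x 3 node coordinates.
#' @param tets M x 4 connectivity (1-based).
#' @return numeric vector of signed volumes (mm^3).
#' @export
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c_ <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
     b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
     b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

#' Build the deformable levator ani shell mesh
#'
#' Parametric funnel/hammock: a mid-surface spanning the pelvic canal from
#' an outer attachment ring (pubis anteriorly, tendinous arch laterally,
#' sacrum/posterior ilia dorsally, sloping dorsocranially) down to an
#' anteriorly-offset hiatal rim, extruded along its normals to
#' \code{shell_thickness} and filled with labelled tetrahedra.
#'
#' Element regions: \code{PVm} for the anterior slings arising from the
#' pubis, \code{PRm} for the inner sling looping around the hiatus
#' posteriorly, \code{ICm} for the outer dorsocranial sheet. Node sets:
#' \code{pubic_attachment}, \code{atml_coupling}, \code{sacral_attachment},
#' \code{cranial_plane_constrained} (with the best-fit sacral plane),
#' \code{distal_prm_loop}, and the ordered \code{mediosagittal_trace}
#' (posterior midline, outer ring to hiatal rim, mid-thickness).
#'
#' The default hiatal dimensions (35 x 55 mm) and shell thickness (7 mm)
#' are calibration choices of the synthetic geometry, set so that the
#' descending reference head first engages the shell near station -3; the
#' outer ring reaches z = +30 mm dorsally for the same reason.
#'
#' @param pelvis a \code{rigid_surface} pelvis (sets the canal size).
#' @param shell_thickness shell thickness, mm.
#' @param hiatus_dims c(width, length) of the urogenital hiatus, mm.
#' @param target_edge target element edge length, mm (4 by default; 2 for
#'   the fine configuration).
#' @return an object of class \code{labeled_tet_mesh}.
#' @export
build_levator <- function(pelvis = build_pelvis(), shell_thickness = 7,
                          hiatus_dims = c(35, 55), target_edge = 4) {
  if (!is.numeric(shell_thickness) || shell_thickness <= 0)
    stop(errorCondition("shell_thickness must be positive",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  if (length(hiatus_dims) != 2L || any(!is.finite(hiatus_dims)) || any(hiatus_dims <= 0))
    stop(errorCondition("hiatus_dims must be two positive numbers",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  a_o <- 75; b_o <- 78                       # outer ring: bony margins + retropubic clearance
  a_i <- hiatus_dims[1] / 2; b_i <- hiatus_dims[2] / 2
  if (a_i >= a_o || b_i >= b_o)
    stop(errorCondition("hiatus larger than the pelvic canal",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  y_h <- 25; z_h <- -25                      # hiatal rim centre
  z_outer <- function(th) 10 - 45 * cos(th)  # -35 at pubis, +55 dorsal dome

  mid <- function(th, s) {
    q <- s^2                                 # dorsocranial shelf, funnel
    cbind(((1 - s) * a_o + s * a_i) * sin(th),
          (1 - s) * b_o * cos(th) + s * (y_h + b_i * cos(th)),
          (1 - q) * z_outer(th) + q * z_h)
  }
  mean_perim <- 2 * pi * mean(c(a_o + a_i, b_o + b_i)) / 2
  n_th <- 4L * max(4L, ceiling(mean_perim / target_edge / 4))
  rad_len <- sqrt((a_o - a_i)^2 + (z_outer(pi) - z_h)^2)
  n_r <- max(4L, ceiling(rad_len / target_edge))
  n_l <- max(2L, round(shell_thickness / target_edge) + 1L)

  th <- (seq_len(n_th) - 1) * 2 * pi / n_th  # th = 0 anterior, pi posterior
  # grade the radial grid so elements are evenly spaced in arc length along
  # the (steep) posterior funnel profile rather than in the parameter s
  sv <- local({
    sf <- seq(0, 1, length.out = 201)
    prof <- mid(rep(pi, 201), sf)
    al <- c(0, cumsum(sqrt(rowSums(diff(prof)^2))))
    stats::approx(al / al[length(al)], sf,
                  xout = seq(0, 1, length.out = n_r + 1))$y
  })
  h <- 1e-5
  nid <- function(it, is, il) ((il - 1) * (n_r + 1) + (is - 1)) * n_th + it
  nodes <- matrix(0, n_th * (n_r + 1) * n_l, 3)
  # the shell thins towards the tendinous pubic origin (anterior outer rim)
  th_ant <- abs(((th + pi) %% (2 * pi)) - pi)
  for (is in seq_len(n_r + 1)) {
    s <- sv[is]
    m <- mid(th, s)
    dth <- (mid(th + h, s) - mid(th - h, s)) / (2 * h)
    sm <- min(max(s, h), 1 - h)
    dsv <- (mid(th, sm + h) - mid(th, sm - h)) / (2 * h)
    nrm <- cbind(dth[, 2] * dsv[, 3] - dth[, 3] * dsv[, 2],
                 dth[, 3] * dsv[, 1] - dth[, 1] * dsv[, 3],
                 dth[, 1] * dsv[, 2] - dth[, 2] * dsv[, 1])
    nrm <- nrm / sqrt(rowSums(nrm^2))
    nrm <- nrm * ifelse(nrm[, 3] < 0, -1, 1)  # orient cranially
    taper <- 1 - 0.65 * exp(-(th_ant / (45 * pi / 180))^2) * (1 - s)^1.5
    for (il in seq_len(n_l)) {
      off <- shell_thickness * taper * ((il - 1) / (n_l - 1) - 0.5)
      nodes[nid(seq_len(n_th), is, il), ] <- m + off * nrm
    }
  }

  hex_split <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                     c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  n_hex <- n_th * n_r * (n_l - 1)
  tets <- matrix(0L, 6 * n_hex, 4)
  region <- character(6 * n_hex)
  e <- 0L
  for (il in seq_len(n_l - 1)) for (is in seq_len(n_r)) for (it in seq_len(n_th)) {
    itn <- it %% n_th + 1L
    corners <- c(nid(it, is, il), nid(itn, is, il), nid(itn, is + 1L, il),
                 nid(it, is + 1L, il), nid(it, is, il + 1L), nid(itn, is, il + 1L),
                 nid(itn, is + 1L, il + 1L), nid(it, is + 1L, il + 1L))
    th_c <- th[it] + pi / n_th
    th_c <- abs(((th_c + pi) %% (2 * pi)) - pi)  # |angle from anterior|
    z_c <- mean(nodes[corners, 3])
    lab <- if (th_c < 70 * pi / 180) "PVm"
    else if (z_c < z_h + 15) "PRm" else "ICm"   # distal sling hugs the rim
    for (q in seq_len(6)) {
      e <- e + 1L
      tets[e, ] <- corners[hex_split[q, ]]
      region[e] <- lab
    }
  }
  vol <- tet_volumes(nodes, tets)
  flip <- which(vol < 0)
  if (length(flip)) {
    tmp <- tets[flip, 3]; tets[flip, 3] <- tets[flip, 4]; tets[flip, 4] <- tmp
    vol[flip] <- -vol[flip]
  }
  if (any(vol <= 0))
    stop(errorCondition("degenerate levator elements generated",
                        class = c("levatorfem_invalid_input", "error", "condition")))

  ang_abs <- abs(((th + pi) %% (2 * pi)) - pi) * 180 / pi
  ring <- function(is, il, keep) nid(which(keep), is, il)
  outer_all <- function(keep) as.integer(sapply(seq_len(n_l), function(il)
    ring(1L, il, keep)))
  sets <- list(
    pubic_attachment = outer_all(ang_abs <= 35),
    atml_coupling = outer_all(ang_abs > 35 & ang_abs <= 110),
    sacral_attachment = outer_all(ang_abs > 110),
    cranial_plane_constrained = as.integer(sapply(seq_len(n_l), function(il)
      unlist(lapply(2:max(2L, floor(n_r / 3)), function(is)
        ring(is, il, ang_abs > 110))))),
    distal_prm_loop = ring(n_r + 1L, 1L, ang_abs >= 120)
  )
  sets <- lapply(sets, function(s) sort(unique(s)))
  i_post <- n_th / 2 + 1L  # th = pi grid line (posterior midline)
  il_mid <- max(1L, round(n_l / 2))
  trace <- vapply(seq_len(n_r + 1L), function(is)
    as.integer(nid(i_post, is, il_mid)), integer(1))

  pc <- nodes[sets$cranial_plane_constrained, , drop = FALSE]
  ev <- eigen(stats::cov(pc), symmetric = TRUE)
  nrm_pl <- ev$vectors[, 3]
  if (nrm_pl[2] < 0) nrm_pl <- -nrm_pl  # orient anteriorly
  plane <- list(point = colMeans(pc), normal = nrm_pl)

  structure(list(nodes = nodes, tets = tets,
                 region = factor(region, levels = c("ICm", "PVm", "PRm")),
                 volumes = vol, sets = sets, mediosagittal_trace = trace,
                 cranial_plane = plane,
                 thickness = shell_thickness, hiatus_dims = hiatus_dims,
                 grid = list(n_th = n_th, n_r = n_r, n_l = n_l),
                 target_edge = target_edge),
            class = "labeled_tet_mesh")
}

#' @export
print.labeled_tet_mesh <- function(x, ...) {
  cat(sprintf("labelled tetrahedral mesh: %d nodes, %d tets (mean edge target %.1f mm)\n",
              nrow(x$nodes), nrow(x$tets), x$target_edge))
  print(table(x$region))
  cat("node sets:", paste(sprintf("%s(%d)", names(x$sets),
                                  vapply(x$sets, length, integer(1))),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Check the outer boundary of a tet mesh is watertight
#'
#' Every triangular face must be shared by exactly one or two tetrahedra;
#' the faces used once form the boundary, which must be closed (every
#' boundary edge shared by exactly two boundary faces).
#'
#' @param mesh a \code{labeled_tet_mesh}.
#' @return TRUE (invisibly) or an error describing the defect.
#' @export
check_watertight <- function(mesh) {
  tf <- rbind(mesh$tets[, c(1, 2, 3)], mesh$tets[, c(1, 2, 4)],
              mesh$tets[, c(1, 3, 4)], mesh$tets[, c(2, 3, 4)])
  key <- apply(t(apply(tf, 1, sort)), 1, paste, collapse = "-")
  cnt <- table(key)
  if (any(cnt > 2))
    stop(errorCondition("non-manifold face (shared by > 2 tets)",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  bnd <- names(cnt)[cnt == 1]
  be <- do.call(rbind, lapply(strsplit(bnd, "-"), function(v) {
    v <- as.integer(v)
    rbind(sort(v[1:2]), sort(v[c(1, 3)]), sort(v[2:3]))
  }))
  ek <- paste(be[, 1], be[, 2])
  if (any(table(ek) != 2))
    stop(errorCondition("boundary surface is not closed",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  invisible(TRUE)
}
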