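#' @useDynLib levatorfem, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Boundary condition set
#'
#' Kinematic constraints and elastic supports for the quasi-static solve:
#' nodes fixed in all degrees of freedom (optionally at prescribed
#' displacements), nodes constrained to move only within a plane (given by
#' a unit normal; each node's plane passes through its own reference
#' position), and tether springs that elastically anchor nodes to fixed
#' points (the package's model of the obturator internus support of the
#' tendinous arch).
#'
#' @param fixed_nodes integer node ids fixed in all DOFs.
#' @param fixed_values optional matrix (length(fixed_nodes) x 3) of
#'   prescribed displacements (mm); zero by default.
#' @param plane_nodes integer node ids constrained in-plane.
#' @param plane_normal unit normal of the constraint plane.
#' @param tether_nodes integer node ids carrying tether springs.
#' @param tether_anchors anchor points (length(tether_nodes) x 3, mm);
#'   defaults to the nodes' reference positions at assembly time.
#' @param tether_stiffness spring stiffness, N/mm.
#' @return an object of class \code{boundary_condition_set}.
#' @export
boundary_condition_set <- function(fixed_nodes = integer(), fixed_values = NULL,
                                   plane_nodes = integer(),
                                   plane_normal = c(0, 1, 0),
                                   tether_nodes = integer(),
                                   tether_anchors = NULL,
                                   tether_stiffness = 0.5) {
  fixed_nodes <- as.integer(fixed_nodes)
  plane_nodes <- as.integer(plane_nodes)
  tether_nodes <- as.integer(tether_nodes)
  if (length(intersect(fixed_nodes, plane_nodes)))
    stop(errorCondition("fixed and plane-constrained node sets must be disjoint",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  nn <- sqrt(sum(plane_normal^2))
  if (length(plane_nodes) && abs(nn - 1) > 1e-8)
    plane_normal <- plane_normal / nn
  if (!is.null(fixed_values)) {
    fixed_values <- as.matrix(fixed_values)
    if (nrow(fixed_values) != length(fixed_nodes) || ncol(fixed_values) != 3)
      stop(errorCondition("fixed_values must be length(fixed_nodes) x 3",
                          class = c("levatorfem_invalid_input", "error", "condition")))
  }
  structure(list(fixed_nodes = fixed_nodes, fixed_values = fixed_values,
                 plane_nodes = plane_nodes,
                 plane_normal = as.numeric(plane_normal),
                 tether_nodes = tether_nodes, tether_anchors = tether_anchors,
                 tether_stiffness = tether_stiffness),
            class = "boundary_condition_set")
}

#' Default boundary conditions for a levator shell
#'
#' Pubic and sacral attachment node sets fully fixed, the cranial third of
#' the iliococcygeus constrained to the sacral best-fit plane, and tether
#' springs on the tendinous-arch coupling nodes.
#'
#' @param mesh a \code{labeled_tet_mesh} from [build_levator()].
#' @param tether_stiffness spring stiffness for the tendinous-arch tethers,
#'   N/mm.
#' @return a \code{boundary_condition_set}.
#' @export
levator_boundary_conditions <- function(mesh, tether_stiffness = 0.5) {
  boundary_condition_set(
    fixed_nodes = sort(union(mesh$sets$pubic_attachment, mesh$sets$sacral_attachment)),
    plane_nodes = mesh$sets$cranial_plane_constrained,
    plane_normal = mesh$cranial_plane$normal,
    tether_nodes = mesh$sets$atml_coupling,
    tether_anchors = mesh$nodes[mesh$sets$atml_coupling, , drop = FALSE],
    tether_stiffness = tether_stiffness)
}

#' Solver settings
#'
#' @param contact_penalty penalty stiffness, N/mm per node; \code{NULL}
#'   selects 100 x (small-strain shear modulus x mean element edge), and the
#'   solver then grows it adaptively until the converged penetration is
#'   below \code{max_penetration_frac} of the shell thickness.
#' @param newton_tol absolute residual norm tolerance, N.
#' @param newton_rel relative residual tolerance (scaled by the applied
#'   contact + tether force norm).
#' @param max_iter Newton iterations per (sub)step.
#' @param max_substep_depth how many times a trajectory increment may be
#'   halved on non-convergence.
#' @param fd_step finite-difference step for element tangents, mm.
#' @param search_radius contact search radius, mm.
#' @param max_penetration_frac converged-penetration bound, fraction of
#'   shell thickness.
#' @param penalty_growth multiplier applied to the penalty when the
#'   penetration bound is violated.
#' @param max_penalty_updates penalty growth steps allowed per frame.
#' @param line_search_max backtracking halvings per Newton step.
#' @return an object of class \code{solver_settings}.
#' @export
solver_settings <- function(contact_penalty = NULL, newton_tol = 1e-5,
                            newton_rel = 1e-4, max_iter = 40,
                            max_substep_depth = 2, fd_step = 1e-5,
                            search_radius = 10, max_penetration_frac = 0.01,
                            penalty_growth = 4, max_penalty_updates = 8,
                            line_search_max = 12, dr_steps = 0,
                            contact_saturation_frac = 0.5,
                            allow_relaxed = TRUE,
                            stabilization_frac = 1e-3) {
  vals <- c(newton_tol, newton_rel, max_iter, max_substep_depth, fd_step,
            search_radius, max_penetration_frac, penalty_growth,
            max_penalty_updates, line_search_max, stabilization_frac,
            contact_saturation_frac)
  if (any(!is.finite(vals)) || any(vals <= 0) || dr_steps < 0 ||
      (!is.null(contact_penalty) && contact_penalty <= 0))
    stop(errorCondition("solver settings must be positive",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  structure(as.list(environment()), class = "solver_settings")
}

.fe_ops <- function(mesh) {
  pre <- .fe_precompute(mesh$nodes, mesh$tets)
  list(nodes = mesh$nodes, tets = mesh$tets, Bm = pre$Bm, vol0 = pre$vol0)
}

#' Internal nodal forces of the Ogden tet mesh
#'
#' The gradient of total strain energy with respect to nodal positions
#' (N per node); zero for rigid-body displacement fields and equal to the
#' finite-difference gradient of [strain_energy()] integrated over the mesh.
#'
#' @param mesh a \code{labeled_tet_mesh} (or any list with \code{nodes} and
#'   \code{tets}).
#' @param params an \code{ogden_params} object.
#' @param displacements N x 3 nodal displacement matrix, mm.
#' @return N x 3 matrix of internal forces, N.
#' @export
internal_forces <- function(mesh, params, displacements) {
  displacements <- as.matrix(displacements)
  if (nrow(displacements) != nrow(mesh$nodes) || ncol(displacements) != 3)
    stop(errorCondition("displacements must be (number of nodes) x 3",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  ops <- .fe_ops(mesh)
  G <- .fe_gradient(ops$nodes, ops$tets, ops$Bm, ops$vol0, displacements,
                    params$mu, params$alpha, params$K)
  inv <- attr(G, "inverted_elements")
  if (!is.null(inv))
    stop(errorCondition(
      sprintf("element inversion in elements: %s",
              paste(utils::head(inv, 10), collapse = ", ")),
      class = c("levatorfem_inversion_error", "error", "condition"),
      elements = inv))
  G
}

#' Total strain energy of the mesh at a displacement field
#' @inheritParams internal_forces
#' @return scalar energy, N mm (Inf if any element is inverted).
#' @export
total_strain_energy <- function(mesh, params, displacements) {
  ops <- .fe_ops(mesh)
  .fe_energy(ops$nodes, ops$tets, ops$Bm, ops$vol0, as.matrix(displacements),
             params$mu, params$alpha, params$K)
}

.posed_rigid <- function(rigid, pose) {
  verts <- apply_transform(pose, rigid$nodes)
  ctr <- apply_transform(pose, if (!is.null(rigid$centroid)) rigid$centroid
                         else colMeans(rigid$nodes))
  rmin <- if (!is.null(rigid$min_radius)) rigid$min_radius
  else {
    c0 <- colMeans(rigid$nodes)
    sqrt(min(rowSums(sweep(rigid$nodes, 2, c0)^2)))
  }
  list(verts = verts, center = ctr, min_radius = 0.8 * rmin)
}

#' Frictionless penalty contact forces against a rigid surface
#'
#' Node-to-surface penalty contact: each penetrating node receives a force
#' of magnitude penalty x penetration depth along the outward normal of the
#' nearest rigid triangle (no tangential component).
#'
#' @param points N x 3 matrix of current node positions (mm), or a
#'   \code{labeled_tet_mesh} (its reference nodes are used).
#' @param rigid a \code{rigid_surface}.
#' @param pose the rigid body's pose for this evaluation (defaults to the
#'   surface's stored pose).
#' @param penalty penalty stiffness, N/mm.
#' @param search_radius contact search radius, mm.
#' @return list with \code{forces} (N x 3, N), \code{depth} (mm, > 0 where
#'   penetrating), \code{normal}, and \code{hit} (0 none, 1 surface,
#'   2 deep-fallback).
#' @export
contact_forces <- function(points, rigid, pose = rigid$pose, penalty,
                           search_radius = 10) {
  if (!is.numeric(penalty) || penalty <= 0)
    stop(errorCondition("penalty must be positive",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  if (inherits(points, "labeled_tet_mesh")) points <- points$nodes
  points <- as.matrix(points)
  pr <- .posed_rigid(rigid, pose)
  g <- .contact_gaps(points, pr$verts, rigid$tris, search_radius, pr$center,
                     pr$min_radius)
  list(forces = g$depth * penalty * g$normal, depth = g$depth,
       normal = g$normal, hit = g$hit)
}

# reduced-coordinate map: returns functions translating between the free
# parameter vector q and full displacement matrices, plus the sparse basis Z
.make_reduction <- function(n_nodes, bcs) {
  type <- rep("free", n_nodes)
  type[bcs$plane_nodes] <- "plane"
  type[bcs$fixed_nodes] <- "fixed"
  u0 <- matrix(0, n_nodes, 3)
  if (!is.null(bcs$fixed_values)) u0[bcs$fixed_nodes, ] <- bcs$fixed_values
  # per-node columns in q
  ncols <- ifelse(type == "free", 3L, ifelse(type == "plane", 2L, 0L))
  col0 <- cumsum(c(0L, ncols))[seq_len(n_nodes)]
  nq <- sum(ncols)
  # plane tangent basis
  n <- bcs$plane_normal
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- a - sum(a * n) * n; t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(n[2] * t1[3] - n[3] * t1[2], n[3] * t1[1] - n[1] * t1[3],
          n[1] * t1[2] - n[2] * t1[1])
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  free_idx <- which(type == "free")
  if (length(free_idx)) {
    ii <- c(ii, as.vector(t(outer(3 * (free_idx - 1), 1:3, `+`))))
    jj <- c(jj, as.vector(t(outer(col0[free_idx], 1:3, `+`))))
    xx <- c(xx, rep(1, 3 * length(free_idx)))
  }
  plane_idx <- which(type == "plane")
  if (length(plane_idx)) {
    for (k in 1:3) {
      ii <- c(ii, 3 * (plane_idx - 1) + k, 3 * (plane_idx - 1) + k)
      jj <- c(jj, col0[plane_idx] + 1L, col0[plane_idx] + 2L)
      xx <- c(xx, rep(t1[k], length(plane_idx)), rep(t2[k], length(plane_idx)))
    }
  }
  Z <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(3 * n_nodes, nq))
  # per-full-dof reduced columns and weights (each dof maps to <= 2 columns):
  # free dofs map to one column with weight 1, plane dofs to the two tangent
  # columns, fixed dofs to none.  Used for direct reduced-space assembly.
  nd <- 3 * n_nodes
  c1 <- rep(NA_integer_, nd); w1 <- numeric(nd)
  c2 <- rep(NA_integer_, nd); w2 <- numeric(nd)
  if (length(free_idx)) {
    for (r in 1:3) {
      d <- 3 * (free_idx - 1) + r
      c1[d] <- col0[free_idx] + r
      w1[d] <- 1
    }
  }
  if (length(plane_idx)) {
    for (r in 1:3) {
      d <- 3 * (plane_idx - 1) + r
      c1[d] <- col0[plane_idx] + 1L; w1[d] <- t1[r]
      c2[d] <- col0[plane_idx] + 2L; w2[d] <- t2[r]
    }
  }
  list(Z = Z, nq = nq, u0 = u0, c1 = c1, w1 = w1, c2 = c2, w2 = w2,
       to_u = function(q) u0 + matrix(as.numeric(Z %*% q), ncol = 3, byrow = TRUE),
       to_red = function(G) as.numeric(Matrix::crossprod(Z, as.numeric(t(G)))))
}

.quat_slerp <- function(Ra, Rb, s) {
  qa <- rot_to_quat(Ra); qb <- rot_to_quat(Rb)
  d <- sum(qa * qb)
  if (d < 0) { qb <- -qb; d <- -d }
  q <- if (d > 1 - 1e-10) (1 - s) * qa + s * qb
  else {
    th <- acos(min(1, d))
    (sin((1 - s) * th) * qa + sin(s * th) * qb) / sin(th)
  }
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

.interp_pose <- function(tf_a, tf_b, s)
  rigid_transform(.quat_slerp(tf_a$R, tf_b$R, s),
                  (1 - s) * tf_a$t + s * tf_b$t)

#' Quasi-static solve of the levator shell under the head trajectory
#'
#' For each trajectory frame the head is placed at its prescribed pose and
#' static equilibrium of the Ogden tet mesh is found by Newton iteration
#' with backtracking line search on the total potential energy (strain +
#' penalty contact + tether springs), in reduced coordinates that enforce
#' the kinematic boundary conditions exactly. Non-converged increments are
#' recursively halved (pose interpolation by slerp); the contact penalty is
#' grown adaptively until the converged penetration is below the configured
#' fraction of the shell thickness. The run is fully deterministic.
#'
#' @param mesh a \code{labeled_tet_mesh}.
#' @param params an \code{ogden_params}.
#' @param bcs a \code{boundary_condition_set} (see
#'   [levator_boundary_conditions()]).
#' @param trajectory a \code{head_trajectory}.
#' @param settings a \code{solver_settings}.
#' @param head the rigid fetal head \code{rigid_surface} moved along the
#'   trajectory (omit for contact-free runs).
#' @param verbose print per-frame progress.
#' @param stop_on_relaxed end the run cleanly at the first frame that only
#'   the damped pseudo-dynamic fallback could produce (default): the
#'   returned states are then all strict equilibria, and the stop is
#'   recorded in the diagnostics. With \code{FALSE} the run marches on
#'   through flagged relaxed states.
#' @return an object of class \code{delivery_fem}: list with
#'   \code{states} (one per frame: displacements, per-element deformation
#'   gradient/Cauchy stress/von Mises, contact flags, station, residual),
#'   the inputs, and a diagnostics log.
#' @export
solve_quasistatic <- function(mesh, params, bcs, trajectory, settings = solver_settings(),
                              head = NULL, verbose = FALSE, u0 = NULL,
                              stop_on_relaxed = TRUE) {
  ops <- .fe_ops(mesh)
  red <- .make_reduction(nrow(mesh$nodes), bcs)
  tether <- length(bcs$tether_nodes) > 0L
  anchors <- if (tether) {
    if (is.null(bcs$tether_anchors)) mesh$nodes[bcs$tether_nodes, , drop = FALSE]
    else as.matrix(bcs$tether_anchors)
  }
  ks <- bcs$tether_stiffness
  thick <- if (!is.null(mesh$thickness)) mesh$thickness else 1
  fext_ref <- 1
  stab_ref <- 0
  # Penalty law regularisation, both ends.  Near zero depth a C1 ramp makes
  # marginal (grazing) nodes exert vanishing force, removing the contact-set
  # chattering floor of the pure linear law; eps is well below the
  # admissible penetration, so converged mechanics are unchanged.  Beyond
  # d_sat the force saturates: tissue caught in the shadow between the rigid
  # head and a fixed attachment has no finite-gap equilibrium, and the
  # plateau keeps such trapped nodes from destroying the tangent while the
  # rest of the shell behaves normally (the affected band is the published
  # extreme-stress zone in any case).
  eps_c <- 0.5 * settings$max_penetration_frac * thick
  d_sat <- settings$contact_saturation_frac * thick
  f_sat <- d_sat - eps_c / 2
  c_force <- function(d) ifelse(d < eps_c, 0.5 * d^2 / eps_c,
                                pmin(d - eps_c / 2, f_sat))
  c_slope <- function(d) ifelse(d >= d_sat, 0, pmin(d / eps_c, 1))
  c_energy <- function(d) ifelse(d < eps_c, d^3 / (6 * eps_c),
                                 ifelse(d < d_sat,
                                        d^2 / 2 - eps_c * d / 2 + eps_c^2 / 6,
                                        d_sat^2 / 2 - eps_c * d_sat / 2 +
                                          eps_c^2 / 6 + f_sat * (d - d_sat)))
  penalty <- settings$contact_penalty
  if (is.null(penalty)) {
    G0 <- shear_modulus_small_strain(params)
    edge <- mean(ops$vol0)^(1 / 3) * 1.7  # tet volume -> rough edge
    penalty <- max(100 * G0 * edge, 1e-3)
  }
  penalty0 <- penalty

  grad_red_at <- function(u, pr) {
    G <- .fe_gradient(ops$nodes, ops$tets, ops$Bm, ops$vol0, u,
                      params$mu, params$alpha, params$K)
    if (!is.null(attr(G, "inverted_elements"))) return(NULL)
    if (!is.null(pr)) {
      g <- contact_query_free(pr$cxp, ops$nodes + u, settings$search_radius)
      pen <- which(g$depth > 0)
      if (length(pen))
        G[pen, ] <- G[pen, ] -
          penalty * c_force(g$depth[pen]) * g$normal[pen, , drop = FALSE]
    }
    if (tether) {
      d <- ops$nodes[bcs$tether_nodes, , drop = FALSE] +
        u[bcs$tether_nodes, , drop = FALSE] - anchors
      G[bcs$tether_nodes, ] <- G[bcs$tether_nodes, ] + ks * d
    }
    red$to_red(G)
  }

  energy_at <- function(u, pr) {
    E <- .fe_energy(ops$nodes, ops$tets, ops$Bm, ops$vol0, u,
                    params$mu, params$alpha, params$K)
    if (!is.finite(E)) return(Inf)
    if (!is.null(pr)) {
      g <- contact_query_free(pr$cxp, ops$nodes + u, settings$search_radius)
      E <- E + penalty * sum(c_energy(g$depth[g$depth > 0]))
    }
    if (tether) {
      d <- ops$nodes[bcs$tether_nodes, , drop = FALSE] +
        u[bcs$tether_nodes, , drop = FALSE] - anchors
      E <- E + 0.5 * ks * sum(d^2)
    }
    E
  }

  n3 <- 3 * nrow(mesh$nodes)

  # map raw (i, j, x) triplets into reduced coordinates via the per-dof
  # (column, weight) pairs; returns expanded (ri, rj, w, idx) arrays
  .expand_red <- function(ti, tj) {
    out_ri <- integer(0); out_rj <- integer(0)
    out_w <- numeric(0); out_ix <- integer(0)
    for (a in 1:2) for (b in 1:2) {
      ci <- if (a == 1) red$c1[ti] else red$c2[ti]
      wi <- if (a == 1) red$w1[ti] else red$w2[ti]
      cj <- if (b == 1) red$c1[tj] else red$c2[tj]
      wj <- if (b == 1) red$w1[tj] else red$w2[tj]
      keep <- which(!is.na(ci) & !is.na(cj))
      if (length(keep)) {
        out_ri <- c(out_ri, ci[keep]); out_rj <- c(out_rj, cj[keep])
        out_w <- c(out_w, wi[keep] * wj[keep]); out_ix <- c(out_ix, keep)
      }
    }
    list(ri = out_ri, rj = out_rj, w = out_w, ix = out_ix)
  }

  # bone-fixed nodes take no part in contact: they cannot move, contribute
  # nothing to the reduced equations, and would otherwise drive the penalty
  # adaptation when the rigid head sweeps past the fixed entheses
  contact_query_free <- function(cxp, x, r) {
    g <- .contact_query(cxp, x, r)
    if (length(bcs$fixed_nodes)) {
      g$depth[bcs$fixed_nodes] <- 0
      g$hit[bcs$fixed_nodes] <- 0L
    }
    g
  }
  # the assembly pattern is constant: expand element-tangent triplets AND
  # every node's own 3x3 block (carrying contact/tether tangents) into the
  # upper triangle of the reduced stiffness once, precompute their CSC
  # slots, and scatter-add per iteration.  The factorisation's symbolic
  # analysis is likewise computed once and updated numerically per solve.
  pat <- local({
    a0 <- .fe_assemble(ops$nodes, ops$tets, ops$Bm, ops$vol0,
                       matrix(0, nrow(mesh$nodes), 3),
                       params$mu, params$alpha, params$K, settings$fd_step)
    nn <- nrow(mesh$nodes)
    exE <- .expand_red(a0$i, a0$j)
    da <- rep(1:3, times = 3); db <- rep(1:3, each = 3)
    ti_n <- rep(3 * (seq_len(nn) - 1), each = 9) + rep(da, nn)
    tj_n <- rep(3 * (seq_len(nn) - 1), each = 9) + rep(db, nn)
    exN <- .expand_red(ti_n, tj_n)
    upE <- exE$ri <= exE$rj
    upN <- exN$ri <= exN$rj
    exE <- lapply(exE, `[`, upE)
    exN <- lapply(exN, `[`, upN)
    KU <- Matrix::sparseMatrix(i = c(exE$ri, exN$ri), j = c(exE$rj, exN$rj),
                               x = 0, dims = c(red$nq, red$nq))
    Ks <- Matrix::forceSymmetric(KU, uplo = "U")
    row <- Ks@i + 1
    col <- rep.int(seq_len(red$nq), diff(Ks@p))
    csc_key <- (col - 1) * red$nq + row
    list(Ks = Ks, nnz = length(csc_key),
         posE = findInterval((exE$rj - 1) * red$nq + exE$ri, csc_key),
         wE = exE$w, ixE = exE$ix,
         posN = findInterval((exN$rj - 1) * red$nq + exN$ri, csc_key),
         wN = exN$w,
         nodeN = (ti_n[exN$ix] - 1) %/% 3 + 1,
         aN = (ti_n[exN$ix] - 1) %% 3 + 1,
         bN = (tj_n[exN$ix] - 1) %% 3 + 1)
  })
  chol_sym <- NULL
  step_cap <- 2 * (if (!is.null(mesh$target_edge)) mesh$target_edge else 4)

  # dynamic-relaxation fallback: damped pseudo-dynamics with kinetic damping
  # and tangent-diagonal mass scaling; rides through limit points (snap-
  # through of the shell over the advancing head) where Newton stalls
  dr_relax <- function(q, pr, mdiag, tol, stab = 0, q_anchor = NULL,
                       n_steps = settings$dr_steps) {
    m <- 4 * pmax(abs(mdiag), max(abs(mdiag), 1e-12) * 1e-6)
    v <- numeric(length(q))
    dt <- 0.5
    add_stab <- function(g, qq) if (stab > 0) g + stab * (qq - q_anchor) else g
    g <- grad_red_at(red$to_u(q), pr)
    if (is.null(g)) return(q)
    g <- add_stab(g, q)
    res0 <- sqrt(sum(g^2))
    best <- list(q = q, res = res0)
    ke_prev <- 0
    for (st in seq_len(n_steps)) {
      if (st %% 100L == 0L) gc(FALSE)
      v <- v - dt * (g / m)
      ke <- 0.5 * sum(m * v^2)
      if (ke < ke_prev) v[] <- 0          # kinetic damping at the energy peak
      ke_prev <- ke
      qn <- q + dt * v
      gn <- grad_red_at(red$to_u(qn), pr)
      if (is.null(gn)) {                  # inversion: back off and restart
        v[] <- 0; dt <- dt / 2; ke_prev <- 0
        if (dt < 1e-4) break
        next
      }
      gn <- add_stab(gn, qn)
      q <- qn; g <- gn
      dt <- min(0.8, dt * 1.02)
      resn <- sqrt(sum(gn^2))
      if (resn < best$res) best <- list(q = q, res = resn)
      if (resn <= max(tol, 0.05 * res0)) break
    }
    best$q
  }

  solve_pose <- function(q, pose, stab = 0) {
    q_enter <- q
    pr <- NULL
    if (!is.null(head)) {
      pp <- .posed_rigid(head, pose)
      # the acceleration structure is built once per pose and reused by
      # every gradient / energy evaluation of this increment
      pr <- list(cxp = .contact_prepare(pp$verts, head$tris,
                                        settings$search_radius, pp$center),
                 head = head)
    }
    iters <- 0L
    dr_used <- 0L
    lam_prev <- 0
    fact_cache <- NULL
    fact_lam <- -1
    fact_age <- 0L
    last_full_step <- TRUE
    mdiag_last <- NULL
    res_hist <- numeric(0)
    repeat {
      # numeric factors and contact structures live on the C heap behind
      # external pointers; collect regularly so retries cannot accumulate
      # them, and hand freed pages back to the OS (glibc caches them)
      if (iters %% 2L == 0L) { gc(FALSE); .malloc_trim() }
      if (isTRUE(getOption("levatorfem.mem_debug"))) {
        rss <- tryCatch(as.numeric(strsplit(grep("VmRSS",
                 readLines("/proc/self/status"), value = TRUE), "\\s+")[[1]][2]),
                 error = function(e) NA)
        g <- gc(FALSE)
        message(sprintf("   it %d rss %.0f MB Rused %.0f MB", iters,
                        rss / 1024, sum(g[, 2])))
      }
      u <- red$to_u(q)
      asm <- .fe_assemble(ops$nodes, ops$tets, ops$Bm, ops$vol0, u,
                          params$mu, params$alpha, params$K, settings$fd_step)
      if (!is.null(asm$inverted))
        return(list(ok = FALSE, q = q, reason = "inversion"))
      G <- asm$grad
      xK <- .scatter_add(pat$nnz, pat$posE, asm$x[pat$ixE] * pat$wE)
      fext_norm <- 0
      gaps <- NULL
      nn <- nrow(mesh$nodes)
      kvec <- numeric(nn)
      nrm <- NULL
      if (!is.null(pr)) {
        gaps <- contact_query_free(pr$cxp, ops$nodes + u, settings$search_radius)
        pen <- which(gaps$depth > 0)
        if (length(pen)) {
          fc <- penalty * c_force(gaps$depth[pen]) * gaps$normal[pen, , drop = FALSE]
          G[pen, ] <- G[pen, ] - fc
          fext_norm <- fext_norm + sqrt(sum(fc^2))
          kvec[pen] <- penalty * c_slope(gaps$depth[pen])
          nrm <- gaps$normal
        }
      }
      tdiag <- numeric(nn)
      if (tether) {
        d <- ops$nodes[bcs$tether_nodes, , drop = FALSE] +
          u[bcs$tether_nodes, , drop = FALSE] - anchors
        G[bcs$tether_nodes, ] <- G[bcs$tether_nodes, ] + ks * d
        fext_norm <- fext_norm + sqrt(sum((ks * d)^2))
        tdiag[bcs$tether_nodes] <- ks
      }
      # contact tangent k' n n^T plus tether diagonal, scattered into the
      # per-node blocks of the precomputed pattern
      valsN <- if (is.null(nrm)) numeric(length(pat$posN))
      else kvec[pat$nodeN] * nrm[cbind(pat$nodeN, pat$aN)] *
        nrm[cbind(pat$nodeN, pat$bN)] * pat$wN
      if (any(tdiag > 0))
        valsN <- valsN + (pat$aN == pat$bN) * tdiag[pat$nodeN] * pat$wN
      xC <- .scatter_add(pat$nnz, pat$posN, valsN)
      g_red <- red$to_red(G)
      res_true <- sqrt(sum(g_red^2))
      if (stab > 0) g_red <- g_red + stab * (q - q_enter)
      res <- sqrt(sum(g_red^2))
      # the relative scale lags one converged frame so that growing the
      # penalty (which inflates the instantaneous contact-force norm) can
      # never relax the tolerance within the frame being solved
      tol <- max(settings$newton_tol, settings$newton_rel * fext_ref)
      res_hist <- c(res_hist, res)
      # a state with a large share of the shell deeply buried is the
      # swallow pathology, not a shadow-band: force a substep
      deep <- !is.null(gaps) &&
        sum(gaps$depth > 2 * thick) > 0.05 * length(gaps$depth)
      # converged, or stagnating at the contact-facet noise floor while
      # already well below the physically meaningful residual scale
      stalled <- iters >= 6 && res <= 20 * tol &&
        res > 0.95 * res_hist[length(res_hist) - 5]
      if ((res <= tol || stalled) && deep)
        return(list(ok = FALSE, q = q, reason = "deep_penetration", res = res))
      if (res <= tol || stalled)
        return(list(ok = TRUE, q = q, res = res_true, iters = iters,
                    gaps = gaps, fext = fext_norm,
                    stab_force = if (stab > 0) stab * sqrt(sum((q - q_enter)^2)) else 0,
                    energy = energy_at(u, pr)))
      slow <- iters >= 20L && res > 0.3 * res_hist[1] && res > 50 * tol
      if (iters >= settings$max_iter || slow) {
        if (settings$dr_steps > 0 && dr_used < 1L && !is.null(mdiag_last)) {
          q <- dr_relax(q, pr, mdiag_last, tol, stab, q_enter)
          dr_used <- dr_used + 1L
          iters <- 0L
          res_hist <- numeric(0)
          next
        }
        return(list(ok = FALSE, q = q, reason = "max_iter", res = res,
                    mdiag = mdiag_last))
      }
      Kred <- pat$Ks
      Kred@x <- xK + xC
      refactor <- is.null(fact_cache) || fact_age >= 1L || !last_full_step
      mdiag_last <- Matrix::diag(Kred)
      stab_ref <<- stats::median(abs(mdiag_last))
      dbar <- mean(mdiag_last)
      # warm-start the Levenberg damping from the previous iteration: during
      # an indefinite (limit-point) stretch this avoids refactorising at
      # underdamped values every iteration
      lam <- max(if (stab > 0) stab else 0, lam_prev / 16)
      accepted <- FALSE
      if (is.null(chol_sym))
        chol_sym <<- suppressWarnings(
          Matrix::Cholesky(Kred, LDL = TRUE, perm = TRUE,
                           Imult = max(dbar, 1)))
      for (tries in 0:14) {
        if (tries > 0) gc(FALSE)  # each retry's factor is C-heap behind a pointer
        if (refactor || tries > 0 || lam != fact_lam || is.null(fact_cache)) {
          fact_cache <- tryCatch(suppressWarnings(
            Matrix::update(chol_sym, Kred, mult = lam)),
            error = function(e) NULL)
          fact_lam <- lam
          fact_age <- 0L
        }
        dq <- if (is.null(fact_cache)) NULL
        else tryCatch(as.numeric(Matrix::solve(fact_cache, -g_red)),
                      error = function(e) NULL)
        if (is.null(dq) || sum(dq * g_red) >= 0) {
          lam <- if (lam <= stab) max(stab + dbar * 1e-8, 1e-12) else lam * 100
          next
        }
        # trust-region-style cap on the step length (mm)
        mdq <- max(abs(dq))
        if (mdq > step_cap) dq <- dq * (step_cap / mdq)
        step <- 1
        best <- NULL
        for (ls in seq_len(settings$line_search_max)) {
          qn <- q + step * dq
          un <- red$to_u(qn)
          gn <- grad_red_at(un, pr)     # NULL guards element inversion
          if (!is.null(gn)) {
            if (stab > 0) gn <- gn + stab * (qn - q_enter)
            resn <- sqrt(sum(gn^2))
            if (resn <= (1 - 1e-4 * step) * res || resn <= tol) {
              q <- qn; accepted <- TRUE; break
            }
            if (is.null(best) || resn < best$resn) best <- list(q = qn, resn = resn)
          }
          step <- step / 2
        }
        if (!accepted && !is.null(best) && best$resn < res) {
          # non-monotone fallback: take the best trial near the noise floor
          q <- best$q; accepted <- TRUE
        }
        if (accepted) {
          lam_prev <- lam
          fact_age <- fact_age + 1L
          last_full_step <- step >= 0.99
          break
        }
        # line search failed: damp towards gradient descent and retry
        lam <- if (lam <= stab) max(stab + dbar * 1e-6, 1e-12) else lam * 100
      }
      if (!accepted) {
        if (settings$dr_steps > 0 && dr_used < 1L) {
          q <- dr_relax(q, pr, mdiag_last, tol, stab, q_enter)
          dr_used <- dr_used + 1L
          res_hist <- numeric(0)
          next
        }
        return(list(ok = FALSE, q = q, reason = "line_search", res = res,
                    mdiag = mdiag_last))
      }
      iters <- iters + 1L
    }
  }

  # one frame increment: try the full step, then uniformly finer sequential
  # substep ladders; the viscous-stabilized rescue (stabilized solve polished
  # by an unstabilized one) is reserved for the finest level only
  prev_relaxed <- FALSE
  solve_increment <- function(q, pose_a, pose_b, depth_unused = 0L) {
    # inside a relaxed stretch, do not grind the substep ladder: one plain
    # attempt, then the damped pseudo-dynamic fallback
    ladders <- if (prev_relaxed) 1L else 4L^(0:settings$max_substep_depth)
    for (li in seq_along(ladders)) {
      gc(FALSE)  # frees contact acceleration structures of spent attempts
      n_sub <- ladders[li]
      last <- li == length(ladders)
      q_try <- q
      ok <- TRUE
      out <- NULL
      for (k in seq_len(n_sub)) {
        pose_k <- if (k == n_sub) pose_b
        else .interp_pose(pose_a, pose_b, k / n_sub)
        out <- solve_pose(q_try, pose_k)
        if (!out$ok && last) {
          # viscous-stabilised rescue, polished unstabilised, once per frame
          s1 <- settings$stabilization_frac * max(stab_ref, 1e-8)
          o1 <- solve_pose(q_try, pose_k, stab = s1)
          if (o1$ok) {
            o2 <- solve_pose(o1$q, pose_k)
            out <- if (o2$ok) o2 else { o1$stabilized <- TRUE; o1 }
          }
          last <- FALSE
        }
        if (!out$ok) { ok <- FALSE; break }
        q_try <- out$q
      }
      if (ok) return(out)
    }
    # terminal fallback: damped pseudo-dynamics through the increment (the
    # quasi-static analogue of riding a limit point with an explicit solver),
    # followed by a Newton polish; the state is flagged when the polish does
    # not reach the strict tolerance
    if (settings$allow_relaxed) {
      pp <- if (!is.null(head)) .posed_rigid(head, pose_b)
      pr <- if (!is.null(head))
        list(cxp = .contact_prepare(pp$verts, head$tris,
                                    settings$search_radius, pp$center),
             head = head)
      g0 <- grad_red_at(red$to_u(q), pr)
      if (!is.null(g0)) {
        md <- if (!is.null(out$mdiag)) out$mdiag else rep(1, red$nq)
        q_dr <- dr_relax(q, pr, md, settings$newton_tol,
                         n_steps = max(settings$dr_steps, 400))
        pol <- solve_pose(q_dr, pose_b)
        if (pol$ok) return(pol)
        u <- red$to_u(q_dr)
        gr <- grad_red_at(u, pr)
        if (!is.null(gr)) {
          gaps <- if (!is.null(pr))
            contact_query_free(pr$cxp, ops$nodes + u, settings$search_radius)
          return(list(ok = TRUE, relaxed = TRUE, q = q_dr,
                      res = sqrt(sum(gr^2)), iters = NA_integer_,
                      gaps = gaps, fext = NULL, energy = energy_at(u, pr)))
        }
      }
    }
    out
  }

  frames <- trajectory$frames
  states <- vector("list", length(frames))
  log <- vector("list", length(frames))
  q <- if (is.null(u0)) numeric(red$nq)
  else as.numeric(Matrix::crossprod(red$Z, as.numeric(t(u0))))
  pose_prev <- frames[[1]]$transform
  t_start <- proc.time()[3]
  for (fi in seq_along(frames)) {
    pose <- frames[[fi]]$transform
    upd <- 0L
    pen_bound <- settings$max_penetration_frac * thick
    fallback <- NULL
    repeat {
      out <- solve_increment(q, pose_prev, pose, 0L)
      if (!out$ok && !is.null(fallback)) {
        # the stiffer penalty is no longer solvable: keep the last solvable
        # equilibrium and its penalty (penetration recorded in the log)
        penalty <- fallback$penalty
        out <- fallback$out
        break
      }
      if (!out$ok) {
        diag_df <- do.call(rbind, log[seq_len(fi - 1)])
        stop(errorCondition(
          sprintf("solver failed at frame %d (%s); %d frames converged",
                  fi, out$reason, fi - 1L),
          class = c("levatorfem_partial_result", "error", "condition"),
          states = states[seq_len(fi - 1)], diagnostics = diag_df))
      }
      dsat <- settings$contact_saturation_frac * thick
      dep <- if (!is.null(out$gaps)) out$gaps$depth else 0
      max_pen <- max(c(0, dep[dep < dsat]))   # shadow-band nodes excluded
      if (isTRUE(out$relaxed)) break
      if (max_pen <= pen_bound || upd >= settings$max_penalty_updates) break
      # secant update: aim the largest contact force at half the bound,
      # capped to a bounded growth per pass
      fallback <- list(penalty = penalty, out = out)
      penalty <- penalty * min(8, max(settings$penalty_growth,
                                      max_pen / (0.5 * pen_bound)))
      upd <- upd + 1L
    }
    if (isTRUE(out$relaxed) && stop_on_relaxed) {
      # quasi-static validity ends here: keep the strictly converged prefix
      if (verbose)
        message(sprintf(
          "frame %d reached only by relaxation; stopping with %d equilibria",
          fi, fi - 1L))
      states <- states[seq_len(fi - 1L)]
      log <- log[seq_len(fi - 1L)]
      break
    }
    q <- out$q
    prev_relaxed <<- isTRUE(out$relaxed)
    # lagged force scale for the relative tolerance; growth is capped so a
    # single penetration-heavy frame cannot blow the tolerance open
    fext_ref <- max(1e-6, min(out$fext %||% fext_ref, 10 * fext_ref))
    # decay an over-grown penalty once contact eases (keeps conditioning sane)
    if (max_pen < 0.05 * pen_bound && penalty > 100 * penalty0)
      penalty <- penalty / 2
    u <- red$to_u(q)
    st <- .fe_element_state(ops$nodes, ops$tets, ops$Bm, ops$vol0, u,
                            params$mu, params$alpha, params$K)
    states[[fi]] <- list(
      frame = fi, station = frames[[fi]]$station,
      relaxed = isTRUE(out$relaxed),
      displacements = u,
      F = st$F, cauchy = st$cauchy, vm = st$vm, J = st$J,
      contact = if (!is.null(out$gaps)) out$gaps$hit else integer(nrow(u)),
      residual = out$res, energy = out$energy)
    log[[fi]] <- data.frame(frame = fi, station = frames[[fi]]$station,
                            relaxed = isTRUE(out$relaxed),
                            iters = out$iters, residual = out$res,
                            energy = out$energy,
                            max_penetration = if (!is.null(out$gaps))
                              max(c(0, out$gaps$depth)) else 0,
                            penalty = penalty, penalty_updates = upd,
                            elapsed_s = proc.time()[3] - t_start)
    pose_prev <- pose
    gc(FALSE)
    .malloc_trim()
    if (verbose)
      message(sprintf("frame %3d station %+d: %2d iters, res %.3g, pen %.3g mm",
                      fi, frames[[fi]]$station, out$iters, out$res,
                      if (!is.null(out$gaps)) max(c(0, out$gaps$depth)) else 0))
  }
  structure(list(states = states, mesh = mesh, params = params, bcs = bcs,
                 trajectory = trajectory, settings = settings, head = head,
                 penalty_final = penalty,
                 diagnostics = do.call(rbind, log)),
            class = "delivery_fem")
}

#' @export
print.delivery_fem <- function(x, ...) {
  n <- length(x$states)
  vmax <- max(vapply(x$states, function(s) max(c(0, s$vm), na.rm = TRUE), numeric(1)))
  cat(sprintf("delivery_fem: %d equilibrium states, %d elements, peak von Mises %.4g MPa\n",
              n, nrow(x$mesh$tets), vmax))
  invisible(x)
}
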