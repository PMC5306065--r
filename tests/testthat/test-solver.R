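# FE solver: internal forces, contact, patch test, sphere-through-ring

test_that("internal forces vanish at rest and for rigid-body motion", {
  m <- two_tet_mesh()
  p <- ref_params()
  expect_equal(max(abs(internal_forces(m, p, matrix(0, 5, 3)))), 0)
  R <- levatorfem:::rot_z(33) %*% levatorfem:::rot_x(12)
  urot <- m$nodes %*% t(R) - m$nodes + rep(1, 5) %o% c(3, -1, 2)
  expect_lt(max(abs(internal_forces(m, p, urot))), 1e-8)
})

test_that("internal forces equal the finite-difference energy gradient", {
  m <- two_tet_mesh()
  p <- ref_params()
  set.seed(2)
  u <- matrix(rnorm(15, sd = 0.08), 5, 3)
  G <- internal_forces(m, p, u)
  h <- 1e-6
  Gfd <- u * 0
  for (i in 1:5) for (r in 1:3) {
    up <- u; up[i, r] <- up[i, r] + h
    um <- u; um[i, r] <- um[i, r] - h
    Gfd[i, r] <- (total_strain_energy(m, p, up) -
                    total_strain_energy(m, p, um)) / (2 * h)
  }
  expect_lt(max(abs(G - Gfd)) / max(abs(Gfd)), 1e-4)
  # inversion is reported with the offending elements
  ubad <- u; ubad[5, ] <- c(-10, -10, -10)
  err <- tryCatch(internal_forces(m, p, ubad), condition = identity)
  expect_s3_class(err, "levatorfem_inversion_error")
  expect_true(length(err$elements) >= 1)
})

test_that("contact forces are frictionless, penalty-linear, and match exhaustive search", {
  sph <- sphere_surface(radius = 10, edge_frac = 0.1)
  # no penetration
  far <- matrix(c(0, 0, 20, 15, 0, 0), 2, 3, byrow = TRUE)
  cf <- contact_forces(far, sph, penalty = 3)
  expect_equal(max(abs(cf$forces)), 0)
  # single node at depth d: force = penalty * d, radially outward
  d <- 1.3
  pts <- matrix(c(0, 0, 10 - d), 1, 3)
  cf <- contact_forces(pts, sph, penalty = 3)
  expect_equal(sum(cf$depth > 0), 1)
  expect_equal(cf$depth[1], d, tolerance = 0.03)
  expect_equal(sqrt(sum(cf$forces^2)), 3 * cf$depth[1], tolerance = 1e-12)
  nrm <- cf$forces / sqrt(sum(cf$forces^2))
  expect_gt(sum(nrm * c(0, 0, 1)), 0.999)  # radial, no tangential component
  # randomised cloud vs brute-force nearest-point over every triangle
  set.seed(9)
  cloud <- matrix(rnorm(60, sd = 6), 20, 3)
  cf <- contact_forces(cloud, sph, penalty = 2)
  v <- sph$nodes
  for (i in seq_len(nrow(cloud))) {
    dists <- vapply(seq_len(nrow(sph$tris)), function(t) {
      tri <- v[sph$tris[t, ], , drop = FALSE]
      # brute-force closest point via quadratic programming on barycentrics
      min(vapply(seq(0, 1, by = 0.05), function(a)
        min(vapply(seq(0, 1 - a, by = 0.05), function(b)
          sqrt(sum((tri[1, ] + a * (tri[2, ] - tri[1, ]) +
                      b * (tri[3, ] - tri[1, ]) - cloud[i, ])^2)),
          numeric(1))), numeric(1)))
    }, numeric(1))
    inside <- sqrt(sum(cloud[i, ]^2)) < 10
    if (inside && cf$depth[i] > 0.05)
      expect_equal(cf$depth[i], min(dists), tolerance = 0.05)
    if (!inside) expect_equal(cf$depth[i], 0)
  }
  expect_error(contact_forces(cloud, sph, penalty = -1),
               class = "levatorfem_invalid_input")
})

test_that("single-element uniaxial patch test matches the closed-form Cauchy stress", {
  p <- ref_params()
  X <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3))
  mesh <- list(nodes = X, tets = matrix(1:4, 1), thickness = 1, target_edge = 3)
  lam <- 1.35
  F <- diag(c(lam, lam^-0.5, lam^-0.5))
  bcs <- boundary_condition_set(fixed_nodes = 1:4,
                                fixed_values = X %*% (t(F) - diag(3)),
                                tether_stiffness = 1)
  fem <- solve_quasistatic(mesh, p, bcs, make_traj(list(rigid_transform())))
  st <- fem$states[[1]]
  expect_equal(matrix(st$F[1, ], 3, 3, byrow = TRUE), F, tolerance = 1e-10)
  sig <- cauchy_stress(p, F)
  got <- st$cauchy[1, ]  # xx, yy, zz, xy, yz, zx
  expect_equal(got[1:3], diag(sig), tolerance = 1e-4)
  expect_equal(st$vm[1], von_mises(sig), tolerance = 1e-6)
  # the axial-lateral stress difference is the nominal-to-true conversion
  expect_equal(got[1] - got[2], lam * uniaxial_nominal_stress(p, lam),
               tolerance = 1e-8)
})

test_that("a distant rigid body leaves the shell undeformed and stress-free", {
  p <- ref_params()
  rg <- ring_mesh(edge = 3)
  mesh <- list(nodes = rg$nodes, tets = rg$tets, thickness = rg$thickness,
               target_edge = rg$target_edge)
  bcs <- boundary_condition_set(fixed_nodes = rg$outer_ring)
  sph <- sphere_surface(radius = 9, edge_frac = 0.2)
  poses <- lapply(c(100, 90, 80), function(z) rigid_transform(t = c(0, 0, z)))
  fem <- solve_quasistatic(mesh, p, bcs, make_traj(poses), head = sph)
  for (s in fem$states) {
    expect_equal(max(abs(s$displacements)), 0)
    expect_equal(max(s$vm), 0, tolerance = 1e-12)
  }
})

test_that("sphere-through-ring: force balance, BC fidelity, peak timing, determinism", {
  p <- ref_params()
  rg <- ring_mesh(r_in = 6, r_out = 16, thick = 2, edge = 2.5)
  mesh <- list(nodes = rg$nodes, tets = rg$tets, thickness = rg$thickness,
               target_edge = rg$target_edge)
  bcs <- boundary_condition_set(fixed_nodes = rg$outer_ring)
  sph <- sphere_surface(radius = 9, edge_frac = 0.12)
  zs <- seq(12, 4, by = -1)
  fem <- solve_quasistatic(mesh, p, bcs,
                           make_traj(lapply(zs, function(z)
                             rigid_transform(t = c(0, 0, z)))),
                           head = sph)
  n <- length(fem$states)
  # ring aperture stretch grows as the sphere pushes deeper; peak von Mises
  # must occur at a frame of maximal aperture stretch (the last frames)
  aperture <- vapply(fem$states, function(s) {
    inner <- mesh$nodes[rg$inner_ring, , drop = FALSE] +
      s$displacements[rg$inner_ring, , drop = FALSE]
    mean(sqrt(inner[, 1]^2 + inner[, 2]^2))
  }, numeric(1))
  peak_vm <- vapply(fem$states, function(s) max(s$vm), numeric(1))
  expect_identical(which.max(peak_vm), which.max(aperture))
  expect_gt(aperture[n], aperture[1])
  # Newton's third law: the reaction on the sphere equals minus the summed
  # nodal contact forces, recomputed independently
  st <- fem$states[[n]]
  x <- mesh$nodes + st$displacements
  cf <- contact_forces(x, sph, pose = rigid_transform(t = c(0, 0, zs[n])),
                       penalty = fem$penalty_final,
                       search_radius = fem$settings$search_radius)
  reaction <- -colSums(cf$forces)
  ids <- which(cf$depth > 0)
  acc <- c(0, 0, 0)
  for (i in ids) acc <- acc + fem$penalty_final * cf$depth[i] * cf$normal[i, ]
  expect_equal(reaction, -acc, tolerance = 1e-9)
  expect_gt(sqrt(sum(acc^2)), 0)
  # BC fidelity: fixed ring exactly immobile
  expect_equal(max(abs(st$displacements[rg$outer_ring, ])), 0)
  # equilibrium: the residual reported is below the solver tolerance scale
  expect_lt(st$residual, 1e-2)
  # determinism: identical inputs give bit-identical states
  fem2 <- solve_quasistatic(mesh, p, bcs,
                            make_traj(lapply(zs, function(z)
                              rigid_transform(t = c(0, 0, z)))),
                            head = sph)
  expect_identical(fem$states[[n]]$displacements, fem2$states[[n]]$displacements)
  expect_identical(fem$states[[n]]$vm, fem2$states[[n]]$vm)
})

test_that("plane-constrained nodes stay exactly in their plane", {
  p <- ref_params()
  rg <- ring_mesh(edge = 3)
  mesh <- list(nodes = rg$nodes, tets = rg$tets, thickness = rg$thickness,
               target_edge = rg$target_edge)
  nrm <- c(0, 0, 1)
  bcs <- boundary_condition_set(fixed_nodes = rg$outer_ring,
                                plane_nodes = rg$inner_ring,
                                plane_normal = nrm)
  sph <- sphere_surface(radius = 9, edge_frac = 0.2)
  fem <- solve_quasistatic(mesh, p, bcs,
                           make_traj(list(rigid_transform(t = c(2, 0, 12)),
                                          rigid_transform(t = c(2, 0, 9)))),
                           head = sph)
  st <- fem$states[[2]]
  expect_lt(max(abs(st$displacements[rg$inner_ring, ] %*% nrm)), 1e-8)
  expect_gt(max(abs(st$displacements[rg$inner_ring, 1:2])), 0)  # slid in-plane
})

test_that("hopeless increments fail with a partial-result error carrying the prefix", {
  p <- ref_params()
  rg <- ring_mesh(edge = 3)
  mesh <- list(nodes = rg$nodes, tets = rg$tets, thickness = rg$thickness,
               target_edge = rg$target_edge)
  bcs <- boundary_condition_set(fixed_nodes = rg$outer_ring)
  sph <- sphere_surface(radius = 9, edge_frac = 0.2)
  poses <- list(rigid_transform(t = c(0, 0, 30)),
                rigid_transform(t = c(0, 0, 0)))  # teleport into the aperture
  err <- tryCatch(
    solve_quasistatic(mesh, p, bcs, make_traj(poses), head = sph,
                      settings = solver_settings(max_iter = 2,
                                                 max_substep_depth = 1,
                                                 max_penalty_updates = 1,
                                                 allow_relaxed = FALSE)),
    condition = identity)
  expect_s3_class(err, "levatorfem_partial_result")
  expect_length(err$states, 1)
})
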