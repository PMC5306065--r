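# shared fixtures, built in code at test time

ref_params <- function() lam_material()

# two-tet patch used for force/energy checks
two_tet_mesh <- function() {
  list(nodes = rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(0, 0, 4),
                     c(4, 4, 4)),
       tets = rbind(c(1L, 2L, 3L, 4L), c(2L, 3L, 4L, 5L)))
}

# unit icosphere fixture as a rigid surface of given radius
sphere_surface <- function(radius = 10, edge_frac = 0.15) {
  ic <- levatorfem:::.icosphere(edge_frac)
  levatorfem:::.rigid_surface(ic$v * radius, ic$f,
                              rbind(center = c(0, 0, 0)),
                              role = "sphere")
}

# annulus plate with a central hole, extruded to a thin tet mesh: the
# sphere-through-ring fixture used in solver tests
ring_mesh <- function(r_in = 6, r_out = 16, thick = 2, edge = 2.5) {
  n_th <- 4L * max(3L, ceiling(2 * pi * (r_in + r_out) / 2 / edge / 4))
  n_r <- max(3L, ceiling((r_out - r_in) / edge))
  n_l <- 2L
  th <- (seq_len(n_th) - 1) * 2 * pi / n_th
  rv <- seq(r_out, r_in, length.out = n_r + 1)
  nid <- function(it, is, il) as.integer(((il - 1) * (n_r + 1) + (is - 1)) * n_th + it)
  nodes <- matrix(0, n_th * (n_r + 1) * n_l, 3)
  for (is in seq_len(n_r + 1)) for (il in seq_len(n_l)) {
    z <- thick * ((il - 1) / (n_l - 1) - 0.5)
    nodes[nid(seq_len(n_th), is, il), ] <- cbind(rv[is] * cos(th),
                                                 rv[is] * sin(th), z)
  }
  hex_split <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                     c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  tets <- NULL
  for (il in seq_len(n_l - 1)) for (is in seq_len(n_r)) for (it in seq_len(n_th)) {
    itn <- it %% n_th + 1L
    corners <- c(nid(it, is, il), nid(itn, is, il), nid(itn, is + 1L, il),
                 nid(it, is + 1L, il), nid(it, is, il + 1L),
                 nid(itn, is, il + 1L), nid(itn, is + 1L, il + 1L),
                 nid(it, is + 1L, il + 1L))
    tets <- rbind(tets, matrix(corners[t(hex_split)], 6, 4, byrow = TRUE))
  }
  vol <- tet_volumes(nodes, tets)
  flip <- which(vol < 0)
  if (length(flip)) {
    tmp <- tets[flip, 3]; tets[flip, 3] <- tets[flip, 4]; tets[flip, 4] <- tmp
  }
  outer_ring <- as.integer(sapply(1:n_l, function(il) nid(seq_len(n_th), 1L, il)))
  inner_ring <- as.integer(sapply(1:n_l, function(il) nid(seq_len(n_th), n_r + 1L, il)))
  list(nodes = nodes, tets = tets, thickness = thick, target_edge = edge,
       outer_ring = sort(outer_ring), inner_ring = sort(inner_ring))
}

# random stable Ogden parameter sets for property-style tests
random_stable_params <- function(n = 1, seed = 42) {
  set.seed(seed)
  out <- list()
  while (length(out) < n) {
    mu <- 10^runif(2, -5, -3)
    al <- sort(runif(2, 0.8, 20))
    if (sum(mu * al) > 0)
      out[[length(out) + 1L]] <- ogden_params(mu, al)
  }
  out
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# ad-hoc trajectory from a list of rigid poses
make_traj <- function(poses, stations = seq_along(poses)) {
  structure(list(frames = lapply(seq_along(poses), function(i)
    list(time = i - 1, station = stations[i], transform = poses[[i]]))),
    class = "head_trajectory")
}
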