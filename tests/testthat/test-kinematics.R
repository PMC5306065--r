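# cardinal-movements trajectory: transforms, net motion, stations

test_that("rigid transforms validate orthogonality and compose correctly", {
  expect_error(rigid_transform(matrix(rnorm(9), 3, 3)),
               class = "levatorfem_invalid_input")
  R <- levatorfem:::rot_z(30)
  tf <- rigid_transform(R, c(1, 2, 3))
  p <- c(1, 0, 0)
  expect_equal(apply_transform(tf, p), as.numeric(R %*% p + c(1, 2, 3)))
  tf2 <- compose_transform(tf, rigid_transform(levatorfem:::rot_x(40), c(0, 1, 0)))
  expect_equal(apply_transform(tf2, p),
               apply_transform(rigid_transform(levatorfem:::rot_x(40), c(0, 1, 0)),
                               apply_transform(tf, p)))
})

test_that("default trajectory reproduces the configured net motion exactly", {
  tr <- build_trajectory(trajectory_config())
  n <- length(tr$frames)
  expect_equal(tr$centroid_track[n, 2] - tr$centroid_track[1, 2], 100.0,
               tolerance = 1e-9)
  ang <- decompose_net_rotation(tr)
  expect_equal(unname(ang["extension"]), 80.25, tolerance = 1e-9)
  expect_equal(unname(ang["internal_rotation"]), 40.13, tolerance = 1e-9)
  expect_equal(unname(ang["lateral_straightening"]), 28.66, tolerance = 1e-9)
  # no lateral shift at any frame
  expect_equal(max(abs(tr$centroid_track[, 1])), 0)
})

test_that("every frame rotation is proper orthogonal and descent is monotone", {
  tr <- build_trajectory(trajectory_config())
  for (f in tr$frames) {
    R <- f$transform$R
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-10)
    expect_equal(det(R), 1, tolerance = 1e-10)
  }
  expect_true(all(diff(tr$vertex_track[, 3]) <= 1e-9))
  st <- vapply(tr$frames, `[[`, numeric(1), "station")
  expect_true(all(diff(st) >= 0))
  # anterior displacement monotone during the descent (curve-of-Carus) phase
  n_desc <- 8 * 5 + 1
  expect_true(all(diff(tr$centroid_track[1:n_desc, 2]) >= -1e-12))
  # internal rotation completes at the configured station and extension
  # only happens afterwards (the nominal schedule reaches +3 after six
  # stations of descent)
  cfgd <- trajectory_config()
  i_done <- (cfgd$rotation_complete_station - cfgd$start_station) *
    cfgd$frames_per_station + 1L
  sub <- tr; sub$frames <- tr$frames[c(1, i_done)]
  ang <- decompose_net_rotation(sub)
  expect_equal(unname(ang["internal_rotation"]), 40.13, tolerance = 1e-6)
  expect_equal(unname(ang["extension"]), 0, tolerance = 1e-9)
})

test_that("station bookkeeping follows the 1 cm schedule", {
  v <- c(0, 0, 47)
  lift <- function(z) rigid_transform(t = c(0, 0, z - 47))
  expect_identical(station_of(lift(0), vertex_local = v), 0L)
  expect_identical(station_of(lift(10), vertex_local = v), -1L)
  expect_identical(station_of(lift(-30), vertex_local = v), 3L)
  pel <- build_pelvis()
  expect_identical(station_of(lift(10), pelvis = pel, vertex_local = v), -1L)
})

test_that("rotation decomposition round-trips and scales", {
  expect_equal(unname(decompose_net_rotation(list(frames = list(
    list(transform = rigid_transform()),
    list(transform = rigid_transform()))))), c(0, 0, 0))
  set.seed(8)
  for (k in 1:12) {
    e <- runif(1, -80, 80); r <- runif(1, -70, 70); s <- runif(1, -60, 60)
    tr <- list(frames = list(
      list(transform = rigid_transform()),
      list(transform = rigid_transform(levatorfem:::.relative_rotation(e, r, s)))))
    ang <- decompose_net_rotation(tr)
    expect_equal(unname(ang), c(e, r, s), tolerance = 1e-6)
  }
  # doubled configured angles give doubled decomposed angles
  cfg2 <- trajectory_config(extension_deg = 2 * 80.25,
                            internal_rotation_deg = 2 * 40.13,
                            lateral_deviation_deg = 2 * 28.66)
  ang2 <- decompose_net_rotation(build_trajectory(cfg2))
  expect_equal(unname(ang2), 2 * c(80.25, 40.13, 28.66), tolerance = 1e-8)
  # gimbal-degenerate internal rotation of 90 degrees is reported as ambiguous
  trg <- list(frames = list(
    list(transform = rigid_transform()),
    list(transform = rigid_transform(levatorfem:::.relative_rotation(10, 90, 5)))))
  expect_error(decompose_net_rotation(trg), class = "levatorfem_ambiguity_error")
})

test_that("trajectory configs are validated", {
  expect_error(trajectory_config(end_station = -5),
               class = "levatorfem_invalid_input")
  expect_error(trajectory_config(rotation_complete_station = 9),
               class = "levatorfem_invalid_input")
  expect_error(trajectory_config(carus_radius = 10),
               class = "levatorfem_invalid_input")
  expect_error(build_trajectory(list()), class = "levatorfem_invalid_input")
})
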