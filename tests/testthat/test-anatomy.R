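# parametric anatomy: landmark fidelity, mesh validity, labelling

test_that("fetal head landmark distances reproduce the four diameters", {
  h <- build_fetal_head(target_edge = 8)
  expect_equal(measure_landmark_distance(h, "parietal_left", "parietal_right"),
               93.7, tolerance = 93.7 * 0.005)
  expect_equal(measure_landmark_distance(h, "occiput", "sinciput"),
               105.7, tolerance = 105.7 * 0.005)
  expect_equal(measure_landmark_distance(h, "suboccipital", "bregma"),
               100.3, tolerance = 100.3 * 0.005)
  expect_equal(measure_landmark_distance(h, "occiput", "mentum"),
               131.9, tolerance = 131.9 * 0.005)
})

test_that("head landmark distances scale with the dimensions and survive refinement", {
  d2 <- head_dimensions(2 * 100.3, 2 * 105.7, 2 * 131.9, 2 * 93.7)
  h2 <- build_fetal_head(d2, target_edge = 10)
  expect_equal(measure_landmark_distance(h2, "occiput", "mentum"),
               2 * 131.9, tolerance = 2 * 131.9 * 0.005)
  h_fine <- build_fetal_head(target_edge = 4)
  h_coarse <- build_fetal_head(target_edge = 8)
  for (pair in list(c("parietal_left", "parietal_right"),
                    c("suboccipital", "bregma")))
    expect_equal(measure_landmark_distance(h_fine, pair[1], pair[2]),
                 measure_landmark_distance(h_coarse, pair[1], pair[2]),
                 tolerance = 0.005 * 100)
  expect_gt(nrow(h_fine$tris), nrow(h_coarse$tris))
  expect_error(head_dimensions(occipitofrontal = 200),
               class = "levatorfem_invalid_input")
  expect_error(build_fetal_head(target_edge = -1),
               class = "levatorfem_invalid_input")
})

test_that("pelvis landmarks reproduce the printed diameters and degenerate dims error", {
  p <- build_pelvis(target_edge = 8)
  expect_equal(measure_landmark_distance(p, "spine_left", "spine_right"),
               146.7, tolerance = 146.7 * 0.005)
  expect_equal(measure_landmark_distance(p, "inlet_left", "inlet_right"),
               148.8, tolerance = 148.8 * 0.005)
  expect_equal(measure_landmark_distance(p, "inlet_anterior", "inlet_posterior"),
               113.4, tolerance = 113.4 * 0.005)
  expect_equal(measure_landmark_distance(p, "outlet_anterior", "outlet_posterior"),
               145.1, tolerance = 145.1 * 0.005)
  expect_error(pelvis_dimensions(interspinous = -1),
               class = "levatorfem_invalid_input")
  expect_error(measure_landmark_distance(p, "spine_left", "nope"),
               class = "levatorfem_lookup_error")
})

test_that("landmark distances are pose-invariant", {
  h <- build_fetal_head(target_edge = 10)
  d0 <- measure_landmark_distance(h, "occiput", "mentum")
  tf <- rigid_transform(levatorfem:::rot_z(73) %*% levatorfem:::rot_x(-21),
                        c(12, -40, 7))
  h2 <- set_pose(h, tf)
  expect_equal(measure_landmark_distance(h2, "occiput", "mentum"), d0,
               tolerance = 1e-10)
  expect_equal(measure_landmark_distance(h, "vertex", "vertex"), 0)
})

test_that("levator mesh is valid, fully labelled, and carries all node sets", {
  m <- build_levator(target_edge = 6)
  expect_true(all(m$volumes > 0))
  expect_true(all(!is.na(m$region)))
  expect_true(all(table(m$region) > 0))
  expect_identical(sort(unique(as.character(m$region))),
                   sort(c("ICm", "PVm", "PRm")))
  need <- c("pubic_attachment", "atml_coupling", "sacral_attachment",
            "cranial_plane_constrained", "distal_prm_loop")
  for (s in need) {
    expect_gt(length(m$sets[[s]]), 0)
    expect_true(all(m$sets[[s]] >= 1 & m$sets[[s]] <= nrow(m$nodes)))
  }
  expect_gt(length(m$mediosagittal_trace), 3)
  expect_true(check_watertight(m))
  # constraint sets disjoint from the fixed attachments
  fixed <- union(m$sets$pubic_attachment, m$sets$sacral_attachment)
  expect_length(intersect(fixed, m$sets$cranial_plane_constrained), 0)
  expect_error(build_levator(shell_thickness = 0),
               class = "levatorfem_invalid_input")
  expect_error(build_levator(hiatus_dims = c(300, 55)),
               class = "levatorfem_invalid_input")
})

test_that("levator region volume fractions are resolution-stable", {
  frac <- function(m) {
    v <- tapply(m$volumes, m$region, sum)
    v / sum(v)
  }
  f4 <- frac(build_levator(target_edge = 4))
  f8 <- frac(build_levator(target_edge = 8))
  expect_equal(unname(f4), unname(f8), tolerance = 0.05)
})

test_that("the hiatal opening is smaller than the presenting head circumference", {
  m <- build_levator()
  rim <- pi * sum(m$hiatus_dims) / 2  # Ramanujan-light ellipse bound
  expect_lt(rim, pi * 100.3)          # suboccipitobregmatic circumference
})
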