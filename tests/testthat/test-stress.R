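# regional summaries, loading order, elongation: brute-force oracles on
# small synthetic fixtures

fake_state <- function(vm, disp = NULL, station = 0L, n_nodes = NULL) {
  list(vm = vm, station = station,
       displacements = if (is.null(disp)) matrix(0, n_nodes, 3) else disp)
}

test_that("region summaries are volume-weighted and match a brute-force loop", {
  m <- build_levator(target_edge = 8)
  n_el <- nrow(m$tets)
  st0 <- fake_state(rep(0, n_el), n_nodes = nrow(m$nodes))
  r0 <- region_summary(st0, m, "ICm")
  expect_equal(unname(unlist(r0[c("mean", "min", "max", "sd")])), rep(0, 4))
  # two congruent (equal-volume) elements at 1 and 3 MPa: closed-form stats
  fix <- list(nodes = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                            c(2 / 3, 2 / 3, 2 / 3)),
              tets = rbind(c(1L, 2L, 3L, 4L), c(5L, 2L, 4L, 3L)))
  fix$volumes <- tet_volumes(fix$nodes, fix$tets)
  expect_equal(fix$volumes[1], fix$volumes[2], tolerance = 1e-12)
  s <- region_summary(fake_state(c(1, 3), n_nodes = 5), fix, c(1L, 2L))
  expect_equal(s$mean, 2)
  expect_equal(s$min, 1)
  expect_equal(s$max, 3)
  expect_equal(s$sd, 1)  # population SD of {1, 3}
  # random fixture vs independent loop
  set.seed(5)
  vm <- runif(n_el, 0, 10)
  ids <- region_elements(m, "ICm")
  r <- region_summary(fake_state(vm, n_nodes = nrow(m$nodes)), m, "ICm")
  w <- m$volumes[ids]; x <- vm[ids]
  mu <- sum(w * x) / sum(w)
  expect_equal(r$mean, mu, tolerance = 1e-12)
  expect_equal(r$sd, sqrt(sum(w * (x - mu)^2) / sum(w)), tolerance = 1e-12)
  expect_equal(r$min, min(x))
  expect_equal(r$max, max(x))
  expect_true(r$min <= r$mean && r$mean <= r$max)
  expect_error(region_elements(m, "nope"), class = "levatorfem_lookup_error")
})

test_that("the three reporting regions are distinct, non-empty element sets", {
  m <- build_levator(target_edge = 6)
  icm <- region_elements(m, "ICm")
  pub <- region_elements(m, "pubic_attachment")
  prm <- region_elements(m, "posteromedial_PRm")
  expect_gt(length(icm), 0)
  expect_gt(length(pub), 0)
  expect_gt(length(prm), 0)
  expect_length(intersect(icm, pub), 0)    # ICm excluded from pubic zone
  expect_length(intersect(pub, prm), 0)    # anterior vs posterior split
  # pubic zone elements hug the pubic attachment nodes
  cent <- (m$nodes[m$tets[pub, 1], ] + m$nodes[m$tets[pub, 2], ] +
             m$nodes[m$tets[pub, 3], ] + m$nodes[m$tets[pub, 4], ]) / 4
  pubn <- m$nodes[m$sets$pubic_attachment, , drop = FALSE]
  dmin <- apply(cent, 1, function(p) sqrt(min(colSums((t(pubn) - p)^2))))
  expect_true(all(dmin <= 25 + 1e-9))
})

test_that("loading order sorts regions by first engagement with threshold and ties", {
  summ <- data.frame(
    frame = rep(1:10, each = 2),
    station = rep(1:10, each = 2),
    region = rep(c("ICm", "PRm"), 10),
    mean = c(rbind(c(0, 0, 1, 2, 3, 4, 5, 6, 7, 8),
                   c(0, 0, 0, 0, 0, 0, 2, 3, 4, 5))),
    min = 0, max = 1, sd = 0)
  lo <- loading_order(summ)
  expect_identical(lo$region, c("ICm", "PRm"))
  expect_identical(lo$first_frame, c(3L, 7L))
  zero <- summ; zero$mean <- 0
  expect_warning(lo0 <- loading_order(zero))
  expect_identical(nrow(lo0), 0L)
})

test_that("elongation report has exact closed-form behaviour on affine fixtures", {
  m <- build_levator(target_edge = 8)
  n <- nrow(m$nodes)
  id <- fake_state(rep(0, nrow(m$tets)), disp = matrix(0, n, 3))
  rep0 <- elongation_report(list(id), m)
  expect_equal(rep0$max_stretch_ratio, 1.0, tolerance = 1e-12)
  expect_equal(rep0$max_caudal_displacement_mm, 0)
  # uniform 2x affine stretch about the origin doubles the trace length
  aff <- fake_state(rep(0, nrow(m$tets)), disp = m$nodes)
  rep2 <- elongation_report(list(id, aff), m)
  expect_equal(rep2$max_stretch_ratio, 2.0, tolerance = 1e-12)
  expect_identical(rep2$frame_of_max, 2L)
  # rigid motion leaves the stretch ratio invariant
  R <- levatorfem:::rot_y(31)
  rig <- fake_state(rep(0, nrow(m$tets)),
                    disp = m$nodes %*% t(R) - m$nodes + rep(1, n) %o% c(3, -2, 5))
  repr <- elongation_report(list(rig), m)
  expect_equal(repr$stretch_ratio[1], 1.0, tolerance = 1e-10)
  # caudal displacement picks the largest -z over the distal loop
  dz <- matrix(0, n, 3)
  dz[m$sets$distal_prm_loop, 3] <- -12.5
  repc <- elongation_report(list(fake_state(rep(0, nrow(m$tets)), disp = dz)), m)
  expect_equal(repc$max_caudal_displacement_mm, 12.5)
  expect_error(elongation_report(list(id), list(nodes = m$nodes)),
               class = "levatorfem_lookup_error")
})

test_that("the stress table exports to CSV and round-trips", {
  f <- tempfile(fileext = ".csv")
  empty <- data.frame(frame = integer(), station = integer(),
                      region = character(), mean = numeric(),
                      min = numeric(), max = numeric(), sd = numeric())
  export_table(empty, f)
  expect_identical(readLines(f), "frame,station,region,mean,min,max,sd")
  one <- data.frame(frame = 1L, station = -3L, region = "ICm",
                    mean = 0.13, min = 0, max = 0.25, sd = 0.13)
  export_table(one, f)
  back <- utils::read.csv(f)
  expect_equal(back$mean, 0.13)
  expect_identical(nrow(back), 1L)
  many <- do.call(rbind, replicate(6, one, simplify = FALSE))
  many$frame <- rep(1:2, each = 3)
  export_table(many, f)
  expect_identical(nrow(utils::read.csv(f)), 6L)  # frames x regions
})
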