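# Ogden constitutive model: closed forms, frozen high-precision oracles,
# and frame-indifference / symmetry properties.

test_that("strain energy vanishes at the reference state and matches the frozen oracle", {
  p <- ref_params()
  expect_identical(strain_energy(p, c(1, 1, 1)), 0)
  # frozen value: 50-digit evaluation of the closed form at the isochoric
  # uniaxial state lambda = (1.5, 1.5^-1/2, 1.5^-1/2)
  W_oracle <- 0.021474876920893298
  expect_equal(strain_energy(p, c(1.5, 1.5^-0.5, 1.5^-0.5)), W_oracle,
               tolerance = 1e-12)
  for (ps in random_stable_params(5, seed = 7))
    expect_equal(strain_energy(ps, c(1, 1, 1)), 0)
})

test_that("strain energy is symmetric in the principal stretches", {
  p <- ref_params()
  set.seed(11)
  for (k in 1:20) {
    lam <- exp(rnorm(3, sd = 0.2))
    perm <- sample(3)
    expect_equal(strain_energy(p, lam), strain_energy(p, lam[perm]),
                 tolerance = 1e-13)
  }
  expect_error(strain_energy(p, c(1, -1, 1)), class = "levatorfem_invalid_input")
})

test_that("uniaxial nominal stress matches the frozen high-precision oracle on a 20-point grid", {
  p <- ref_params()
  # 50-digit evaluation of P(lambda) = sum 2 mu_j (l^(a_j-1) - l^(-a_j/2-1))
  # at 20 equispaced stretches on [1, 1.6]
  grid <- 1 + 0.6 * (0:19) / 19
  oracle <- c(0, 0.00032471396951932135, 0.00075698380296824704,
              0.0013752406958654872, 0.0022898184591763623,
              0.0036583903811075409, 0.0057067543392359253,
              0.0087569491303386149, 0.013265207079601467,
              0.019872925864824931, 0.029474701645382645,
              0.043308539436116375, 0.06307468642284339,
              0.091091168981573769, 0.13049611287375116,
              0.18550935670086413, 0.26176881057764721,
              0.36676055696321854, 0.51036594452872018,
              0.70555401042244313)
  P <- uniaxial_nominal_stress(p, grid)
  expect_identical(P[1], 0)
  expect_equal(P, oracle, tolerance = 1e-12)
  expect_equal(uniaxial_nominal_stress(p, 1.5), 0.24729215510704159,
               tolerance = 1e-12)
  expect_error(uniaxial_nominal_stress(p, 0), class = "levatorfem_invalid_input")
})

test_that("uniaxial stress is the stretch-derivative of the strain energy", {
  h <- 1e-7
  for (ps in c(list(ref_params()), random_stable_params(3, seed = 3))) {
    for (lam in c(1.1, 1.3, 1.55)) {
      W <- function(l) strain_energy(ps, c(l, l^-0.5, l^-0.5))
      dW <- (W(lam + h) - W(lam - h)) / (2 * h)
      expect_equal(uniaxial_nominal_stress(ps, lam), dW, tolerance = 1e-6)
    }
  }
})

test_that("P is strictly increasing on [1, 2] for stable parameter sets", {
  grid <- seq(1, 2, length.out = 60)
  for (ps in c(list(ref_params()), random_stable_params(8, seed = 5)))
    expect_true(all(diff(uniaxial_nominal_stress(ps, grid)) > 0))
})

test_that("Cauchy stress is symmetric, objective, and consistent with the uniaxial closed form", {
  p <- ref_params()
  expect_equal(max(abs(cauchy_stress(p, diag(3)))), 0, tolerance = 1e-14)
  lam <- 1.4
  F <- diag(c(lam, lam^-0.5, lam^-0.5))
  s <- cauchy_stress(p, F)
  # nominal-to-true conversion at J = 1: axial minus lateral stress equals
  # lambda * P(lambda) (the lateral pressure cancels in the difference)
  expect_equal(s[1, 1] - s[2, 2], lam * uniaxial_nominal_stress(p, lam),
               tolerance = 1e-10)
  set.seed(21)
  for (k in 1:10) {
    F <- diag(3) + matrix(rnorm(9, sd = 0.05), 3, 3)
    if (det(F) <= 0) next
    s <- cauchy_stress(p, F)
    expect_equal(s, t(s), tolerance = 1e-12)
    R <- random_rotation()
    expect_equal(cauchy_stress(p, R %*% F), R %*% s %*% t(R), tolerance = 1e-8)
  }
  expect_error(cauchy_stress(p, diag(c(-1, 1, 1))),
               class = "levatorfem_inversion_error")
})

test_that("cauchy_stress equals the finite-difference gradient of strain energy", {
  # dW/dF = P (first Piola-Kirchhoff); sigma = P F^T / J
  p <- ref_params()
  set.seed(31)
  h <- 1e-6
  for (k in 1:25) {
    F <- diag(3) + matrix(rnorm(9, sd = 0.04), 3, 3)
    J <- det(F)
    if (J < 0.95 || J > 1.05) next
    Wf <- function(Fm) {
      sv <- svd(Fm)$d
      strain_energy(p, sv)
    }
    P_fd <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      Fp <- F; Fp[i, j] <- Fp[i, j] + h
      Fm <- F; Fm[i, j] <- Fm[i, j] - h
      P_fd[i, j] <- (Wf(Fp) - Wf(Fm)) / (2 * h)
    }
    sig_fd <- P_fd %*% t(F) / J
    expect_equal(cauchy_stress(p, F), (sig_fd + t(sig_fd)) / 2,
                 tolerance = 1e-4)
  }
})

test_that("von Mises stress has the defining invariances", {
  expect_equal(von_mises(2.7 * diag(3)), 0)
  expect_equal(von_mises(diag(c(5, 0, 0))), 5)
  expect_equal(von_mises(diag(c(-3, 0, 0))), 3)
  set.seed(41)
  for (k in 1:15) {
    A <- matrix(rnorm(9), 3, 3)
    s <- (A + t(A)) / 2
    R <- random_rotation()
    expect_equal(von_mises(R %*% s %*% t(R)), von_mises(s), tolerance = 1e-10)
    expect_equal(von_mises(s + rnorm(1) * diag(3)), von_mises(s),
                 tolerance = 1e-9)
  }
  expect_error(von_mises(matrix(rnorm(9), 3, 3)),
               class = "levatorfem_invalid_input")
})

test_that("stability check implements the sum(mu*alpha) criterion with boundary excluded", {
  expect_true(stability_check(ref_params())$stable)
  expect_false(stability_check(mu = c(1, -1), alpha = c(1, 1))$stable)
  expect_false(stability_check(mu = c(0, 0), alpha = c(2, 9))$stable)
  expect_equal(stability_check(ref_params())$margin,
               sum(c(8e-5, 1.7e-4) * c(1.81, 17.25)))
  expect_error(stability_check(mu = c(1, 2), alpha = 1),
               class = "levatorfem_invalid_input")
  expect_error(ogden_params(mu = c(1, -1), alpha = c(1, 1)),
               class = "levatorfem_invalid_input")
})

test_that("bulk modulus follows from Poisson's ratio and the numerical shear modulus", {
  p <- ref_params()
  G <- shear_modulus_small_strain(p)
  # analytic small-strain shear modulus of this energy form is sum(mu*alpha)
  expect_equal(G, sum(p$mu * p$alpha), tolerance = 1e-6)
  expect_equal(p$K, 2 * G * 1.499 / (3 * 0.002), tolerance = 1e-6)
  expect_gt(p$K / G, 400)  # near-incompressible
})
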