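#' Ogden hyperelastic parameter set
#'
#' Constructs and validates an N-term Ogden parameter set for nearly
#' incompressible soft tissue. The strain energy density used throughout the
#' package is
#' \deqn{W = \sum_{i=1}^{3}\sum_{j=1}^{N} \frac{2\mu_j}{\alpha_j}
#'       (\bar\lambda_i^{\alpha_j} - 1) + \frac{K}{2}(J-1)^2,}
#' with isochoric principal stretches \eqn{\bar\lambda_i = J^{-1/3}\lambda_i}
#' and \eqn{J = \det F}. Units are MPa for the moduli \code{mu} and the bulk
#' modulus \code{K}; the exponents \code{alpha} are dimensionless.
#'
#' Small-deformation stability requires \eqn{\sum_j \mu_j \alpha_j > 0}; the
#' constructor enforces it (see [stability_check()]).
#'
#' If \code{K} is not supplied it is derived from Poisson's ratio \code{nu}
#' and the small-strain shear modulus implied by the Ogden set (computed
#' numerically from the uniaxial tangent, not assumed), via
#' \eqn{K = 2G(1+\nu) / (3(1-2\nu))}.
#'
#' @param mu numeric vector of shear-like moduli (MPa).
#' @param alpha numeric vector of exponents, same length as \code{mu}.
#' @param K bulk modulus (MPa), or \code{NULL} to derive it from \code{nu}.
#' @param nu Poisson's ratio used when \code{K} is \code{NULL}.
#' @param density mass density in tonne/mm^3 (consistent mm-MPa-N-tonne
#'   units); the default is 1.06e-9 tonne/mm^3, i.e. 1.06 kg/l, typical of
#'   mammalian skeletal muscle.
#' @return an object of class \code{ogden_params}.
#' @seealso [lam_material()] for the packaged levator ani reference set.
#' @export
ogden_params <- function(mu, alpha, K = NULL, nu = 0.499, density = 1.06e-9) {
  if (length(mu) != length(alpha))
    stop(errorCondition("mu and alpha must have the same length",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  if (length(mu) < 1L || !is.numeric(mu) || !is.numeric(alpha) ||
      any(!is.finite(mu)) || any(!is.finite(alpha)))
    stop(errorCondition("mu and alpha must be finite numeric vectors",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  st <- stability_check(mu = mu, alpha = alpha)
  if (!st$stable)
    stop(errorCondition(
      sprintf("unstable Ogden set: sum(mu*alpha) = %g <= 0", st$margin),
      class = c("levatorfem_invalid_input", "error", "condition")))
  obj <- structure(list(mu = as.numeric(mu), alpha = as.numeric(alpha),
                        K = NA_real_, nu = nu, density = density,
                        n_terms = length(mu)),
                   class = "ogden_params")
  if (is.null(K)) {
    if (!is.numeric(nu) || nu <= -1 || nu >= 0.5)
      stop(errorCondition("nu must lie in (-1, 0.5)",
                          class = c("levatorfem_invalid_input", "error", "condition")))
    K <- bulk_from_poisson(obj, nu)
  }
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0)
    stop(errorCondition("K must be a positive scalar",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  obj$K <- as.numeric(K)
  obj
}

#' @export
print.ogden_params <- function(x, ...) {
  cat(sprintf("Ogden material, %d term(s)\n", x$n_terms))
  for (j in seq_len(x$n_terms))
    cat(sprintf("  term %d: mu = %.6g MPa, alpha = %.6g\n", j, x$mu[j], x$alpha[j]))
  cat(sprintf("  bulk modulus K = %.6g MPa, stability margin sum(mu*alpha) = %.6g MPa\n",
              x$K, sum(x$mu * x$alpha)))
  invisible(x)
}

#' Reference levator ani material parameters
#'
#' The two-term Ogden set identified for passive levator ani muscle from a
#' cadaver uniaxial tension test: mu1 = 8e-5 MPa, mu2 = 1.7e-4 MPa,
#' alpha1 = 1.81, alpha2 = 17.25, Poisson's ratio 0.499 and density
#' 1.06 kg/l. This is the default material for every simulation in the
#' package.
#'
#' @return an \code{ogden_params} object.
#' @export
lam_material <- function() {
  ogden_params(mu = c(8e-5, 1.7e-4), alpha = c(1.81, 17.25), nu = 0.499)
}

#' Small-deformation stability check for an Ogden set
#'
#' An Ogden material behaves stably about the reference state when
#' \eqn{\sum_j \mu_j \alpha_j > 0} (the sum equals the small-strain shear
#' modulus of the energy form used here). The boundary value 0 is excluded.
#'
#' @param params an \code{ogden_params} object, or \code{NULL} if \code{mu}
#'   and \code{alpha} are given directly.
#' @param mu,alpha raw parameter vectors (used when \code{params} is NULL).
#' @return list with elements \code{stable} (logical) and \code{margin}
#'   (the value of \eqn{\sum \mu_j\alpha_j}, MPa).
#' @export
stability_check <- function(params = NULL, mu = NULL, alpha = NULL) {
  if (!is.null(params)) {
    mu <- params$mu; alpha <- params$alpha
  }
  if (length(mu) != length(alpha))
    stop(errorCondition("mu and alpha must have the same length",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  margin <- sum(mu * alpha)
  list(stable = is.finite(margin) && margin > 0, margin = margin)
}

.check_stretches <- function(stretches) {
  if (!is.numeric(stretches) || length(stretches) != 3L ||
      any(!is.finite(stretches)) || any(stretches <= 0))
    stop(errorCondition("principal stretches must be three strictly positive numbers",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  as.numeric(stretches)
}

#' Ogden strain energy density
#'
#' Evaluates the strain energy density (MPa) at a triple of principal
#' stretches, using the isochoric split \eqn{\bar\lambda_i = J^{-1/3}
#' \lambda_i} with \eqn{J = \lambda_1\lambda_2\lambda_3} and the volumetric
#' term \eqn{(K/2)(J-1)^2}. The energy is zero at the reference state and
#' symmetric in the three stretches.
#'
#' @param params an \code{ogden_params} object.
#' @param stretches numeric length-3 vector of principal stretches (> 0).
#' @return energy density, MPa (= N mm / mm^3).
#' @export
strain_energy <- function(params, stretches) {
  stretches <- .check_stretches(stretches)
  J <- prod(stretches)
  lbar <- J^(-1 / 3) * stretches
  W <- 0
  for (j in seq_len(params$n_terms))
    W <- W + sum(2 * params$mu[j] / params$alpha[j] * (lbar^params$alpha[j] - 1))
  W + params$K / 2 * (J - 1)^2
}

#' Uniaxial nominal (first Piola-Kirchhoff) stress
#'
#' Closed-form nominal stress for incompressible uniaxial tension
#' (\eqn{\lambda_2 = \lambda_3 = \lambda^{-1/2}}, \eqn{J = 1}):
#' \deqn{P(\lambda) = \sum_{j=1}^{N} 2\mu_j (\lambda^{\alpha_j - 1} -
#'       \lambda^{-\alpha_j/2 - 1}).}
#' Vectorised over \code{lam}.
#'
#' @param params an \code{ogden_params} object.
#' @param lam stretch(es), must be > 0.
#' @return nominal stress, MPa.
#' @export
uniaxial_nominal_stress <- function(params, lam) {
  if (!is.numeric(lam) || length(lam) < 1L || any(!is.finite(lam)) || any(lam <= 0))
    stop(errorCondition("stretch must be strictly positive",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  P <- numeric(length(lam))
  for (j in seq_len(params$n_terms)) {
    a <- params$alpha[j]
    P <- P + 2 * params$mu[j] * (lam^(a - 1) - lam^(-a / 2 - 1))
  }
  P
}

#' Cauchy stress from a deformation gradient
#'
#' Full Cauchy stress tensor of the (nearly incompressible) Ogden energy at
#' a deformation gradient \code{F}. Principal directions are taken from the
#' left Cauchy-Green tensor \eqn{b = FF^T}; the deviatoric principal
#' Kirchhoff stresses are
#' \eqn{\tau_i^{dev} = \beta_i - \frac13\sum_k \beta_k} with
#' \eqn{\beta_i = \sum_j 2\mu_j \bar\lambda_i^{\alpha_j}}, and the
#' volumetric part is \eqn{J K (J - 1)} on the diagonal. The returned tensor
#' is \eqn{\sigma = \tau / J}, symmetric and frame-indifferent.
#'
#' @param params an \code{ogden_params} object.
#' @param F 3x3 deformation gradient with positive determinant.
#' @return symmetric 3x3 Cauchy stress, MPa.
#' @export
cauchy_stress <- function(params, F) {
  if (!is.matrix(F) || any(dim(F) != c(3L, 3L)) || any(!is.finite(F)))
    stop(errorCondition("F must be a finite 3x3 matrix",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  J <- det(F)
  if (J <= 0)
    stop(errorCondition("element inversion: det(F) <= 0",
                        class = c("levatorfem_inversion_error", "error", "condition")))
  b <- F %*% t(F)
  eb <- eigen((b + t(b)) / 2, symmetric = TRUE)
  lam <- sqrt(pmax(eb$values, .Machine$double.eps))
  lbar <- J^(-1 / 3) * lam
  beta <- numeric(3)
  for (j in seq_len(params$n_terms))
    beta <- beta + 2 * params$mu[j] * lbar^params$alpha[j]
  tau <- (beta - mean(beta)) + J * params$K * (J - 1)
  sig <- eb$vectors %*% diag(tau / J) %*% t(eb$vectors)
  (sig + t(sig)) / 2
}

#' Von Mises equivalent stress
#'
#' \eqn{\sigma_{vm} = \sqrt{\frac{3}{2} s : s}} with \eqn{s} the deviator of
#' a symmetric Cauchy stress tensor. Invariant under rotations and under
#' added hydrostatic pressure.
#'
#' @param sigma symmetric 3x3 stress tensor (MPa).
#' @param tol relative symmetry tolerance.
#' @return scalar von Mises stress, MPa.
#' @export
von_mises <- function(sigma, tol = 1e-6) {
  if (!is.matrix(sigma) || any(dim(sigma) != c(3L, 3L)) || any(!is.finite(sigma)))
    stop(errorCondition("sigma must be a finite 3x3 matrix",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  scale <- max(abs(sigma), 1e-300)
  if (max(abs(sigma - t(sigma))) > tol * scale)
    stop(errorCondition("sigma is not symmetric within tolerance",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  s <- sigma - diag(sum(diag(sigma)) / 3, 3)
  sqrt(1.5 * sum(s * s))
}

#' Small-strain shear modulus implied by an Ogden set
#'
#' Computed numerically as one third of the uniaxial nominal tangent at the
#' reference state, \eqn{G = P'(1)/3}, by central differences. (For the
#' energy form used here this equals \eqn{\sum_j \mu_j\alpha_j} analytically;
#' the numerical route keeps the derivation independent of that identity.)
#'
#' @param params an \code{ogden_params} object.
#' @param h finite-difference step.
#' @return shear modulus, MPa.
#' @export
shear_modulus_small_strain <- function(params, h = 1e-6) {
  (uniaxial_nominal_stress(params, 1 + h) -
     uniaxial_nominal_stress(params, 1 - h)) / (2 * h) / 3
}

#' Bulk modulus from Poisson's ratio
#'
#' \eqn{K = 2G(1+\nu)/(3(1-2\nu))} with the small-strain shear modulus
#' \eqn{G} obtained numerically from the Ogden set.
#'
#' @param params an \code{ogden_params} object (its \code{K} is ignored).
#' @param nu Poisson's ratio, in (-1, 0.5).
#' @return bulk modulus, MPa.
#' @export
bulk_from_poisson <- function(params, nu = 0.499) {
  G <- shear_modulus_small_strain(params)
  2 * G * (1 + nu) / (3 * (1 - 2 * nu))
}
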