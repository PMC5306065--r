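#' @importFrom stats coef predict residuals fitted rnorm runif sd simulate
NULL

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Uniaxial stress-stretch dataset
#'
#' Validating constructor for a uniaxial tension dataset: stretches must be
#' strictly increasing with \code{stretch[1] >= 1}, and the nominal stress
#' vector must match in length.
#'
#' @param stretch numeric vector of stretches (dimensionless, >= 1).
#' @param stress numeric vector of nominal stresses (MPa).
#' @param provenance "synthetic" or "user-file".
#' @return a data frame of class \code{uniaxial_data} with columns
#'   \code{stretch} and \code{nominal_stress_mpa}.
#' @export
uniaxial_data <- function(stretch, stress, provenance = "user-file") {
  if (length(stretch) != length(stress) || length(stretch) < 1L)
    stop(errorCondition("stretch and stress must be non-empty and equal length",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  if (any(!is.finite(stretch)) || any(!is.finite(stress)))
    stop(errorCondition("non-finite values in dataset",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  if (stretch[1] < 1 || (length(stretch) > 1L && any(diff(stretch) <= 0)))
    stop(errorCondition("stretch must be strictly increasing with stretch[1] >= 1",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  structure(data.frame(stretch = as.numeric(stretch),
                       nominal_stress_mpa = as.numeric(stress)),
            provenance = provenance,
            class = c("uniaxial_data", "data.frame"))
}

#' Synthetic uniaxial tension test
#'
#' Generates a uniaxial nominal stress-stretch dataset from an Ogden
#' parameter set, with optional additive Gaussian noise. This is the
#' package's stand-in for a cadaver tensile test: the default grid spans
#' stretches 1 to 1.6 in 50 points and noise-free generation returns the
#' exact closed-form stresses.
#'
#' @param params an \code{ogden_params} object.
#' @param lam_grid stretch grid (strictly increasing, first value >= 1).
#' @param noise_sd standard deviation of additive Gaussian noise, MPa.
#' @param seed integer seed for the noise (ignored when \code{noise_sd = 0}).
#' @return a \code{uniaxial_data} object with provenance "synthetic".
#' @export
generate_uniaxial_data <- function(params, lam_grid = seq(1, 1.6, length.out = 50),
                                   noise_sd = 0, seed = NULL) {
  if (length(lam_grid) < 1L)
    stop(errorCondition("empty stretch grid",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop(errorCondition("noise_sd must be >= 0",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  P <- uniaxial_nominal_stress(params, lam_grid)
  if (noise_sd > 0)
    P <- P + .with_seed(seed, rnorm(length(lam_grid), 0, noise_sd))
  uniaxial_data(lam_grid, P, provenance = "synthetic")
}

#' Least-squares stress error
#'
#' The fitting objective \eqn{E = \frac12 \sum_i (P_i^{test} -
#' P_i^{model})^2} between a uniaxial dataset and the closed-form Ogden
#' prediction (MPa^2).
#'
#' @param dataset a \code{uniaxial_data} object.
#' @param params an \code{ogden_params} object.
#' @return scalar error E, MPa^2.
#' @export
sse_ogden <- function(dataset, params) {
  r <- dataset$nominal_stress_mpa - uniaxial_nominal_stress(params, dataset$stretch)
  0.5 * sum(r^2)
}

.ogden_residuals <- function(theta, n_terms, dataset, stab_weight = 1e4) {
  mu <- theta[seq_len(n_terms)]
  alpha <- theta[n_terms + seq_len(n_terms)]
  P <- numeric(nrow(dataset))
  for (j in seq_len(n_terms))
    P <- P + 2 * mu[j] * (dataset$stretch^(alpha[j] - 1) -
                            dataset$stretch^(-alpha[j] / 2 - 1))
  r <- P - dataset$nominal_stress_mpa
  margin <- sum(mu * alpha)
  c(r, stab_weight * max(0, 1e-8 - margin))
}

#' Fit an N-term Ogden model to uniaxial data
#'
#' Constrained nonlinear least squares identification of \eqn{(\mu_j,
#' \alpha_j)} from a uniaxial nominal stress-stretch dataset, minimising
#' \eqn{E = \frac12\sum (P^{test} - P^{model})^2} by Levenberg-Marquardt
#' (\code{minpack.lm::nls.lm}) under box bounds, with the small-deformation
#' stability constraint \eqn{\sum\mu_j\alpha_j > 0} enforced by a smooth
#' penalty plus rejection of unstable local minima.
#'
#' Ogden terms are exchangeable, so the returned terms are sorted by
#' ascending \code{alpha}. Because the objective is multimodal the fit is
#' multi-started: one deterministic heuristic start plus seeded random
#' restarts with \eqn{\mu} log-uniform on 1e-6..1e-2 MPa and \eqn{\alpha}
#' uniform on 0.5..25.
#'
#' @param data a \code{uniaxial_data} object (needs at least
#'   \code{2 * n_terms} points).
#' @param n_terms number of Ogden terms.
#' @param lower,upper box bounds on \code{c(mu, alpha)}; defaults keep
#'   \code{mu > 0} and \code{alpha} within -30..30.
#' @param n_restarts number of random restarts (in addition to the
#'   heuristic start).
#' @param seed integer seed for the restart draws.
#' @param nu Poisson's ratio attached to the returned parameter set.
#' @return an object of class \code{ogden_fit} with components
#'   \code{params} (an \code{ogden_params}), \code{sse} (final E, MPa^2),
#'   \code{n_restarts_used}, \code{converged}, \code{starts} (per-start
#'   diagnostics) and \code{data}.
#' @export
fit_ogden <- function(data, n_terms = 2L,
                      lower = c(rep(1e-12, n_terms), rep(-30, n_terms)),
                      upper = c(rep(1, n_terms), rep(30, n_terms)),
                      n_restarts = 8L, seed = 1L, nu = 0.499) {
  if (!inherits(data, "uniaxial_data"))
    data <- uniaxial_data(data$stretch, data$nominal_stress_mpa)
  n_terms <- as.integer(n_terms)
  if (n_terms < 1L)
    stop(errorCondition("n_terms must be >= 1",
                        class = c("levatorfem_invalid_input", "error", "condition")))
  if (nrow(data) < 2L * n_terms)
    stop(errorCondition(sprintf("need at least %d data points for %d terms",
                                2L * n_terms, n_terms),
                        class = c("levatorfem_invalid_input", "error", "condition")))
  if (length(lower) != 2L * n_terms || length(upper) != 2L * n_terms ||
      any(lower >= upper))
    stop(errorCondition("infeasible bounds",
                        class = c("levatorfem_invalid_input", "error", "condition")))

  starts <- list()
  # heuristic start: share the small-strain slope across terms with spread alphas
  slope <- tryCatch({
    i <- which(data$stretch > 1)
    if (length(i) == 0) NA_real_
    else max(1e-8, (data$nominal_stress_mpa[i[1]]) / (data$stretch[i[1]] - 1) / 3)
  }, error = function(e) NA_real_)
  a0 <- seq(2, 18, length.out = n_terms)
  m0 <- rep(if (is.finite(slope)) slope / (n_terms * mean(a0)) else 1e-4, n_terms)
  starts[[1]] <- pmin(pmax(c(m0, a0), lower + 1e-12), upper - 1e-12)
  rand <- .with_seed(seed, {
    lapply(seq_len(max(0L, n_restarts - 1L)), function(k) {
      mu0 <- 10^runif(n_terms, -6, -2)
      al0 <- sort(runif(n_terms, 0.5, 25))
      pmin(pmax(c(mu0, al0), lower + 1e-12), upper - 1e-12)
    })
  })
  starts <- c(starts, rand)

  runs <- lapply(starts, function(th0) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, lower = lower, upper = upper,
                         fn = .ogden_residuals, n_terms = n_terms, dataset = data,
                         control = minpack.lm::nls.lm.control(maxiter = 500,
                                                              ftol = 1e-14,
                                                              ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    th <- fit$par
    mu <- th[seq_len(n_terms)]; alpha <- th[n_terms + seq_len(n_terms)]
    margin <- sum(mu * alpha)
    resid <- data$nominal_stress_mpa -
      vapply(seq_len(nrow(data)), function(i) {
        sum(2 * mu * (data$stretch[i]^(alpha - 1) - data$stretch[i]^(-alpha / 2 - 1)))
      }, numeric(1))
    list(mu = mu, alpha = alpha, margin = margin, sse = 0.5 * sum(resid^2),
         info = fit$info, start = th0)
  })
  runs <- Filter(function(r) !is.null(r) && is.finite(r$sse) && r$margin > 0, runs)
  if (length(runs) == 0L)
    stop(errorCondition("all restarts diverged or violated the stability constraint",
                        class = c("levatorfem_nonconvergence", "error", "condition")))
  sses <- vapply(runs, `[[`, numeric(1), "sse")
  best <- runs[[which.min(sses)]]
  ord <- order(best$alpha)
  params <- ogden_params(mu = best$mu[ord], alpha = best$alpha[ord], nu = nu)
  structure(list(params = params, sse = best$sse,
                 n_restarts_used = length(starts),
                 converged = best$info %in% 1:4,
                 start_sse = vapply(runs, function(r)
                   sse_ogden(data, structure(list(
                     mu = r$start[seq_len(n_terms)],
                     alpha = r$start[n_terms + seq_len(n_terms)],
                     n_terms = n_terms), class = "ogden_params")), numeric(1)),
                 all_sse = sses, data = data, n_terms = n_terms,
                 call = match.call()),
            class = "ogden_fit")
}

#' @export
print.ogden_fit <- function(x, ...) {
  cat("Ogden uniaxial fit (nonlinear least squares)\n")
  cat(sprintf("  terms: %d, data points: %d, E = %.6g MPa^2, converged: %s\n",
              x$n_terms, nrow(x$data), x$sse, x$converged))
  print(x$params)
  invisible(x)
}

#' @export
summary.ogden_fit <- function(object, ...) {
  r <- residuals(object)
  structure(list(fit = object,
                 rmse = sqrt(mean(r^2)),
                 margin = sum(object$params$mu * object$params$alpha),
                 restart_spread = range(object$all_sse)),
            class = "summary.ogden_fit")
}

#' @export
print.summary.ogden_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual RMSE: %.6g MPa; stability margin: %.6g MPa\n",
              x$rmse, x$margin))
  cat(sprintf("  restart E spread: [%.6g, %.6g] over %d kept restarts\n",
              x$restart_spread[1], x$restart_spread[2], length(x$fit$all_sse)))
  invisible(x)
}

#' @export
coef.ogden_fit <- function(object, ...) {
  p <- object$params
  stats::setNames(c(p$mu, p$alpha),
                  c(paste0("mu", seq_len(p$n_terms)),
                    paste0("alpha", seq_len(p$n_terms))))
}

#' @export
predict.ogden_fit <- function(object, newdata = NULL, ...) {
  lam <- if (is.null(newdata)) object$data$stretch
  else if (is.numeric(newdata)) newdata
  else newdata$stretch
  uniaxial_nominal_stress(object$params, lam)
}

#' @export
fitted.ogden_fit <- function(object, ...) predict(object)

#' @export
residuals.ogden_fit <- function(object, ...)
  object$data$nominal_stress_mpa - fitted(object)

#' @export
simulate.ogden_fit <- function(object, nsim = 1, seed = NULL, ...) {
  noise <- sd(residuals(object))
  lapply(seq_len(nsim), function(k)
    generate_uniaxial_data(object$params, object$data$stretch,
                           noise_sd = noise,
                           seed = if (is.null(seed)) NULL else seed + k - 1L))
}

#' @export
plot.ogden_fit <- function(x, ...) {
  lam <- x$data$stretch
  grid <- seq(min(lam), max(lam), length.out = 200)
  graphics::plot(lam, x$data$nominal_stress_mpa, pch = 16, cex = 0.7,
                 xlab = "stretch [-]", ylab = "nominal stress [MPa]",
                 main = "Ogden uniaxial fit", ...)
  graphics::lines(grid, uniaxial_nominal_stress(x$params, grid), col = "firebrick")
  invisible(x)
}

#' Read a uniaxial stress-stretch CSV
#'
#' Expects a header with columns \code{stretch,nominal_stress_mpa}.
#'
#' @param path file path.
#' @return a \code{uniaxial_data} object with provenance "user-file".
#' @export
read_uniaxial_csv <- function(path) {
  d <- tryCatch(utils::read.csv(path), error = function(e)
    stop(errorCondition(paste("cannot read CSV:", conditionMessage(e)),
                        class = c("levatorfem_io_error", "error", "condition"))))
  if (!all(c("stretch", "nominal_stress_mpa") %in% names(d)))
    stop(errorCondition(
      "CSV must have header columns 'stretch' and 'nominal_stress_mpa'",
      class = c("levatorfem_io_error", "error", "condition")))
  uniaxial_data(d$stretch, d$nominal_stress_mpa, provenance = "user-file")
}

#' Write a uniaxial stress-stretch CSV
#'
#' @param data a \code{uniaxial_data} object.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_uniaxial_csv <- function(data, path) {
  utils::write.csv(data.frame(stretch = data$stretch,
                              nominal_stress_mpa = data$nominal_stress_mpa),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
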