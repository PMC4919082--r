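#' Efficiency exponent of semelparity
#'
#' For a semelparous life history growing from birth size \eqn{x} to mature
#' size \eqn{x^*} with fecundity \eqn{\phi(x^*)}, the efficiency exponent of
#' semelparity (EES) is
#' \deqn{\rho^* = \frac{\ln \phi(x^*)}{\ln (x^*/x)}.}
#' It governs the sign of the effect of internal stochasticity on both the
#' intrinsic rate of natural increase and the carrying capacity: noise helps
#' when \eqn{\rho^* > 1}, is neutral at \eqn{\rho^* = 1} and harms when
#' \eqn{\rho^* < 1}.
#'
#' @param model A semelparous model (\code{\link{gbm_model}} or
#'   \code{\link{two_resource_model}}), or a birth size (with \code{xstar}
#'   and \code{phi} supplied).
#' @param ... Unused.
#' @return The dimensionless exponent \eqn{\rho^*} (> 0 when \eqn{\phi > 1}).
#' @examples
#' ees(gbm_model(0.15, 0.5, 0.01, x0 = 0.01, xstar = 1.5, phi = 10))
#' @export
ees <- function(model, ...) UseMethod("ees")

#' @export
ees.life_history_model <- function(model, ...) {
  if (!model$semelparous)
    stop("the efficiency exponent is defined for semelparous models")
  ees_value(model$x0, model$xstar, model$phi)
}

#' @rdname ees
#' @param x0,xstar,phi Birth size, mature size and fecundity.
#' @export
ees.numeric <- function(model, xstar, phi, ...) ees_value(model, xstar, phi)

ees_value <- function(x0, xstar, phi) {
  if (!(xstar > x0 && x0 > 0))
    stop("mature size must exceed the (positive) birth size")
  if (phi <= 0) stop("fecundity must be positive")
  log(phi) / log(xstar / x0)
}

# Positive root of the Feynman-Kac characteristic quadratic
#   (s2/2) rho^2 + (b - cg*Gamma - s2/2) rho - (mu0 + lambda) = 0
# for effective drift b, variance s2, density coefficient cg.  The quadratic
# arises from substituting psi ~ x^rho into the stationary backward equation;
# its positive root is the decay exponent of the discounted first-passage
# transform E[exp(-(lambda + mu0) a*)] = (x/x*)^rho.
rho_quadratic <- function(b, s2, mu0, lambda, Gamma = 0, cg = 1) {
  beta <- b - cg * Gamma
  if (mu0 + lambda <= 0)
    stop("need mu0 + lambda > 0")
  if (s2 == 0) {
    if (beta <= 0)
      stop("non-maturing regime: zero noise and nonpositive net growth")
    return((mu0 + lambda) / beta)
  }
  p <- beta - s2 / 2
  rho <- (-p + sqrt(p^2 + 2 * s2 * (mu0 + lambda))) / s2
  rho
}

#' Characteristic exponent of the discounted first-passage transform
#'
#' Returns the positive root \eqn{\rho_\lambda(\Gamma)} of the Feynman-Kac
#' quadratic
#' \deqn{\tfrac{\sigma^2}{2}\rho^2 + (b - \Gamma - \tfrac{\sigma^2}{2})\rho
#'       - (\mu_0 + \lambda) = 0,}
#' so that the characteristic function of the semelparous GBM life history
#' is \eqn{\psi_\lambda(x,\Gamma) = (x/x^*)^{\rho_\lambda(\Gamma)}
#' \phi(x^*)}.  At \eqn{\sigma = 0} the deterministic limit
#' \eqn{\rho = (\mu_0+\lambda)/(b-\Gamma)} is used (an explicit branch, not
#' a numerical limit); a nonpositive net growth rate at zero noise is a
#' non-maturing regime and raises an error.
#'
#' The returned value carries the quadratic residual as attribute
#' \code{"residual"} so callers can verify the defining property directly.
#'
#' @param model A \code{\link{gbm_model}} or \code{\link{two_resource_model}}.
#' @param lambda Discount rate (the Euler-Lotka argument); \code{mu0 +
#'   lambda} must be positive.
#' @param Gamma Scalar density effect.
#' @param v Constant control (two-resource models only).
#' @return \eqn{\rho_\lambda(\Gamma)} with attribute \code{"residual"}.
#' @examples
#' m <- gbm_model(0.15, 0.5, 0.01, x0 = 0.01, xstar = 1.5, phi = 10)
#' rho_lambda(m, lambda = irni_closed_form(m))  # equals ees(m)
#' @export
rho_lambda <- function(model, lambda = 0, Gamma = 0, v = NULL) {
  ep <- effective_params(model, v)
  Gamma <- density_effect(Gamma)
  rho <- rho_quadratic(ep$b, ep$sigma2, model$mu0, lambda, Gamma, ep$cgamma)
  res <- ep$sigma2 / 2 * rho^2 +
    (ep$b - ep$cgamma * Gamma - ep$sigma2 / 2) * rho - (model$mu0 + lambda)
  structure(rho, residual = res)
}

#' Intrinsic rate of natural increase, closed form
#'
#' Solves the Euler-Lotka equation \eqn{\psi_\lambda(x, 0) = 1} in closed
#' form for the semelparous GBM life history:
#' \deqn{\lambda^* = \left[b - \tfrac{\sigma^2}{2}(1 - \rho^*)\right]\rho^*
#'       - \mu_0,}
#' with \eqn{\rho^*} the efficiency exponent of semelparity.  At
#' \eqn{\rho^* = 1} the noise term vanishes: internal stochasticity has no
#' effect on the growth rate.
#'
#' @inheritParams rho_lambda
#' @return The intrinsic rate of natural increase \eqn{\lambda^*}.
#' @export
irni_closed_form <- function(model, v = NULL) {
  ep <- effective_params(model, v)
  rs <- ees(model)
  (ep$b - ep$sigma2 / 2 * (1 - rs)) * rs - model$mu0
}

#' Equilibrium density effect and carrying capacity, closed form
#'
#' The nontrivial equilibrium of the density-regulated semelparous GBM
#' population satisfies \eqn{\psi_0(x, \Gamma^*) = 1}, i.e.
#' \eqn{\rho_0(\Gamma^*) = \rho^*}, giving
#' \deqn{\Gamma^* = b - \tfrac{\sigma^2}{2}(1-\rho^*) - \mu_0/\rho^*,}
#' (divided by the competition coefficient when the drift carries a split
#' factor) and, with a constant interaction kernel \eqn{\gamma_0}, carrying
#' capacity \eqn{N^* = \Gamma^*/\gamma_0}.  When the intrinsic rate of
#' natural increase is nonpositive there is no positive equilibrium and the
#' result is flagged non-persistent with \eqn{N^* = 0}.
#'
#' @inheritParams rho_lambda
#' @return A list with components \code{Gamma} (equilibrium density effect),
#'   \code{N} (carrying capacity) and \code{persistent} (logical).
#' @examples
#' m <- gbm_model(0.15, 0.5, 0.01, x0 = 0.01, xstar = 1.5, phi = 10)
#' carrying_capacity_closed_form(m)
#' @export
carrying_capacity_closed_form <- function(model, v = NULL) {
  ep <- effective_params(model, v)
  rs <- ees(model)
  if (rs <= 0) {
    # fecundity at most one: psi < 1 at every density, no equilibrium
    return(list(Gamma = NA_real_, N = 0, persistent = FALSE))
  }
  Gstar <- (ep$b - ep$sigma2 / 2 * (1 - rs) - model$mu0 / rs) / ep$cgamma
  persistent <- irni_closed_form(model, v) > 0
  list(Gamma = Gstar,
       N = if (persistent) Gstar / model$gamma0 else 0,
       persistent = persistent)
}

#' Closed-form characteristic function of the semelparous GBM family
#'
#' \deqn{\psi_\lambda(x, \Gamma) = (x/x^*)^{\rho_\lambda(\Gamma)}\phi(x^*),}
#' the expected discounted lifetime reproduction
#' \eqn{E_x[\phi(x^*) e^{-(\lambda+\mu_0)a^*}]} with \eqn{a^*} the first
#' passage of size to the mature size.  Sizes at or above \eqn{x^*} return
#' \eqn{\phi(x^*)} (already mature).
#'
#' @inheritParams rho_lambda
#' @param x Initial size (defaults to the model's birth size).
#' @return The characteristic-function value \eqn{\psi \ge 0}.
#' @export
psi_closed_form <- function(model, lambda = 0, Gamma = 0, v = NULL,
                            x = model$x0) {
  if (x >= model$xstar) return(model$phi)
  rho <- as.numeric(rho_lambda(model, lambda, Gamma, v))
  (x / model$xstar)^rho * model$phi
}

#' Adaptive mature size
#'
#' Maximises the efficiency exponent of semelparity
#' \eqn{\rho^*(x^*) = \ln\phi(x^*) / \ln(x^*/x)} over candidate mature
#' sizes: because both the growth rate and the carrying capacity are
#' increasing in \eqn{\rho^*} throughout the persistent regime, the size
#' maximising \eqn{\rho^*} is evolutionarily stable under both r- and
#' K-selection.  A dense grid search is followed by local golden-section
#' refinement; a supremum attained at an interval end point is flagged
#' (\code{boundary = TRUE}: not an interior optimum), and a flat objective
#' (e.g. \eqn{\phi(x^*) = (x^*/x)^\beta}) is flagged \code{degenerate}.
#'
#' @param x0 Birth size.
#' @param phi_fun Fecundity as a function of the mature size; must be
#'   positive on the interval.
#' @param interval Search interval for the mature size, a subset of
#'   \code{(x0, Inf)}.
#' @param n_grid Number of grid points for the global search.
#' @param tol Relative tolerance of the local refinement.
#' @return List with \code{xstar} (the adaptive mature size), \code{rho}
#'   (the maximised exponent), \code{boundary}, \code{degenerate}.
#' @export
optimal_mature_size <- function(x0, phi_fun, interval, n_grid = 2001L,
                                tol = 1e-9) {
  stopifnot(is.function(phi_fun), length(interval) == 2L,
            interval[1L] > x0, interval[2L] > interval[1L])
  xs <- seq(interval[1L], interval[2L], length.out = n_grid)
  obj <- vapply(xs, function(s) ees_value(x0, s, phi_fun(s)), numeric(1L))
  if (any(!is.finite(obj))) stop("phi_fun must be positive on the interval")
  spread <- diff(range(obj))
  if (spread <= 1e-12 * max(abs(obj), 1)) {
    return(list(xstar = xs[1L], rho = obj[1L],
                boundary = FALSE, degenerate = TRUE))
  }
  i <- which.max(obj)
  if (i == 1L || i == n_grid) {
    return(list(xstar = xs[i], rho = obj[i],
                boundary = TRUE, degenerate = FALSE))
  }
  opt <- stats::optimize(function(s) ees_value(x0, s, phi_fun(s)),
                         lower = xs[i - 1L], upper = xs[i + 1L],
                         maximum = TRUE, tol = tol)
  list(xstar = opt$maximum, rho = opt$objective,
       boundary = FALSE, degenerate = FALSE)
}
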