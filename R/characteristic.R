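# Finite-difference solve of the stationary backward (Feynman-Kac) equation
#   (s2/2) psi'' + (b - cg*Gamma - s2/2) psi' - (mu0 + lambda) psi = 0
# in log-size u on [umin, ustar], Dirichlet psi(ustar) = phi, and a
# regularity (bounded-solution) condition at the far-left boundary imposed
# as a Robin condition psi' = rho_loc * psi with rho_loc the local positive
# characteristic exponent (GBM never reaches size 0; the bounded branch is
# the positive-exponent one).  Coefficients may vary per node (used by the
# HJB policy iteration).  Second-order central differences; the Robin row
# uses a ghost node, preserving second-order accuracy and tridiagonality.
solve_fk_ode <- function(u, bcoef, s2coef, mu0, lambda, phi) {
  n <- length(u)
  h <- u[2L] - u[1L]
  drift <- bcoef - s2coef / 2
  diffu <- s2coef / 2
  kill <- mu0 + lambda
  lower <- (diffu[-1L] / h^2 - drift[-1L] / (2 * h))[-(n - 1L)]
  diagm <- -2 * diffu / h^2 - kill
  upper <- (diffu / h^2 + drift / (2 * h))[-n]
  rhs <- numeric(n - 1L)
  # Robin closure at node 1 via ghost node: psi' (central) = rho_loc psi
  p1 <- drift[1L]
  rho_loc <- if (s2coef[1L] > 0)
    (-p1 + sqrt(p1^2 + 2 * s2coef[1L] * kill)) / s2coef[1L]
  else kill / max(bcoef[1L], .Machine$double.eps)
  diag1 <- -2 * diffu[1L] / h^2 * (1 + h * rho_loc) + drift[1L] * rho_loc -
    kill
  upper1 <- 2 * diffu[1L] / h^2
  dg <- c(diag1, diagm[2:(n - 1L)])
  up <- c(upper1, upper[2:(n - 2L)])
  lo <- lower
  rhs[n - 1L] <- -(diffu[n - 1L] / h^2 + drift[n - 1L] / (2 * h)) * phi
  psi <- thomas_cpp(lo, dg, up, rhs)
  c(psi, phi)
}

# Interpolate a positive grid function log-linearly (exact for the
# exponential solutions of constant-coefficient problems).
interp_log <- function(u, psi, u0) {
  if (u0 <= u[1L]) return(psi[1L])
  i <- findInterval(u0, u)
  w <- (u0 - u[i]) / (u[i + 1L] - u[i])
  exp((1 - w) * log(psi[i]) + w * log(psi[i + 1L]))
}

#' Characteristic function by Feynman-Kac boundary-value solve
#'
#' Solves the stationary backward equation
#' \eqn{-(\bar H_x(\Gamma) + \lambda)\psi + F_S(x) = 0} for the semelparous
#' GBM family on a log-size grid.  The point-mass fertility at the mature
#' size enters as the Dirichlet condition \eqn{\psi(x^*) = \phi(x^*)};
#' the left boundary (at \code{xmin_factor} times the birth size) carries
#' the bounded-solution regularity condition.  A coarse/fine comparison
#' provides an a posteriori error estimate; the solve refuses if it exceeds
#' \code{tol}.
#'
#' @inheritParams rho_lambda
#' @param n_grid Number of log-size nodes (default 8001).
#' @param xmin_factor Left boundary as a fraction of the birth size.
#' @param tol Acceptable relative error estimate.
#' @return \eqn{\psi_\lambda(x,\Gamma)} with attribute
#'   \code{"error_estimate"}.
#' @examples
#' m <- gbm_model(0.15, 0.5, 0.01, x0 = 0.01, xstar = 1.5, phi = 10)
#' psi_ode(m, lambda = irni_closed_form(m))  # Euler-Lotka: equals 1
#' @export
psi_ode <- function(model, lambda = 0, Gamma = 0, v = NULL,
                    n_grid = 8001L, xmin_factor = 1e-3, tol = 1e-6) {
  ep <- effective_params(model, v)
  Gamma <- density_effect(Gamma)
  if (model$x0 >= model$xstar) return(structure(model$phi, error_estimate = 0))
  if (ep$sigma2 == 0) {
    # deterministic branch: exact exponential discounting along the path
    beta <- ep$b - ep$cgamma * Gamma
    if (beta <= 0) stop("non-maturing regime at zero noise")
    astar <- log(model$xstar / model$x0) / beta
    return(structure(model$phi * exp(-(lambda + model$mu0) * astar),
                     error_estimate = 0))
  }
  ustar <- log(model$xstar)
  u0 <- log(model$x0)
  beff <- ep$b - ep$cgamma * Gamma
  # grid aligned so the birth size is a node at every resolution used by
  # the Richardson extrapolation (spacings h, 2h, 4h)
  h_target <- (ustar - log(model$x0 * xmin_factor)) / (n_grid - 1L)
  m2 <- 4L * max(round((ustar - u0) / (4 * h_target)), 1L)
  h <- (ustar - u0) / m2
  m1 <- 4L * max(ceiling(-log(xmin_factor) / (4 * h)), 1L)
  run <- function(stride) {
    u <- seq(u0 - m1 * h, ustar, by = h * stride)
    psi <- solve_fk_ode(u, rep(beff, length(u)),
                        rep(ep$sigma2, length(u)),
                        model$mu0, lambda, model$phi)
    psi[length(u) - m2 %/% stride]        # value at the birth-size node
  }
  p1 <- run(1L); p2 <- run(2L); p4 <- run(4L)
  r1 <- (4 * p1 - p2) / 3                 # second-order extrapolants
  r2 <- (4 * p2 - p4) / 3
  err <- abs(r1 - r2) / max(abs(r1), .Machine$double.eps)
  if (err > tol)
    stop("psi_ode grid too coarse: error estimate ", format(err),
         " exceeds tol = ", tol, "; increase n_grid")
  structure(r1, error_estimate = err)
}

#' Characteristic function by Monte Carlo
#'
#' Estimates \eqn{\psi_\lambda(x,\Gamma)} as the discounted path functional
#' of a simulated ensemble (see \code{\link{path_functional}}).
#'
#' @inheritParams rho_lambda
#' @param policy A \code{\link{control_policy}} (two-resource models).
#' @param n_paths,dt,horizon,seed Simulation options, see
#'   \code{\link{simulate_paths}}.
#' @return List with \code{estimate}, \code{se} and simulation metadata.
#' @export
psi_mc <- function(model, lambda = 0, Gamma = 0, policy = NULL,
                   n_paths = 1e5L, dt = 0.05, horizon = NULL, seed = NULL) {
  ens <- simulate_paths(model, policy = policy, Gamma = Gamma,
                        n_paths = n_paths, dt = dt, horizon = horizon,
                        seed = seed)
  pf <- path_functional(ens, lambda)
  c(pf, list(lambda = lambda, Gamma = Gamma, n_paths = n_paths, dt = dt))
}

#' Characteristic (fitness) function of a life history
#'
#' The characteristic function
#' \deqn{\psi_\lambda^v(x,\Gamma) = \int_0^\alpha e^{-\lambda a}
#'   E_x\!\left[F(X_a,\Gamma)\, e^{-\int_0^a \mu\,d\tau}\right] da}
#' is the single fitness criterion of the framework: \eqn{\psi = 1} at
#' \eqn{\Gamma = 0} defines the intrinsic rate of natural increase
#' (Euler-Lotka), \eqn{\psi = 1} at \eqn{\lambda = 0} defines the
#' equilibrium density effect, and \eqn{\psi(\lambda = 0, \Gamma = 0)} is
#' the basic reproductive number R0.  Three routes are available: the GBM
#' closed form, the Feynman-Kac ODE solve, and Monte Carlo path simulation.
#'
#' @inheritParams psi_mc
#' @param method One of \code{"closed_form"}, \code{"ode"}, \code{"mc"}.
#' @param include_density Also compute the breeding-age density and its
#'   first \code{n_cumulants} cumulants.
#' @param n_cumulants Number of cumulants when \code{include_density}.
#' @param ... Passed to the route (\code{\link{psi_ode}} or
#'   \code{\link{psi_mc}}).
#' @return An object of class \code{"characteristic_result"}.
#' @export
characteristic_fn <- function(model, lambda = 0, Gamma = 0, policy = NULL,
                              method = c("closed_form", "ode", "mc"),
                              include_density = FALSE, n_cumulants = 2L,
                              ...) {
  method <- match.arg(method)
  v <- if (!is.null(policy)) eval_policy(policy) else NULL
  res <- switch(method,
    closed_form = list(psi = psi_closed_form(model, lambda, Gamma, v),
                       se = NA_real_),
    ode = list(psi = as.numeric(psi_ode(model, lambda, Gamma, v, ...)),
               se = NA_real_),
    mc = {
      p <- psi_mc(model, lambda, Gamma, policy, ...)
      list(psi = p$estimate, se = p$se)
    })
  out <- list(lambda = lambda, Gamma = Gamma, psi = res$psi, se = res$se,
              method = method)
  if (include_density) {
    dens <- breeding_age_density(model, Gamma = Gamma, v = v)
    out$density <- dens
    out$cumulants <- breeding_age_cumulants(dens, K = n_cumulants)
  }
  structure(out, class = "characteristic_result")
}

#' @export
print.characteristic_result <- function(x, ...) {
  cat("psi(lambda = ", format(x$lambda), ", Gamma = ", format(x$Gamma),
      ") = ", format(x$psi), "  [", x$method, "]\n", sep = "")
  if (is.finite(x$se)) cat("  MC standard error:", format(x$se), "\n")
  if (!is.null(x$cumulants))
    cat("  breeding-age cumulants:", format(x$cumulants), "\n")
  invisible(x)
}

#' Breeding-age density
#'
#' The age distribution of reproduction,
#' \eqn{A(a,\Gamma) = E_x[F(X_a,\Gamma)e^{-\int\mu}] / \psi_0(x,\Gamma)},
#' which for the semelparous GBM family is the first-passage (inverse
#' Gaussian, in log-size) density tilted by survivorship:
#' \eqn{A(a) = \phi(x^*) f_{a^*}(a) e^{-\mu_0 a} / \psi_0}.  Internal
#' stochasticity shifts its mode towards precocity.  The grid is geometric
#' (first-passage densities are right-skewed); a point mass (zero noise)
#' is represented in the narrowest grid cell.
#'
#' @inheritParams rho_lambda
#' @param n Number of age-grid points.
#' @param age_range Optional c(min, max) age range; defaults to cover all
#'   but a negligible tail mass.
#' @param normalize_tol Acceptable deviation of the grid quadrature from
#'   unit mass before normalisation (larger deficits indicate a too-short
#'   horizon and raise an error).
#' @return A data.frame of class \code{"breeding_age_density"} with
#'   columns \code{age} and \code{density}, integrating to 1 on its grid.
#' @export
breeding_age_density <- function(model, Gamma = 0, v = NULL, n = 1024L,
                                 age_range = NULL, normalize_tol = 1e-4) {
  ep <- effective_params(model, v)
  Gamma <- density_effect(Gamma)
  if (!model$semelparous)
    stop("breeding-age density implemented for semelparous models")
  L <- log(model$xstar / model$x0)
  nu <- ep$b - ep$cgamma * Gamma - ep$sigma2 / 2
  psi0 <- psi_closed_form(model, 0, Gamma, v)
  if (psi0 <= 0) stop("no reproduction: psi_0 = 0")
  if (ep$sigma2 == 0) {
    if (nu <= 0) stop("non-maturing regime at zero noise")
    astar <- L / nu
    width <- astar * 1e-6
    out <- data.frame(age = astar + width * c(-0.5, 0.5),
                      density = c(1 / width, 1 / width))
    attr(out, "point_mass") <- astar
    class(out) <- c("breeding_age_density", class(out))
    return(out)
  }
  s2 <- ep$sigma2
  rate <- nu^2 / (2 * s2) + model$mu0   # asymptotic decay of the integrand
  if (is.null(age_range))
    age_range <- c(L^2 / (2 * s2 * 80), log(1e14) / rate)
  a <- exp(seq(log(age_range[1L]), log(age_range[2L]), length.out = n))
  fp <- L / sqrt(2 * pi * s2 * a^3) * exp(-(L - nu * a)^2 / (2 * s2 * a))
  dens <- model$phi * fp * exp(-model$mu0 * a) / psi0
  mass <- sum(diff(a) * (dens[-1L] + dens[-n]) / 2)
  if (abs(mass - 1) > max(normalize_tol, 1e-3))
    stop("breeding-age density mass deficit ", format(1 - mass),
         ": widen age_range")
  out <- data.frame(age = a, density = dens / mass)
  class(out) <- c("breeding_age_density", class(out))
  out
}

#' Cumulants of the breeding age
#'
#' Grid-quadrature cumulants of a breeding-age density.  The log
#' characteristic function is the cumulant generating function of the
#' breeding age in \eqn{-\lambda}, so the first cumulant equals
#' \eqn{-\partial_\lambda \ln\psi|_{\lambda=0}} and the second its
#' curvature — a duality the test suite checks by finite differences.
#'
#' @param density A \code{\link{breeding_age_density}}.
#' @param K Number of cumulants (at most 4; higher grid cumulants are not
#'   reliably validatable).
#' @return Numeric vector of cumulants \eqn{\langle a^*\rangle^{(1..K)}}.
#' @export
breeding_age_cumulants <- function(density, K = 2L) {
  stopifnot(inherits(density, "breeding_age_density"))
  if (K > 4L) stop("cumulants above order 4 are not supported")
  if (!is.null(attr(density, "point_mass"))) {
    out <- c(attr(density, "point_mass"), rep(0, K - 1L))
    return(out[seq_len(K)])
  }
  a <- density$age; d <- density$density
  quad <- function(f) sum(diff(a) * (f[-1L] + f[-length(f)]) / 2)
  m1 <- quad(a * d)
  mom <- vapply(2:4, function(k) quad((a - m1)^k * d), numeric(1L))
  kappa <- c(m1, mom[1L], mom[2L], mom[3L] - 3 * mom[1L]^2)
  kappa[seq_len(K)]
}
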