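#' Closed-form adaptive utilisation ratio of the two-resource model
#'
#' For efficiency exponent \eqn{\rho^* < 1} the Hamiltonian of the
#' two-resource model is strictly convex in the control and the adaptive
#' utilisation ratio is
#' \deqn{\tilde v(\rho^*, \Gamma) = \mathrm{clamp}\!\left(
#'   \frac{\sigma_1^2}{\sigma_1^2+\sigma_2^2}
#'   - \frac{b_1-b_2+(1-2\kappa)\Gamma}
#'          {(\sigma_1^2+\sigma_2^2)(1-\rho^*)},\; 0,\; 1\right).}
#' The first term is the pure variance hedge, the second the drift penalty
#' for moving onto the slower resource.  At \eqn{\kappa = 0.5} the density
#' effect drops out and the r- and K-strategies coincide.
#'
#' @param model A \code{\link{two_resource_model}}.
#' @param Gamma Scalar density effect.
#' @param rho Efficiency exponent (defaults to the model's own
#'   \code{\link{ees}}); must be below 1 — at and above 1 the interior
#'   optimum disappears and only the limit analysis applies, see
#'   \code{\link{kappa_threshold}}.
#' @return The adaptive constant control \eqn{\tilde v \in [0, 1]}.
#' @examples
#' tr <- two_resource_model(0.15, 0.05, 0.6, 0.02, kappa = 0.5,
#'                          mu0 = 0.01, x0 = 0.01, xstar = 1.5, phi = 10)
#' two_resource_policy(tr)          # about 0.486
#' @export
two_resource_policy <- function(model, Gamma = 0, rho = ees(model)) {
  stopifnot(inherits(model, "two_resource_model"))
  Gamma <- density_effect(Gamma)
  if (rho >= 1)
    stop("the interior optimum exists only for an efficiency exponent ",
         "below 1; for the limit as it approaches 1 see kappa_threshold()")
  s2sum <- model$sigma1^2 + model$sigma2^2
  raw <- model$sigma1^2 / s2sum -
    (model$b1 - model$b2 + (1 - 2 * model$kappa) * Gamma) /
    (s2sum * (1 - rho))
  min(max(raw, 0), 1)
}

#' Critical competition split of the two-resource model
#'
#' As the efficiency exponent approaches one from below, internal
#' stochasticity stops affecting the carrying capacity and the K-strategy
#' collapses onto a pure strategy: the resource-2 specialist when
#' \eqn{\kappa > \kappa_0}, the resource-1 specialist when
#' \eqn{\kappa < \kappa_0}, where comparing the pure-strategy equilibrium
#' density effects \eqn{(b_1-\mu_0)/\kappa} and \eqn{(b_2-\mu_0)/(1-\kappa)}
#' gives
#' \deqn{\kappa_0 = \frac{1}{1 + (b_2-\mu_0)/(b_1-\mu_0)}.}
#' At \eqn{\kappa = \kappa_0} all strategies share the same carrying
#' capacity and no adaptive strategy exists.  Requires both pure
#' strategies viable at the limit (\eqn{b_2 > \mu_0}).
#'
#' @param model A \code{\link{two_resource_model}}.
#' @return The threshold \eqn{\kappa_0 \in (0, 1)}.
#' @export
kappa_threshold <- function(model) {
  stopifnot(inherits(model, "two_resource_model"))
  if (model$b2 <= model$mu0)
    stop("kappa threshold needs b2 > mu0 (resource-2 specialist viable)")
  1 / (1 + (model$b2 - model$mu0) / (model$b1 - model$mu0))
}

#' Stationary Hamilton-Jacobi-Bellman solve
#'
#' Solves the stationary HJB equation
#' \eqn{-\inf_{v \in V}[\bar H^v_x(\Gamma) + \lambda]\tilde\psi + F = 0}
#' on a log-size grid by policy iteration: a linear Feynman-Kac solve at
#' the current policy alternates with a pointwise minimisation of the
#' Hamiltonian over the control.  For the two-resource family the
#' Hamiltonian is quadratic in the control (drift affine, variance
#' quadratic), so the interior minimiser is analytic, clamped into
#' \eqn{[0,1]}; where the second-order condition fails the endpoints are
#' compared.  Iteration stops when the policy is stationary to
#' \code{tol_policy} and the discrete residual is below \code{tol_res};
#' updates are damped after 20 sweeps and the solve errors after
#' \code{max_sweeps}.
#'
#' @param model A \code{\link{two_resource_model}} (a
#'   \code{\link{gbm_model}} is accepted: its control set is a single
#'   point and the solve reduces to \code{\link{psi_ode}}).
#' @param lambda Discount rate.
#' @param Gamma Scalar density effect.
#' @param n_grid Number of log-size nodes.
#' @param xmin_factor Left boundary as a fraction of the birth size.
#' @param tol_policy,tol_res,max_sweeps Convergence controls.
#' @return An object of class \code{"hjb_solution"}: grid, value surface
#'   \code{psi}, \code{policy} on the grid, value \code{psi_x} at the
#'   birth size, convergence diagnostics.
#' @export
solve_stationary_hjb <- function(model, lambda = 0, Gamma = 0,
                                 n_grid = 2001L, xmin_factor = 1e-3,
                                 tol_policy = 1e-8, tol_res = 1e-8,
                                 max_sweeps = 200L) {
  Gamma <- density_effect(Gamma)
  umin <- log(model$x0 * xmin_factor)
  ustar <- log(model$xstar)
  u <- seq(umin, ustar, length.out = n_grid)
  h <- u[2L] - u[1L]
  if (!inherits(model, "two_resource_model")) {
    ep <- effective_params(model, NULL)
    psi <- solve_fk_ode(u, rep(ep$b - Gamma, n_grid),
                        rep(ep$sigma2, n_grid), model$mu0, lambda,
                        model$phi)
    return(structure(list(u = u, psi = psi, policy = rep(NA_real_, n_grid),
                          psi_x = interp_log(u, psi, log(model$x0)),
                          lambda = lambda, Gamma = Gamma, sweeps = 0L,
                          converged = TRUE),
                     class = "hjb_solution"))
  }
  s1s <- model$sigma1^2; s2s <- model$sigma2^2
  dtheta <- model$b1 - model$b2 + (1 - 2 * model$kappa) * Gamma  # th1-th2
  bfun <- function(v) (model$b1 * (1 - v) + model$b2 * v) -
    (model$kappa + (1 - 2 * model$kappa) * v) * Gamma
  s2fun <- function(v) (1 - v)^2 * s1s + v^2 * s2s
  hamiltonian <- function(v, du, d2u)
    -(bfun(v) - s2fun(v) / 2) * du - s2fun(v) / 2 * d2u
  v <- rep(0.5, n_grid)
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    psi <- solve_fk_ode(u, bfun(v), s2fun(v), model$mu0, lambda,
                        model$phi)
    du <- c(NA, (psi[-(1:2)] - psi[1:(n_grid - 2L)]) / (2 * h), NA)
    d2u <- c(NA, (psi[-(1:2)] - 2 * psi[2:(n_grid - 1L)] +
                    psi[1:(n_grid - 2L)]) / h^2, NA)
    du[1L] <- du[2L]; d2u[1L] <- d2u[2L]
    du[n_grid] <- du[n_grid - 1L]; d2u[n_grid] <- d2u[n_grid - 1L]
    # interior minimiser of the (quadratic in v) Hamiltonian; convex
    # where du - d2u > 0, i.e. local exponent below 1
    curv <- du - d2u
    vint <- (s1s - dtheta * du / curv) / (s1s + s2s)
    vint[!is.finite(vint) | curv <= 0] <- NA
    vnew <- pmin(pmax(vint, 0), 1)
    bad <- is.na(vnew)
    if (any(bad)) {
      h0 <- hamiltonian(0, du[bad], d2u[bad])
      h1 <- hamiltonian(1, du[bad], d2u[bad])
      vnew[bad] <- ifelse(h0 <= h1, 0, 1)
    }
    if (sweeps > 20L) vnew <- (vnew + v) / 2    # damp slow oscillations
    delta <- max(abs(vnew - v))
    v <- vnew
    if (delta < tol_policy) break
    if (sweeps >= max_sweeps)
      stop("HJB policy iteration failed to converge in ", max_sweeps,
           " sweeps (last policy change ", format(delta), ")")
  }
  psi <- solve_fk_ode(u, bfun(v), s2fun(v), model$mu0, lambda, model$phi)
  structure(list(u = u, psi = psi, policy = v,
                 psi_x = interp_log(u, psi, log(model$x0)),
                 lambda = lambda, Gamma = Gamma, sweeps = sweeps,
                 converged = TRUE),
            class = "hjb_solution")
}

#' @export
print.hjb_solution <- function(x, ...) {
  cat("Stationary HJB solution: lambda =", format(x$lambda),
      ", Gamma =", format(x$Gamma), "\n  psi at birth size:",
      format(x$psi_x), " sweeps:", x$sweeps, "\n")
  if (!all(is.na(x$policy)))
    cat("  policy range: [", format(min(x$policy)), ", ",
        format(max(x$policy)), "]\n", sep = "")
  invisible(x)
}

#' Dominant root and adaptive strategy
#'
#' Solves the characteristic equation of the adaptive species,
#' \eqn{\tilde\psi_\lambda(x,\Gamma) = 1}, for the dominant root
#' \eqn{\tilde\lambda} and the maximising strategy \eqn{\tilde v}: the
#' strategy maximising the characteristic function also maximises the
#' growth rate (the monotonicity of \eqn{\psi} in \eqn{\lambda} makes the
#' two orderings equivalent), so no suboptimal policy can exceed
#' \eqn{\psi = 1} at \eqn{\tilde\lambda}.  The \code{"closed_form"} route
#' uses the analytic optimal control and the Feynman-Kac quadratic; the
#' \code{"hjb"} route wraps a Brent iteration around the numerical
#' stationary solve.
#'
#' @inheritParams solve_stationary_hjb
#' @param method \code{"closed_form"} or \code{"hjb"}.
#' @param ... Passed to \code{\link{solve_stationary_hjb}} for the
#'   numerical route.
#' @return List with \code{lambda} (the dominant root), \code{v} (the
#'   adaptive control: a scalar for the closed form, the grid policy for
#'   the numerical route) and, for the numerical route, the
#'   \code{"hjb_solution"}.
#' @export
solve_adaptive_root <- function(model, Gamma = 0,
                                method = c("closed_form", "hjb"), ...) {
  method <- match.arg(method)
  Gamma <- density_effect(Gamma)
  if (method == "closed_form") {
    v <- if (inherits(model, "two_resource_model"))
      two_resource_policy(model, Gamma) else NULL
    ep <- effective_params(model, v)
    rs <- ees(model)
    lam <- (ep$b - ep$cgamma * Gamma - ep$sigma2 / 2 * (1 - rs)) * rs -
      model$mu0
    return(list(lambda = lam, v = v))
  }
  f <- function(lambda)
    solve_stationary_hjb(model, lambda, Gamma, ...)$psi_x - 1
  lam <- solve_decreasing_root(f, floor = -model$mu0,
                               no_root_msg = "adaptive psi not bracketable",
                               tol = 1e-10)
  sol <- solve_stationary_hjb(model, lam, Gamma, ...)
  list(lambda = lam, v = sol$policy, solution = sol)
}

#' K-strategy: the adaptive strategy at its own equilibrium
#'
#' Solves the coupled fixed point defining the evolutionarily stable
#' strategy under K-selection: the adaptive control evaluated at the
#' equilibrium density effect it itself generates,
#' \eqn{\tilde v_K = \tilde v(\Gamma = \tilde\Gamma)} with
#' \eqn{\tilde\psi_0(x, \tilde\Gamma) = 1}.  At the solution no constant
#' strategy attains a basic reproductive number above one (the resident
#' cannot be invaded), and with a constant interaction kernel
#' \eqn{\tilde\Gamma} dominates every fixed strategy's equilibrium density
#' effect — the K-strategy maximises the carrying capacity.
#'
#' @param model A \code{\link{two_resource_model}}.
#' @param damping Damping factor of the \eqn{(\Gamma, v)} alternation.
#' @param tol Convergence tolerance on \eqn{(\Gamma, v)}.
#' @param max_iter Maximum alternation steps.
#' @return List with \code{Gamma} (\eqn{\tilde\Gamma}), \code{v}
#'   (\eqn{\tilde v_K}), \code{N} (the maximised carrying capacity),
#'   \code{iterations}, \code{converged}, and the iterate \code{trace}.
#' @examples
#' tr <- two_resource_model(0.15, 0.05, 0.6, 0.02, kappa = 0.5,
#'                          mu0 = 0.01, x0 = 0.01, xstar = 1.5, phi = 10)
#' kstrategy_equilibrium(tr)[c("Gamma", "v")]
#' @export
kstrategy_equilibrium <- function(model, damping = 0.5, tol = 1e-12,
                                  max_iter = 500L) {
  stopifnot(inherits(model, "two_resource_model"))
  vr <- two_resource_policy(model, Gamma = 0)
  if (psi_closed_form(model, 0, 0, vr) <= 1)
    stop("persistence fails: R0 at zero density does not exceed 1")
  Gamma <- 0; v <- vr
  trace <- data.frame(iter = 0L, Gamma = Gamma, v = v)
  for (it in seq_len(max_iter)) {
    v_new <- two_resource_policy(model, Gamma)
    Gstar <- carrying_capacity_closed_form(model, v_new)$Gamma
    Gamma_new <- (1 - damping) * Gamma + damping * Gstar
    trace <- rbind(trace, data.frame(iter = it, Gamma = Gamma_new,
                                     v = v_new))
    done <- abs(Gamma_new - Gamma) < tol && abs(v_new - v) < tol
    Gamma <- Gamma_new; v <- v_new
    if (done)
      return(list(Gamma = Gamma, v = v, N = Gamma / model$gamma0,
                  iterations = it, converged = TRUE, trace = trace))
  }
  stop("K-strategy fixed point did not converge; iterate trace:\n",
       paste(utils::capture.output(utils::tail(trace)), collapse = "\n"))
}

#' Sweep the r- and K-strategies across the competition split
#'
#' Recomputes, for each value of the competition split \eqn{\kappa}, the
#' r-strategy (adaptive control at zero density), the K-strategy (the
#' \code{\link{kstrategy_equilibrium}} fixed point) and the equilibrium
#' density effect / carrying capacity of the K-strategy.
#'
#' @param model A \code{\link{two_resource_model}} serving as the
#'   template (its \code{kappa} is replaced along the sweep).
#' @param kappa_grid Values of the competition split in (0, 1).
#' @return Data.frame with columns \code{kappa}, \code{v_r}, \code{v_K},
#'   \code{Gamma}, \code{N_K}.
#' @export
ess_sweep <- function(model, kappa_grid = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(inherits(model, "two_resource_model"))
  rows <- lapply(kappa_grid, function(k) {
    m <- two_resource_model(model$b1, model$b2, model$sigma1,
                            model$sigma2, k, model$mu0, model$x0,
                            model$xstar, model$phi, model$gamma0)
    ks <- kstrategy_equilibrium(m)
    data.frame(kappa = k, v_r = two_resource_policy(m, Gamma = 0),
               v_K = ks$v, Gamma = ks$Gamma, N_K = ks$N)
  })
  do.call(rbind, rows)
}
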