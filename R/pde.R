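# Finite-volume discretisation of the Fokker-Planck operator for a
# log-linear scalar life history on a log-size grid: cells of width h on
# [umin, ustar], zero-flux at the far-left boundary (GBM never reaches size
# zero; mass is conserved there), absorbing wall at the mature size (the
# maturation flux is the reproduction stream of the semelparous renewal).
# Advection is centred (cell Peclet numbers are tiny at the default grids),
# diffusion standard three-point.
fp_operator <- function(umin, ustar, n_cells, nu, sigma2) {
  h <- (ustar - umin) / n_cells
  edges <- umin + h * (0:n_cells)
  centers <- edges[-1L] - h / 2
  D <- sigma2 / 2
  list(umin = umin, ustar = ustar, h = h, edges = edges,
       centers = centers, nu = nu, D = D, n = n_cells)
}

# One implicit Euler step of dq/da = -d/du(nu q) + D d2/du2 q.
# Returns the updated density and the mass absorbed at the mature-size
# wall during the step (exact discrete accounting: the solve conserves
# mass up to that boundary flux).
fp_implicit_step <- function(op, q, dt) {
  n <- op$n; h <- op$h; nu <- op$nu; D <- op$D
  # interior interface i+1/2 (i = 1..n-1): F = nu*(q_i+q_{i+1})/2
  #                                            - D*(q_{i+1}-q_i)/h
  # right wall: F = max(nu,0)*q_n + 2D*q_n/h   (Dirichlet 0 at the wall)
  # assemble (I - dt*M) q_new = q_old with (M q)_i =
  #   (F_{i-1/2} - F_{i+1/2})/h; summing rows telescopes the fluxes, so
  #   the discrete mass balance is exact up to the wall flux.
  lo <- rep(-dt * (nu / 2 + D / h) / h, n - 1L)
  up <- rep(-dt * (-nu / 2 + D / h) / h, n - 1L)
  dg <- rep(1 + 2 * dt * D / h^2, n)
  # boundary rows
  dg[1L] <- 1 + dt * (D / h^2 + nu / (2 * h))      # no-flux left wall
  wall <- max(nu, 0) + 2 * D / h
  dg[n] <- 1 + dt * (D / h^2 - nu / (2 * h) + wall / h)
  qn <- thomas_cpp(lo, dg, up, q)
  m_old <- sum(q) * h
  m_new <- sum(qn) * h
  list(q = qn, absorbed = m_old - m_new,
       wall_flux = dt * wall * qn[n])
}

#' Population state on a log-size grid
#'
#' The state of the nonlinear structured population reduced over age: the
#' model families couple to the population only through the total density
#' effect (constant interaction kernel) and through the maturation flux at
#' the mature size, and their transport, mortality and noise coefficients
#' do not depend on age — so the size-marginal density evolves closed, and
#' is what the integrator advances.  Age-resolved equilibrium structure is
#' available from \code{\link{equilibrium_decomposition}}.
#'
#' @param model A \code{\link{gbm_model}} or \code{\link{two_resource_model}}.
#' @param v Constant control (two-resource models).
#' @param n0 Initial total population (placed as a neonate point mass
#'   unless \code{density} is given).
#' @param density Optional initial density over the cells.
#' @param n_cells Number of log-size cells.
#' @param xmin_factor Left boundary as a fraction of the birth size.
#' @param t Initial time.
#' @return An object of class \code{"population_state"}.
#' @export
population_state <- function(model, v = NULL, n0 = 1e-4, density = NULL,
                             n_cells = 800L, xmin_factor = 1e-9, t = 0) {
  ep <- effective_params(model, v)
  op <- fp_operator(log(model$x0 * xmin_factor), log(model$xstar),
                    n_cells, NA_real_, ep$sigma2)
  q <- numeric(n_cells)
  i0 <- findInterval(log(model$x0), op$edges)
  if (is.null(density)) {
    q[i0] <- n0 / op$h
  } else {
    stopifnot(length(density) == n_cells, all(density >= 0))
    q <- density
  }
  structure(list(t = t, q = q, op = op, i0 = i0, model = model, v = v,
                 ep = ep, n_flux = 0,
                 Gamma = model$gamma0 * sum(q) * op$h),
            class = "population_state")
}

#' Advance the population by one time step
#'
#' Operator splitting: an implicit (unconditionally stable) Fokker-Planck
#' substep in log-size with the density effect frozen at its current value,
#' exact exponential mortality decay, then renewal — the mass absorbed at
#' the mature-size wall is removed (semelparous death upon reproduction)
#' and re-injected at the birth size multiplied by the fecundity.  The
#' density effect is recomputed from the updated density.  Per-step mass
#' accounting (change = births - deaths - maturations) is verified to
#' \code{1e-6} relative; negative densities or accounting failures abort.
#'
#' @param state A \code{\link{population_state}}.
#' @param dt Time step.
#' @param force_Gamma Optionally hold the density effect at a fixed value
#'   (e.g. 0 to expose the low-density exponential phase).
#' @return The updated \code{"population_state"} (fields \code{t},
#'   \code{q}, \code{Gamma}, \code{n_flux}).
#' @export
population_step <- function(state, dt, force_Gamma = NULL) {
  model <- state$model; ep <- state$ep; op <- state$op
  Gamma <- if (is.null(force_Gamma)) state$Gamma else force_Gamma
  op$nu <- ep$b - ep$cgamma * Gamma - ep$sigma2 / 2
  m_old <- sum(state$q) * op$h
  fp <- fp_implicit_step(op, state$q, dt)
  decay <- exp(-model$mu0 * dt)
  q <- fp$q * decay
  # within-step mortality applies to the maturing cohort as well
  deaths <- (sum(fp$q) * op$h + fp$absorbed) * (1 - decay)
  matured <- fp$absorbed * decay
  births <- model$phi * matured
  q[state$i0] <- q[state$i0] + births / op$h
  m_new <- sum(q) * op$h
  resid <- abs(m_new - (m_old - deaths - matured + births)) /
    max(m_old, .Machine$double.eps)
  if (resid > 1e-6)
    stop("mass accounting residual ", format(resid), " at t = ", state$t)
  if (any(q < -1e-12 * max(q)))
    stop("negative density after step at t = ", state$t)
  state$q <- pmax(q, 0)
  state$t <- state$t + dt
  state$n_flux <- births / dt
  state$Gamma <- model$gamma0 * m_new
  state
}

#' Integrate the nonlinear population dynamics
#'
#' Runs the density-regulated structured population forward in time.
#' Starting from a small founding population the trajectory shows the
#' r-phase (exponential growth at the intrinsic rate of natural increase)
#' followed by saturation at the carrying capacity; forcing the density
#' effect to zero isolates the linear dynamics.
#'
#' @inheritParams population_state
#' @param t_end End time.
#' @param dt Time step (default 0.25; the implicit transport step is
#'   unconditionally stable, the explicit density-effect coupling needs
#'   \code{dt} small against \code{1/Gamma}).
#' @param force_Gamma Optional fixed density effect (see
#'   \code{\link{population_step}}).
#' @param record_every Record the trajectory every so many steps.
#' @param state Optional starting \code{\link{population_state}}
#'   (overrides \code{n0}).
#' @return An object of class \code{"population_trajectory"}: a data.frame
#'   with columns \code{t}, \code{N}, \code{n_flux}, \code{Gamma}, with
#'   the final \code{"population_state"} attached as attribute
#'   \code{"state"}.
#' @examples
#' \donttest{
#' m <- gbm_model(0.15, 0.5, 0.01, x0 = 0.01, xstar = 1.5, phi = 10)
#' tr <- simulate_population(m, n0 = 1e-4, t_end = 400, dt = 0.5)
#' tail(tr$N, 1)   # approaches carrying_capacity_closed_form(m)$N
#' }
#' @export
simulate_population <- function(model, v = NULL, n0 = 1e-4, t_end = 600,
                                dt = 0.25, n_cells = 800L,
                                xmin_factor = 1e-9, force_Gamma = NULL,
                                record_every = 1L, state = NULL) {
  if (is.null(state))
    state <- population_state(model, v, n0, n_cells = n_cells,
                              xmin_factor = xmin_factor)
  n_steps <- ceiling((t_end - state$t) / dt)
  rec <- seq(0L, n_steps, by = record_every)
  out <- data.frame(t = numeric(length(rec)), N = NA_real_,
                    n_flux = NA_real_, Gamma = NA_real_)
  ri <- 1L
  record <- function(k) {
    out$t[ri] <<- state$t
    out$N[ri] <<- sum(state$q) * state$op$h
    out$n_flux[ri] <<- state$n_flux
    out$Gamma[ri] <<- state$Gamma
    ri <<- ri + 1L
  }
  record(0L)
  for (k in seq_len(n_steps)) {
    state <- population_step(state, dt, force_Gamma)
    if (k %in% rec) record(k)
  }
  structure(out, state = state, class = c("population_trajectory",
                                          class(out)))
}

#' Numerical stability probe of the nontrivial equilibrium
#'
#' Integrates the nonlinear dynamics from the relaxed equilibrium profile
#' scaled by \eqn{1 \pm \epsilon} and classifies the equilibrium as
#' numerically stable if the total-population deviation decays below
#' \eqn{0.1\,\epsilon N^*} within the probe horizon.  Subcritical models
#' report extinction-stable decay to zero; a zero perturbation must stay
#' at the fixed point.
#'
#' @inheritParams simulate_population
#' @param eps Relative perturbation (default 0.1).
#' @param settle_time Integration time used to relax onto the equilibrium
#'   profile before perturbing.
#' @param probe_time Horizon of the perturbed runs.
#' @return List with \code{verdict} (\code{"stable"}, \code{"unstable"} or
#'   \code{"extinction-stable"}), the deviation trajectories and
#'   \code{N_star}.
#' @export
stability_probe <- function(model, v = NULL, eps = 0.1,
                            settle_time = 1500, probe_time = 800,
                            dt = 0.5, n_cells = 800L) {
  cc <- carrying_capacity_closed_form(model, v)
  if (!cc$persistent) {
    tr <- simulate_population(model, v, n0 = 0.01, t_end = probe_time,
                              dt = dt, n_cells = n_cells)
    decayed <- tail(tr$N, 1L) < 0.1 * tr$N[1L]
    return(list(verdict = if (decayed) "extinction-stable" else "unstable",
                trajectories = list(tr), N_star = 0))
  }
  base <- simulate_population(model, v, n0 = cc$N / 2,
                              t_end = settle_time, dt = dt,
                              n_cells = n_cells, record_every = 10L)
  eq_state <- attr(base, "state")
  N_eq <- sum(eq_state$q) * eq_state$op$h
  run_from <- function(scale) {
    st <- eq_state
    st$q <- st$q * scale
    st$Gamma <- st$model$gamma0 * sum(st$q) * st$op$h
    st$t <- 0
    simulate_population(model, v, t_end = probe_time, dt = dt,
                        state = st, record_every = 10L)
  }
  if (eps == 0) {
    tr <- run_from(1)
    drift <- max(abs(tr$N - N_eq)) / N_eq
    return(list(verdict = if (drift < 1e-3) "stable" else "unstable",
                trajectories = list(tr), N_star = N_eq))
  }
  trs <- lapply(c(1 + eps, 1 - eps), run_from)
  ok <- vapply(trs, function(tr)
    abs(tail(tr$N, 1L) - N_eq) < 0.1 * eps * N_eq, logical(1L))
  list(verdict = if (all(ok)) "stable" else "unstable",
       trajectories = trs, N_star = N_eq)
}

#' Individual-based cross-check of the population dynamics
#'
#' A birth-death simulation distributionally equivalent to the structured
#' model: each agent carries a log-size following the Euler-Maruyama
#' update, dies with probability \eqn{1 - e^{-\mu_0 dt}} per step,
#' reproduces (and is removed) upon crossing the mature size, and the
#' density effect is computed from the living ensemble via the system size
#' \code{omega} (agents per unit of population density).  Demographic noise
#' scales as \eqn{1/\sqrt{\Omega}}; averaging trajectories over seeds
#' recovers the deterministic dynamics.
#'
#' @inheritParams simulate_population
#' @param n0 Founding number of agents.
#' @param omega System size: simulated density = agents / omega.
#' @param seed Integer seed.
#' @param cap Maximum living agents (exceeding it truncates the run with a
#'   warning).
#' @param record_every Record every so many steps.
#' @return Data.frame with columns \code{t}, \code{agents}, \code{N}
#'   (density scale), \code{Gamma}; attribute \code{"truncated"}.
#' @export
simulate_abm <- function(model, v = NULL, n0 = 100L, omega = 1e4,
                         t_end = 600, dt = 0.25, seed = NULL,
                         cap = 1e5L, record_every = 4L) {
  ep <- effective_params(model, v)
  if (!is.null(seed)) set.seed(seed)
  u <- rep(log(model$x0), n0)
  ustar <- log(model$xstar)
  u0 <- log(model$x0)
  n_steps <- ceiling(t_end / dt)
  rec <- seq(0L, n_steps, by = record_every)
  out <- data.frame(t = rec * dt, agents = NA_real_, N = NA_real_,
                    Gamma = NA_real_)
  sig <- sqrt(ep$sigma2); sqdt <- sqrt(dt)
  pdeath <- 1 - exp(-model$mu0 * dt)
  phi_lo <- floor(model$phi); phi_fr <- model$phi - phi_lo
  truncated <- FALSE
  ri <- 1L
  for (k in 0:n_steps) {
    Gamma <- model$gamma0 * length(u) / omega
    if (k %in% rec) {
      out$agents[ri] <- length(u)
      out$N[ri] <- length(u) / omega
      out$Gamma[ri] <- Gamma
      ri <- ri + 1L
    }
    if (k == n_steps || !length(u)) {
      if (!length(u) && ri <= nrow(out)) {
        out$agents[ri:nrow(out)] <- 0
        out$N[ri:nrow(out)] <- 0
        out$Gamma[ri:nrow(out)] <- 0
      }
      break
    }
    nu <- ep$b - ep$cgamma * Gamma - ep$sigma2 / 2
    u <- u + nu * dt + sig * sqdt * stats::rnorm(length(u))
    u <- u[stats::runif(length(u)) >= pdeath]
    crossed <- sum(u >= ustar)
    u <- u[u < ustar]
    if (crossed > 0) {
      kids <- crossed * phi_lo + stats::rbinom(1L, crossed, phi_fr)
      u <- c(u, rep(u0, kids))
    }
    if (length(u) > cap) {
      warning("agent cap exceeded at t = ", k * dt, "; truncating run")
      truncated <- TRUE
      out <- out[seq_len(ri - 1L), ]
      break
    }
  }
  structure(out, truncated = truncated)
}
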