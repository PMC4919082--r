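#' State space specification
#'
#' Describes the set of admissible individual states: a box of per-coordinate
#' open intervals with absorbing boundaries (drift and diffusion vanish on the
#' boundary, so paths never leave the interior).
#'
#' @param dimension Number of state coordinates (positive integer).
#' @param lower,upper Numeric vectors of per-coordinate bounds
#'   (\code{lower < upper}; \code{Inf} allowed for \code{upper}).
#' @return An object of class \code{"state_spec"}.
#' @export
state_spec <- function(dimension = 1L, lower = 0, upper = Inf) {
  dimension <- as.integer(dimension)
  stopifnot(dimension >= 1L, length(lower) == dimension,
            length(upper) == dimension)
  if (any(!is.finite(lower) & lower != -Inf))
    stop("lower bounds must be finite or -Inf")
  if (any(lower >= upper))
    stop("each lower bound must be strictly below its upper bound")
  structure(list(dimension = dimension, lower = lower, upper = upper,
                 boundary = "absorbing"),
            class = "state_spec")
}

#' General controlled life-history model
#'
#' A life history is the quadruple (growth, fertility, mortality, interaction):
#' state transitions follow the Ito stochastic differential equation
#' \deqn{dX_a = g(X_a, v, \Gamma)\,da + \sigma(X_a, v, \Gamma)\,dB_a,}
#' individuals reproduce at state-dependent rate \eqn{F(y,\Gamma) \ge 0}, die
#' at rate \eqn{\mu(y,v,\Gamma) \ge \mu_0 > 0}, and feed back on the
#' population through nonnegative interaction kernels \eqn{\gamma^m(a,y)}
#' whose population-weighted integrals form the density-effect vector
#' \eqn{\Gamma}.
#'
#' @param state_spec A \code{\link{state_spec}}.
#' @param drift Function \code{(y, v, Gamma) -> numeric(d)}, the expected
#'   state transition rate.
#' @param diffusion Function \code{(y, v, Gamma) -> d x N matrix} of noise
#'   loadings (the covariance \eqn{\sigma\sigma^T} must be positive
#'   semidefinite).
#' @param mortality Function \code{(y, v, Gamma) -> rate >= mu0}.
#' @param fertility Function \code{(y, Gamma) -> rate >= 0}; semelparous
#'   point-mass fertility is encoded by \code{semelparous = TRUE} together
#'   with \code{xstar} and \code{phi} rather than by a numerical delta.
#' @param interaction Function \code{(a, y) -> numeric(M)} of nonnegative
#'   interaction kernels, or a single nonnegative constant.
#' @param alpha Maximum age (finite or \code{Inf}).
#' @param x0 Initial state, interior to the state space.
#' @param semelparous Logical marker: reproduction is concentrated at the
#'   first passage to a mature state, upon which the individual dies.
#' @param xstar,phi Mature size and fecundity for semelparous models.
#' @return An object of class \code{"life_history_model"}.
#' @export
life_history_model <- function(state_spec, drift, diffusion, mortality,
                               fertility = NULL, interaction = 1,
                               alpha = Inf, x0,
                               semelparous = FALSE, xstar = NULL, phi = NULL) {
  stopifnot(inherits(state_spec, "state_spec"), is.function(drift),
            is.function(diffusion), is.function(mortality))
  if (length(x0) != state_spec$dimension)
    stop("x0 must have one entry per state coordinate")
  if (any(x0 <= state_spec$lower) || any(x0 >= state_spec$upper))
    stop("x0 must be interior to the state space")
  if (alpha <= 0) stop("alpha must be positive")
  if (semelparous) {
    if (is.null(xstar) || is.null(phi))
      stop("semelparous models need 'xstar' and 'phi'")
  } else if (is.null(fertility)) {
    stop("non-semelparous models need a fertility function")
  }
  structure(list(state_spec = state_spec, drift = drift,
                 diffusion = diffusion, mortality = mortality,
                 fertility = fertility, interaction = interaction,
                 alpha = alpha, x0 = x0, semelparous = semelparous,
                 xstar = xstar, phi = phi),
            class = "life_history_model")
}

#' Semelparous geometric-Brownian-motion life history
#'
#' The resource acquisition competition model: individual size grows as a
#' geometric Brownian motion whose mean rate is reduced by intraspecific
#' competition,
#' \deqn{dX_a = (b_1 - \Gamma) X_a\,da + \sigma_1 X_a\,dB_a,\qquad X_0 = x,}
#' reproduction is semelparous (a point mass of \eqn{\phi(x^*)} offspring at
#' the first passage of size to the mature size \eqn{x^*}, followed by
#' death), background mortality is the constant \eqn{\mu_0 > 0}, and the
#' interaction kernel is the constant \eqn{\gamma_0}, so the density effect
#' is \eqn{\Gamma = \gamma_0 N}.
#'
#' @param b1 Mean specific growth rate (1/time).
#' @param sigma1 Magnitude of the internal stochasticity (noise on the
#'   specific growth rate); \code{sigma1 >= 0}.
#' @param mu0 Background mortality rate (> 0).
#' @param x0 Size at birth (> 0).
#' @param xstar Mature size (> \code{x0}).
#' @param phi Fecundity at maturity (offspring per individual, > 1 for a
#'   viable population).
#' @param gamma0 Interaction constant linking total population size to the
#'   density effect, \eqn{\Gamma = \gamma_0 N}.
#' @return An object of class \code{c("gbm_model", "life_history_model")}.
#' @seealso \code{\link{ees}}, \code{\link{irni_closed_form}},
#'   \code{\link{two_resource_model}}
#' @examples
#' m <- gbm_model(b1 = 0.15, sigma1 = 0.5, mu0 = 0.01,
#'                x0 = 0.01, xstar = 1.5, phi = 10)
#' ees(m)
#' irni_closed_form(m)
#' @export
gbm_model <- function(b1, sigma1, mu0, x0, xstar, phi, gamma0 = 1) {
  stopifnot(is.numeric(b1), length(b1) == 1L, sigma1 >= 0, mu0 > 0,
            gamma0 > 0)
  if (!(xstar > x0 && x0 > 0))
    stop("need xstar > x0 > 0")
  if (phi <= 0) stop("phi must be positive")
  m <- life_history_model(
    state_spec = state_spec(1L, 0, Inf),
    drift      = function(y, v, Gamma) (b1 - Gamma) * y,
    diffusion  = function(y, v, Gamma) matrix(sigma1 * y, 1L, 1L),
    mortality  = function(y, v, Gamma) mu0,
    interaction = gamma0, alpha = Inf, x0 = x0,
    semelparous = TRUE, xstar = xstar, phi = phi)
  m$b1 <- b1; m$sigma1 <- sigma1; m$mu0 <- mu0; m$gamma0 <- gamma0
  class(m) <- c("gbm_model", class(m))
  m
}

#' Density-dependent two-resource utilisation model
#'
#' A semelparous species allocates foraging effort between two resources.
#' Specialising on resource 1 gives specific growth rate \eqn{b_1} with
#' noise \eqn{\sigma_1}; resource 2 gives \eqn{b_2 < b_1} with
#' \eqn{\sigma_2 < \sigma_1} (lower risk, lower mean).  Competition of total
#' strength \eqn{\Gamma} is split between the resources in ratio
#' \eqn{\kappa : (1-\kappa)}.  Under a constant utilisation ratio
#' \eqn{v \in [0,1]} (weight on resource 2, the two driving noises being
#' independent) size follows a geometric Brownian motion with effective
#' drift \eqn{\theta_1(1-v) + \theta_2 v}, where \eqn{\theta_1 = b_1 -
#' \kappa\Gamma}, \eqn{\theta_2 = b_2 - (1-\kappa)\Gamma}, and effective
#' variance \eqn{(1-v)^2\sigma_1^2 + v^2\sigma_2^2}.  Reproduction and
#' mortality are as in \code{\link{gbm_model}}.
#'
#' @inheritParams gbm_model
#' @param b2 Mean specific growth rate on resource 2 (may be negative,
#'   must be < \code{b1}).
#' @param sigma2 Noise magnitude on resource 2 (\code{0 <= sigma2 < sigma1}).
#' @param kappa Ratio of competition strength borne on resource 1,
#'   in (0, 1).
#' @return An object of class
#'   \code{c("two_resource_model", "life_history_model")}.
#' @seealso \code{\link{two_resource_policy}}, \code{\link{kstrategy_equilibrium}}
#' @export
two_resource_model <- function(b1, b2, sigma1, sigma2, kappa, mu0,
                               x0, xstar, phi, gamma0 = 1) {
  stopifnot(b1 > b2, sigma1 > sigma2, sigma2 >= 0, mu0 > 0, gamma0 > 0)
  if (!(kappa > 0 && kappa < 1)) stop("kappa must lie in (0, 1)")
  if (!(xstar > x0 && x0 > 0)) stop("need xstar > x0 > 0")
  if (phi <= 0) stop("phi must be positive")
  m <- life_history_model(
    state_spec = state_spec(1L, 0, Inf),
    drift = function(y, v, Gamma)
      ((b1 - kappa * Gamma) * (1 - v) + (b2 - (1 - kappa) * Gamma) * v) * y,
    diffusion = function(y, v, Gamma)
      matrix(c((1 - v) * sigma1 * y, v * sigma2 * y), 1L, 2L),
    mortality = function(y, v, Gamma) mu0,
    interaction = gamma0, alpha = Inf, x0 = x0,
    semelparous = TRUE, xstar = xstar, phi = phi)
  m$b1 <- b1; m$b2 <- b2; m$sigma1 <- sigma1; m$sigma2 <- sigma2
  m$kappa <- kappa; m$mu0 <- mu0; m$gamma0 <- gamma0
  class(m) <- c("two_resource_model", class(m))
  m
}

#' Control policy
#'
#' A strategy regulating state transitions, taking values in a compact
#' interval (per control coordinate).  Policies may be constant, an
#' age-indexed table (step function in age), or an arbitrary function of
#' \code{(a, y, Gamma)}; evaluations are always clamped into the admissible
#' set.
#'
#' @param value A constant, or for \code{kind = "age_table"} a
#'   \code{data.frame} with columns \code{age} and \code{v}, or a function
#'   \code{(a, y, Gamma) -> v}.
#' @param lower,upper Bounds of the admissible set V.
#' @param kind One of \code{"constant"}, \code{"age_table"},
#'   \code{"feedback"}; inferred from \code{value} when missing.
#' @return An object of class \code{"control_policy"}; call it via
#'   \code{\link{eval_policy}}.
#' @export
control_policy <- function(value, lower = 0, upper = 1, kind = NULL) {
  stopifnot(lower <= upper)
  if (is.null(kind)) {
    kind <- if (is.function(value)) "feedback"
            else if (is.data.frame(value)) "age_table"
            else "constant"
  }
  kind <- match.arg(kind, c("constant", "age_table", "feedback"))
  if (kind == "constant") stopifnot(is.numeric(value), length(value) == 1L)
  if (kind == "age_table") stopifnot(all(c("age", "v") %in% names(value)))
  structure(list(value = value, lower = lower, upper = upper, kind = kind),
            class = "control_policy")
}

#' @rdname control_policy
#' @param v A constant control value.
#' @export
constant_policy <- function(v, lower = 0, upper = 1)
  control_policy(v, lower, upper, kind = "constant")

#' Evaluate a control policy
#'
#' @param policy A \code{\link{control_policy}} (or \code{NULL}, treated as
#'   the constant 0).
#' @param a Age.
#' @param y State.
#' @param Gamma Density effect.
#' @return Control value(s), clamped into the admissible set.
#' @export
eval_policy <- function(policy, a = 0, y = NULL, Gamma = 0) {
  if (is.null(policy)) return(0)
  stopifnot(inherits(policy, "control_policy"))
  v <- switch(policy$kind,
    constant  = rep(policy$value, length.out = max(length(a), 1L)),
    age_table = {
      tab <- policy$value
      idx <- findInterval(a, tab$age, rightmost.closed = FALSE)
      tab$v[pmax(idx, 1L)]
    },
    feedback  = policy$value(a, y, Gamma))
  pmin(pmax(v, policy$lower), policy$upper)
}

#' Density-effect vector
#'
#' Validates a density-effect vector: finite, nonnegative components
#' (the zero vector encodes r-selection, i.e. negligible density).
#'
#' @param Gamma Numeric vector of density-effect components.
#' @return The validated numeric vector.
#' @export
density_effect <- function(Gamma) {
  if (!is.numeric(Gamma) || any(!is.finite(Gamma)) || any(Gamma < 0))
    stop("Gamma must be a finite, nonnegative numeric vector")
  Gamma
}

# Effective scalar-GBM parameters of a model under a constant control v and
# density effect split: list(b = drift intercept, sigma2 = variance,
# cgamma = coefficient multiplying Gamma in the drift).  All closed forms
# work off this reduction.
effective_params <- function(model, v = NULL) {
  UseMethod("effective_params")
}

#' @export
effective_params.gbm_model <- function(model, v = NULL) {
  list(b = model$b1, sigma2 = model$sigma1^2, cgamma = 1)
}

#' @export
effective_params.two_resource_model <- function(model, v = NULL) {
  if (is.null(v)) stop("two-resource models need a constant control v")
  if (inherits(v, "control_policy")) {
    if (v$kind != "constant")
      stop("closed-form reductions need a constant policy")
    v <- v$value
  }
  stopifnot(is.numeric(v), length(v) == 1L, v >= 0, v <= 1)
  list(b = model$b1 * (1 - v) + model$b2 * v,
       sigma2 = (1 - v)^2 * model$sigma1^2 + v^2 * model$sigma2^2,
       cgamma = model$kappa + (1 - 2 * model$kappa) * v)
}

#' @export
print.life_history_model <- function(x, ...) {
  cat("Life history model (", class(x)[1L], ")\n", sep = "")
  cat("  state dimension:", x$state_spec$dimension,
      " initial state:", format(x$x0), "\n")
  if (x$semelparous)
    cat("  semelparous: mature size", x$xstar, ", fecundity", x$phi, "\n")
  for (f in intersect(c("b1", "b2", "sigma1", "sigma2", "kappa",
                        "mu0", "gamma0"), names(x)))
    cat("  ", f, " = ", format(x[[f]]), "\n", sep = "")
  invisible(x)
}

#' @export
print.control_policy <- function(x, ...) {
  cat("Control policy (", x$kind, ") on [", x$lower, ", ", x$upper, "]\n",
      sep = "")
  if (x$kind == "constant") cat("  v =", x$value, "\n")
  invisible(x)
}
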