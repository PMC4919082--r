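---
title: "Methods: stochastic control and structured populations for r/K selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic control and structured populations for r/K selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rkselect)
```

## The model

`rkselect` studies how life-history strategies evolve when two forces act
together: *density dependence* (individuals degrade each other's vital
rates as the population grows) and *internal stochasticity* (diffusion-like
individual variation in growth trajectories, as opposed to environmental
noise acting on the whole population).

An individual of age $a$ carries a state $X_a$ (here: body size) obeying a
controlled Ito stochastic differential equation

$$dX_a = g(X_a, v, \Gamma)\,da + \sigma(X_a, v, \Gamma)\,dB_a,$$

with a strategy $v$ taking values in a compact set, mortality rate
$\mu(X_a, v, \Gamma) \ge \mu_0 > 0$, fertility rate $F(X_a, \Gamma)$, and a
density effect $\Gamma$ — the population-weighted integral of an
interaction kernel $\gamma(a, y)$ — feeding back into all of these.  The
population density $P_t(a, x \to y)$ follows a nonlinear transport /
Fokker–Planck equation in age and state, renewed at age zero by the birth
flux.

Everything the package computes flows from one object, the
**characteristic function**

$$\psi_\lambda^v(x, \Gamma) = \int_0^\alpha e^{-\lambda a}\,
  E_x\!\left[F(X_a, \Gamma)\, e^{-\int_0^a \mu\,d\tau}\right] da,$$

the $\lambda$-discounted, survival-weighted lifetime reproduction.  It is
continuous and strictly decreasing in $\lambda$, which gives three roots a
precise meaning:

* $\psi_{\lambda^*}(x, 0) = 1$: the **Euler–Lotka equation**; $\lambda^*$
  is the intrinsic rate of natural increase (the r-selection fitness).
* $\psi_0(x, \Gamma^*) = 1$: the basic reproductive number equals one at
  the **equilibrium density effect**; with a constant interaction kernel
  $\gamma_0$, the carrying capacity is $N^* = \Gamma^*/\gamma_0$.
* the strategy maximising $\psi$ — obtained from a stationary
  **Hamilton–Jacobi–Bellman equation** — simultaneously maximises
  $\lambda^*$ at $\Gamma = 0$ (the r-strategy) and, evaluated at the
  equilibrium $\tilde\Gamma$ it generates, is an evolutionarily stable
  strategy that maximises the carrying capacity (the K-strategy).

Monotonicity of $\psi$ in $\lambda$ is what makes "maximise $\psi$" and
"maximise $\lambda^*$" the same ordering; the test suite checks it
explicitly, because every root-finder in the package relies on it.

## The two concrete families

Two solvable families make every numerical route checkable against closed
forms.

**Resource acquisition competition model** (`gbm_model`): size grows as a
geometric Brownian motion whose mean rate is reduced by competition,
$dX_a = (b_1 - \Gamma)X_a\,da + \sigma_1 X_a\,dB_a$, $X_0 = x$.
Reproduction is semelparous: at the first passage $a^*$ of size to the
mature size $x^*$, the individual produces $\phi(x^*)$ offspring of size
$x$ and dies; before that it dies at the background rate $\mu_0$.  The
interaction kernel is the constant $\gamma_0$, so $\Gamma = \gamma_0 N$.
Substituting $\psi \propto x^\rho$ into the stationary backward equation
gives the characteristic quadratic

$$\tfrac{\sigma_1^2}{2}\rho^2 + \left(b_1 - \Gamma -
  \tfrac{\sigma_1^2}{2}\right)\rho - (\mu_0 + \lambda) = 0,$$

whose positive root $\rho_\lambda(\Gamma)$ yields
$\psi_\lambda = (x/x^*)^{\rho_\lambda(\Gamma)}\phi(x^*)$ and, through the
**efficiency exponent of semelparity**
$\rho^* = \ln\phi(x^*)/\ln(x^*/x)$, the closed forms

$$\lambda^* = \left[b_1 - \tfrac{\sigma_1^2}{2}(1 - \rho^*)\right]\rho^*
  - \mu_0, \qquad
  \Gamma^* = b_1 - \tfrac{\sigma_1^2}{2}(1 - \rho^*) - \mu_0/\rho^*.$$

$\rho^*$ controls the sign of every noise effect: growth rate and capacity
fall with $\sigma_1^2$ when $\rho^* < 1$ (slope
$\partial N^*/\partial\sigma_1^2 = -(1-\rho^*)/2\gamma_0$, exactly linear),
are noise-free at $\rho^* = 1$, and rise when $\rho^* > 1$.

**Two-resource utilisation model** (`two_resource_model`): the control
$v \in [0,1]$ splits foraging between a fast/noisy resource
($b_1, \sigma_1$) and a slow/safe one ($b_2, \sigma_2$), with competition
split $\kappa : (1-\kappa)$ between them.  Under a constant $v$ this is
again a GBM with drift $\theta_1(1-v) + \theta_2 v$,
$\theta_i = b_i - \kappa_i\Gamma$, and variance
$(1-v)^2\sigma_1^2 + v^2\sigma_2^2$ (independent noises), so the same
quadratic applies.  The Hamiltonian is quadratic in $v$, giving the
closed-form adaptive control (for $\rho^* < 1$)

$$\tilde v = \mathrm{clamp}\!\left(
  \frac{\sigma_1^2}{\sigma_1^2 + \sigma_2^2}
  - \frac{b_1 - b_2 + (1 - 2\kappa)\Gamma}
         {(\sigma_1^2 + \sigma_2^2)(1 - \rho^*)},\ 0,\ 1\right),$$

a variance hedge minus a drift penalty.  As $\rho^* \uparrow 1$ the hedge
collapses onto a pure strategy, with the winner decided by the critical
split $\kappa_0 = 1/(1 + (b_2 - \mu_0)/(b_1 - \mu_0))$; we re-derived
$\kappa_0$ by equating the pure-strategy equilibrium density effects
$(b_1-\mu_0)/\kappa$ and $(b_2-\mu_0)/(1-\kappa)$ in the noise-free limit,
and the package's fixed-point solver confirms the collapse on both sides
of the threshold.

```{r closed-forms}
m <- gbm_model(b1 = 0.15, sigma1 = 0.5, mu0 = 0.01,
               x0 = 0.01, xstar = 1.5, phi = 10)
c(ees = ees(m), irni = irni_closed_form(m),
  Gamma_star = carrying_capacity_closed_form(m)$Gamma)
```

## Three routes to one function

Every quantity above is computed by at least two independent routes, and
the tests hold them against each other:

1. **Closed form** (`psi_closed_form`, `irni_closed_form`,
   `carrying_capacity_closed_form`): the quadratic-root expressions.
   The printed-formula route is never trusted alone — `rho_lambda`
   returns its quadratic residual as an attribute so the defining property
   can be asserted directly.
2. **Feynman–Kac boundary-value solve** (`psi_ode`): the stationary
   backward ODE on a log-size grid, with the semelparous point-mass
   fertility entering as a Dirichlet condition $\psi(x^*) = \phi(x^*)$
   (no numerical delta function) and a bounded-solution Robin condition at
   the far-left boundary.
3. **Monte Carlo** (`simulate_paths` + `path_functional`, `psi_mc`):
   Euler–Maruyama in log-size (positivity is exact; each log-increment is
   exactly Gaussian), first-passage detection with a Brownian-bridge
   correction, and the estimator
   $\hat\psi = \phi(x^*)\,\overline{e^{-(\lambda+\mu_0)a^*}}$ with its
   standard error.

`solve_irni` and `solve_equilibrium` wrap Brent root-finding around routes
2 or 3; `solve_stationary_hjb` runs policy iteration (linear solve at the
current policy, then the analytic pointwise minimiser of the quadratic
Hamiltonian, with endpoint comparison where the second-order condition
fails); `solve_adaptive_root` adds the outer Brent iteration on
$\tilde\psi(x;\lambda) = 1$.  One subtlety worth recording: the
closed-form control above holds where the value surface has exponent
$\rho^*$, i.e. *at the dominant root* — comparing the numerical HJB policy
against it at an arbitrary $\lambda$ is a category error, and the tests
therefore compare at the root.

## Numerical choices

* **Feynman–Kac grid.** Log-size transform, second-order central
  differences, Thomas (tridiagonal) solves in compiled code.  The birth
  size is aligned onto the grid and the solve is run at spacings $h$,
  $2h$, $4h$; Richardson extrapolation of the two pairs gives the value
  (relative accuracy about $10^{-9}$ at the default `n_grid = 8001`) and
  an a-posteriori error estimate — the solve refuses if the estimate
  exceeds its tolerance rather than returning a silently degraded value.
  The left boundary sits at $10^{-3}$ times the birth size; the Robin
  closure uses the local positive characteristic exponent (GBM never
  reaches size zero, and the bounded branch is the positive-exponent one).
* **Zero noise** is an explicit analytic branch everywhere (deterministic
  crossing time, point-mass breeding-age density), never a small-$\sigma$
  limit of the stochastic code.
* **First passage.** Default time step `dt = 0.05` for exploratory work
  (the convergence tests halve it); overshoot steps are interpolated
  linearly in log-state (exact for $\sigma = 0$) and within-step
  excursions are recovered by Brownian-bridge sampling, reducing the
  $O(\sqrt{dt})$ late bias of plain grid crossing.  Paths are simulated
  sequentially from R's RNG, so a fixed seed reproduces the ensemble
  bitwise and enlarging `n_paths` leaves earlier paths unchanged.
  For semelparous models with unbounded age the horizon defaults to the
  age where survivorship falls below $10^{-8}$, a bound on the truncated
  contribution that `path_functional` also reports.
* **Population integrator.** The concrete families couple to the
  population only through the total density effect (constant kernel) and
  the maturation flux at $x^*$, and their coefficients are
  age-independent, so the size-marginal density evolves autonomously;
  `simulate_population` advances it with an implicit finite-volume
  Fokker–Planck step (unconditionally stable), exact exponential
  mortality, and renewal that removes the mass absorbed at the
  mature-size wall and re-injects it at the birth size times $\phi$.
  The discrete fluxes telescope, so mass accounting
  (change = births − deaths − maturations) is exact and is enforced to
  $10^{-6}$ per step.  The age-resolved equilibrium structure
  $P^*(a, x \to y) = n^* K^*_a(x \to y)$ is recovered separately by
  propagating the projection kernel (`equilibrium_decomposition`), with a
  closure test that re-integration recovers $\Gamma^*$ within 1%.
* **The left wall of the population grid** deserves a note: at the Fig-1
  style equilibria the log-size drift is negative, and a substantial
  fraction of the standing population drifts far below the birth size
  before dying.  A grid cut at $10^{-3} x$ would truncate that mass and
  bias the carrying capacity by over a percent, so the default domain
  reaches $10^{-9} x$ with a zero-flux wall (mass is conserved, and
  misplaced tail mass is dynamically inert — it only re-enters the
  dynamics through the distant mature-size boundary).  Defaults
  `n_cells = 800`, `dt = 0.25` put the plateau within 0.1–0.3% of the
  closed form across $\sigma_1 \in \{0.4, 0.5, 0.6\}$; the density effect
  is refreshed once per step (explicit coupling), valid because
  `dt` is small against $1/\Gamma$.
* **Fixed points and roots.** Brent with bracket-doubling everywhere
  ($10^{-12}$ on the root variable); the K-strategy $(\Gamma, v)$
  alternation is damped at $0.5$ and errors with its iterate trace after
  500 steps; clamp ties at the control bounds resolve toward the interior.
* **Individual-based cross-check** (`simulate_abm`): a birth–death
  realisation with the density effect computed from the living ensemble
  through a system size $\Omega$; demographic noise scales as
  $\Omega^{-1/2}$, and the PDE trajectory is required to sit inside the
  multi-seed Monte Carlo band.

## What the generators emulate — and what they do not

The package's "data" are entirely synthetic: the two model families *are*
the study conditions, with defaults fixed at the reference parameter set
($b_1 = 0.15$, $\sigma_1 \in \{0.4, 0.5, 0.6\}$ or $0.6$, $b_2 = 0.05$,
$\sigma_2 = 0.02$, $x = 0.01$, $x^* = 1.5$, $\phi = 10$, $\mu_0 = 0.01$,
$\gamma_0 = 1$), and `make_fixture` adds the deterministic edge cases the
tests need (efficiency exponent exactly one; subcritical fecundity; a
$\kappa$ pair straddling $\kappa_0$).  Passing tests therefore show that
the solvers agree with each other and with the analytic structure of these
families — they do not show that any real species follows a GBM growth
law, that competition is well summarised by a single scalar, or that
mortality is state-independent.  In particular the framework deliberately
excludes environmental (external) stochasticity, age-varying mortality
below maturity, and multi-dimensional state; conclusions about real
populations need those assumptions defended separately.

## Known limitations

* Closed forms exist only for the two families; other
  `life_history_model`s get the Monte Carlo route and the reference R
  integrator (scalar state only).
* The deterministic ($\sigma_1 = 0$) semelparous population is a pulsed
  cohort train with no mixing; its long-run behaviour is a neutral cycle
  rather than a point equilibrium, so equilibrium-level comparisons are
  made only for $\sigma_1 > 0$ (the zero-noise tests check the growth
  rate of the pulse envelope instead).
* The interior optimal-control formula requires $\rho^* < 1$; at and
  above one, only the limit analysis through $\kappa_0$ is provided, and
  `two_resource_policy` refuses rather than extrapolating.
* Vector-valued density effects are not exposed: both families are
  scalar-$\Gamma$.
* Multiple equilibria, cycles or chaos in the density feedback are out of
  scope; the stability verdict is a numerical perturbation probe, not a
  spectral criterion.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run Monte Carlo ensembles of
$2\times 10^4$–$2\times 10^5$ paths (`dt` 0.02–0.05), Feynman–Kac grids of
8001 nodes, population runs to $t = 2000$ at `dt = 0.25` on 800 cells, and
$\kappa$ sweeps at resolution 0.05 — sizes chosen so every consistency
band (3 Monte Carlo standard errors; 1% on population plateaus; $10^{-6}$
on closed-form agreement) is comfortably resolved.
```{r session, echo = FALSE}
sessionInfo()$R.version$version.string
```
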