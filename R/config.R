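# Scenario configuration: YAML/JSON mapping with blocks
#   model:   type ("gbm" | "two_resource") + parameters
#   policy:  kind ("constant") + v            (optional)
#   solver:  tolerances, grids, seed          (optional)
#   outputs: dir, formats                     (optional)
# Unknown keys anywhere are rejected so typos fail loudly.

.schema <- list(
  top = c("model", "policy", "solver", "outputs"),
  model_gbm = c("type", "b1", "sigma1", "mu0", "x0", "xstar", "phi",
                "gamma0"),
  model_two = c("type", "b1", "b2", "sigma1", "sigma2", "kappa", "mu0",
                "x0", "xstar", "phi", "gamma0"),
  policy = c("kind", "v", "lower", "upper"),
  solver = c("n_grid", "n_paths", "dt", "horizon", "seed", "tol"),
  outputs = c("dir", "formats"))

check_keys <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra))
    stop("unknown key(s) in ", where, ": ", paste(extra, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
}

#' Read and validate a scenario configuration
#'
#' Scenario files are YAML (or JSON) mappings with a \code{model} block
#' (\code{type} plus the model parameters), and optional \code{policy},
#' \code{solver} and \code{outputs} blocks.  Unknown keys are rejected
#' with an explicit message.
#'
#' @param path Path to a YAML or JSON scenario file.
#' @return The validated configuration list.
#' @seealso \code{\link{model_from_config}}, \code{\link{make_fixture}}
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("no such scenario file: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  validate_scenario_config(cfg)
}

#' @rdname read_scenario_config
#' @param cfg A configuration list (as parsed from YAML/JSON).
#' @export
validate_scenario_config <- function(cfg) {
  if (!is.list(cfg) || is.null(cfg$model))
    stop("a scenario needs a 'model' block")
  check_keys(cfg, .schema$top, "scenario")
  type <- cfg$model$type
  if (is.null(type) || !type %in% c("gbm", "two_resource"))
    stop("model$type must be 'gbm' or 'two_resource'")
  check_keys(cfg$model,
             if (type == "gbm") .schema$model_gbm else .schema$model_two,
             paste0("model (type ", type, ")"))
  if (!is.null(cfg$policy)) check_keys(cfg$policy, .schema$policy, "policy")
  if (!is.null(cfg$solver)) check_keys(cfg$solver, .schema$solver, "solver")
  if (!is.null(cfg$outputs))
    check_keys(cfg$outputs, .schema$outputs, "outputs")
  cfg
}

#' Build a model (and policy) from a scenario configuration
#'
#' @param cfg A validated configuration list or a path to a scenario file.
#' @return List with \code{model}, \code{policy} (possibly \code{NULL})
#'   and the \code{solver} block.
#' @export
model_from_config <- function(cfg) {
  if (is.character(cfg)) cfg <- read_scenario_config(cfg)
  cfg <- validate_scenario_config(cfg)
  pars <- cfg$model[setdiff(names(cfg$model), "type")]
  model <- switch(cfg$model$type,
    gbm = do.call(gbm_model, pars),
    two_resource = do.call(two_resource_model, pars))
  policy <- if (!is.null(cfg$policy))
    control_policy(cfg$policy$v,
                   lower = cfg$policy$lower %||% 0,
                   upper = cfg$policy$upper %||% 1,
                   kind = cfg$policy$kind %||% "constant")
  list(model = model, policy = policy, solver = cfg$solver)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate deterministic test fixtures
#'
#' Writes small, byte-stable scenario files used by the test suite and as
#' worked examples: \code{"ees1"} (fecundity tuned so the efficiency
#' exponent is exactly one, making growth rate and carrying capacity
#' noise-insensitive), \code{"subcritical"} (fecundity at most one:
#' extinction), and \code{"kappa-pair"} (two-resource scenarios straddling
#' the critical competition split).
#'
#' @param kind One of \code{"ees1"}, \code{"subcritical"},
#'   \code{"kappa-pair"}.
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the solver block.
#' @return Paths of the files written, invisibly.
#' @export
make_fixture <- function(kind = c("ees1", "subcritical", "kappa-pair"),
                         dir = ".", seed = 1L) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- list(b1 = 0.15, sigma1 = 0.5, mu0 = 0.01, x0 = 0.01,
               xstar = 1.5, gamma0 = 1)
  scen <- switch(kind,
    ees1 = list(list(name = "ees1",
      model = c(list(type = "gbm"), base,
                list(phi = base$xstar / base$x0)))),
    subcritical = list(list(name = "subcritical",
      model = c(list(type = "gbm"), base, list(phi = 0.9)))),
    "kappa-pair" = {
      two <- function(kappa, name) list(name = name,
        model = list(type = "two_resource", b1 = 0.15, b2 = 0.05,
                     sigma1 = 0.6, sigma2 = 0.02, kappa = kappa,
                     mu0 = 0.01, x0 = 0.01, xstar = 1.5, phi = 10,
                     gamma0 = 1))
      k0 <- 1 / (1 + (0.05 - 0.01) / (0.15 - 0.01))
      list(two(round(k0 - 0.05, 4), "kappa_below"),
           two(round(k0 + 0.05, 4), "kappa_above"))
    })
  paths <- vapply(scen, function(s) {
    cfg <- s[setdiff(names(s), "name")]
    cfg$solver <- list(seed = as.integer(seed))
    p <- file.path(dir, paste0(s$name, ".yaml"))
    yaml::write_yaml(cfg, p)
    p
  }, character(1L))
  invisible(paths)
}

# Property assertion helper: failures signal a dedicated condition class
# so the command-line wrapper can map them to its own exit code.
assert_property <- function(ok, what) {
  if (!isTRUE(ok))
    stop(structure(class = c("rk_property_error", "error", "condition"),
                   list(message = paste("property check failed:", what),
                        call = sys.call(-1))))
  invisible(TRUE)
}

#' Reproduce the study figures' data
#'
#' Computes, with the package's solvers, the curve tables behind the five
#' standard illustrations of the framework on the semelparous GBM and
#' two-resource models (parameters \code{b1 = 0.15}, \code{b2 = 0.05},
#' \code{sigma1} in 0.4-0.6 / 0.6, \code{sigma2 = 0.02}, \code{x = 0.01},
#' \code{xstar = 1.5}, \code{phi = 10}, \code{mu0 = 0.01}):
#' \describe{
#'   \item{fig1}{mature-age densities under r- and K-selection for three
#'     noise levels — the density mode moves to earlier ages as noise
#'     grows;}
#'   \item{fig2}{the K-strategy utilisation ratio across the competition
#'     split — resource-1 specialists, generalists, resource-2
#'     specialists in turn;}
#'   \item{fig3}{growth rates of the r- and K-strategies — the r-strategy
#'     is never below;}
#'   \item{fig4}{potential basic reproductive numbers at zero density —
#'     the K-strategy's can dip below the r-strategy's;}
#'   \item{fig5}{carrying capacities — the K-strategy dominates every
#'     constant strategy.}
#' }
#' Each run asserts its qualitative property and errors (condition class
#' \code{"rk_property_error"}) if it fails.
#'
#' @param tag One of \code{"fig1"} ... \code{"fig5"}.
#' @param kappa_grid Competition-split grid for the two-resource sweeps.
#' @param plot Draw a base-graphics rendering of the table.
#' @return A data.frame of the curve data (invisibly when plotted).
#' @export
run_figure <- function(tag = c("fig1", "fig2", "fig3", "fig4", "fig5"),
                       kappa_grid = seq(0.05, 0.95, by = 0.05),
                       plot = FALSE) {
  tag <- match.arg(tag)
  out <- switch(tag,
                fig1 = figure_mature_age(),
                fig2 = figure_policy_sweep(kappa_grid),
                fig3 = figure_irni_sweep(kappa_grid),
                fig4 = figure_r0_sweep(kappa_grid),
                fig5 = figure_capacity_sweep(kappa_grid))
  if (plot) {
    plot_figure(tag, out)
    return(invisible(out))
  }
  out
}

fig_gbm <- function(sigma1)
  gbm_model(b1 = 0.15, sigma1 = sigma1, mu0 = 0.01, x0 = 0.01,
            xstar = 1.5, phi = 10)

fig_two <- function(kappa)
  two_resource_model(b1 = 0.15, b2 = 0.05, sigma1 = 0.6, sigma2 = 0.02,
                     kappa = kappa, mu0 = 0.01, x0 = 0.01, xstar = 1.5,
                     phi = 10)

figure_mature_age <- function() {
  rows <- list()
  modes <- numeric(0)
  for (s1 in c(0.4, 0.5, 0.6)) {
    m <- fig_gbm(s1)
    Gs <- carrying_capacity_closed_form(m)$Gamma
    for (sel in c("r", "K")) {
      G <- if (sel == "r") 0 else max(Gs, 0)
      d <- breeding_age_density(m, Gamma = G)
      rows[[length(rows) + 1L]] <-
        data.frame(sigma1 = s1, selection = sel, age = d$age,
                   density = d$density)
      if (sel == "r") modes <- c(modes, d$age[which.max(d$density)])
    }
  }
  assert_property(all(diff(modes) < 0),
                  "mature-age density mode decreases with noise")
  do.call(rbind, rows)
}

figure_policy_sweep <- function(kappa_grid) {
  out <- ess_sweep(fig_two(0.5), kappa_grid)
  reg <- findInterval(out$v_K, c(1e-9, 1 - 1e-9)) # 0: R1, 1: gen, 2: R2
  assert_property(all(diff(reg) >= 0) && all(0:2 %in% reg),
                  "R1-specialist, generalist, R2-specialist in turn")
  out
}

figure_irni_sweep <- function(kappa_grid) {
  out <- data.frame(kappa = kappa_grid)
  out$lambda_r <- vapply(kappa_grid, function(k)
    solve_adaptive_root(fig_two(k))$lambda, numeric(1L))
  out$lambda_K <- vapply(kappa_grid, function(k) {
    vK <- kstrategy_equilibrium(fig_two(k))$v
    irni_closed_form(fig_two(k), vK)
  }, numeric(1L))
  assert_property(all(out$lambda_r >= out$lambda_K - 1e-12),
                  "the r-strategy growth rate is never exceeded")
  out
}

figure_r0_sweep <- function(kappa_grid) {
  out <- data.frame(kappa = kappa_grid)
  out$R0_r <- vapply(kappa_grid, function(k) {
    m <- fig_two(k)
    psi_closed_form(m, 0, 0, two_resource_policy(m, 0))
  }, numeric(1L))
  out$R0_K <- vapply(kappa_grid, function(k) {
    m <- fig_two(k)
    psi_closed_form(m, 0, 0, kstrategy_equilibrium(m)$v)
  }, numeric(1L))
  assert_property(any(out$R0_K < out$R0_r - 1e-9),
                  "the K-strategy's potential R0 dips below the r-strategy's")
  out
}

figure_capacity_sweep <- function(kappa_grid) {
  v_grid <- seq(0, 1, by = 0.1)
  out <- data.frame(kappa = kappa_grid)
  out$N_K <- vapply(kappa_grid, function(k)
    kstrategy_equilibrium(fig_two(k))$N, numeric(1L))
  out$N_r <- vapply(kappa_grid, function(k) {
    m <- fig_two(k)
    cc <- carrying_capacity_closed_form(m, two_resource_policy(m, 0))
    max(cc$N, 0)
  }, numeric(1L))
  N_best_const <- vapply(kappa_grid, function(k) {
    m <- fig_two(k)
    max(vapply(v_grid, function(v)
      carrying_capacity_closed_form(m, v)$N, numeric(1L)), 0)
  }, numeric(1L))
  assert_property(all(out$N_K >= out$N_r - 1e-9) &&
                    all(out$N_K >= N_best_const - 1e-9),
                  "the K-strategy maximises the carrying capacity")
  out
}

plot_figure <- function(tag, d) {
  switch(tag,
    fig1 = {
      sub <- d[d$selection == "r", ]
      graphics::matplot(NA, NA, xlim = range(log10(sub$age)),
                        ylim = range(log10(pmax(sub$density, 1e-12))),
                        xlab = "log10 age", ylab = "log10 density",
                        type = "n", main = "Mature-age density")
      for (s1 in unique(sub$sigma1)) {
        ss <- sub[sub$sigma1 == s1, ]
        graphics::lines(log10(ss$age), log10(pmax(ss$density, 1e-12)))
      }
    },
    fig2 = graphics::plot(d$kappa, d$v_K, type = "l", xlab = "kappa",
                          ylab = "utilisation ratio",
                          main = "K-strategy policy"),
    fig3 = {
      graphics::plot(d$kappa, d$lambda_r, type = "l", xlab = "kappa",
                     ylab = "growth rate", main = "r vs K growth rate")
      graphics::lines(d$kappa, d$lambda_K, lty = 2)
    },
    fig4 = {
      graphics::plot(d$kappa, d$R0_r, type = "l", xlab = "kappa",
                     ylab = "potential R0", main = "Potential R0")
      graphics::lines(d$kappa, d$R0_K, lty = 2)
    },
    fig5 = {
      graphics::plot(d$kappa, d$N_K, type = "l", xlab = "kappa",
                     ylab = "carrying capacity", main = "Carrying capacity")
      graphics::lines(d$kappa, d$N_r, lty = 2)
    })
  invisible(NULL)
}
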