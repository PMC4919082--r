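# Independent oracles: the characteristic exponent as a brute-force root of
# its defining quadratic, and the growth rate / equilibrium density effect
# derived from it by direct substitution, kept free of the package's own
# closed-form code paths.
oracle_rho <- function(b, s2, mu0, lambda, Gamma = 0) {
  f <- function(r) s2 / 2 * r^2 + (b - Gamma - s2 / 2) * r - (mu0 + lambda)
  uniroot(f, c(0, 100), tol = 1e-14)$root
}
oracle_lambda_at_rho <- function(b, s2, mu0, rho)
  s2 / 2 * rho^2 + (b - s2 / 2) * rho - mu0
oracle_Gamma_at_rho <- function(b, s2, mu0, rho) {
  f <- function(G) oracle_rho(b, s2, mu0, 0, G) - rho
  uniroot(f, c(-1, b), tol = 1e-14)$root
}

test_that("efficiency exponent of semelparity matches its definition", {
  m <- ref_gbm()
  expect_equal(ees(m), log(10) / log(150), tolerance = 1e-12)
  expect_gt(ees(m), 0)
  # numerator equal to denominator: exponent exactly one
  expect_equal(ees(gbm_model(0.1, 0.3, 0.01, 0.01, 1.5, 150)), 1)
  # phi a perfect square of the size ratio: exponent exactly two
  expect_equal(ees(gbm_model(0.1, 0.3, 0.01, 0.01, 1.5, 150^2)), 2)
  expect_error(ees(0.2, xstar = 0.1, phi = 5), "mature size")
  expect_error(ees(0.01, xstar = 1.5, phi = -1), "positive")
})

test_that("characteristic exponent solves its quadratic on a parameter grid", {
  grid <- expand.grid(b1 = c(0.1, 0.15), sigma1 = c(0.2, 0.5, 0.8),
                      lambda = c(-0.005, 0, 0.03, 0.2),
                      Gamma = c(0, 0.05))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    m <- gbm_model(g$b1, g$sigma1, 0.01, 0.01, 1.5, 10)
    r <- rho_lambda(m, g$lambda, g$Gamma)
    expect_lt(abs(attr(r, "residual")), 1e-12)
    expect_equal(as.numeric(r),
                 oracle_rho(g$b1, g$sigma1^2, 0.01, g$lambda, g$Gamma),
                 tolerance = 1e-10)
  }
})

test_that("zero-noise exponent uses the deterministic branch", {
  m0 <- gbm_model(0.15, 0, 0.01, 0.01, 1.5, 10)
  expect_equal(as.numeric(rho_lambda(m0, 0)), 0.01 / 0.15,
               tolerance = 1e-14)
  # net growth nonpositive at zero noise: no maturation
  expect_error(rho_lambda(m0, 0, Gamma = 0.2), "non-maturing")
})

test_that("growth rate closed form agrees with the quadratic oracle", {
  m <- ref_gbm(sigma1 = 0.5)
  lam_oracle <- oracle_lambda_at_rho(0.15, 0.25, 0.01, log(10) / log(150))
  expect_equal(irni_closed_form(m), lam_oracle, tolerance = 1e-12)
  expect_equal(lam_oracle, 0.0279, tolerance = 2e-3)
  # Euler-Lotka consistency: rho at lambda* recovers the EES
  expect_equal(as.numeric(rho_lambda(m, irni_closed_form(m))), ees(m),
               tolerance = 1e-10)
  # EES = 1 removes the noise dependence entirely
  for (s1 in c(0, 0.3, 0.7)) {
    m1 <- gbm_model(0.15, s1, 0.01, 0.01, 1.5, 150)
    expect_equal(irni_closed_form(m1), 0.15 - 0.01, tolerance = 1e-14)
  }
  # deterministic limit
  m0 <- gbm_model(0.15, 0, 0.01, 0.01, 1.5, 10)
  expect_equal(irni_closed_form(m0), 0.15 * ees(m0) - 0.01,
               tolerance = 1e-14)
})

test_that("carrying capacity matches a bisection oracle and equilibrium identity", {
  for (s1 in c(0.4, 0.5, 0.6)) {
    m <- ref_gbm(sigma1 = s1)
    cc <- carrying_capacity_closed_form(m)
    expect_equal(cc$Gamma,
                 oracle_Gamma_at_rho(0.15, s1^2, 0.01, ees(m)),
                 tolerance = 1e-10)
    # R0 = 1 at the equilibrium density effect
    expect_equal(as.numeric(rho_lambda(m, 0, cc$Gamma)), ees(m),
                 tolerance = 1e-10)
    expect_equal(cc$N, cc$Gamma / m$gamma0)
  }
  expect_equal(carrying_capacity_closed_form(ref_gbm(sigma1 = 0.5))$Gamma,
               0.0607, tolerance = 1e-3)
  # EES = 1: capacity independent of noise
  caps <- vapply(c(0.1, 0.5, 0.9), function(s1)
    carrying_capacity_closed_form(gbm_model(0.15, s1, 0.01, 0.01, 1.5,
                                            150))$Gamma, numeric(1L))
  expect_equal(caps, rep(0.15 - 0.01, 3L), tolerance = 1e-14)
  # subcritical fecundity above one: negative formal density effect,
  # flagged non-persistent
  sub <- gbm_model(0.15, 0.5, 0.01, 0.01, 1.5, 2)
  cc <- carrying_capacity_closed_form(sub)
  expect_false(cc$persistent)
  expect_identical(cc$N, 0)
  expect_lte(cc$Gamma, 0)
  # fecundity at most one: no equilibrium closure at all
  cc0 <- carrying_capacity_closed_form(gbm_model(0.15, 0.5, 0.01, 0.01,
                                                 1.5, 0.9))
  expect_false(cc0$persistent)
  expect_true(is.na(cc0$Gamma))
})

test_that("noise sensitivity of capacity is exactly -(1 - rho*)/(2 gamma0)", {
  h <- 1e-4
  for (phi in c(10, 150, 150^1.5)) {
    m <- function(s2) gbm_model(0.15, sqrt(s2), 0.01, 0.01, 1.5, phi,
                                gamma0 = 2)
    rho <- ees(m(0.25))
    fd <- (carrying_capacity_closed_form(m(0.25 + h))$Gamma / 2 -
             carrying_capacity_closed_form(m(0.25 - h))$Gamma / 2) / (2 * h)
    expect_equal(fd, -(1 - rho) / (2 * 2), tolerance = 1e-6)
  }
})

test_that("noise sensitivity of the growth rate changes sign at EES one", {
  h <- 1e-5
  dlam <- function(phi) {
    (irni_closed_form(gbm_model(0.15, sqrt(0.25 + h), 0.01, 0.01, 1.5,
                                phi)) -
       irni_closed_form(gbm_model(0.15, sqrt(0.25 - h), 0.01, 0.01, 1.5,
                                  phi))) / (2 * h)
  }
  expect_lt(dlam(10), 0)                 # EES < 1: noise harms
  expect_equal(dlam(150), 0, tolerance = 1e-10)  # EES = 1: neutral
  expect_gt(dlam(150^1.5), 0)            # EES > 1: noise helps
})

test_that("adaptive mature size maximises the efficiency exponent", {
  # decreasing fecundity: compare against a dense grid-search oracle
  phi_fun <- function(s) 20 - 10 * s
  grid <- seq(0.02, 1.9, by = 1e-4)
  oracle <- grid[which.max(log(phi_fun(grid)) / log(grid / 0.01))]
  r <- optimal_mature_size(0.01, phi_fun, c(0.02, 1.9))
  expect_equal(r$xstar, oracle, tolerance = 1e-4)
  expect_true(all(r$rho >= log(phi_fun(grid)) / log(grid / 0.01) - 1e-9))
  # constant fecundity: supremum at the lower boundary
  rb <- optimal_mature_size(0.01, function(s) 10, c(0.5, 1.9))
  expect_true(rb$boundary)
  expect_equal(rb$xstar, 0.5)
  # power-law fecundity: flat objective flagged degenerate
  rd <- optimal_mature_size(0.01, function(s) (s / 0.01)^0.7, c(0.02, 1.9))
  expect_true(rd$degenerate)
  expect_equal(rd$rho, 0.7, tolerance = 1e-9)
})

test_that("model constructors enforce their invariants", {
  expect_error(gbm_model(0.15, 0.5, 0.01, x0 = 1.5, xstar = 0.01, phi = 10),
               "xstar > x0")
  expect_error(gbm_model(0.15, 0.5, 0.01, 0.01, 1.5, phi = -2), "positive")
  expect_error(gbm_model(0.15, 0.5, mu0 = 0, x0 = 0.01, xstar = 1.5,
                         phi = 10))
  expect_error(two_resource_model(0.05, 0.15, 0.6, 0.02, 0.5, 0.01,
                                  0.01, 1.5, 10))
  expect_error(two_resource_model(0.15, 0.05, 0.6, 0.02, kappa = 1.2,
                                  mu0 = 0.01, x0 = 0.01, xstar = 1.5,
                                  phi = 10), "kappa")
  expect_error(density_effect(-0.1), "nonnegative")
  expect_error(density_effect(Inf), "finite")
  p <- control_policy(data.frame(age = c(0, 10), v = c(0.2, 5)))
  expect_equal(eval_policy(p, a = c(1, 12)), c(0.2, 1))  # clamped into V
})
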