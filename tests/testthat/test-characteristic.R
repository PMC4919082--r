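test_that("boundary-value solve reproduces the closed form to 1e-6", {
  for (s1 in c(0.4, 0.5, 0.6)) {
    for (lam in c(0, 0.0279, 0.1)) {
      m <- ref_gbm(sigma1 = s1)
      expect_equal(as.numeric(psi_ode(m, lam)),
                   psi_closed_form(m, lam),
                   tolerance = 1e-6)
    }
  }
  # with a density effect
  m <- ref_gbm(sigma1 = 0.5)
  expect_equal(as.numeric(psi_ode(m, 0, Gamma = 0.0607)),
               psi_closed_form(m, 0, Gamma = 0.0607), tolerance = 1e-6)
})

test_that("Euler-Lotka and already-mature limits of the boundary solve", {
  m <- ref_gbm(sigma1 = 0.5)
  expect_equal(as.numeric(psi_ode(m, irni_closed_form(m))), 1,
               tolerance = 1e-6)
  # birth size at the mature size: psi is the fecundity itself
  mat <- gbm_model(0.15, 0.5, 0.01, x0 = 1.49999, xstar = 1.5, phi = 10)
  expect_equal(psi_closed_form(mat, 5, x = 1.5), 10)
  # R0 equals the closed form with the zero-discount exponent
  rho0 <- as.numeric(rho_lambda(m, 0))
  expect_equal(as.numeric(psi_ode(m, 0)), (0.01 / 1.5)^rho0 * 10,
               tolerance = 1e-6)
})

test_that("the solve refuses a grid too coarse to meet its tolerance", {
  m <- ref_gbm(sigma1 = 0.5)
  expect_error(psi_ode(m, 0, n_grid = 20L), "too coarse")
})

test_that("Monte Carlo and boundary-value routes agree within 3 SE", {
  set.seed(77)
  for (s1 in c(0.4, 0.6)) {
    for (lam in c(0, 0.05)) {
      m <- ref_gbm(sigma1 = s1)
      mc <- psi_mc(m, lam, n_paths = 3e4L, dt = 0.05)
      ode <- as.numeric(psi_ode(m, lam))
      expect_lt(abs(mc$estimate - ode), 3 * mc$se + 1e-3)
    }
  }
})

test_that("zero-noise characteristic function is the deterministic discount", {
  m0 <- gbm_model(0.15, 0, 0.01, 0.01, 1.5, 10)
  astar <- log(150) / 0.15
  for (lam in c(0, 0.03)) {
    exact <- 10 * exp(-(lam + 0.01) * astar)
    expect_equal(as.numeric(psi_ode(m0, lam)), exact, tolerance = 1e-12)
    mc <- psi_mc(m0, lam, n_paths = 10L, dt = 0.05, seed = 1)
    expect_equal(mc$estimate, exact, tolerance = 1e-8)
  }
})

test_that("psi is strictly decreasing and continuous in the discount rate", {
  m <- ref_gbm(sigma1 = 0.5)
  lams <- seq(-0.009, 0.3, length.out = 60L)
  psis <- vapply(lams, function(l) psi_closed_form(m, l), numeric(1L))
  expect_true(all(diff(psis) < 0))
  # continuity: refining the grid shrinks the largest jump proportionally
  lams2 <- seq(-0.009, 0.3, length.out = 120L)
  psis2 <- vapply(lams2, function(l) psi_closed_form(m, l), numeric(1L))
  expect_lt(max(abs(diff(psis2))), 0.75 * max(abs(diff(psis))))
})

test_that("breeding-age density normalises and shifts with noise", {
  modes <- vapply(c(0.4, 0.5, 0.6), function(s1) {
    d <- breeding_age_density(ref_gbm(sigma1 = s1))
    mass <- sum(diff(d$age) * (d$density[-1L] + d$density[-nrow(d)]) / 2)
    expect_equal(mass, 1, tolerance = 1e-6)
    d$age[which.max(d$density)]
  }, numeric(1L))
  # stochasticity promotes precocity: the mode falls as noise rises
  expect_true(all(diff(modes) < 0))
  expect_lt(modes[3L], modes[1L])
})

test_that("zero-noise breeding age is a point mass with zero variance", {
  d0 <- breeding_age_density(gbm_model(0.15, 0, 0.01, 0.01, 1.5, 10))
  expect_equal(attr(d0, "point_mass"), log(150) / 0.15, tolerance = 1e-12)
  k <- breeding_age_cumulants(d0, K = 2L)
  expect_equal(k[2L], 0)
})

test_that("cumulants match the log-psi derivatives (generating duality)", {
  h <- 1e-5
  for (s1 in c(0.4, 0.5)) {
    m <- ref_gbm(sigma1 = s1)
    d <- breeding_age_density(m)
    k <- breeding_age_cumulants(d, K = 2L)
    lnpsi <- function(l) log(psi_closed_form(m, l))
    fd1 <- -(lnpsi(h) - lnpsi(-h)) / (2 * h)
    fd2 <- (lnpsi(h) - 2 * lnpsi(0) + lnpsi(-h)) / h^2
    expect_equal(k[1L], fd1, tolerance = 1e-3)
    expect_equal(k[2L], fd2, tolerance = 1e-3)
  }
  expect_error(breeding_age_cumulants(breeding_age_density(ref_gbm()),
                                      K = 5L), "order 4")
})

test_that("small-mortality mean breeding age approaches the IG mean", {
  # mortality tilts the density toward early ages, so the mean increases
  # toward the inverse-Gaussian mean as mu0 shrinks
  means <- vapply(c(0.01, 1e-3, 1e-5), function(mu0) {
    m <- gbm_model(0.15, 0.4, mu0, 0.01, 1.5, 10)
    breeding_age_cumulants(breeding_age_density(m), K = 1L)
  }, numeric(1L))
  expect_true(all(diff(means) > 0))
  expect_equal(means[3L], log(150) / 0.07, tolerance = 1e-2)
})

test_that("characteristic_fn wraps the three routes consistently", {
  m <- ref_gbm(sigma1 = 0.5)
  cf <- characteristic_fn(m, lambda = 0.02, method = "closed_form",
                          include_density = TRUE)
  expect_s3_class(cf, "characteristic_result")
  expect_equal(cf$psi, psi_closed_form(m, 0.02))
  expect_length(cf$cumulants, 2L)
  ode <- characteristic_fn(m, lambda = 0.02, method = "ode")
  expect_equal(ode$psi, cf$psi, tolerance = 1e-6)
})
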