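test_that("closed-form utilisation ratio: hedge, clamps and density terms", {
  tr <- ref_two(kappa = 0.5)
  # direct evaluation at the reference parameters
  raw <- 0.36 / 0.3604 - 0.1 / (0.3604 * (1 - log(10) / log(150)))
  expect_equal(two_resource_policy(tr), raw, tolerance = 1e-12)
  expect_equal(two_resource_policy(tr), 0.486, tolerance = 2e-3)
  # kappa = 0.5 removes the density effect entirely
  expect_equal(two_resource_policy(tr, Gamma = 0.3),
               two_resource_policy(tr, Gamma = 0))
  # a large drift gap clamps to the pure fast-resource strategy
  wide <- two_resource_model(1.5, 0.05, 0.6, 0.02, 0.5, 0.01, 0.01, 1.5,
                             10)
  expect_equal(two_resource_policy(wide), 0)
  # equal drifts leave the pure variance hedge (via the density term at
  # kappa = 0.5 the drift gap is all that remains)
  nearly <- two_resource_model(0.15, 0.15 - 1e-12, 0.6, 0.02, 0.5, 0.01,
                               0.01, 1.5, 10)
  expect_equal(two_resource_policy(nearly), 0.36 / 0.3604,
               tolerance = 1e-9)
  # outside its domain the interior formula refuses
  high <- ref_two(phi = 150^1.2)
  expect_error(two_resource_policy(high), "below 1")
})

test_that("numerical HJB policy matches the closed form over (kappa, Gamma)", {
  # the closed-form control holds where the value surface has exponent
  # rho*, i.e. at the dominant root of each (kappa, Gamma) problem
  for (kappa in c(0.2, 0.5, 0.8)) {
    for (G in c(0, 0.03)) {
      tr <- ref_two(kappa = kappa)
      lam <- solve_adaptive_root(tr, Gamma = G)$lambda
      sol <- solve_stationary_hjb(tr, lambda = lam, Gamma = G)
      expect_true(sol$converged)
      expect_true(all(sol$policy >= 0 & sol$policy <= 1))
      expect_equal(sol$psi_x, 1, tolerance = 1e-5)
      vref <- two_resource_policy(tr, Gamma = G)
      expect_lt(max(abs(sol$policy - vref)), 2e-3)
    }
  }
})

test_that("HJB solution satisfies its defining root and value properties", {
  tr <- ref_two(kappa = 0.5)
  ar <- solve_adaptive_root(tr, method = "hjb")
  # the characteristic equation holds at the dominant root
  sol <- solve_stationary_hjb(tr, lambda = ar$lambda, Gamma = 0)
  expect_equal(sol$psi_x, 1, tolerance = 1e-6)
  expect_true(all(sol$psi >= 0))
  # and matches the closed-form dominant root
  cf <- solve_adaptive_root(tr, method = "closed_form")
  expect_equal(ar$lambda, cf$lambda, tolerance = 1e-5)
  # a single-point control set reduces the solve to the plain boundary
  # value problem
  m <- ref_gbm(sigma1 = 0.5)
  # (the plain solve is second order; the dedicated route extrapolates)
  red <- solve_stationary_hjb(m, lambda = 0.01, Gamma = 0, n_grid = 8001L)
  expect_equal(red$psi_x, as.numeric(psi_ode(m, 0.01)), tolerance = 1e-6)
})

test_that("no constant policy beats the adaptive root (invasion ordering)", {
  tr <- ref_two(kappa = 0.5)
  ar <- solve_adaptive_root(tr)
  vs <- seq(0, 1, by = 0.1)
  psis <- vapply(vs, function(v) psi_closed_form(tr, ar$lambda, 0, v),
                 numeric(1L))
  expect_true(all(psis <= 1 + 1e-10))
  # the optimum itself attains one
  expect_equal(psi_closed_form(tr, ar$lambda, 0, ar$v), 1,
               tolerance = 1e-10)
  # equivalently in growth rates
  lams <- vapply(vs, function(v) irni_closed_form(tr, v), numeric(1L))
  expect_true(all(lams <= ar$lambda + 1e-12))
})

test_that("bang-bang limit: no generalist without slow-resource noise", {
  # sigma2 = 0 and EES near 1: the interior hedge disappears
  tr <- two_resource_model(0.15, 0.05, 0.6, 0, 0.5, 0.01, 0.01, 1.5,
                           phi = 150^0.995)
  v <- two_resource_policy(tr)
  expect_true(v %in% c(0, 1))
  lam <- solve_adaptive_root(tr)$lambda
  sol <- solve_stationary_hjb(tr, lambda = lam, Gamma = 0)
  expect_lt(mean(sol$policy > 1e-3 & sol$policy < 1 - 1e-3), 0.01)
})

test_that("K-strategy fixed point is an ESS and maximises the capacity", {
  tr <- ref_two(kappa = 0.5)
  ks <- kstrategy_equilibrium(tr)
  expect_true(ks$converged)
  # resident cannot be invaded: R0 at the K equilibrium is at most one,
  # with equality at the K-strategy itself
  vs <- seq(0, 1, length.out = 101L)
  r0 <- vapply(vs, function(v) psi_closed_form(tr, 0, ks$Gamma, v),
               numeric(1L))
  expect_lte(max(r0), 1 + 1e-6)
  expect_equal(psi_closed_form(tr, 0, ks$Gamma, ks$v), 1,
               tolerance = 1e-9)
  expect_equal(vs[which.max(r0)], ks$v, tolerance = 0.011)
  # capacity dominance over every constant strategy, across kappa
  for (kappa in seq(0.1, 0.9, by = 0.2)) {
    m <- ref_two(kappa = kappa)
    G_K <- kstrategy_equilibrium(m)$Gamma
    G_const <- vapply(seq(0, 1, by = 0.1), function(v)
      carrying_capacity_closed_form(m, v)$Gamma, numeric(1L))
    expect_true(all(G_K >= G_const - 1e-9))
  }
})

test_that("critical competition split governs the EES-to-one limit", {
  tr <- ref_two()
  k0 <- kappa_threshold(tr)
  expect_equal(k0, 1 / (1 + 0.04 / 0.14), tolerance = 1e-12)
  # brute-force oracle: the split equalising the pure-strategy
  # equilibrium density effects in the noise-free limit
  oracle <- uniroot(function(k) (0.15 - 0.01) / k - (0.05 - 0.01) / (1 - k),
                    c(0.01, 0.99), tol = 1e-12)$root
  expect_equal(k0, oracle, tolerance = 1e-9)
  # above the threshold the K-strategy collapses to the slow-resource
  # specialist as the EES approaches one; below, to the fast one
  above <- ref_two(kappa = 0.9, phi = 150^0.999)
  expect_equal(kstrategy_equilibrium(above)$v, 1, tolerance = 1e-3)
  below <- ref_two(kappa = 0.6, phi = 150^0.999)
  expect_equal(kstrategy_equilibrium(below)$v, 0, tolerance = 1e-3)
})

test_that("r- versus K-strategy orderings across the competition split", {
  kappas <- seq(0.1, 0.9, by = 0.1)
  lam_r <- lam_K <- r0_r <- r0_K <- numeric(length(kappas))
  for (i in seq_along(kappas)) {
    m <- ref_two(kappa = kappas[i])
    vr <- two_resource_policy(m, Gamma = 0)
    vK <- kstrategy_equilibrium(m)$v
    lam_r[i] <- irni_closed_form(m, vr)
    lam_K[i] <- irni_closed_form(m, vK)
    r0_r[i] <- psi_closed_form(m, 0, 0, vr)
    r0_K[i] <- psi_closed_form(m, 0, 0, vK)
  }
  # the r-strategy growth rate is never exceeded, strictly where the
  # policies differ
  expect_true(all(lam_r >= lam_K - 1e-12))
  expect_true(any(lam_r > lam_K + 1e-6))
  # and there are splits where the K-strategy's potential R0 is lower
  expect_true(any(r0_K < r0_r - 1e-6))
})
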