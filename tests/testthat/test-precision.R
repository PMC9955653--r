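# Precision engine: the random variance factor, expected width, assurance
# probability, and their Monte Carlo oracles.

test_that("random variance factor matches its moment and t-square identities", {
  des <- canonical_design(P = 1, theta = 0)
  rv <- random_v(des, 30)
  expect_equal(rv$a, 1.5 / 10, tolerance = 1e-12)
  expect_equal(rv$b, 1 / (rv$nu + 1), tolerance = 1e-12)
  expect_equal(rv$xi, 0)
  # mean of V: a (1 + b m/(m - 2)) with m = nu + 1 central-F denominator df
  m <- rv$nu + 1
  set.seed(11)
  vbar <- mean(rv$sample(1e6))
  expect_lt(abs(vbar - rv$a * (1 + rv$b * m / (m - 2))), 4e-4)
  # P = 1, xi = 0: F(1, m) is the square of t(m) at matching quantiles
  for (p in c(0.5, 0.9, 0.99)) {
    expect_equal(rv$quantile(p),
                 rv$a * (1 + rv$b * qt((1 + p) / 2, m)^2), tolerance = 1e-9)
  }
  # xi is linear in theta at fixed a
  des2 <- canonical_design(P = 1, theta = 0.8)
  des1 <- canonical_design(P = 1, theta = 0.4)
  expect_equal(random_v(des2, 30)$xi, 2 * random_v(des1, 30)$xi,
               tolerance = 1e-12)
})

test_that("exact expected width matches table value and its MC oracle", {
  des <- canonical_design(P = 1, theta = 0)
  ew <- expected_width(des, 75)
  expect_equal(ew$value, 0.9845, tolerance = 5e-4)
  mc <- mc_precision(des, 75, omega = 1, reps = 1e5, seed = 21)
  expect_lt(abs(ew$value - mc$omega_hat), 3 * mc$omega_se)
  g <- assurance_prob(des, 75, 1.00)
  expect_lt(abs(g$value - mc$gamma_hat), 3 * mc$gamma_se)
})

test_that("quadrature equals Monte Carlo on randomized designs", {
  specs <- list(
    list(contrast = c(1, -1), P = 1, theta = 0, NT = 30),
    list(contrast = c(1, -1), P = 3, theta = 0.4, NT = 40),
    list(contrast = c(1, -0.5, -0.5), P = 1, theta = 0.4, NT = 45),
    list(contrast = c(1, -0.5, -0.5), P = 3, theta = 0, NT = 36),
    list(contrast = c(3, -1, -1, -1), P = 1, theta = 0, NT = 48),
    list(contrast = c(1, 1, -1, -1), P = 3, theta = 0.4, NT = 60))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    des <- design_spec(s$contrast, P = s$P, psi_star = 0.5, theta = s$theta)
    ew <- expected_width(des, s$NT)$value
    omega <- ew    # bound at the expected width keeps Gamma off 0 and 1
    mc <- mc_precision(des, s$NT, omega, reps = 1e5, seed = 300 + i)
    expect_lt(abs(ew - mc$omega_hat), 3 * mc$omega_se)
    gq <- assurance_prob(des, s$NT, omega)$value
    expect_lt(abs(gq - mc$gamma_hat), 3 * mc$gamma_se)
  }
})

test_that("precision depends on the covariate model only through theta", {
  mu_X <- list(c(0.3, -0.2), c(-0.1, 0.1), c(-0.1, 0.1))
  Sigma_X <- matrix(c(1.3, 0.4, 0.4, 0.9), 2)
  cvec <- c(1, -0.5, -0.5)
  th <- covariate_disparity(cvec, mu_X, Sigma_X)
  expect_gt(th, 0)
  d_explicit <- design_spec(cvec, P = 2, psi_star = 0.5,
                            mu_X = mu_X, Sigma_X = Sigma_X)
  d_scalar <- design_spec(cvec, P = 2, psi_star = 0.5, theta = th)
  expect_equal(expected_width(d_explicit, 45)$value,
               expected_width(d_scalar, 45)$value, tolerance = 1e-10)
  expect_equal(assurance_prob(d_explicit, 45, 1.3)$value,
               assurance_prob(d_scalar, 45, 1.3)$value, tolerance = 1e-10)
  # identical covariate means across groups mean zero disparity
  expect_equal(covariate_disparity(cvec, rep(list(c(1, 2)), 3), Sigma_X), 0,
               tolerance = 1e-12)
})

test_that("expected width decreases in NT; assurance increases in omega and NT", {
  des <- canonical_design(P = 1, theta = 0)
  ews <- vapply(c(30, 45, 60, 75), function(n) expected_width(des, n)$value,
                numeric(1))
  expect_true(all(diff(ews) < 0))
  # bounds below the smallest attainable width (2 z sqrt(a)) give Gamma = 0,
  # so the grids start just above it to keep the comparison informative
  gam_w <- vapply(c(1.00, 1.03, 1.06, 1.10),
                  function(w) assurance_prob(des, 75, w)$value, numeric(1))
  expect_true(all(diff(gam_w) > -1e-6))
  expect_gt(gam_w[4] - gam_w[1], 0.1)
  gam_n <- vapply(c(45, 60, 75),
                  function(n) assurance_prob(des, n, 1.25)$value, numeric(1))
  expect_true(all(diff(gam_n) > -1e-6))
  expect_gt(gam_n[3] - gam_n[1], 0.5)
  # probability limits in the bound
  expect_gt(assurance_prob(des, 60, 25)$value, 1 - 1e-5)
  expect_equal(assurance_prob(des, 60, 1e-3)$value, 0)
})

test_that("approximate method drops the covariate layer", {
  des <- canonical_design(P = 1, theta = 0)
  oa <- expected_width(des, 48, method = "approximate")
  expect_equal(oa$value, 1.2257, tolerance = 5e-4)
  # the exact method integrates V >= a, so it is wider even at theta = 0
  expect_lt(expected_width(des, 75, "approximate")$value,
            expected_width(des, 75, "exact")$value)
  # approximate values are insensitive to theta by construction
  des5 <- canonical_design(P = 1, theta = 0.5)
  expect_equal(expected_width(des5, 48, "approximate")$value, oa$value,
               tolerance = 1e-10)
  # single-draw MC oracle for the approximate law
  k <- stancova:::design_constants(des, 48)
  set.seed(41)
  tt <- suppressWarnings(rt(1e5, k$nu, ncp = des$psi_star / sqrt(k$a)))
  wf <- stancova:::make_width_fun(k$nu, 0.025, 0.025, max(abs(tt)) * 1.01, 801)
  W <- sqrt(k$a) * wf(tt)
  expect_lt(abs(oa$value - mean(W)), 3 * sd(W) / sqrt(1e5))
  ga <- assurance_prob(des, 48, 1.25, method = "approximate")$value
  p <- mean(W <= 1.25)
  expect_lt(abs(ga - p), 3 * sqrt(p * (1 - p) / 1e5))
})

test_that("precision preconditions are enforced", {
  des <- canonical_design()
  expect_error(expected_width(des, 76), "lattice")
  expect_error(expected_width(des, 3), "degrees of freedom")
  expect_error(assurance_prob(des, 60, -1))
})
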