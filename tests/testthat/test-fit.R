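# ANCOVA fitting, contrast estimation, and the unbiasing factor.

test_that("fit agrees with the full-design-matrix least-squares oracle", {
  df <- make_raw_data(G = 3, P = 2, n = 6)
  fit <- fit_ancova(df)
  ora <- lm_oracle(df)
  expect_equal(fit$mu, ora$mu, tolerance = 1e-8)
  expect_equal(fit$beta, ora$beta, tolerance = 1e-8)
  expect_equal(fit$SSE, ora$SSE, tolerance = 1e-8)
  expect_equal(fit$nu, nrow(df) - 3 - 2)
  expect_equal(fit$sigma_sq, ora$SSE / fit$nu, tolerance = 1e-10)
  # adjusted means are intercepts shifted by the grand-mean covariate term
  expect_equal(fit$mu_star - fit$mu,
               rep(sum(fit$Xbar_grand * fit$beta), 3), tolerance = 1e-10)
})

test_that("exact zero-slope data give zero slopes and group means", {
  df <- make_raw_data(G = 2, P = 1, n = 5, beta = 0, sigma = 0,
                      mu = c(2, -1))
  fit <- fit_ancova(df)
  expect_equal(fit$beta, 0, tolerance = 1e-10)
  expect_equal(fit$SSE, 0, tolerance = 1e-10)
  expect_equal(fit$mu_star, c(2, -1), tolerance = 1e-10)
})

test_that("location and scale equivariance hold", {
  df <- make_raw_data()
  fit <- fit_ancova(df)
  df2 <- df; df2$y <- df2$y + 7.3
  fit2 <- fit_ancova(df2)
  expect_equal(fit2$mu, fit$mu + 7.3, tolerance = 1e-9)
  expect_equal(fit2$mu_star, fit$mu_star + 7.3, tolerance = 1e-9)
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-9)
  expect_equal(fit2$SSE, fit$SSE, tolerance = 1e-9)

  cvec <- c(1, -0.5, -0.5)
  df3 <- df; df3$y <- df3$y * 4.2
  e1 <- contrast_estimate(fit, cvec)
  e3 <- contrast_estimate(fit_ancova(df3), cvec)
  expect_equal(e3$psi_hat, 4.2 * e1$psi_hat, tolerance = 1e-10)
  expect_equal(e3$psi_star, e1$psi_star, tolerance = 1e-10)
  expect_equal(e3$tO, e1$tO, tolerance = 1e-10)
})

test_that("permuting subjects within groups changes nothing", {
  df <- make_raw_data()
  set.seed(9)
  idx <- unlist(lapply(split(seq_len(nrow(df)), df$group), sample))
  fit1 <- fit_ancova(df)
  fit2 <- fit_ancova(df[idx, ])
  for (f in c("mu", "mu_star", "beta", "SSE", "sigma_sq")) {
    expect_equal(fit2[[f]], fit1[[f]], tolerance = 1e-10)
  }
})

test_that("contrast quantities match their definitions", {
  df <- make_raw_data()
  fit <- fit_ancova(df)
  cvec <- c(1, -0.5, -0.5)
  est <- contrast_estimate(fit, cvec)
  # Q by explicit inversion on this small instance
  cx <- as.numeric(fit$Xbar %*% cvec)
  Q_brute <- as.numeric(t(cx) %*% solve(fit$V_XX) %*% cx)
  expect_equal(est$Q, Q_brute, tolerance = 1e-10)
  expect_gte(est$Q, 0)
  expect_equal(est$a, sum(cvec^2 / fit$Ni), tolerance = 1e-12)
  expect_equal(est$V, est$a + est$Q / (fit$NT - fit$G), tolerance = 1e-12)
  expect_gte(est$V, est$a)
  expect_equal(est$psi_hat, sum(cvec * fit$mu_star), tolerance = 1e-10)
  expect_equal(est$tO * sqrt(est$V), est$psi_star, tolerance = 1e-10)
})

test_that("identical group covariate means give zero disparity", {
  df <- make_raw_data(G = 3, P = 1, n = 4, sigma = 0.5)
  # force identical group covariate means by recentring within groups
  for (g in 1:3) {
    r <- df$group == g
    df$x1[r] <- df$x1[r] - mean(df$x1[r])
  }
  est <- contrast_estimate(fit_ancova(df), c(1, -0.5, -0.5))
  expect_equal(est$Q, 0, tolerance = 1e-12)
  expect_equal(est$V, est$a, tolerance = 1e-12)
})

test_that("learning-disabilities summary reproduces the variance factor", {
  est <- fleiss_learning_example()
  expect_equal(est$a, 1/19 + 0.25/20 + 0.25/20, tolerance = 1e-12)
  expect_equal(round(est$V, 4), 0.0814)
  expect_equal(round(est$psi_hat, 4), 2.4823)
  expect_equal(round(est$psi_star, 4), 1.3721)
})

test_that("unbiasing factor matches direct gamma evaluation and limits", {
  # nu = 10: Gamma(5) / (sqrt(5) * Gamma(4.5))
  expect_equal(unbias_factor(10), gamma(5) / (sqrt(5) * gamma(4.5)),
               tolerance = 1e-12)
  expect_equal(unbias_factor(10), 0.9227456, tolerance = 1e-7)
  expect_equal(unbias_factor(1e6), 1, tolerance = 1e-5)
  nus <- 2:200
  u <- vapply(nus, unbias_factor, numeric(1))
  expect_true(all(u > 0 & u < 1))
  expect_true(all(diff(u) > 0))
  # small-sample approximation 1 - 3/(4 nu - 1): close from nu = 5 on
  # (at nu = 2..4 the true factor deviates by up to 0.007)
  approx <- 1 - 3 / (4 * nus - 1)
  expect_lt(max(abs(u - approx)[nus >= 5]), 0.002)
  expect_lt(max(abs(u - approx)), 0.008)
})

test_that("unbiased estimator reduces bias at nu = 11", {
  nu <- 11; psi_star <- 1.5; V <- 0.3
  set.seed(101)
  R <- 20000
  psih <- rnorm(R, psi_star, sqrt(V))          # sigma = 1 scale
  s2h <- rchisq(R, nu) / nu
  psh <- psih / sqrt(s2h)
  u <- unbias_factor(nu)
  expect_lt(abs(mean(u * psh) - psi_star), abs(mean(psh) - psi_star))
})

test_that("degenerate inputs fail loudly", {
  df <- make_raw_data(G = 3, P = 1, n = 2)   # NT = 6, nu = 2: fine
  expect_s3_class(fit_ancova(df), "ancova_fit")
  # collinear covariates
  bad <- make_raw_data(G = 3, P = 2, n = 6)
  bad$x2 <- 2 * bad$x1
  expect_error(fit_ancova(bad), "collinear")
  # too few residual degrees of freedom
  tiny <- make_raw_data(G = 3, P = 2, n = 1)
  expect_error(fit_ancova(tiny), "degrees of freedom")
  # contrast validation
  fit <- fit_ancova(df)
  expect_error(contrast_estimate(fit, c(1, -0.5)), "per group")
  expect_error(contrast_estimate(fit, c(1, 1, 1)), "sum to zero")
  expect_error(contrast_estimate(fit, c(0, 0, 0)), "nonzero")
  expect_error(unbias_factor(1), "undefined")
})

test_that("the data reader enforces types and reports rows", {
  df <- make_raw_data()
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  back <- read_ancova_data(path)
  expect_equal(back$y, df$y, tolerance = 1e-12)
  expect_equal(fit_ancova(back)$mu, fit_ancova(df)$mu, tolerance = 1e-9)

  df_na <- df; df_na$y[4] <- NA
  path2 <- tempfile(fileext = ".csv")
  write.csv(df_na, path2, row.names = FALSE)
  expect_error(read_ancova_data(path2), "row\\(s\\): 4")
  expect_error(read_ancova_data(tempfile()), "not found")
})
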