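# Shared fixtures: the canonical three-group planning design and the
# learning-disabilities summary statistics.

canonical_design <- function(P = 1, theta = 0, alpha = 0.05) {
  design_spec(c(1, -0.5, -0.5), ratios = c(1, 1, 1), P = P,
              psi_star = 0.5, sigma_sq = 1, theta = theta, alpha = alpha)
}

# Full-precision summary inputs of the worked example
FLEISS <- list(psi_hat = 2.4823, sigma_sq = 3.2728, nu = 55, V = 0.081437)
FLEISS$psi_star <- FLEISS$psi_hat / sqrt(FLEISS$sigma_sq)

# A small raw dataset with known structure, built in code
make_raw_data <- function(G = 3, P = 2, n = 6, seed = 42, beta = c(0.8, -0.3),
                          mu = c(1, 0, -1), sigma = 1) {
  set.seed(seed)
  NT <- G * n
  X <- matrix(rnorm(NT * P), ncol = P)
  group <- rep(seq_len(G), each = n)
  y <- mu[group] + as.numeric(X %*% rep_len(beta, P)) + sigma * rnorm(NT)
  out <- data.frame(group = group, y = y)
  colnames(X) <- paste0("x", seq_len(P))
  cbind(out, as.data.frame(X))
}

# Independent full-design-matrix least-squares oracle via stats::lm
lm_oracle <- function(df) {
  xcols <- setdiff(names(df), c("group", "y"))
  f <- stats::as.formula(paste("y ~ 0 + factor(group) +",
                               paste(xcols, collapse = " + ")))
  m <- stats::lm(f, data = df)
  co <- stats::coef(m)
  G <- length(unique(df$group))
  list(mu = unname(co[seq_len(G)]),
       beta = unname(co[-seq_len(G)]),
       SSE = sum(stats::resid(m)^2))
}

# Monte Carlo estimate of expected width and assurance under the
# unconditional model: direct draws of (F_X, V, T), widths through the
# noncentrality factorization.  Independent of the quadrature path.
mc_precision <- function(design, NT, omega, reps = 1e5, seed = 1) {
  rv <- random_v(design, NT)
  nu <- rv$nu
  set.seed(seed)
  V <- rv$sample(reps)
  tt <- suppressWarnings(stats::rt(reps, nu, ncp = design$psi_star / sqrt(V)))
  wf <- stancova:::make_width_fun(nu, design$alpha / 2, design$alpha / 2,
                                  max(abs(tt)) * 1.01, 801L)
  W <- sqrt(V) * wf(tt)
  list(omega_hat = mean(W), omega_se = stats::sd(W) / sqrt(reps),
       gamma_hat = mean(W <= omega),
       gamma_se = sqrt(mean(W <= omega) * (1 - mean(W <= omega)) / reps))
}
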