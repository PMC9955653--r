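# Monte Carlo engines: conditional coverage simulation of the three
# interval procedures, full-model precision simulation, and the synthetic
# dataset generator used throughout the tests.

#' Simulation configuration
#'
#' @param reps number of Monte Carlo replicates.
#' @param error_law `"normal"` or `"t10"` (t with 10 degrees of freedom,
#'   rescaled to the target error variance).
#' @param covariate_law one of `"normal"`, `"exponential"`, `"gamma"`,
#'   `"laplace"`, `"lognormal"`, `"uniform"`.  Non-normal laws are drawn
#'   with their conventional parameters -- Exponential(1), Gamma(5,
#'   5^(-1/2)), Laplace(0, 1), Lognormal(0, 1/4), Uniform(0, 1) -- and then
#'   affinely standardized to the target means and unit variance, so the
#'   covariate disparity `theta` is preserved across laws.
#' @param beta common covariate slope (nuisance in the precision analysis);
#'   a vector of length `P` is also accepted by the generator.
#' @param gamma_param whether the second Gamma argument is a `"scale"` or a
#'   `"rate"`; immaterial after standardization, exposed for completeness.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(reps = 10000L,
                       error_law = c("normal", "t10"),
                       covariate_law = c("normal", "exponential", "gamma",
                                         "laplace", "lognormal", "uniform"),
                       beta = 0.5,
                       gamma_param = c("scale", "rate")) {
  structure(list(reps = as.integer(reps),
                 error_law = match.arg(error_law),
                 covariate_law = match.arg(covariate_law),
                 beta = beta,
                 gamma_param = match.arg(gamma_param)),
            class = "sim_config")
}

# Standardized (mean 0, variance 1) draws from the configured covariate law.
std_draws <- function(n, law, gamma_param = "scale") {
  switch(law,
    normal = stats::rnorm(n),
    exponential = stats::rexp(n, rate = 1) - 1,
    gamma = {
      x <- if (gamma_param == "scale") {
        stats::rgamma(n, shape = 5, scale = 5^(-1/2))
      } else {
        stats::rgamma(n, shape = 5, rate = 5^(-1/2))
      }
      (x - mean_gamma(gamma_param)) / sd_gamma(gamma_param)
    },
    laplace = {
      s <- sample(c(-1, 1), n, replace = TRUE)
      s * stats::rexp(n, rate = 1) / sqrt(2)
    },
    lognormal = {
      x <- stats::rlnorm(n, meanlog = 0, sdlog = 0.5)
      m <- exp(0.125)
      (x - m) / sqrt((exp(0.25) - 1) * exp(0.25))
    },
    uniform = (stats::runif(n) - 0.5) * sqrt(12),
    stop("unknown covariate law: ", law))
}

mean_gamma <- function(p) if (p == "scale") 5 * 5^(-1/2) else 5 / 5^(-1/2)
sd_gamma <- function(p) if (p == "scale") sqrt(5) * 5^(-1/2) else sqrt(5) / 5^(-1/2)

std_errors <- function(n, law) {
  switch(law,
    normal = stats::rnorm(n),
    t10 = stats::rt(n, df = 10) / sqrt(10 / 8),
    stop("unknown error law: ", law))
}

# Covariate mean vectors implied by a design: explicit means if supplied,
# otherwise the disparity is placed on the first covariate of the first
# group: mu_X1 = (sqrt(theta), 0, ..., 0), the rest zero.
design_mu_X <- function(design) {
  if (!is.null(design$mu_X)) return(design$mu_X)
  mu <- rep(list(numeric(design$P)), design$G)
  mu[[1]][1] <- sqrt(design$theta)
  mu
}

design_intercepts <- function(design) {
  i <- which(design$contrast != 0)[1]
  mu <- numeric(design$G)
  mu[i] <- design$psi_star * sqrt(design$sigma_sq) / design$contrast[i]
  mu
}

# Draw the covariate block (NT x P) and the error vector for `reps`
# replicates, using separate streams for covariates and errors so the two
# sources of randomness are independently reproducible.
draw_model_arrays <- function(design, NT, reps, seed, config) {
  k <- design_constants(design, NT)
  P <- design$P
  mu_X <- design_mu_X(design)
  mu_rows <- do.call(rbind, mu_X)[rep(seq_len(design$G), k$Ni), , drop = FALSE]
  L <- if (!is.null(design$Sigma_X)) chol(design$Sigma_X) else NULL
  if (!is.null(seed)) set.seed(seed)
  Z <- matrix(std_draws(NT * P * reps, config$covariate_law,
                        config$gamma_param), ncol = P)
  if (!is.null(L)) Z <- Z %*% L
  if (!is.null(seed)) set.seed(seed + 1L)
  E <- matrix(std_errors(NT * reps, config$error_law) *
                sqrt(design$sigma_sq), ncol = reps)
  list(Z = Z, E = E, mu_rows = mu_rows, k = k)
}

#' Generate a synthetic ANCOVA dataset
#'
#' One draw from the model used throughout the precision analysis:
#' covariates from the design's covariate model (multinormal by default,
#' standardized non-normal laws on request), responses from the
#' fixed-effects ANCOVA model with common slopes `beta` and error variance
#' `sigma_sq`, intercepts placed so the contrast of adjusted means equals
#' `psi_star * sigma`.
#'
#' @param design a [design_spec()].
#' @param NT total sample size on the ratio lattice.
#' @param seed optional integer seed; identical seeds give identical data.
#' @param config a [sim_config()] (only the laws and `beta` are used).
#' @param intercepts optional explicit group intercepts overriding the
#'   default placement.
#' @return a `data.frame` with columns `group`, `y`, `x1`, ..., `xP`.
#' @export
generate_dataset <- function(design, NT, seed = NULL, config = sim_config(),
                             intercepts = NULL) {
  arr <- draw_model_arrays(design, NT, 1L, seed, config)
  P <- design$P
  beta <- rep_len(config$beta, P)
  mu <- if (is.null(intercepts)) design_intercepts(design) else intercepts
  stopifnot(length(mu) == design$G)
  group <- rep(seq_len(design$G), arr$k$Ni)
  X <- arr$Z + arr$mu_rows
  y <- mu[group] + as.numeric(X %*% beta) + arr$E[, 1]
  out <- data.frame(group = group, y = y)
  colnames(X) <- paste0("x", seq_len(P))
  cbind(out, as.data.frame(X))
}

#' Conditional coverage simulation of the three interval procedures
#'
#' Reproduces the conditional Monte Carlo design in which the covariate
#' statistic is held fixed: each replicate draws the contrast estimate
#' `psi_hat ~ N(psi, sigma_sq * V)` and, independently, the variance
#' estimate `sigma_sq_hat = sigma_sq * chi2(nu) / nu`, with
#' `V = sum c_i^2 / N_i + Q / (NT - G)` built from a supplied covariate
#' disparity statistic `Q`.  For each replicate the exact, asymptotic and
#' direct intervals are formed; one-sided coverage at level `1 - alpha/2`
#' and equal-tail two-sided coverage at `1 - alpha` are reported with
#' their deviations from nominal and binomial standard errors.
#'
#' Exact-interval coverage is assessed through the pivotal identity: the
#' two-sided interval contains `psi_star` exactly when the noncentral-t CDF
#' at the observed statistic, evaluated at noncentrality
#' `psi_star / sqrt(V)`, falls in `(alpha/2, 1 - alpha/2)` -- the same
#' event as forming the interval and checking inclusion, without the root
#' solves.
#'
#' @param NT total sample size.
#' @param psi_star true standardized contrast.
#' @param alpha two-sided level complement (0.10 gives 90% two-sided and
#'   95% one-sided intervals).
#' @param contrast,ratios contrast coefficients and group-size ratios.
#' @param P number of covariates (enters only through `nu`).
#' @param Q fixed covariate disparity statistic.
#' @param sigma_sq error variance.
#' @param reps replicates.
#' @param seed optional seed for exact reproducibility.
#' @return a `data.frame` of class `coverage_sim`: one row per method and
#'   side with columns `coverage`, `nominal`, `deviation`, `se`.
#' @examples
#' simulate_coverage(NT = 15, psi_star = 3, reps = 2000, seed = 1)
#' @export
simulate_coverage <- function(NT, psi_star, alpha = 0.10,
                              contrast = c(-1, 0.5, 0.5),
                              ratios = c(1, 1, 1), P = 1,
                              Q = 0.2131, sigma_sq = 3.2728,
                              reps = 10000L, seed = NULL) {
  G <- length(contrast)
  validate_contrast(contrast, G)
  n <- NT / sum(ratios)
  stopifnot(abs(n - round(n)) < 1e-9)
  Ni <- ratios * n
  nu <- NT - G - P
  stopifnot(nu >= 1, Q >= 0, sigma_sq > 0, reps >= 1)
  V <- sum(contrast^2 / Ni) + Q / (NT - G)
  a1 <- alpha / 2

  if (!is.null(seed)) set.seed(seed)
  psi <- psi_star * sqrt(sigma_sq)
  psih <- stats::rnorm(reps, psi, sqrt(sigma_sq * V))
  s2h <- sigma_sq * stats::rchisq(reps, nu) / nu
  psh <- psih / sqrt(s2h)
  tO <- psh / sqrt(V)

  # exact: pivotal check (see Details)
  u <- suppressWarnings(stats::pt(tO, nu, ncp = psi_star / sqrt(V)))
  ex_up <- u <= 1 - a1   # lower bound interval (L, Inf) covers
  ex_lo <- u >= a1       # upper bound interval (-Inf, U) covers
  # asymptotic
  tau <- sqrt(V + psh^2 / (2 * nu))
  z <- stats::qnorm(1 - a1)
  as_up <- psh - z * tau <= psi_star
  as_lo <- psi_star <= psh + z * tau
  # direct division
  tq <- stats::qt(1 - a1, nu)
  di_up <- psh - tq * sqrt(V) <= psi_star
  di_lo <- psi_star <= psh + tq * sqrt(V)

  row <- function(method, side, ind, nominal) {
    p <- mean(ind)
    data.frame(method = method, side = side, coverage = p,
               nominal = nominal, deviation = p - nominal,
               se = sqrt(p * (1 - p) / reps))
  }
  out <- rbind(
    row("exact", "upper", ex_up, 1 - a1),
    row("exact", "lower", ex_lo, 1 - a1),
    row("exact", "two.sided", ex_up & ex_lo, 1 - alpha),
    row("asymptotic", "upper", as_up, 1 - a1),
    row("asymptotic", "lower", as_lo, 1 - a1),
    row("asymptotic", "two.sided", as_up & as_lo, 1 - alpha),
    row("direct", "upper", di_up, 1 - a1),
    row("direct", "lower", di_lo, 1 - a1),
    row("direct", "two.sided", di_up & di_lo, 1 - alpha))
  attr(out, "settings") <- list(NT = NT, psi_star = psi_star, alpha = alpha,
                                V = V, nu = nu, Q = Q, sigma_sq = sigma_sq,
                                reps = reps)
  class(out) <- c("coverage_sim", "data.frame")
  out
}

#' Full-model precision simulation
#'
#' Each replicate generates `NT` covariate vectors from the design's
#' covariate model and responses from the fixed-effects ANCOVA model,
#' fits the model by least squares, and computes the width of the exact
#' confidence interval of the standardized contrast.  Returns the mean
#' width and the fraction of replicates with width at most `omega`,
#' with Monte Carlo standard errors.  Replicates with a singular covariate
#' cross-product are re-drawn (and counted); more than 0.1% of them is an
#' error.
#'
#' @param design a [design_spec()].
#' @param NT total sample size on the ratio lattice.
#' @param omega width bound for the assurance fraction.
#' @param reps replicates.
#' @param seed optional seed (covariates and errors use separate streams
#'   derived from it).
#' @param config a [sim_config()].
#' @param intercepts optional explicit group intercepts.
#' @return a list of class `precision_sim` with `mean_width`, `width_se`,
#'   `assurance`, `assurance_se`, `reps`, `redrawn`.
#' @examples
#' \donttest{
#' des <- design_spec(c(1, -0.5, -0.5), P = 1, psi_star = 0.5, theta = 0)
#' simulate_precision(des, NT = 75, omega = 1, reps = 500, seed = 1)
#' }
#' @export
simulate_precision <- function(design, NT, omega, reps = 10000L, seed = NULL,
                               config = sim_config(), intercepts = NULL) {
  stopifnot(omega > 0, reps >= 1)
  P <- design$P
  G <- design$G
  nu <- NT - G - P
  beta <- rep_len(config$beta, P)
  mu <- if (is.null(intercepts)) design_intercepts(design) else intercepts
  arr <- draw_model_arrays(design, NT, reps, seed, config)
  group <- rep(seq_len(G), arr$k$Ni)

  tO <- numeric(reps)
  V <- numeric(reps)
  redrawn <- 0L
  for (r in seq_len(reps)) {
    X <- arr$Z[((r - 1) * NT + 1):(r * NT), , drop = FALSE] + arr$mu_rows
    y <- mu[group] + as.numeric(X %*% beta) + arr$E[, r]
    est <- tryCatch({
      fit <- fit_core(group, y, X, G)
      contrast_estimate(fit, design$contrast)
    }, error = function(e) NULL)
    while (is.null(est)) {
      redrawn <- redrawn + 1L
      if (redrawn > max(1, reps * 0.001)) {
        stop("more than 0.1% of replicates produced singular fits")
      }
      X <- matrix(std_draws(NT * P, config$covariate_law, config$gamma_param),
                  ncol = P)
      if (!is.null(design$Sigma_X)) X <- X %*% chol(design$Sigma_X)
      X <- X + arr$mu_rows
      y <- mu[group] + as.numeric(X %*% beta) +
        std_errors(NT, config$error_law) * sqrt(design$sigma_sq)
      est <- tryCatch({
        fit <- fit_core(group, y, X, G)
        contrast_estimate(fit, design$contrast)
      }, error = function(e) NULL)
    }
    tO[r] <- est$tO
    V[r] <- est$V
  }

  a1 <- design$alpha / 2
  wf <- make_width_fun(nu, a1, a1, max(abs(tO)) * 1.01,
                       max(161L, min(801L, reps)))
  W <- sqrt(V) * wf(tO)
  g <- mean(W <= omega)
  structure(list(mean_width = mean(W), width_se = stats::sd(W) / sqrt(reps),
                 assurance = g, assurance_se = sqrt(g * (1 - g) / reps),
                 reps = reps, redrawn = redrawn, NT = NT, omega = omega),
            class = "precision_sim")
}

#' @export
print.precision_sim <- function(x, digits = 4, ...) {
  cat(sprintf("Precision simulation (%d replicates, NT = %d):\n",
              x$reps, x$NT))
  cat(sprintf("  mean width %.*f (SE %.*f);  P(width <= %g) = %.*f (SE %.*f)\n",
              digits, x$mean_width, digits, x$width_se, x$omega,
              digits, x$assurance, digits, x$assurance_se))
  if (x$redrawn > 0) cat("  re-drawn singular replicates:", x$redrawn, "\n")
  invisible(x)
}
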