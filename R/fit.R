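# Least-squares fitting of the fixed-effects ANCOVA model and the
# standardized contrast estimate with its variance factor.

#' Fit the fixed-effects ANCOVA model
#'
#' Fits `Y_ij = mu_i + sum_k X_kij beta_k + e_ij` by least squares: the
#' slope vector solves the pooled within-group normal equations
#' `S_XX beta = S_XY`, where `S_XX` and `S_XY` are the within-group centered
#' cross-product matrices.  Adjusted group means are the intercepts
#' evaluated at the grand covariate means.
#'
#' The linear system is solved directly (never by explicit inversion);
#' `S_XX` with a condition number above `1e12` is rejected as collinear.
#'
#' @param data a `data.frame` with columns `group`, `y` and one or more
#'   numeric covariate columns, as returned by [read_ancova_data()] or
#'   [generate_dataset()].
#' @return an object of class `ancova_fit`: a list with intercepts `mu`,
#'   adjusted means `mu_star`, slopes `beta`, group covariate means
#'   `Xbar` (P x G), grand covariate means `Xbar_grand`, cross-product
#'   matrices `S_XX`, `S_XY`, `V_XX = S_XX / (NT - G)`, `SSE`, the error
#'   variance estimate `sigma_sq = SSE / nu`, residual degrees of freedom
#'   `nu = NT - G - P`, group sizes `Ni`, and the group labels.
#' @examples
#' d <- generate_dataset(design_spec(c(1, -0.5, -0.5)), NT = 30, seed = 1)
#' fit <- fit_ancova(d)
#' fit$mu_star
#' @export
fit_ancova <- function(data) {
  v <- validate_ancova_data(data)
  fit_core(v$group, v$y, v$X, v$G, v$labels)
}

# Lean fitting path shared with the simulation suite: `group` is an
# integer index 1..G, `X` a numeric NT x P matrix.
fit_core <- function(group, y, X, G, labels = as.character(seq_len(G))) {
  P <- ncol(X)
  NT <- length(y)
  nu <- NT - G - P
  if (nu < 1) {
    stop("insufficient residual degrees of freedom: NT - G - P = ", nu)
  }
  Ni <- tabulate(group, nbins = G)
  if (any(Ni < 1)) stop("every group must contain at least one subject")

  ybar <- vapply(seq_len(G), function(i) mean(y[group == i]), numeric(1))
  Xbar <- vapply(seq_len(G),
                 function(i) colMeans(X[group == i, , drop = FALSE]),
                 numeric(P))
  Xbar <- matrix(Xbar, nrow = P)  # P x G
  Xbar_grand <- as.numeric(Xbar %*% (Ni / NT))

  Xc <- X - t(Xbar)[group, , drop = FALSE]
  yc <- y - ybar[group]
  S_XX <- crossprod(Xc)
  S_XY <- as.numeric(crossprod(Xc, yc))

  if (!all(is.finite(S_XX)) || kappa(S_XX, exact = FALSE) > 1e12) {
    stop("collinear covariates: pooled cross-product matrix is singular ",
         "or ill-conditioned")
  }
  beta <- as.numeric(solve(S_XX, S_XY))
  SSE <- sum(yc^2) - sum(S_XY * beta)
  SSE <- max(SSE, 0)

  mu <- ybar - as.numeric(crossprod(Xbar, beta))
  mu_star <- mu + sum(Xbar_grand * beta)

  structure(list(
    mu = mu, mu_star = mu_star, beta = beta,
    Xbar = Xbar, Xbar_grand = Xbar_grand,
    S_XX = S_XX, S_XY = S_XY, V_XX = S_XX / (NT - G),
    SSE = SSE, sigma_sq = SSE / nu, nu = nu,
    Ni = Ni, G = G, P = P, NT = NT, labels = labels
  ), class = "ancova_fit")
}

#' @export
print.ancova_fit <- function(x, digits = 4, ...) {
  cat("ANCOVA fit:", x$G, "groups,", x$P, "covariate(s),",
      x$NT, "subjects\n")
  tab <- rbind(intercept = x$mu, `adjusted mean` = x$mu_star, n = x$Ni)
  colnames(tab) <- x$labels
  print(round(tab, digits))
  cat("slopes:", paste(round(x$beta, digits), collapse = ", "), "\n")
  cat("sigma^2 =", round(x$sigma_sq, digits), " (nu =", x$nu, ")\n")
  invisible(x)
}

#' Small-sample unbiasing factor for the standardized contrast
#'
#' The plug-in standardized contrast overestimates its target because
#' `E[1/sigma_hat] > 1/sigma`.  Multiplying by
#' `u = Gamma(nu/2) / ((nu/2)^(1/2) Gamma((nu-1)/2))` removes the bias.
#' Computed through `lgamma` so large `nu` does not overflow; `u` lies in
#' (0, 1) and tends to 1 as `nu` grows.
#'
#' @param nu residual degrees of freedom, must exceed 1.
#' @return the factor `u`.
#' @export
unbias_factor <- function(nu) {
  if (!is.numeric(nu) || length(nu) != 1 || nu <= 1) {
    stop("unbiased correction undefined: nu must exceed 1")
  }
  exp(lgamma(nu / 2) - 0.5 * log(nu / 2) - lgamma((nu - 1) / 2))
}

#' Standardized contrast estimate and variance factor
#'
#' Evaluates a linear contrast of the fitted intercepts (equivalently, of
#' the adjusted means) and all derived quantities used by the interval
#' estimators: the covariate-disparity statistic
#' `Q = (sum_i c_i Xbar_i)' V_XX^{-1} (sum_i c_i Xbar_i)`, the variance
#' factor `V = a + Q/(NT - G)` with `a = sum c_i^2 / N_i`, the standardized
#' estimate `psi_star = psi_hat / sigma_hat`, its unbiased version, and the
#' observed statistic `tO = psi_star / sqrt(V)`.
#'
#' @param fit an [fit_ancova()] result.
#' @param contrast numeric coefficients, one per group in first-appearance
#'   order of the group labels; must sum to zero (tolerance 1e-12 relative
#'   to their magnitude) with at least one nonzero entry.
#' @return an object of class `contrast_estimate` with fields `psi_hat`,
#'   `psi_star`, `psi_star_ub`, `u`, `a`, `Q`, `V`, `tau_sq`, `tO`,
#'   `sigma_sq`, `nu`, `Ni`, `contrast`.
#' @export
contrast_estimate <- function(fit, contrast) {
  stopifnot(inherits(fit, "ancova_fit"))
  validate_contrast(contrast, fit$G)
  cvec <- as.numeric(contrast)

  psi_hat <- sum(cvec * fit$mu)
  a <- sum(cvec^2 / fit$Ni)
  cx <- as.numeric(fit$Xbar %*% cvec)
  Q <- as.numeric(crossprod(cx, solve(fit$V_XX, cx)))
  V <- a + Q / (fit$NT - fit$G)
  tau_sq <- fit$sigma_sq * V
  psi_star <- psi_hat / sqrt(fit$sigma_sq)
  u <- if (fit$nu > 1) unbias_factor(fit$nu) else NA_real_
  structure(list(
    psi_hat = psi_hat, psi_star = psi_star,
    psi_star_ub = u * psi_star, u = u,
    a = a, Q = Q, V = V, tau_sq = tau_sq,
    tO = psi_star / sqrt(V),
    sigma_sq = fit$sigma_sq, nu = fit$nu,
    Ni = fit$Ni, contrast = cvec
  ), class = "contrast_estimate")
}

#' @export
print.contrast_estimate <- function(x, digits = 4, ...) {
  cat("Contrast", paste0("{", paste(x$contrast, collapse = ", "), "}:\n"))
  cat(sprintf("  psi_hat = %.*f   psi_star = %.*f (unbiased %.*f)\n",
              digits, x$psi_hat, digits, x$psi_star, digits, x$psi_star_ub))
  cat(sprintf("  a = %.*f   Q = %.*f   V = %.*f   nu = %d\n",
              digits, x$a, digits, x$Q, digits, x$V, as.integer(x$nu)))
  invisible(x)
}

validate_contrast <- function(contrast, G) {
  if (!is.numeric(contrast) || length(contrast) != G) {
    stop("'contrast' must be numeric with one coefficient per group (", G, ")")
  }
  scale <- max(abs(contrast))
  if (scale == 0) stop("'contrast' must have at least one nonzero coefficient")
  if (abs(sum(contrast)) > 1e-12 * max(1, scale)) {
    stop("'contrast' coefficients must sum to zero")
  }
  invisible(contrast)
}
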