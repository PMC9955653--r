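# Design specifications for planning: contrast, group-size ratios,
# covariate model reduced to the disparity index theta.

#' Population covariate disparity index
#'
#' `theta = (sum_i c_i mu_Xi)' Sigma_X^{-1} (sum_i c_i mu_Xi)`: a quadratic
#' form measuring the imbalance of the contrast of covariate mean vectors,
#' scaled by the common covariate covariance.  Under a randomized design
#' with identical covariate distributions across groups, `theta = 0`.
#'
#' @param contrast numeric contrast coefficients (must sum to zero).
#' @param mu_X list of `P`-dimensional covariate mean vectors, one per group.
#' @param Sigma_X common positive-definite `P x P` covariate covariance.
#' @return the scalar disparity `theta >= 0`.
#' @export
covariate_disparity <- function(contrast, mu_X, Sigma_X) {
  G <- length(contrast)
  validate_contrast(contrast, G)
  stopifnot(is.list(mu_X), length(mu_X) == G)
  P <- length(mu_X[[1]])
  stopifnot(all(vapply(mu_X, length, 1L) == P),
            is.matrix(Sigma_X), nrow(Sigma_X) == P, ncol(Sigma_X) == P)
  ev <- eigen(Sigma_X, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("'Sigma_X' must be positive definite")
  cm <- Reduce(`+`, Map(`*`, mu_X, as.list(contrast)))
  as.numeric(crossprod(cm, solve(Sigma_X, cm)))
}

#' Design specification for precision and sample-size analysis
#'
#' Bundles the quantities a planned ANCOVA needs before any data exist:
#' the contrast, group-size ratios, number of covariates, the anticipated
#' standardized effect and error variance, the covariate model (either the
#' disparity scalar `theta` directly, or explicit group covariate means
#' with a common covariance, from which `theta` is computed), and the
#' confidence level.
#'
#' Ratios must be positive integers: group sizes are `N_i = r_i * n` for
#' integer `n`, and rounding a fractional ratio would silently change the
#' variance factor `a`.
#'
#' @param contrast contrast coefficients (sum to zero, one per group).
#' @param ratios positive integer group-size ratios, same length.
#' @param P number of covariates (>= 1).
#' @param psi_star anticipated standardized contrast effect.
#' @param sigma_sq anticipated error variance (only the standardized scale
#'   enters the precision functions; kept for interface completeness).
#' @param theta covariate disparity index (>= 0); mutually exclusive with
#'   `mu_X`/`Sigma_X`.
#' @param mu_X,Sigma_X explicit covariate means (list of `P`-vectors, one
#'   per group) and common covariance; used to derive `theta`.
#' @param alpha two-sided confidence level complement (default 0.05).
#' @return an object of class `design_spec`.
#' @examples
#' design_spec(c(1, -0.5, -0.5), P = 1, psi_star = 0.5, theta = 0)
#' @export
design_spec <- function(contrast, ratios = rep(1L, length(contrast)),
                        P = 1L, psi_star = 0.5, sigma_sq = 1,
                        theta = NULL, mu_X = NULL, Sigma_X = NULL,
                        alpha = 0.05) {
  G <- length(contrast)
  validate_contrast(contrast, G)
  if (length(ratios) != G || any(ratios <= 0)) {
    stop("'ratios' must be positive, one per group")
  }
  if (any(abs(ratios - round(ratios)) > 1e-12)) {
    stop("'ratios' must be integers; rounding would corrupt the variance factor")
  }
  ratios <- as.integer(round(ratios))
  stopifnot(P >= 1, sigma_sq > 0, alpha > 0, alpha < 1)
  if (!is.null(theta) && !is.null(mu_X)) {
    stop("supply either 'theta' or explicit covariate means, not both")
  }
  if (is.null(theta)) {
    theta <- if (is.null(mu_X)) 0 else {
      if (is.null(Sigma_X)) Sigma_X <- diag(P)
      covariate_disparity(contrast, mu_X, Sigma_X)
    }
  }
  if (theta < 0) stop("'theta' must be nonnegative")
  structure(list(contrast = as.numeric(contrast), ratios = ratios,
                 G = G, P = as.integer(P), psi_star = psi_star,
                 sigma_sq = sigma_sq, theta = theta,
                 mu_X = mu_X, Sigma_X = Sigma_X, alpha = alpha),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat("ANCOVA design: G =", x$G, ", P =", x$P,
      ", contrast {", paste(x$contrast, collapse = ", "), "}",
      ", ratios {", paste(x$ratios, collapse = ", "), "}\n")
  cat("  psi* =", x$psi_star, ", sigma^2 =", x$sigma_sq,
      ", theta =", format(x$theta), ", 1 - alpha =", 1 - x$alpha, "\n")
  invisible(x)
}

# Per-size constants of the design: group sizes, a = sum c_i^2/N_i,
# nu, b = P/(nu + 1), and the noncentrality xi = theta/a of the
# covariate F factor.
design_constants <- function(design, NT, min_nu = 1) {
  stopifnot(inherits(design, "design_spec"))
  rsum <- sum(design$ratios)
  n <- NT / rsum
  if (abs(n - round(n)) > 1e-9 || n < 1) {
    stop("NT = ", NT, " is not on the ratio lattice (multiples of ", rsum, ")")
  }
  n <- as.integer(round(n))
  Ni <- design$ratios * n
  nu <- NT - design$G - design$P
  if (nu < min_nu) {
    stop("insufficient residual degrees of freedom at NT = ", NT,
         " (nu = ", nu, ")")
  }
  a <- sum(design$contrast^2 / Ni)
  list(n = n, Ni = Ni, nu = nu, a = a,
       b = design$P / (nu + 1), xi = design$theta / a)
}

#' Distribution of the random variance factor
#'
#' Under stochastic multinormal covariates the variance factor of the
#' contrast is `V = a (1 + b F_X)` with `a = sum c_i^2 / N_i`,
#' `b = P / (nu + 1)` and `F_X` noncentral `F(P, nu + 1, xi)`,
#' `xi = theta / a`.  Returns the constants together with quantile,
#' density and sampling access for the law of `V`.
#'
#' @param design a [design_spec()].
#' @param NT total sample size on the ratio lattice.
#' @return an object of class `random_v`: list with `a`, `b`, `nu`, `xi`,
#'   `Ni`, and functions `quantile(p)`, `density(v)`, `sample(m)`.
#' @export
random_v <- function(design, NT) {
  k <- design_constants(design, NT)
  a <- k$a; b <- k$b; nu <- k$nu; xi <- k$xi; P <- design$P
  structure(list(
    a = a, b = b, nu = nu, xi = xi, Ni = k$Ni,
    quantile = function(p) a * (1 + b * stats::qf(p, P, nu + 1, ncp = xi)),
    density = function(v) {
      f <- (v / a - 1) / b
      out <- numeric(length(v))
      ok <- f > 0
      out[ok] <- stats::df(f[ok], P, nu + 1, ncp = xi) / (a * b)
      out
    },
    sample = function(m) a * (1 + b * stats::rf(m, P, nu + 1, ncp = xi))
  ), class = "random_v")
}
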