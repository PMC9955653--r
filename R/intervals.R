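# Confidence intervals for the standardized (and unstandardized) contrast:
# exact noncentrality inversion, asymptotic normal approximation, and
# direct division of the unstandardized limits.

new_interval <- function(lower, upper, method, nu, V, level,
                         alpha1 = NA_real_, alpha2 = NA_real_,
                         half_width = NA_real_) {
  structure(list(lower = lower, upper = upper, method = method,
                 level = level, alpha1 = alpha1, alpha2 = alpha2,
                 nu = nu, V = V, half_width = half_width),
            class = "stancova_ci")
}

#' @export
print.stancova_ci <- function(x, digits = 4, ...) {
  cat(sprintf("%s %g%% CI: {%.*f, %.*f}\n",
              x$method, 100 * x$level, digits, x$lower, digits, x$upper))
  invisible(x)
}

check_ci_inputs <- function(nu, V, alpha = NULL) {
  stopifnot(is.numeric(nu), length(nu) == 1, nu >= 1,
            is.numeric(V), length(V) == 1, V >= 0)
  if (!is.null(alpha)) stopifnot(alpha > 0, alpha < 1)
}

#' Exact confidence interval for the standardized contrast
#'
#' Inverts the noncentral-t distribution of the observed statistic
#' `tO = psi_star_hat / sqrt(V)`: the lower limit is `lambda_L * sqrt(V)`
#' where `lambda_L` solves `P[t(nu, lambda_L) <= tO] = 1 - alpha1`, and the
#' upper limit is `lambda_U * sqrt(V)` where `lambda_U` solves
#' `P[t(nu, lambda_U) <= tO] = alpha2`.  With `sides = "two.sided"` and
#' equal tails the interval has level `1 - alpha1 - alpha2`; one-sided
#' intervals return `(L, Inf)` or `(-Inf, U)`.
#'
#' Unlike its two competitors this interval is generally not equidistant
#' about the estimate (it is only when `psi_star_hat = 0`, where the
#' noncentral-t CDF at zero reduces to a normal tail and the limits are
#' `-+ z * sqrt(V)`).
#'
#' @param psi_star_hat standardized contrast estimate.
#' @param nu residual degrees of freedom.
#' @param V variance factor of the contrast.
#' @param alpha1,alpha2 one-sided tail levels (defaults `alpha/2` each via
#'   `alpha`); their sum must be below 1.
#' @param alpha overall two-sided level used when `alpha1`/`alpha2` are not
#'   supplied.
#' @param sides `"two.sided"`, `"greater"` (interval `(L, Inf)` at level
#'   `1 - alpha1`) or `"less"` (interval `(-Inf, U)` at level `1 - alpha2`).
#' @return a `stancova_ci` object.
#' @examples
#' exact_ci(2.4823 / sqrt(3.2728), nu = 55, V = 0.081437, alpha = 0.10)
#' @export
exact_ci <- function(psi_star_hat, nu, V, alpha = 0.10,
                     alpha1 = alpha / 2, alpha2 = alpha / 2,
                     sides = c("two.sided", "greater", "less")) {
  sides <- match.arg(sides)
  check_ci_inputs(nu, V)
  stopifnot(alpha1 > 0, alpha2 > 0, alpha1 + alpha2 < 1)
  if (V == 0) stop("exact interval requires a positive variance factor V")
  tO <- psi_star_hat / sqrt(V)
  if (!is.finite(tO)) stop("observed statistic is not finite")
  if (sides == "two.sided") {
    lim <- ncp_limits(tO, nu, alpha1, alpha2) * sqrt(V)
    new_interval(lim[1], lim[2], "exact", nu, V,
                 level = 1 - alpha1 - alpha2, alpha1 = alpha1, alpha2 = alpha2)
  } else if (sides == "greater") {
    L <- solve_ncp(tO, nu, 1 - alpha1) * sqrt(V)
    new_interval(L, Inf, "exact", nu, V, level = 1 - alpha1, alpha1 = alpha1)
  } else {
    U <- solve_ncp(tO, nu, alpha2) * sqrt(V)
    new_interval(-Inf, U, "exact", nu, V, level = 1 - alpha2, alpha2 = alpha2)
  }
}

#' Asymptotic confidence interval for the standardized contrast
#'
#' Large-sample normal approximation: the estimate is treated as
#' `N(psi_star, V + psi_star^2/(2 nu))`, giving the equidistant limits
#' `psi_star_hat -+ z_{alpha/2} * sqrt(V + psi_star_hat^2/(2 nu))`.
#'
#' @inheritParams exact_ci
#' @param alpha overall two-sided level.
#' @export
asymptotic_ci <- function(psi_star_hat, nu, V, alpha = 0.10) {
  check_ci_inputs(nu, V, alpha)
  H <- stats::qnorm(1 - alpha / 2) * sqrt(V + psi_star_hat^2 / (2 * nu))
  new_interval(psi_star_hat - H, psi_star_hat + H, "asymptotic", nu, V,
               level = 1 - alpha, alpha1 = alpha / 2, alpha2 = alpha / 2,
               half_width = H)
}

#' Direct-division confidence interval for the standardized contrast
#'
#' Divides the unstandardized t-interval limits by the error standard
#' deviation estimate: `psi_star_hat -+ t_{nu, alpha/2} * sqrt(V)`.  Simple,
#' but it ignores the sampling variability of the standardizer and
#' undercovers for nonzero effects.
#'
#' @inheritParams asymptotic_ci
#' @export
direct_ci <- function(psi_star_hat, nu, V, alpha = 0.10) {
  check_ci_inputs(nu, V, alpha)
  H <- stats::qt(1 - alpha / 2, nu) * sqrt(V)
  new_interval(psi_star_hat - H, psi_star_hat + H, "direct", nu, V,
               level = 1 - alpha, alpha1 = alpha / 2, alpha2 = alpha / 2,
               half_width = H)
}

#' Confidence interval for the unstandardized contrast
#'
#' The classical pivot `(psi_hat - psi)/tau_hat ~ t(nu)` with
#' `tau_hat^2 = sigma_sq_hat * V` gives
#' `psi_hat -+ t_{nu, alpha/2} * sqrt(sigma_sq_hat * V)`.  Dividing these
#' limits by `sqrt(sigma_sq_hat)` reproduces [direct_ci()] exactly.
#'
#' @param psi_hat contrast estimate in response units.
#' @param sigma_sq_hat error variance estimate (positive).
#' @inheritParams asymptotic_ci
#' @export
unstandardized_ci <- function(psi_hat, sigma_sq_hat, nu, V, alpha = 0.10) {
  check_ci_inputs(nu, V, alpha)
  if (sigma_sq_hat <= 0) stop("'sigma_sq_hat' must be positive")
  H <- stats::qt(1 - alpha / 2, nu) * sqrt(sigma_sq_hat * V)
  new_interval(psi_hat - H, psi_hat + H, "unstandardized", nu, V,
               level = 1 - alpha, alpha1 = alpha / 2, alpha2 = alpha / 2,
               half_width = H)
}

#' All intervals for a fitted contrast
#'
#' Convenience wrapper computing the unstandardized interval and the three
#' standardized intervals from a [contrast_estimate()] (or from summary
#' statistics via [summary_estimate()]).
#'
#' @param est a `contrast_estimate` object.
#' @param alpha overall two-sided level.
#' @return a `data.frame` with columns `method`, `lower`, `upper`, `level`.
#' @export
contrast_cis <- function(est, alpha = 0.10) {
  stopifnot(inherits(est, "contrast_estimate"))
  ivs <- list(
    unstandardized_ci(est$psi_hat, est$sigma_sq, est$nu, est$V, alpha),
    exact_ci(est$psi_star, est$nu, est$V, alpha = alpha),
    asymptotic_ci(est$psi_star, est$nu, est$V, alpha),
    direct_ci(est$psi_star, est$nu, est$V, alpha)
  )
  data.frame(method = vapply(ivs, `[[`, "", "method"),
             lower = vapply(ivs, `[[`, 0, "lower"),
             upper = vapply(ivs, `[[`, 0, "upper"),
             level = vapply(ivs, `[[`, 0, "level"))
}

#' Contrast estimate from summary statistics
#'
#' Builds a `contrast_estimate` from the summary quantities a published
#' analysis reports (contrast estimate, error variance, degrees of freedom
#' and variance factor), so the interval estimators can be applied without
#' raw data.  The standardized estimate is computed as
#' `psi_hat / sqrt(sigma_sq_hat)` at full precision.
#'
#' @param psi_hat contrast estimate in response units.
#' @param sigma_sq_hat error variance estimate.
#' @param nu residual degrees of freedom.
#' @param V variance factor of the contrast.
#' @return a `contrast_estimate` object (fields that require raw data,
#'   such as `Q` and `a`, are `NA`).
#' @export
summary_estimate <- function(psi_hat, sigma_sq_hat, nu, V) {
  stopifnot(sigma_sq_hat > 0, nu >= 1, V > 0)
  psi_star <- psi_hat / sqrt(sigma_sq_hat)
  u <- if (nu > 1) unbias_factor(nu) else NA_real_
  structure(list(
    psi_hat = psi_hat, psi_star = psi_star, psi_star_ub = u * psi_star,
    u = u, a = NA_real_, Q = NA_real_, V = V,
    tau_sq = sigma_sq_hat * V, tO = psi_star / sqrt(V),
    sigma_sq = sigma_sq_hat, nu = nu, Ni = NULL, contrast = NULL
  ), class = "contrast_estimate")
}
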