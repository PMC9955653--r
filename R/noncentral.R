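# Noncentrality machinery shared by the interval estimators and the
# precision engine: root solving on the noncentral-t CDF, and quadrature
# rules on the probability scale.

# Solve P[t(nu, lambda) <= tO] = target for the noncentrality lambda.
# The CDF is continuous and strictly decreasing in lambda, so the root is
# unique.  Brackets start around the observed statistic (where lambda-hat
# concentrates) and expand geometrically.  For targets in the far upper
# tail the complement is solved on the survival scale, which keeps the
# small tail probability in full relative precision.
solve_ncp <- function(tO, nu, target) {
  stopifnot(is.finite(tO), nu >= 1, target > 0, target < 1)
  f <- if (target <= 0.5) {
    function(l) suppressWarnings(stats::pt(tO, nu, ncp = l)) - target
  } else {
    function(l) (1 - target) -
      suppressWarnings(stats::pt(tO, nu, ncp = l, lower.tail = FALSE))
  }
  step <- 2 + abs(tO)
  lo <- tO - step
  hi <- tO + step
  bracketed <- FALSE
  for (i in 1:64) {
    if (f(lo) > 0 && f(hi) < 0) {
      bracketed <- TRUE
      break
    }
    step <- step * 2
    lo <- tO - step
    hi <- tO + step
  }
  if (!bracketed) {
    stop("noncentrality search failed: tail level ", format(target),
         " not bracketed at t = ", format(tO), ", nu = ", nu)
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Noncentrality limits of the exact interval
#'
#' For an observed noncentral-t statistic `tO` with `nu` degrees of freedom,
#' returns the noncentrality parameters `(lambda_L, lambda_U)` whose
#' noncentral-t CDFs evaluated at `tO` equal `1 - alpha1` and `alpha2`.
#' The exact confidence limits for the standardized contrast are these
#' values multiplied by the square root of the variance factor `V`.
#'
#' @param tO observed statistic (contrast estimate divided by its estimated
#'   standard error).
#' @param nu residual degrees of freedom.
#' @param alpha1,alpha2 lower and upper one-sided tail levels; their sum
#'   must be below 1.
#' @return numeric vector `c(lower, upper)` in noncentrality units.
#' @keywords internal
ncp_limits <- function(tO, nu, alpha1, alpha2) {
  stopifnot(alpha1 > 0, alpha2 > 0, alpha1 + alpha2 < 1)
  c(solve_ncp(tO, nu, 1 - alpha1), solve_ncp(tO, nu, alpha2))
}

#' Exact interval width in noncentrality units
#'
#' The width of the exact confidence interval factorizes as
#' `W = sqrt(V) * d(tO)` where `d(tO) = lambda_U - lambda_L` depends only on
#' the observed statistic, the degrees of freedom and the tail levels --
#' not on the variance factor `V`.  This function computes `d`.
#'
#' `d` is symmetric in `tO` for equal tails and attains its minimum
#' `2 * qnorm(1 - alpha)` at `tO = 0`, where the noncentral-t CDF at zero
#' reduces to a normal tail probability.
#'
#' @param tO observed statistic(s); vectorized.
#' @param nu residual degrees of freedom.
#' @param alpha1,alpha2 one-sided tail levels (defaults give an equal-tail
#'   two-sided interval at level `1 - alpha1 - alpha2`).
#' @return width(s) in noncentrality units, same length as `tO`.
#' @examples
#' ncp_width(0, 55, 0.05, 0.05)  # equals 2 * qnorm(0.95)
#' @export
ncp_width <- function(tO, nu, alpha1 = 0.05, alpha2 = alpha1) {
  vapply(tO, function(t) {
    lim <- ncp_limits(t, nu, alpha1, alpha2)
    lim[2] - lim[1]
  }, numeric(1))
}

# Cubic-spline evaluator for the width function d(|t|) over [0, tmax].
# d is analytic and even in t for equal tails; grid points follow an
# asinh spacing -- near-unit resolution around zero where the curvature
# concentrates, geometric growth toward tmax where d is asymptotically
# linear -- so accuracy does not degrade when heavy tails push tmax into
# the thousands.  The spline is queried at |t|.  Used by the precision
# engine and the simulation suite to avoid re-solving two noncentrality
# roots per abscissa.
make_width_fun <- function(nu, alpha1, alpha2, tmax, ngrid = 161L) {
  stopifnot(tmax > 0, ngrid >= 21)
  grid <- sinh(seq(0, asinh(tmax), length.out = ngrid))
  d <- ncp_width(grid, nu, alpha1, alpha2)
  sf <- stats::splinefun(grid, d, method = "fmm")
  function(t) sf(abs(t))
}

# Composite Gauss-Legendre rule on the probability scale (eps, 1 - eps):
# a plain rule on the central block (delta, 1 - delta) plus log-transformed
# rules in both tails, substituting u = exp(-s) so that quantile-mapped
# integrands with polynomial tails become smooth decaying exponentials in s.
# Returns nodes, weights and the truncated tail mass (a diagnostic: the
# integrand is not evaluated outside (eps, 1 - eps)).
prob_rule <- function(n, eps = 1e-7, delta = 1e-2) {
  stopifnot(n >= 16, eps > 0, eps < delta, delta < 0.5)
  n_mid <- max(16L, as.integer(n) %/% 2L)
  n_tail <- max(8L, as.integer(n) %/% 4L)
  mid <- pracma::gaussLegendre(n_mid, delta, 1 - delta)
  tail_s <- pracma::gaussLegendre(n_tail, log(1 / delta), log(1 / eps))
  lo_x <- exp(-tail_s$x)
  lo_w <- tail_s$w * lo_x
  list(x = c(lo_x, mid$x, 1 - lo_x),
       w = c(lo_w, mid$w, lo_w),
       trunc_mass = 2 * eps)
}
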