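# Minimal sample sizes for the expected-width and assurance criteria.

new_plan <- function(design, criterion, method, omega, assurance, n, achieved,
                     previous, trace) {
  structure(list(NT = sum(design$ratios) * n, n = n,
                 Ni = design$ratios * n,
                 criterion = criterion, method = method,
                 omega = omega, assurance = assurance,
                 achieved = achieved, previous = previous,
                 trace = trace),
            class = "sample_size_plan")
}

#' @export
print.sample_size_plan <- function(x, digits = 4, ...) {
  lab <- if (x$criterion == "expected_width") {
    sprintf("expected width <= %g", x$omega)
  } else {
    sprintf("P(width <= %g) >= %g", x$omega, x$assurance)
  }
  cat(sprintf("Minimal total sample size for %s [%s method]:\n", lab, x$method))
  cat(sprintf("  NT = %d  (per group: %s)\n", x$NT,
              paste(x$Ni, collapse = ", ")))
  cat(sprintf("  achieved %.*f; previous size %s gives %.*f (criterion fails)\n",
              digits, x$achieved,
              if (nrow(x$trace) > 1) x$NT - sum(x$Ni) / x$n else "none",
              digits, x$previous))
  invisible(x)
}

# Smallest n on the lattice giving nu >= 2 and every N_i >= 2.
lattice_start <- function(design) {
  rsum <- sum(design$ratios)
  n <- 1L
  repeat {
    nu <- rsum * n - design$G - design$P
    if (nu >= 2 && min(design$ratios) * n >= 2) return(n)
    n <- n + 1L
  }
}

search_lattice <- function(design, feasible, value_fn, NT_max) {
  rsum <- sum(design$ratios)
  n <- lattice_start(design)
  trace_n <- integer(0)
  trace_v <- numeric(0)
  prev <- NA_real_
  repeat {
    NT <- rsum * n
    if (NT > NT_max) {
      stop("criterion unattainable within bound NT <= ", NT_max)
    }
    val <- value_fn(NT)
    trace_n <- c(trace_n, n)
    trace_v <- c(trace_v, val)
    if (feasible(val)) {
      return(list(n = n, achieved = val, previous = prev,
                  trace = data.frame(n = trace_n, NT = rsum * trace_n,
                                     value = trace_v)))
    }
    prev <- val
    n <- n + 1L
  }
}

#' Minimal sample size for the expected-width criterion
#'
#' Finds the smallest total sample size `NT` on the lattice
#' `N_i = r_i * n`, `n = 1, 2, ...` such that the expected width of the
#' exact confidence interval satisfies `Omega(NT) <= omega`.  The search is
#' a linear ascent from the smallest feasible size (monotonicity of the
#' criterion in `NT` is an empirical regularity, not a theorem), and the
#' returned plan carries a minimality certificate: the value at the
#' preceding lattice size, which violates the criterion.  Equality counts
#' as feasible.
#'
#' @param design a [design_spec()].
#' @param omega positive width bound in standardized units.
#' @param method `"exact"` (nested quadrature over the covariate factor)
#'   or `"approximate"` (covariate layer omitted).
#' @param control a [precision_control()].
#' @param NT_max search cap; exceeding it is an error.
#' @return a `sample_size_plan` with fields `NT`, `Ni`, `achieved`,
#'   `previous` and the search `trace`.
#' @examples
#' \donttest{
#' des <- design_spec(c(1, -0.5, -0.5), P = 1, psi_star = 0.5, theta = 0)
#' sample_size_width(des, omega = 1.5)
#' }
#' @export
sample_size_width <- function(design, omega, method = c("exact", "approximate"),
                              control = precision_control(), NT_max = 20000L) {
  method <- match.arg(method)
  stopifnot(omega > 0)
  s <- search_lattice(design, function(v) v <= omega, function(NT) {
    expected_width(design, NT, method, control)$value
  }, NT_max)
  new_plan(design, "expected_width", method, omega, NA_real_,
           s$n, s$achieved, s$previous, s$trace)
}

#' Minimal sample size for the assurance-probability criterion
#'
#' Smallest lattice `NT` with `Gamma(NT, omega) >= assurance`, where
#' `Gamma` is the probability that the exact interval's width stays within
#' `omega`.  Search and certificate as in [sample_size_width()].
#'
#' @inheritParams sample_size_width
#' @param assurance target probability `1 - gamma` in (0, 1).
#' @export
sample_size_assurance <- function(design, omega, assurance = 0.80,
                                  method = c("exact", "approximate"),
                                  control = precision_control(),
                                  NT_max = 20000L) {
  method <- match.arg(method)
  stopifnot(omega > 0, assurance > 0, assurance < 1)
  s <- search_lattice(design, function(v) v >= assurance, function(NT) {
    assurance_prob(design, NT, omega, method, control)$value
  }, NT_max)
  new_plan(design, "assurance", method, omega, assurance,
           s$n, s$achieved, s$previous, s$trace)
}
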