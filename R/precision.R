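# Precision engine: exact and approximate expected width and assurance
# probability of the exact confidence interval under the unconditional
# (random-covariate) model.

#' Quadrature control for the precision engine
#'
#' The expectations over the covariate factor and the test statistic are
#' computed by Gauss-Legendre rules mapped through the noncentral-F and
#' noncentral-t quantile functions on the probability scale, with
#' log-substituted tail blocks (see the methods vignette).  Node counts and
#' the width-spline grid double until two successive evaluations agree to
#' `tol`; failing that after `max_levels` levels is an error carrying the
#' diagnostics.
#'
#' @param n_outer base node count for the covariate (noncentral-F) layer.
#' @param n_inner base node count for the test-statistic (noncentral-t)
#'   layer.
#' @param n_grid base number of abscissae for the cached width spline.
#' @param eps truncation point of the probability scale; the omitted tail
#'   mass `2 * eps` is reported as a diagnostic.
#' @param delta boundary between the central and tail quadrature blocks.
#' @param tol convergence tolerance on successive values.
#' @param max_levels maximum number of node-doubling levels.
#' @param check_event verify the assurance inner event by a fine-grid
#'   indicator integration (2,000 abscissae); a disagreement beyond `1e-4`
#'   with the single-crossing solution is an error.
#' @return a list of class `precision_control`.
#' @export
precision_control <- function(n_outer = 64L, n_inner = 96L, n_grid = 161L,
                              eps = 1e-7, delta = 1e-2, tol = 1e-4,
                              max_levels = 3L, check_event = TRUE) {
  structure(list(n_outer = as.integer(n_outer), n_inner = as.integer(n_inner),
                 n_grid = as.integer(n_grid), eps = eps, delta = delta,
                 tol = tol, max_levels = as.integer(max_levels),
                 check_event = isTRUE(check_event)),
            class = "precision_control")
}

new_precision_result <- function(value, criterion, method, NT, omega = NA_real_,
                                 diagnostics) {
  structure(list(value = value, criterion = criterion, method = method,
                 NT = NT, omega = omega, diagnostics = diagnostics),
            class = "precision_result")
}

#' @export
print.precision_result <- function(x, digits = 4, ...) {
  lab <- if (x$criterion == "expected_width") "expected width Omega"
         else sprintf("assurance probability Gamma (omega = %g)", x$omega)
  cat(sprintf("%s [%s method], NT = %d: %.*f\n",
              lab, x$method, x$NT, digits, x$value))
  cat(sprintf("  quadrature: %d outer x %d inner nodes, width grid %d,\n",
              x$diagnostics$n_outer, x$diagnostics$n_inner,
              x$diagnostics$n_grid))
  cat(sprintf("  last change %.2e, truncated tail mass %.1e\n",
              x$diagnostics$change, x$diagnostics$trunc_mass))
  invisible(x)
}

# One expected-width evaluation at a fixed resolution level.
omega_eval <- function(design, NT, method, n_outer, n_inner, n_grid,
                       eps, delta) {
  k <- design_constants(design, NT, min_nu = 2)
  nu <- k$nu
  a1 <- design$alpha / 2
  inner <- prob_rule(n_inner, eps, delta)
  if (method == "exact") {
    outer_rule <- prob_rule(n_outer, eps, delta)
    Fx <- suppressWarnings(
      stats::qf(outer_rule$x, design$P, nu + 1, ncp = k$xi))
    V <- k$a * (1 + k$b * Fx)
    lam <- design$psi_star / sqrt(V)
    tq <- suppressWarnings(
      vapply(lam, function(l) stats::qt(inner$x, nu, ncp = l),
             numeric(length(inner$x))))
    wf <- make_width_fun(nu, a1, a1, max(abs(tq)) * 1.01, n_grid)
    inner_means <- colSums(inner$w * matrix(wf(tq), nrow = length(inner$x)))
    sum(outer_rule$w * sqrt(V) * inner_means)
  } else {
    lam <- design$psi_star / sqrt(k$a)
    tq <- suppressWarnings(stats::qt(inner$x, nu, ncp = lam))
    wf <- make_width_fun(nu, a1, a1, max(abs(tq)) * 1.01, n_grid)
    sqrt(k$a) * sum(inner$w * wf(tq))
  }
}

# One assurance evaluation at a fixed resolution level.  The inner event
# {d(T) <= omega / sqrt(V)} is treated as an interval |T| <= t* with the
# crossing t* solved on the width spline (d is even with its minimum at
# zero); a fine-grid indicator integration over 2,000 abscissae guards the
# assumed unimodality and must agree to 1e-4.
gamma_eval <- function(design, NT, omega, method, n_outer, n_grid,
                       eps, delta, check_event) {
  k <- design_constants(design, NT, min_nu = 2)
  nu <- k$nu
  a1 <- design$alpha / 2
  d0 <- ncp_width(0, nu, a1, a1)
  if (method == "exact") {
    # The event has positive probability only where V < (omega/d0)^2, i.e.
    # below the boundary u* on the probability scale of F_X.  The inner
    # probability vanishes like sqrt(u* - u) there, so when the boundary
    # falls inside the domain the outer rule substitutes u = u* - (u* -
    # eps) w^2, which removes the square-root kink; otherwise the standard
    # composite rule applies.
    Fstar <- ((omega / d0)^2 / k$a - 1) / k$b
    ustar <- if (Fstar <= 0) 0 else {
      suppressWarnings(stats::pf(Fstar, design$P, nu + 1, ncp = k$xi))
    }
    if (ustar <= eps) return(0)
    if (ustar >= 1 - eps) {
      outer_rule <- prob_rule(n_outer, eps, delta)
    } else {
      gl <- pracma::gaussLegendre(n_outer, 0, 1)
      outer_rule <- list(x = ustar - (ustar - eps) * gl$x^2,
                         w = gl$w * 2 * gl$x * (ustar - eps),
                         trunc_mass = 2 * eps)
    }
    Fx <- suppressWarnings(
      stats::qf(outer_rule$x, design$P, nu + 1, ncp = k$xi))
    V <- k$a * (1 + k$b * Fx)
  } else {
    outer_rule <- list(x = 0.5, w = 1, trunc_mass = 0)
    V <- k$a
  }
  lam <- design$psi_star / sqrt(V)
  cc <- omega / sqrt(V)
  pe <- numeric(length(V))
  feasible <- cc > d0
  if (any(feasible)) {
    cmax <- max(cc[feasible])
    thi <- 2
    while (ncp_width(thi, nu, a1, a1) < cmax) {
      thi <- thi * 2
      if (thi > 1e6) stop("assurance crossing search failed: bound too large")
    }
    wf <- make_width_fun(nu, a1, a1, thi * 1.05, n_grid)
    for (i in which(feasible)) {
      ts <- stats::uniroot(function(t) wf(t) - cc[i], c(0, thi * 1.05),
                           tol = 1e-11)$root
      pe[i] <- suppressWarnings(stats::pt(ts, nu, ncp = lam[i]) -
                                  stats::pt(-ts, nu, ncp = lam[i]))
    }
    if (check_event) {
      pg <- event_prob_grid(wf, thi * 1.05, cc, lam, nu)
      dev <- max(abs(pg - pe))
      if (dev > 1e-4) {
        stop("assurance inner event is not a single interval in |t| ",
             "(single-crossing and grid integrations differ by ",
             format(dev), ")")
      }
    }
  }
  sum(outer_rule$w * pe)
}

# General event probability by run detection on a fine |t| grid: locates
# every sign change of d(t) - c, refines the boundaries, and accumulates
# CDF differences over the symmetric event.  Makes no unimodality
# assumption; used as the verification fallback.
event_prob_grid <- function(wf, tmax, cc, lam, nu, ngrid = 2000L) {
  tg <- seq(0, tmax, length.out = ngrid)
  dg <- wf(tg)
  vapply(seq_along(cc), function(i) {
    inside <- dg <= cc[i]
    if (!any(inside)) return(0)
    r <- rle(inside)
    ends <- cumsum(r$lengths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    p <- 0
    for (j in which(r$values)) {
      lo <- tg[starts[j]]
      hi <- tg[ends[j]]
      if (starts[j] > 1L) {
        lo <- stats::uniroot(function(t) wf(t) - cc[i],
                             c(tg[starts[j] - 1L], lo), tol = 1e-11)$root
      }
      if (ends[j] < ngrid) {
        hi <- stats::uniroot(function(t) wf(t) - cc[i],
                             c(hi, tg[ends[j] + 1L]), tol = 1e-11)$root
      }
      p <- p + suppressWarnings(stats::pt(hi, nu, ncp = lam[i]) -
                                  stats::pt(lo, nu, ncp = lam[i]))
      if (lo > 0) {
        p <- p + suppressWarnings(stats::pt(-lo, nu, ncp = lam[i]) -
                                    stats::pt(-hi, nu, ncp = lam[i]))
      } else {
        # run starts at t = 0: mirror contributes the block (-hi, 0)
        p <- p + suppressWarnings(stats::pt(0, nu, ncp = lam[i]) -
                                    stats::pt(-hi, nu, ncp = lam[i]))
      }
    }
    p
  }, numeric(1))
}

# Doubling loop shared by the two criteria.
converge_levels <- function(eval_at, control, what) {
  prev <- eval_at(1L)
  change <- NA_real_
  for (lev in seq(2L, max(2L, control$max_levels))) {
    cur <- eval_at(lev)
    change <- abs(cur - prev)
    if (change <= control$tol) {
      return(list(value = cur, change = change, level = lev))
    }
    prev <- cur
  }
  stop(what, " quadrature did not converge: last change ",
       format(change), " exceeds tol ", format(control$tol),
       " after ", control$max_levels, " levels")
}

#' Expected width of the exact confidence interval
#'
#' Under stochastic multinormal covariates the exact interval's width is
#' `W = sqrt(V) * d(T)` where `V = a (1 + b F_X)` with `F_X` noncentral
#' `F(P, nu + 1, theta/a)`, and, given `V`, `T` is noncentral
#' `t(nu, psi_star / sqrt(V))`.  The exact method computes
#' `Omega = E_F[ sqrt(V) E_T[ d(T) ] ]` by nested quadrature; the
#' approximate method drops the covariate layer, replacing `V` by `a`
#' throughout (`Omega_a = sqrt(a) E[d(T)]` with `T ~ t(nu, psi_star /
#' sqrt(a))`).
#'
#' @param design a [design_spec()].
#' @param NT total sample size on the ratio lattice; must leave
#'   `nu = NT - G - P >= 2`.
#' @param method `"exact"` or `"approximate"`.
#' @param control a [precision_control()].
#' @return a `precision_result` whose `value` is the expected width in
#'   standardized units.
#' @examples
#' \donttest{
#' des <- design_spec(c(1, -0.5, -0.5), P = 1, psi_star = 0.5, theta = 0)
#' expected_width(des, NT = 75)
#' }
#' @export
expected_width <- function(design, NT, method = c("exact", "approximate"),
                           control = precision_control()) {
  method <- match.arg(method)
  res <- converge_levels(function(lev) {
    m <- 2^(lev - 1L)
    omega_eval(design, NT, method,
               control$n_outer * m, control$n_inner * m,
               (control$n_grid - 1L) * m + 1L,
               control$eps, control$delta)
  }, control, "expected width")
  m <- 2^(res$level - 1L)
  new_precision_result(res$value, "expected_width", method, NT,
                       diagnostics = list(
                         n_outer = control$n_outer * m,
                         n_inner = control$n_inner * m,
                         n_grid = (control$n_grid - 1L) * m + 1L,
                         change = res$change,
                         trunc_mass = 2 * control$eps))
}

#' Assurance probability of the exact interval width
#'
#' Probability that the exact interval's width `W = sqrt(V) * d(T)` does
#' not exceed the bound `omega`.  The exact method integrates
#' `P_T[ d(T) <= omega / sqrt(V) ]` over the noncentral-F law of the
#' covariate factor; the approximate method evaluates the same inner
#' probability at `V = a`.
#'
#' @inheritParams expected_width
#' @param omega positive width bound in standardized units.
#' @return a `precision_result` whose `value` is the probability.
#' @examples
#' \donttest{
#' des <- design_spec(c(1, -0.5, -0.5), P = 1, psi_star = 0.5, theta = 0)
#' assurance_prob(des, NT = 75, omega = 1.00)
#' }
#' @export
assurance_prob <- function(design, NT, omega,
                           method = c("exact", "approximate"),
                           control = precision_control()) {
  method <- match.arg(method)
  stopifnot(omega > 0)
  res <- converge_levels(function(lev) {
    m <- 2^(lev - 1L)
    gamma_eval(design, NT, omega, method,
               control$n_outer * m, (control$n_grid - 1L) * m + 1L,
               control$eps, control$delta, control$check_event)
  }, control, "assurance probability")
  m <- 2^(res$level - 1L)
  new_precision_result(res$value, "assurance", method, NT, omega = omega,
                       diagnostics = list(
                         n_outer = control$n_outer * m,
                         n_inner = NA_integer_,
                         n_grid = (control$n_grid - 1L) * m + 1L,
                         change = res$change,
                         trunc_mass = 2 * control$eps))
}
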