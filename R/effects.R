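#' Effect estimate container
#'
#' Point estimate with standard error and 95% confidence interval,
#' carrying its units and the interval method used (`"delta-method"`
#' intervals are symmetric about the estimate; `"endpoint-inversion"`
#' intervals are reciprocals of a Wald interval and need not be).
#'
#' @param estimate,se,ci_low,ci_high Numeric scalars (`se` may be `NA`).
#' @param units Free-text units, e.g. `"per 1,000 person-years"`.
#' @param method `"delta-method"` or `"endpoint-inversion"`.
#' @return A list of class `effect_estimate`.
#' @keywords internal
effect_estimate <- function(estimate, se, ci_low, ci_high, units,
                            method = "delta-method") {
  structure(list(estimate = estimate, se = se, ci_low = ci_low,
                 ci_high = ci_high, units = units, method = method),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%.4g [95%%-CI: %.4g; %.4g] %s (%s)\n", x$estimate,
              x$ci_low, x$ci_high, x$units, x$method))
  invisible(x)
}

.coef_se <- function(fit) {
  if (inherits(fit, "ahaz_fit")) {
    list(beta = fit$beta, se = fit$beta_se)
  } else if (inherits(fit, "linying_fit")) {
    list(beta = fit$beta, se = fit$se)
  } else if (is.list(fit) && !is.null(fit$beta)) {
    list(beta = fit$beta, se = fit$beta_se %||% fit$se)
  } else stop("need an 'ahaz_fit', 'linying_fit' or a list with beta/se",
              call. = FALSE)
}

#' Hazard (rate) difference between arms
#'
#' The time-constant absolute effect: the fitted hazard difference
#' \eqn{\hat\beta} rescaled to events per `scale` person-years, with a
#' Wald 95% confidence interval.
#'
#' @param fit An [ahaz_fit()], a [fit_linying()] result, or any list
#'   with elements `beta` and `beta_se`/`se` (per person-year).
#' @param scale Person-year scale of the report (default 1,000).
#' @return An [effect_estimate()].
#' @export
rate_difference <- function(fit, scale = 1000) {
  cs <- .coef_se(fit)
  z <- 1.96
  effect_estimate(scale * cs$beta, scale * cs$se,
                  scale * (cs$beta - z * cs$se),
                  scale * (cs$beta + z * cs$se),
                  units = sprintf("per %s person-years",
                                  format(scale, big.mark = ",")),
                  method = "delta-method")
}

#' Number needed to treat in person-years
#'
#' The reciprocal of the hazard difference, \eqn{1/\hat\beta}: the
#' number of person-*years* of treatment needed to prevent (or, with
#' positive sign, to cause) one additional event.  This is not a number
#' of patients — a hazard difference has units 1/time, so its
#' reciprocal has units of time, unlike the dimensionless NNT from a
#' risk difference (see [km_nnt()]).
#'
#' For parametric fits the confidence interval is the delta method on
#' \eqn{1/\beta} (standard error \eqn{SE(\beta)/\beta^2}); for the
#' semiparametric Lin-Ying fit the interval is instead obtained by
#' inverting the endpoints of the Wald interval for \eqn{\beta}, and
#' the method used is recorded in the result.
#'
#' @inheritParams rate_difference
#' @param method Interval method; default `"delta-method"` for
#'   parametric fits and `"endpoint-inversion"` for Lin-Ying fits.
#' @return An [effect_estimate()] in person-years.
#' @export
nnt <- function(fit, method = NULL) {
  cs <- .coef_se(fit)
  if (is.null(method))
    method <- if (inherits(fit, "linying_fit"))
      "endpoint-inversion" else "delta-method"
  if (cs$beta == 0)
    stop("hazard difference is 0: NNT is undefined (infinite)",
         call. = FALSE)
  est <- 1 / cs$beta
  z <- 1.96
  if (method == "delta-method") {
    se <- cs$se / cs$beta^2
    effect_estimate(est, se, est - z * se, est + z * se,
                    units = "person-years", method = method)
  } else {
    lo <- cs$beta - z * cs$se
    hi <- cs$beta + z * cs$se
    if (sign(lo) != sign(hi))
      warning("beta CI crosses 0: inverted NNT interval is unbounded",
              call. = FALSE)
    ci <- sort(1 / c(lo, hi))
    effect_estimate(est, NA_real_, ci[1L], ci[2L],
                    units = "person-years", method = method)
  }
}

#' Mode of the fitted event-time distribution, by arm
#'
#' For the control arm this is the mode of the fitted baseline density
#' \eqn{f_0}; for the treated arm it is the argmax of
#' \eqn{f_1(t) = (h_0(t) + \beta) S_0(t) e^{-t\beta}}, found
#' numerically.  The 95% confidence interval is the delta method on the
#' mode as a function of the unconstrained parameters (numerical
#' gradient); it may cross zero.  The exponential baseline has mode 0
#' by definition with no meaningful interval, flagged as degenerate.
#'
#' @param fit An [ahaz_fit()].
#' @param arm 0 (baseline/control, default) or 1 (treated).
#' @return An [effect_estimate()] in years, with attribute `degenerate`
#'   set when the mode sits on the boundary with zero gradient.
#' @export
mode_estimate <- function(fit, arm = 0L) {
  stopifnot(inherits(fit, "ahaz_fit"), arm %in% c(0L, 1L))
  p <- fit$n_params - 1L
  fname <- fit$family_name
  cp <- fit$cutpoints
  upper <- 3 * fit$max_time
  mode_of <- function(u) {
    fam <- .u_to_family(fname, u[seq_len(p)], cp)
    if (arm == 0L) return(mode0(fam, upper = upper))
    b <- u[p + 1L]
    .numeric_mode(function(t)
      (hazard0(fam, t) + b) * exp(-(cumhaz0(fam, t) + t * b)),
      upper = upper, tol = 1e-8)
  }
  est <- unname(mode_of(fit$u_hat))
  if (fname == "exponential" && arm == 0L) {
    out <- effect_estimate(0, NA_real_, NA_real_, NA_real_,
                           units = "years", method = "delta-method")
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  g <- pracma::grad(mode_of, fit$u_hat, heps = 1e-4)
  se <- sqrt(max(0, drop(t(g) %*% fit$vcov_u %*% g)))
  out <- effect_estimate(est, se, est - 1.96 * se, est + 1.96 * se,
                         units = "years", method = "delta-method")
  attr(out, "degenerate") <- est == 0 && all(abs(g) < 1e-10)
  out
}

#' Between-arm mode difference for the linear-hazard-rate family
#'
#' With a linear baseline hazard \eqn{a + bt} and hazard shift
#' \eqn{\beta}, both arm densities have interior modes
#' \eqn{(\sqrt b - a - x\beta)/b} when positive, so the treated-minus-
#' control mode difference has the closed form \eqn{-\beta/b}: the
#' delay (in years) of the most probable event time under treatment.
#' The confidence interval is the delta method on \eqn{-\beta/b} using
#' the joint covariance of \eqn{(\beta, b)}.
#'
#' @param fit An [ahaz_fit()] with `family = "lhr"` and fitted slope
#'   \eqn{\hat b > 0}.
#' @return An [effect_estimate()] in years.
#' @export
mode_difference_lhr <- function(fit) {
  stopifnot(inherits(fit, "ahaz_fit"))
  if (fit$family_name != "lhr")
    stop("mode_difference_lhr() requires family = 'lhr'", call. = FALSE)
  b <- fit$family$theta[["b"]]
  if (b <= 0) stop("mode difference undefined for b <= 0", call. = FALSE)
  p <- fit$n_params - 1L
  g_of <- function(u) unname(-u[p + 1L] / exp(u[2L]))   # -beta / b
  est <- g_of(fit$u_hat)
  g <- pracma::grad(g_of, fit$u_hat)
  se <- sqrt(max(0, drop(t(g) %*% fit$vcov_u %*% g)))
  effect_estimate(est, se, est - 1.96 * se, est + 1.96 * se,
                  units = "years", method = "delta-method")
}
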