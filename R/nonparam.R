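#' Actuarial life table with interval hazard estimates
#'
#' Partitions follow-up into intervals of the given width and computes
#' the classical actuarial hazard per interval,
#' \deqn{\hat h_j = d_j / \{w\,(n'_j - d_j/2)\}, \qquad
#'       n'_j = n_j - c_j/2,}
#' with \eqn{n_j} entering, \eqn{d_j} events and \eqn{c_j} censorings
#' in interval \eqn{j} of width \eqn{w} (censored subjects count for
#' half an interval at risk).  The standard error is
#' \eqn{\hat h_j \sqrt{(1 - (\hat h_j w/2)^2)/d_j}} and the 95%
#' interval is log-transformed Wald.  Intervals without events are
#' reported with hazard 0, not dropped.
#'
#' @param ds A [survival_dataset()].
#' @param arm 0 or 1.
#' @param width Interval width in years (default 0.25, quarter years).
#' @return A data frame of class `life_table` with columns `start`,
#'   `end`, `n_enter`, `events`, `censored`, `hazard`, `se`, `lower`,
#'   `upper`.
#' @export
life_table <- function(ds, arm, width = 0.25) {
  stopifnot(inherits(ds, "survival_dataset"), width > 0)
  idx <- ds$arm == as.integer(arm)
  if (!any(idx)) stop("arm ", arm, " not present", call. = FALSE)
  tt <- ds$time[idx]; ev <- ds$event[idx]
  K <- floor(max(tt) / width) + 1L
  start <- (seq_len(K) - 1L) * width
  end <- start + width
  d <- cc <- n_enter <- integer(K)
  n <- length(tt)
  for (j in seq_len(K)) {
    n_enter[j] <- n
    in_j <- tt >= start[j] & tt < end[j]
    d[j] <- sum(in_j & ev == 1L)
    cc[j] <- sum(in_j & ev == 0L)
    n <- n - d[j] - cc[j]
  }
  n_eff <- n_enter - cc / 2
  denom <- width * (n_eff - d / 2)
  haz <- ifelse(denom > 0, d / denom, NA_real_)
  se <- ifelse(d > 0, haz * sqrt(pmax(0, 1 - (haz * width / 2)^2) / d),
               NA_real_)
  lower <- ifelse(d > 0, haz * exp(-1.96 * se / haz), NA_real_)
  upper <- ifelse(d > 0, haz * exp(1.96 * se / haz), NA_real_)
  out <- data.frame(start = start, end = end, n_enter = n_enter,
                    events = d, censored = cc, hazard = haz, se = se,
                    lower = lower, upper = upper)
  class(out) <- c("life_table", "data.frame")
  attr(out, "width") <- width
  attr(out, "arm") <- as.integer(arm)
  out
}

#' Kaplan-Meier survival curve for one arm
#'
#' Product-limit estimator with Greenwood standard errors, computed via
#' [survival::survfit()]; steps are right-continuous at event times.
#'
#' @param ds A [survival_dataset()].
#' @param arm 0 or 1.
#' @return A data frame of class `km_curve` with columns `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`, `se` (Greenwood SE of the
#'   survival probability), `lower`, `upper`.
#' @export
km <- function(ds, arm) {
  stopifnot(inherits(ds, "survival_dataset"))
  idx <- ds$arm == as.integer(arm)
  if (!any(idx)) stop("arm ", arm, " not present", call. = FALSE)
  sub <- data.frame(time = ds$time[idx], event = ds$event[idx])
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = sub,
                          conf.type = "log")
  out <- data.frame(time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, n_censor = sf$n.censor,
                    surv = sf$surv, se = sf$surv * sf$std.err,
                    lower = sf$lower, upper = sf$upper)
  class(out) <- c("km_curve", "data.frame")
  attr(out, "arm") <- as.integer(arm)
  out
}

# step-function lookup: S(t) and its Greenwood SE, last value carried
# forward; S = 1 with SE 0 before the first observed time
km_at <- function(curve, t) {
  i <- findInterval(t, curve$time)
  if (i == 0L) return(c(surv = 1, se = 0))
  c(surv = curve$surv[i], se = curve$se[i])
}

#' Kaplan-Meier based time-dependent NNT
#'
#' The classical, dimensionless NNT at horizon `t`:
#' \eqn{1/\{\hat S_1(t) - \hat S_0(t)\}}, the number of *patients* to
#' treat for `t` years to prevent one additional event by time `t`.
#' The confidence interval inverts the endpoints of the Wald interval
#' for the survival difference, with Greenwood variances.  Unlike the
#' person-years NNT of [nnt()], this quantity depends on the chosen
#' horizon.
#'
#' @param ds A [survival_dataset()].
#' @param t Horizon in years; must not exceed follow-up in either arm.
#' @return An [effect_estimate()] with units `"patients"`.
#' @export
km_nnt <- function(ds, t) {
  stopifnot(inherits(ds, "survival_dataset"), t > 0)
  k1 <- km(ds, 1L); k0 <- km(ds, 0L)
  if (t > max(k1$time) || t > max(k0$time))
    stop("horizon exceeds observed follow-up in at least one arm",
         call. = FALSE)
  a1 <- km_at(k1, t); a0 <- km_at(k0, t)
  d <- a1[["surv"]] - a0[["surv"]]
  if (d == 0)
    stop("survival curves coincide at t: NNT undefined", call. = FALSE)
  sd_d <- sqrt(a1[["se"]]^2 + a0[["se"]]^2)
  lo <- d - 1.96 * sd_d
  hi <- d + 1.96 * sd_d
  if (sign(lo) == sign(hi)) {
    ci <- sort(1 / c(lo, hi))
  } else {
    warning("risk-difference CI crosses 0: inverted NNT interval is unbounded",
            call. = FALSE)
    ci <- c(-Inf, Inf)
  }
  effect_estimate(1 / d, NA_real_, ci[1L], ci[2L], units = "patients",
                  method = "endpoint-inversion")
}
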