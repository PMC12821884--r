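#' Additive-hazard log-likelihood
#'
#' Log-likelihood of a two-arm dataset under the additive hazard model
#' \eqn{h_x(t) = h_0(t) + x\beta}, where \eqn{x} is the binary arm
#' indicator.  An observed event contributes \eqn{\log f_x(t_i)} with
#' \eqn{f_x(t) = (h_0(t) + x\beta)\, S_0(t) e^{-t x \beta}}, a censored
#' observation contributes \eqn{\log S_x(t_i)} with
#' \eqn{S_x(t) = S_0(t) e^{-t x \beta}}, so
#' \deqn{l = \sum_i \delta_i \log(h_0(t_i) + x_i\beta) - H_0(t_i) -
#'       t_i x_i \beta,}
#' with \eqn{\delta_i = 1} for an event.  Outside the model's domain
#' (a non-positive treated-arm hazard at an event time, or a cumulative
#' treated-arm hazard below zero) the function returns `-Inf`, which the
#' optimizer treats as an infeasible point.
#'
#' @param ds A [survival_dataset()].
#' @param fam A [baseline_family()].
#' @param beta Hazard difference for the treated arm, per person-year.
#' @return The log-likelihood (scalar), or `-Inf` outside the domain.
#' @export
ahaz_loglik <- function(ds, fam, beta) {
  stopifnot(inherits(ds, "survival_dataset"))
  h0 <- hazard0(fam, ds$time)
  H0 <- cumhaz0(fam, ds$time)
  hx <- h0 + ds$arm * beta
  Hx <- H0 + ds$time * ds$arm * beta
  ev <- ds$event == 1L
  if (any(hx[ev] <= 0) || any(Hx < 0)) return(-Inf)
  sum(log(hx[ev])) - sum(Hx)
}

#' Optimizer control for [ahaz_fit()]
#'
#' @param restarts Number of jittered restarts around the deterministic
#'   starting point (default 5).
#' @param jitter_sd Standard deviation of the Gaussian jitter applied on
#'   the unconstrained parameter scale.
#' @param seed Seed for the restart jitter (local to the fit; the
#'   global RNG state is preserved).
#' @param maxit Maximum Nelder-Mead iterations per start.
#' @param reltol Relative convergence tolerance of the log-likelihood.
#' @param hessian_step Central-difference step for the numerical Hessian
#'   on the unconstrained scale.
#' @return A list of class `ahaz_control`.
#' @export
ahaz_control <- function(restarts = 5L, jitter_sd = 0.3, seed = 1L,
                         maxit = 5000L, reltol = 1e-9,
                         hessian_step = 1e-5) {
  structure(list(restarts = as.integer(restarts), jitter_sd = jitter_sd,
                 seed = as.integer(seed), maxit = as.integer(maxit),
                 reltol = reltol, hessian_step = hessian_step),
            class = "ahaz_control")
}

# evaluate f() with a temporary RNG state, restoring the caller's state
.with_local_seed <- function(seed, f) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  f()
}

# deterministic starting point: exponential occurrence/exposure rates
.ahaz_start <- function(ds, family, cutpoints) {
  s0 <- summarize_arm(ds, 0L)
  s1 <- summarize_arm(ds, 1L)
  lam0 <- max(s0$rate, 0.5 / s0$person_years)
  beta0 <- s1$rate - lam0
  theta0 <- switch(family,
    exponential   = lam0,
    lhr           = c(lam0, 1e-4),
    weibull       = c(1, 1 / lam0),
    loglogistic   = c(1, 1 / lam0),
    gompertz      = c(lam0, 1e-4),
    gammagompertz = c(lam0, 0.05, 0.1),
    piecewise     = .piecewise_start(ds, cutpoints, lam0)
  )
  list(fam = baseline_family(family, theta0, cutpoints = cutpoints),
       beta = beta0)
}

# per-piece occurrence/exposure rates in the control arm
.piecewise_start <- function(ds, cutpoints, lam0) {
  t0 <- ds$time[ds$arm == 0L]
  e0 <- ds$event[ds$arm == 0L]
  edges <- c(0, cutpoints, Inf)
  K <- length(cutpoints) + 1L
  vapply(seq_len(K), function(k) {
    lo <- edges[k]; hi <- edges[k + 1L]
    expo <- sum(pmax(0, pmin(t0, hi) - lo))
    d <- sum(e0[t0 >= lo & t0 < hi])
    if (expo > 0 && d > 0) d / expo else lam0
  }, numeric(1))
}

#' Fit a parametric additive hazard model by maximum likelihood
#'
#' Maximizes [ahaz_loglik()] over the baseline parameters and the
#' hazard difference `beta` jointly, on an unconstrained parameter
#' scale (log scale for positive parameters).  The optimum is located
#' by Nelder-Mead from a deterministic occurrence/exposure starting
#' point plus jittered restarts, followed by a BFGS polish; the
#' covariance matrix is the inverse of the negative numerical Hessian
#' at the optimum, mapped to the natural scale by the delta method.
#'
#' @param ds A [survival_dataset()].
#' @param family Family name, see [ahaz_families()].
#' @param cutpoints Cutpoints for the `piecewise` family (fixed, not
#'   estimated).  If omitted, derived from `width` and the observed
#'   follow-up via [piecewise_cutpoints()].
#' @param width Piece width in years used to derive default cutpoints
#'   (`piecewise` only, default 0.25).
#' @param control An [ahaz_control()] list.
#' @return An object of class `ahaz_fit` with elements `family` (the
#'   fitted [baseline_family()]), `beta`, `beta_se`, `loglik`, `bic`,
#'   `vcov_u` (unconstrained scale, `beta` last), `vcov_nat`,
#'   `n_subjects`, `n_params`, `converged`, `u_hat`, `trace`.
#' @examples
#' des <- simulation_design("exponential", 0.03, beta = -0.01,
#'                          n_control = 400, n_treated = 800,
#'                          admin_time = 4, seed = 7)
#' ds <- simulate_trial(des)
#' fit <- ahaz_fit(ds, "exponential")
#' rate_difference(fit)
#' @export
ahaz_fit <- function(ds, family, cutpoints = NULL, width = 0.25,
                     control = ahaz_control()) {
  stopifnot(inherits(ds, "survival_dataset"))
  family <- match.arg(family, ahaz_families())
  if (family == "piecewise" && is.null(cutpoints))
    cutpoints <- piecewise_cutpoints(max(ds$time), width)
  start <- .ahaz_start(ds, family, cutpoints)
  u0 <- c(.theta_to_u(start$fam), start$beta)
  p <- length(u0) - 1L
  negll <- function(u) {
    fam <- try(.u_to_family(family, u[seq_len(p)], cutpoints),
               silent = TRUE)
    if (inherits(fam, "try-error")) return(Inf)
    ll <- ahaz_loglik(ds, fam, u[p + 1L])
    if (!is.finite(ll)) Inf else -ll
  }
  starts <- c(list(u0), .with_local_seed(control$seed, function()
    lapply(seq_len(control$restarts), function(i)
      u0 + stats::rnorm(length(u0), sd = control$jitter_sd))))
  best <- NULL
  trace <- list()
  for (s in starts) {
    if (!is.finite(negll(s))) next
    opt <- stats::optim(s, negll, method = "Nelder-Mead",
                        control = list(maxit = control$maxit,
                                       reltol = control$reltol))
    polish <- try(stats::optim(opt$par, negll, method = "BFGS",
                               control = list(maxit = 200L,
                                              reltol = control$reltol)),
                  silent = TRUE)
    if (!inherits(polish, "try-error") && is.finite(polish$value) &&
        polish$value <= opt$value)
      opt <- polish
    trace[[length(trace) + 1L]] <-
      list(value = -opt$value, convergence = opt$convergence)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("no feasible starting point found for family '", family, "'",
         call. = FALSE)
  u_hat <- unname(best$par)
  ll <- -best$value
  H <- pracma::hessian(negll, u_hat, h = control$hessian_step)
  vcov_u <- tryCatch(solve(H), error = function(e) pracma::pinv(H))
  vcov_u <- (vcov_u + t(vcov_u)) / 2
  hess_ok <- all(is.finite(vcov_u)) && all(diag(vcov_u) > 0)
  # delta-method map of the covariance to the natural parameter scale
  nat <- function(u) c(.family_spec(family)$from_u(u[seq_len(p)]),
                       u[p + 1L])
  J <- pracma::jacobian(nat, u_hat)
  vcov_nat <- J %*% vcov_u %*% t(J)
  fam_hat <- .u_to_family(family, u_hat[seq_len(p)], cutpoints)
  par_names <- c(names(fam_hat$theta), "beta")
  dimnames(vcov_u) <- dimnames(vcov_nat) <- list(par_names, par_names)
  names(u_hat) <- par_names
  n <- nrow(ds)
  npar <- length(u_hat)
  fit <- structure(list(
    family = fam_hat, family_name = family,
    beta = unname(u_hat[p + 1L]),
    beta_se = if (hess_ok) unname(sqrt(vcov_u[npar, npar]))
              else NA_real_,
    loglik = ll, minus2loglik = -2 * ll,
    bic = -2 * ll + npar * log(n),
    n_subjects = n, n_params = npar,
    vcov_u = vcov_u, vcov_nat = vcov_nat, u_hat = u_hat,
    converged = best$convergence == 0L && hess_ok,
    max_time = max(ds$time), cutpoints = cutpoints,
    arm_summaries = list(summarize_arm(ds, 0L), summarize_arm(ds, 1L)),
    trace = trace), class = "ahaz_fit")
  fit
}

#' Default piecewise-constant cutpoints
#'
#' Cutpoints on a regular grid of the given width covering the whole
#' years of observed follow-up; the final piece is open-ended.  With
#' 4.6 years of follow-up this gives 5 pieces of 12 months, 9 pieces of
#' 6 months, or 17 pieces of 3 months for widths 1, 0.5 and 0.25.
#'
#' @param max_time Maximum observed follow-up time in years.
#' @param width Piece width in years.
#' @return Numeric vector of cutpoints.
#' @export
piecewise_cutpoints <- function(max_time, width = 0.25) {
  stopifnot(width > 0, max_time > width)
  seq(width, max(width, floor(max_time)), by = width)
}

#' @export
logLik.ahaz_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params,
            nobs = object$n_subjects, class = "logLik")
}

#' Deviance-scale fit statistics
#'
#' `minus2loglik()` returns \eqn{-2 l(\hat\theta, \hat\beta)};
#' `stats::BIC()` on an `ahaz_fit` gives
#' \eqn{-2 l + p \ln(n)} with `n` the number of *subjects*.
#'
#' @param fit An [ahaz_fit()].
#' @return A scalar.
#' @export
minus2loglik <- function(fit) {
  stopifnot(inherits(fit, "ahaz_fit"))
  fit$minus2loglik
}

#' @export
print.ahaz_fit <- function(x, ...) {
  cat(sprintf("Additive hazard model, %s baseline (%d subjects, %d + %d params)\n",
              x$family_name, x$n_subjects, x$n_params - 1L, 1L))
  th <- x$family$theta
  se <- sqrt(pmax(diag(x$vcov_nat), 0))
  cat("baseline parameters (natural scale):\n")
  print(cbind(estimate = th, se = se[seq_along(th)]))
  rd <- rate_difference(x)
  cat(sprintf("hazard difference: %.4g per person-year (rate difference %.1f [%.1f; %.1f] per 1,000 PY)\n",
              x$beta, rd$estimate, rd$ci_low, rd$ci_high))
  cat(sprintf("-2LogL = %.1f   BIC = %.1f   converged: %s\n",
              x$minus2loglik, x$bic, x$converged))
  invisible(x)
}

#' Predicted hazard, survival or density with pointwise bands
#'
#' Evaluates the fitted arm-specific hazard \eqn{h_x = h_0 + x\beta},
#' survival \eqn{S_x = S_0 e^{-t x \beta}} or density
#' \eqn{f_x = h_x S_x} on a time grid, with pointwise 95% delta-method
#' confidence intervals computed on the log scale for hazard and
#' density and the complementary log-log scale for survival.
#'
#' @param object An [ahaz_fit()].
#' @param t Non-negative time grid in years.
#' @param arm 0 or 1.
#' @param quantity One of `"hazard"`, `"survival"`, `"density"`.
#' @param level Confidence level (default 0.95).
#' @param ... Unused.
#' @return A data frame with columns `time`, `estimate`, `lower`,
#'   `upper`; an `extrapolated` attribute flags grid points beyond
#'   1.5 times the observed follow-up.
#' @export
predict.ahaz_fit <- function(object, t, arm = 0L,
                             quantity = c("hazard", "survival",
                                          "density"),
                             level = 0.95, ...) {
  quantity <- match.arg(quantity)
  stopifnot(all(t >= 0), arm %in% c(0L, 1L))
  if (any(t > 1.5 * object$max_time))
    warning("extrapolating: grid extends beyond 1.5 x observed follow-up",
            call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- object$n_params - 1L
  fname <- object$family_name
  cp <- object$cutpoints
  value_at <- function(u, tt) {
    fam <- .u_to_family(fname, u[seq_len(p)], cp)
    b <- u[p + 1L] * arm
    switch(quantity,
           hazard   = hazard0(fam, tt) + b,
           survival = exp(-(cumhaz0(fam, tt) + tt * b)),
           density  = (hazard0(fam, tt) + b) *
                      exp(-(cumhaz0(fam, tt) + tt * b)))
  }
  est <- value_at(object$u_hat, t)
  lower <- upper <- numeric(length(t))
  for (i in seq_along(t)) {
    if (quantity == "survival" && t[i] == 0) {     # S(0) = 1 exactly
      lower[i] <- upper[i] <- 1
      next
    }
    trans <- switch(quantity,
      hazard   = function(u) log(value_at(u, t[i])),
      density  = function(u) log(value_at(u, t[i])),
      survival = function(u) log(-log(value_at(u, t[i]))))
    g <- pracma::grad(trans, object$u_hat)
    se <- sqrt(max(0, drop(t(g) %*% object$vcov_u %*% g)))
    ctr <- trans(object$u_hat)
    if (quantity == "survival") {
      lower[i] <- exp(-exp(ctr + z * se))
      upper[i] <- exp(-exp(ctr - z * se))
    } else {
      lower[i] <- exp(ctr - z * se)
      upper[i] <- exp(ctr + z * se)
    }
  }
  out <- data.frame(time = t, estimate = est, lower = lower,
                    upper = upper)
  attr(out, "extrapolated") <- t > 1.5 * object$max_time
  attr(out, "quantity") <- quantity
  attr(out, "arm") <- arm
  out
}

#' Serialize a fit report
#'
#' Machine-readable summary of a fitted additive hazard model: family,
#' natural and unconstrained parameter estimates with standard errors,
#' the hazard difference and derived effect measures, deviance-scale
#' fit statistics and convergence diagnostics.
#'
#' @param fit An [ahaz_fit()] or [linying_fit()].
#' @param path Optional file path; if given, the report is written as
#'   JSON.
#' @return The report as a list, invisibly if `path` is given.
#' @export
fit_report <- function(fit, path = NULL) {
  if (inherits(fit, "linying_fit")) {
    rep <- list(model = "linying", beta = fit$beta, se = fit$se,
                ci = c(fit$ci_low, fit$ci_high),
                rate_difference_per_1000py =
                  unclass(rate_difference(fit))[c("estimate", "ci_low",
                                                  "ci_high")],
                nnt_person_years = unclass(nnt(fit))[c("estimate",
                                                       "ci_low",
                                                       "ci_high")])
  } else {
    stopifnot(inherits(fit, "ahaz_fit"))
    rd <- rate_difference(fit)
    nn <- nnt(fit)
    rep <- list(
      model = fit$family_name,
      theta_natural = as.list(fit$family$theta),
      theta_unconstrained = as.list(fit$u_hat[-fit$n_params]),
      beta = fit$beta, beta_se = fit$beta_se,
      rate_difference_per_1000py = unclass(rd)[c("estimate", "ci_low",
                                                 "ci_high")],
      nnt_person_years = unclass(nn)[c("estimate", "ci_low", "ci_high")],
      minus2loglik = fit$minus2loglik, bic = fit$bic,
      n_subjects = fit$n_subjects, n_params = fit$n_params,
      converged = fit$converged)
    if (!is.null(fit$cutpoints)) rep$cutpoints <- fit$cutpoints
  }
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(rep))
  }
  rep
}
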