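# shared fixtures and independent oracles for the test suite

# representative parameter points for every supported family
family_zoo <- function() {
  list(
    baseline_family("exponential", 0.03),
    baseline_family("lhr", c(a = 0.0211, b = 0.00419)),
    baseline_family("weibull", c(shape = 1.4, scale = 12)),
    baseline_family("loglogistic", c(shape = 1.8, scale = 9)),
    baseline_family("gompertz", c(a = 0.015, b = 0.12)),
    baseline_family("gammagompertz", c(a = 0.02, b = 0.3, sigma2 = 0.8)),
    baseline_family("piecewise", c(0.01, 0.03, 0.02),
                    cutpoints = c(1, 2.5))
  )
}

# small two-arm dataset with a mix of events and censorings
toy_dataset <- function(seed = 1, n = 50) {
  withr::with_seed(seed, {
    survival_dataset(time = round(runif(n, 0.05, 4), 3),
                     event = rbinom(n, 1, 0.5),
                     arm = rep_len(c(0L, 1L), n))
  })
}

# independent oracle: cumulative hazard by adaptive quadrature of h0
quad_cumhaz <- function(fam, t) {
  vapply(t, function(tt) {
    if (tt == 0) return(0)
    stats::integrate(function(s) hazard0(fam, s), 0, tt,
                     rel.tol = 1e-12, abs.tol = 1e-14,
                     subdivisions = 2000L)$value
  }, numeric(1))
}

# independent oracle: additive-hazard log-likelihood with S_x obtained
# by numerical quadrature of the total hazard h0(t) + x*beta
quad_loglik <- function(ds, fam, beta) {
  sum(vapply(seq_len(nrow(ds)), function(i) {
    x <- ds$arm[i]; tt <- ds$time[i]
    Hx <- stats::integrate(function(s) hazard0(fam, s) + x * beta,
                           0, tt, rel.tol = 1e-12, abs.tol = 1e-14,
                           subdivisions = 2000L)$value
    if (ds$event[i] == 1L)
      log(hazard0(fam, tt) + x * beta) - Hx
    else -Hx
  }, numeric(1)))
}

# independent product-limit estimator: naive loop over event times
naive_km <- function(time, event, at) {
  s <- 1
  for (u in sort(unique(time[event == 1L]))) {
    if (u > at) break
    n_risk <- sum(time >= u)
    d <- sum(time == u & event == 1L)
    s <- s * (1 - d / n_risk)
  }
  s
}

# independent Lin-Ying estimating equation: O(n^2) direct evaluation
naive_linying <- function(ds) {
  tt <- ds$time; ev <- ds$event; x <- ds$arm
  num <- 0
  for (i in which(ev == 1L)) {
    at_risk <- tt >= tt[i]
    num <- num + (x[i] - mean(x[at_risk]))
  }
  s <- sort(unique(tt))
  edges <- c(0, s)
  den <- 0
  for (j in seq_along(s)) {
    at_risk <- tt >= s[j]
    Y1 <- sum(x[at_risk] == 1L); Y0 <- sum(x[at_risk] == 0L)
    if (Y1 + Y0 > 0)
      den <- den + (s[j] - edges[j]) * Y1 * Y0 / (Y1 + Y0)
  }
  num / den
}
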