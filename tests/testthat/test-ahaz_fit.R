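test_that("log-likelihood matches closed forms for single records", {
  ex <- baseline_family("exponential", 0.02)
  cens <- survival_dataset(2, 0, 1, require_two_arms = FALSE)
  # censored treated record: log S_x(2) = -2 * (0.02 + 0.01)
  expect_equal(ahaz_loglik(cens, ex, 0.01), -0.06)
  ev <- survival_dataset(2, 1, 1, require_two_arms = FALSE)
  # event: log(h0 + beta) - H_x = log(0.03) - 0.06
  expect_equal(ahaz_loglik(ev, ex, 0.01), log(0.03) - 0.06)
})

test_that("at beta = 0 the likelihood collapses to the pooled one-sample likelihood", {
  ds <- toy_dataset(seed = 3)
  for (fam in family_zoo()) {
    pooled <- sum(ds$event * log(hazard0(fam, ds$time))) -
      sum(cumhaz0(fam, ds$time))
    expect_equal(ahaz_loglik(ds, fam, 0), pooled, info = fam$name)
  }
})

test_that("likelihood returns -Inf outside the model domain", {
  ex <- baseline_family("exponential", 0.02)
  ds <- survival_dataset(c(1, 2), c(1, 1), c(0, 1))
  expect_equal(ahaz_loglik(ds, ex, -0.02), -Inf)  # treated hazard 0 at event
  expect_equal(ahaz_loglik(ds, ex, -0.5), -Inf)
  expect_true(is.finite(ahaz_loglik(ds, ex, -0.019)))
})

test_that("likelihood agrees with a quadrature oracle for every family", {
  ds <- toy_dataset(seed = 8, n = 50)
  beta <- -0.004
  for (fam in family_zoo()) {
    expect_equal(ahaz_loglik(ds, fam, beta), quad_loglik(ds, fam, beta),
                 tolerance = 1e-6, info = fam$name)
  }
})

test_that("the exponential MLE equals the occurrence/exposure rates", {
  ds <- simulate_trial(simulation_design("exponential", 0.025,
                                         beta = -0.008,
                                         n_control = 800,
                                         n_treated = 1200,
                                         admin_time = 4, seed = 5))
  fit <- ahaz_fit(ds, "exponential")
  s0 <- summarize_arm(ds, 0); s1 <- summarize_arm(ds, 1)
  expect_equal(fit$family$theta[["lambda"]], s0$rate, tolerance = 1e-6)
  expect_equal(fit$beta, s1$rate - s0$rate, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("the LHR likelihood with slope 0 at the exponential MLE reproduces the exponential fit", {
  ds <- toy_dataset(seed = 12, n = 80)
  fit <- ahaz_fit(ds, "exponential")
  lhr0 <- baseline_family("lhr", c(fit$family$theta[["lambda"]], 0))
  expect_equal(ahaz_loglik(ds, lhr0, fit$beta), fit$loglik,
               tolerance = 1e-6)
})

test_that("maximized log-likelihood is invariant to a time rescale up to the Jacobian", {
  ds <- simulate_trial(simulation_design("lhr", c(0.02, 0.004),
                                         beta = -0.006,
                                         n_control = 400,
                                         n_treated = 600,
                                         admin_time = 4, accrual = 1,
                                         seed = 21))
  ds_m <- survival_dataset(ds$time * 12, ds$event, ds$arm)  # months
  fit_y <- ahaz_fit(ds, "lhr")
  fit_m <- ahaz_fit(ds_m, "lhr")
  d_events <- sum(ds$event)
  expect_equal(fit_m$loglik, fit_y$loglik - d_events * log(12),
               tolerance = 1e-4)
  # two independent optimizations: agreement to optimizer precision
  expect_equal(fit_m$beta, fit_y$beta / 12, tolerance = 1e-3)
})

test_that("the richer nested model never fits worse", {
  ds <- simulate_trial(simulation_design("gompertz", c(0.02, 0.1),
                                         beta = -0.005,
                                         n_control = 500,
                                         n_treated = 500,
                                         admin_time = 4, seed = 31))
  fit_gz <- ahaz_fit(ds, "gompertz")
  fit_gg <- ahaz_fit(ds, "gammagompertz")
  expect_gte(fit_gg$loglik, fit_gz$loglik - 1e-4)
})

test_that("BIC follows the subject-count definition", {
  # -2*(-2200.9) + 3*ln(7020) = 4428.37
  expect_equal(-2 * (-2200.9) + 3 * log(7020), 4428.37,
               tolerance = 5e-3)
  expect_equal(4418.7 + 2 * log(7020), 4436.4, tolerance = 5e-2)
  expect_equal(4401.7 + 4 * log(7020), 4437.1, tolerance = 5e-2)
  ds <- toy_dataset(seed = 4, n = 60)
  fit <- ahaz_fit(ds, "weibull")
  expect_equal(fit$bic,
               fit$minus2loglik + fit$n_params * log(nrow(ds)))
  expect_equal(BIC(fit), fit$bic)
  expect_equal(minus2loglik(fit), -2 * as.numeric(logLik(fit)))
})

test_that("predictions are additive in the hazard and anchored at S(0) = 1", {
  ds <- simulate_trial(simulation_design("lhr", c(0.02, 0.004),
                                         beta = -0.006,
                                         n_control = 300,
                                         n_treated = 500,
                                         admin_time = 4, seed = 9))
  fit <- ahaz_fit(ds, "lhr")
  tg <- c(0, 0.5, 1.5, 3)
  h0 <- predict(fit, tg, arm = 0L, quantity = "hazard")
  h1 <- predict(fit, tg, arm = 1L, quantity = "hazard")
  expect_equal(h1$estimate - h0$estimate, rep(fit$beta, length(tg)))
  # control-arm predictions are pure baseline quantities
  expect_equal(h0$estimate, hazard0(fit$family, tg))
  s0 <- predict(fit, tg, arm = 0L, quantity = "survival")
  expect_equal(s0$estimate, survival0(fit$family, tg))
  expect_equal(unlist(s0[s0$time == 0, c("estimate", "lower", "upper")],
                      use.names = FALSE), c(1, 1, 1))
  f1 <- predict(fit, tg, arm = 1L, quantity = "density")
  s1 <- predict(fit, tg, arm = 1L, quantity = "survival")
  expect_equal(f1$estimate, h1$estimate * s1$estimate)
  expect_true(all(s0$lower <= s0$estimate & s0$estimate <= s0$upper))
  expect_warning(predict(fit, 3 * max(ds$time), arm = 0L),
                 "extrapolat")
})

test_that("a wrong family name or unfittable input fails loudly", {
  ds <- toy_dataset(seed = 2)
  expect_error(ahaz_fit(ds, "cauchy"))
  expect_error(ahaz_fit(ds, "piecewise", cutpoints = c(3, 1)),
               "increasing")
})

test_that("fit reports serialize to JSON with the expected fields", {
  ds <- toy_dataset(seed = 6, n = 60)
  fit <- ahaz_fit(ds, "exponential")
  path <- withr::local_tempfile(fileext = ".json")
  fit_report(fit, path = path)
  rep <- jsonlite::read_json(path)
  expect_equal(rep$model, "exponential")
  expect_equal(rep$beta, fit$beta, tolerance = 1e-12)
  expect_equal(rep$bic, fit$bic, tolerance = 1e-12)
  # the Lin-Ying report carries no likelihood-based fields
  # the toy data give a beta CI crossing 0, so the inverted NNT
  # interval is flagged as unbounded
  rep_ly <- suppressWarnings(fit_report(fit_linying(ds)))
  expect_false(any(c("minus2loglik", "bic") %in% names(rep_ly)))
})
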