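test_that("simulation is reproducible and leaves the caller's RNG alone", {
  des <- empareg_like_design(seed = 3)
  set.seed(999)
  before <- runif(1)
  set.seed(999)
  ds1 <- simulate_trial(des)
  after <- runif(1)
  ds2 <- simulate_trial(des)
  expect_identical(ds1, ds2)              # bit-for-bit
  expect_identical(before, after)         # global RNG untouched
  ds3 <- simulate_trial(empareg_like_design(seed = 4))
  expect_false(identical(ds1$time, ds3$time))
})

test_that("the shipped trial scenario has the intended shape", {
  des <- empareg_like_design(seed = 1)
  ds <- simulate_trial(des)
  expect_equal(summarize_arm(ds, 0)$n, 2333L)
  expect_equal(summarize_arm(ds, 1)$n, 4687L)
  expect_true(all(ds$time <= 4.6))
  # heavy censoring, as in a cardiovascular outcome trial
  cens_frac <- 1 - mean(ds$event)
  expect_gt(cens_frac, 0.88)
  expect_lt(cens_frac, 0.97)
})

test_that("a treated-arm hazard of exactly zero yields no treated events", {
  des <- simulation_design("exponential", 0.02, beta = -0.02,
                           n_control = 200, n_treated = 200,
                           admin_time = 4, seed = 8)
  # a zero-hazard arm never fails: flagged as mass at infinity
  expect_warning(ds <- simulate_trial(des), "improper")
  expect_equal(summarize_arm(ds, 1)$events, 0L)
  expect_true(all(ds$time[ds$arm == 1] == 4))
  # below zero the design is rejected up front
  expect_error(simulation_design("exponential", 0.02, beta = -0.021,
                                 n_control = 10, n_treated = 10,
                                 admin_time = 4),
               "negative")
})

test_that("the generic root-finding sampler matches closed-form inversion", {
  n <- 2000L
  lam <- 0.35; shift <- 0.1
  # replicate the internal draw: one Exp(1) variate per subject
  E <- withr::with_seed(20, rexp(n))
  T_closed <- E / (lam + shift)
  # weibull with shape 1 equals the exponential, but a nonzero shift
  # forces the generic bisection path
  fam <- baseline_family("weibull", c(1, 1 / lam))
  T_generic <- withr::with_seed(20,
    ahazpar:::.sample_event_times(fam, shift, n))
  expect_equal(T_generic, T_closed, tolerance = 1e-9)
  # and the root actually inverts the cumulative hazard: H0(T) + c*T = E
  gg <- baseline_family("gammagompertz", c(0.3, 0.5, 0.7))
  Tg <- withr::with_seed(21, ahazpar:::.sample_event_times(gg, 0.05, 500L))
  Eg <- withr::with_seed(21, rexp(500L))
  expect_equal(cumhaz0(gg, Tg) + 0.05 * Tg, Eg, tolerance = 1e-8)
})

test_that("an improper total hazard is censored administratively with a warning", {
  # gompertz with negative slope: finite total hazard, cure fraction
  des <- simulation_design("gompertz", c(0.1, -1.5), beta = 0,
                           n_control = 300, n_treated = 300,
                           admin_time = 4, seed = 33)
  expect_warning(ds <- simulate_trial(des), "improper")
  expect_true(all(ds$time <= 4))
  expect_true(any(ds$event == 0))
})

test_that("empirical survival of a simulated arm matches the design survival", {
  des <- simulation_design("lhr", c(0.15, 0.1), beta = -0.05,
                           n_control = 100000, n_treated = 100000,
                           admin_time = 20, seed = 50)
  ds <- simulate_trial(des)
  for (arm in 0:1) {
    tt <- ds$time[ds$arm == arm & ds$event == 1]
    tg <- seq(0.5, 10, by = 0.5)
    emp <- vapply(tg, function(u) mean(ds$time[ds$arm == arm] > u),
                  numeric(1))
    shift <- arm * des$beta
    theo <- exp(-(cumhaz0(des$family, tg) + shift * tg))
    expect_lt(max(abs(emp - theo)), 0.01)   # KS-style bound at n = 1e5
  }
})

test_that("recovery studies summarize bias, SE calibration and coverage", {
  des <- simulation_design("exponential", 0.05, beta = -0.015,
                           n_control = 1500, n_treated = 1500,
                           admin_time = 4, seed = 60)
  rs <- recovery_study(des, reps = 100)
  expect_equal(nrow(rs$replicates), 100L)
  expect_equal(rs$n_nonconverged, 0L)
  expect_lt(abs(rs$bias), 3 * rs$mcse_bias + 1e-12)
  expect_gt(rs$coverage, 0.85)
  # the empirical SE carries ~7% Monte-Carlo error at 100 replicates
  expect_gt(rs$mean_model_se / rs$empirical_se, 0.75)
  expect_lt(rs$mean_model_se / rs$empirical_se, 1.3)
  # reproducible under the same design seed
  rs2 <- recovery_study(des, reps = 100)
  expect_identical(rs$replicates$beta_hat, rs2$replicates$beta_hat)
})
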