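test_that("hazard and survival match closed forms at spot-check points", {
  expect_equal(hazard0(baseline_family("exponential", 0.02), 5), 0.02)
  expect_equal(hazard0(baseline_family("lhr", c(0.0211, 0.00419)), 10),
               0.0211 + 0.00419 * 10)  # = 0.0630
  expect_equal(hazard0(baseline_family("gompertz", c(0.02, 0.05)), 0),
               0.02)
  expect_equal(survival0(baseline_family("exponential", 0.02), 3.1),
               exp(-0.062))
  pw <- baseline_family("piecewise", c(0.01, 0.03), cutpoints = 1)
  expect_equal(survival0(pw, 2), exp(-(0.01 * 1 + 0.03 * 1)))
  for (fam in family_zoo())
    expect_equal(survival0(fam, 0), 1, info = fam$name)
})

test_that("invalid family parameters are rejected", {
  expect_error(baseline_family("exponential", -1), "lambda")
  expect_error(baseline_family("lhr", c(0, 0)), "a \\+ b > 0")
  expect_error(baseline_family("weibull", c(1, -2)), "scale")
  expect_error(baseline_family("gammagompertz", c(0.1, -0.2, 0.5)),
               "b > 0")
  expect_error(baseline_family("piecewise", c(0.1, 0.2)), "cutpoints")
  expect_error(baseline_family("piecewise", c(0.1, 0.2, 0.3),
                               cutpoints = c(2, 1)), "increasing")
})

test_that("density identity f0 = h0 * S0 holds for all families on a grid", {
  tg <- c(0, 0.05, 0.5, 1, 2.5, 4, 7, 15)
  for (fam in family_zoo())
    expect_equal(density0(fam, tg), hazard0(fam, tg) * survival0(fam, tg),
                 info = fam$name)
})

test_that("closed-form cumulative hazards agree with quadrature of h0", {
  tg <- c(0.3, 1, 2.7, 4.9, 9)
  for (fam in family_zoo()) {
    expect_equal(cumhaz0(fam, tg), quad_cumhaz(fam, tg),
                 tolerance = 1e-8, info = fam$name)
    expect_equal(-log(survival0(fam, tg)), quad_cumhaz(fam, tg),
                 tolerance = 1e-8, info = fam$name)
  }
})

test_that("survival is nonincreasing from S0(0) = 1", {
  tg <- seq(0, 20, by = 0.1)
  for (fam in family_zoo()) {
    s <- survival0(fam, tg)
    expect_equal(s[1], 1, info = fam$name)
    expect_true(all(diff(s) <= 1e-15), info = fam$name)
  }
})

test_that("closed-form modes match their textbook expressions", {
  expect_equal(mode0(baseline_family("exponential", 0.7)), 0)
  expect_equal(mode0(baseline_family("lhr", c(0.0211, 0.00419))),
               (sqrt(0.00419) - 0.0211) / 0.00419)  # 10.41 y
  expect_equal(mode0(baseline_family("weibull", c(1.5, 10))),
               10 * (0.5 / 1.5)^(1 / 1.5))          # 4.807 y
  expect_equal(mode0(baseline_family("gompertz", c(0.02, 0.05))),
               log(0.05 / 0.02) / 0.05)             # 18.33 y
  expect_equal(mode0(baseline_family("loglogistic", c(2, 5))),
               5 * (1 / 3)^(1 / 2))
  # boundary cases sit at 0
  expect_equal(mode0(baseline_family("weibull", c(0.8, 10))), 0)
  expect_equal(mode0(baseline_family("gompertz", c(0.2, 0.1))), 0)
  expect_equal(mode0(baseline_family("lhr", c(0.9, 0.1))), 0)
})

test_that("closed-form modes agree with grid-search maximization of f0", {
  for (fam in family_zoo()) {
    m <- mode0(fam)
    up <- max(1, 3 * m, 30)
    tg <- seq(0, up, length.out = 200001L)
    m_grid <- tg[which.max(density0(fam, tg))]
    expect_lt(abs(m - m_grid), 1e-4)
  }
})

test_that("Gamma-Gompertz converges to Gompertz as the frailty variance vanishes", {
  gz <- baseline_family("gompertz", c(0.02, 0.09))
  tg <- seq(0, 10, by = 0.5)
  for (s2 in c(1e-4, 1e-6)) {
    gg <- baseline_family("gammagompertz", c(0.02, 0.09, s2))
    expect_equal(hazard0(gg, tg), hazard0(gz, tg), tolerance = 1e-3)
    expect_equal(survival0(gg, tg), survival0(gz, tg), tolerance = 1e-3)
  }
  gg <- baseline_family("gammagompertz", c(0.02, 0.09, 1e-8))
  expect_equal(hazard0(gg, tg), hazard0(gz, tg), tolerance = 1e-6)
  expect_equal(mode0(gg), mode0(gz), tolerance = 1e-4)
})

test_that("degenerate parameter values collapse to the exponential", {
  tg <- c(0, 0.5, 1, 2, 5)
  ex <- baseline_family("exponential", 0.04)
  lhr0 <- baseline_family("lhr", c(0.04, 0))
  expect_equal(hazard0(lhr0, tg), hazard0(ex, tg))
  expect_equal(survival0(lhr0, tg), survival0(ex, tg))
  wb1 <- baseline_family("weibull", c(1, 1 / 0.04))
  expect_equal(hazard0(wb1, tg), hazard0(ex, tg))
  expect_equal(survival0(wb1, tg), survival0(ex, tg))
})

test_that("distribution functions agree with an independent survival-distribution library", {
  skip_if_not_installed("flexsurv")
  tg <- c(0.2, 1, 3, 7)
  gz <- baseline_family("gompertz", c(0.02, 0.11))
  expect_equal(hazard0(gz, tg), flexsurv::hgompertz(tg, 0.11, 0.02),
               tolerance = 1e-12)
  expect_equal(survival0(gz, tg),
               flexsurv::pgompertz(tg, 0.11, 0.02, lower.tail = FALSE),
               tolerance = 1e-12)
  ll <- baseline_family("loglogistic", c(1.8, 9))
  expect_equal(survival0(ll, tg),
               flexsurv::pllogis(tg, shape = 1.8, scale = 9,
                                 lower.tail = FALSE),
               tolerance = 1e-12)
})
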