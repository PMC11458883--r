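test_that("survival curves evaluate their closed forms and start at 1", {
  expect_equal(surv_prob(survival_curve("exponential", rate = 0.5), 2),
               exp(-1), tolerance = 1e-12)
  expect_equal(surv_prob(survival_curve("exponential", rate = 0.5), 2),
               0.367879, tolerance = 1e-5)
  # shape-1 Weibull reduces to the exponential with rate = 1/scale
  expect_equal(surv_prob(survival_curve("weibull", shape = 1, scale = 2), 2),
               surv_prob(survival_curve("exponential", rate = 0.5), 2),
               tolerance = 1e-12)
  for (cv in list(survival_curve("exponential", rate = 2),
                  survival_curve("weibull", shape = 1.5, scale = 3),
                  survival_curve("lognormal", meanlog = 0.5, sdlog = 1),
                  survival_curve("loglogistic", shape = 2, scale = 1),
                  survival_curve("gompertz", shape = 0.2, rate = 0.5))) {
    expect_equal(surv_prob(cv, 0), 1)
  }
})

test_that("every family is non-increasing in [0, 1] on a dense 80-year grid", {
  withr::local_seed(42)
  for (i in 1:25) {
    cv <- random_curve()
    s <- surv_prob(cv, grid_80y)
    expect_true(all(s >= 0 & s <= 1), info = format(cv))
    expect_true(all(diff(s) <= 1e-12), info = format(cv))
    expect_equal(s[1], 1)
  }
})

test_that("invalid parameters and domains are rejected", {
  expect_error(survival_curve("exponential", rate = -1), "invalid parameters")
  expect_error(survival_curve("weibull", shape = 0, scale = 2), "invalid")
  expect_error(survival_curve("weibull", shape = 1), "requires parameters")
  expect_error(survival_curve("lognormal", meanlog = 0, sdlog = -1), "invalid")
  expect_error(surv_prob(survival_curve("exponential", rate = 1), -0.1),
               "non-negative")
  expect_error(apply_hazard_ratio(survival_curve("exponential", rate = 1), 0),
               "positive")
  expect_error(apply_hazard_ratio(survival_curve("exponential", rate = 1), -2),
               "positive")
})

test_that("hazard ratios act as a power on survival", {
  wb <- survival_curve("weibull", shape = 1.4, scale = 4)
  tt <- seq(0, 20, by = 0.5)
  # identity
  expect_equal(surv_prob(apply_hazard_ratio(wb, 1), tt), surv_prob(wb, tt))
  # S = 0.8, hr = 2 -> 0.64
  t80 <- surv_quantile(wb, 0.8)
  expect_equal(surv_prob(apply_hazard_ratio(wb, 2), t80), 0.64,
               tolerance = 1e-9)
  # exponential PH algebra: rate scales exactly
  ex <- apply_hazard_ratio(survival_curve("exponential", rate = 0.3), 2)
  expect_equal(ex$params[["rate"]], 0.6)
  expect_equal(surv_prob(ex, tt),
               surv_prob(survival_curve("exponential", rate = 0.6), tt))
  # hr > 1 lowers survival pointwise; hr < 1 raises it
  expect_true(all(surv_prob(apply_hazard_ratio(wb, 1.7), tt) <=
                    surv_prob(wb, tt)))
  expect_true(all(surv_prob(apply_hazard_ratio(wb, 0.6), tt) >=
                    surv_prob(wb, tt)))
})

test_that("restricted mean is a valid quadrature and monotone in the hazard ratio", {
  expect_identical(restricted_mean(survival_curve("exponential", rate = 1), 0), 0)
  expect_equal(restricted_mean(survival_curve("exponential", rate = 1), 40),
               1, tolerance = 2e-3)
  expect_equal(
    restricted_mean(survival_curve("weibull", shape = 1, scale = 2), 40,
                    step = 1 / 52),
    restricted_mean(survival_curve("exponential", rate = 0.5), 40,
                    step = 1 / 52),
    tolerance = 1e-10)
  ln <- survival_curve("lognormal", meanlog = 0.7, sdlog = 0.8)
  rm_by_hr <- vapply(c(0.5, 1, 2), function(h) {
    restricted_mean(apply_hazard_ratio(ln, h), 40, step = 1 / 52)
  }, numeric(1))
  expect_true(all(diff(rm_by_hr) < 0))
})

test_that("cycle event probabilities are conditional per-cycle event risks", {
  delta <- 14 / 365.25
  ex <- survival_curve("exponential", rate = 0.8)
  q <- cycle_event_prob(ex, 0:51, delta)
  # memorylessness: identical across cycles
  expect_equal(q, rep(1 - exp(-0.8 * delta), 52), tolerance = 1e-12)
  # cumulative product identity: prod(1 - q) telescopes to S(U delta)
  wb <- survival_curve("weibull", shape = 1.6, scale = 2.5)
  qw <- cycle_event_prob(wb, 0:199, delta)
  expect_equal(prod(1 - qw), surv_prob(wb, 200 * delta), tolerance = 1e-12)
  expect_true(all(qw >= 0 & qw <= 1))
  # exhausted survival floor -> certain event
  fast <- survival_curve("exponential", rate = 100)
  expect_equal(cycle_event_prob(fast, 50, 1), 1)
  # degenerate flat interval -> no events (gompertz with negative shape
  # plateaus; probe far in the tail where S is constant to double precision)
  gp <- survival_curve("gompertz", shape = -2, rate = 0.1)
  expect_equal(cycle_event_prob(gp, 5000, 1), 0, tolerance = 1e-9)
})
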