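test_that("km_points validates its invariants", {
  expect_s3_class(km_points(c(1, 2), c(0.9, 0.8)), "km_points")
  expect_error(km_points(c(2, 1), c(0.9, 0.8)), "ascending")
  expect_error(km_points(c(1, 2), c(0.8, 0.9)), "non-increasing")
  expect_error(km_points(c(1, 2), c(0.9, 1.2)), "\\[0, 1\\]")
  expect_error(km_points(c(-1, 2), c(1, 0.8)), "non-negative")
  expect_error(km_points(c(1, 2), c(0.9, 0.8), n_at_risk = c(10, -3)),
               "positive")
})

test_that("noiseless summary points recover generating parameters", {
  tm <- seq(0.1, 12, by = 0.1)
  # exponential: closed-form WLS, near machine precision
  f <- fit_parametric(km_points(tm, exp(-0.4 * tm)), "exponential")
  expect_equal(f$curve$params[["rate"]], 0.4, tolerance = 1e-6)
  truth <- list(
    exponential = survival_curve("exponential", rate = 0.7),
    weibull = survival_curve("weibull", shape = 1.6, scale = 3.2),
    lognormal = survival_curve("lognormal", meanlog = 0.8, sdlog = 0.7),
    loglogistic = survival_curve("loglogistic", shape = 1.9, scale = 2.4),
    gompertz = survival_curve("gompertz", shape = 0.25, rate = 0.3)
  )
  for (fam in names(truth)) {
    km <- km_points(tm, surv_prob(truth[[fam]], tm))
    fit <- fit_parametric(km, fam)
    rel <- abs(fit$curve$params - truth[[fam]]$params) /
      abs(truth[[fam]]$params)
    expect_true(all(rel < 1e-4), info = fam)
    expect_lt(fit$rss, 1e-8)
  }
})

test_that("degenerate summary inputs are rejected", {
  expect_error(fit_parametric(km_points(c(1, 2), c(0.9, 0.8)), "weibull"),
               "too few")
  expect_error(fit_parametric(km_points(c(1, 2, 3), c(1, 1, 1)), "exponential"),
               "no events")
  expect_error(fit_parametric(data.frame(time_years = c(1, 2, 3),
                                         survival = c(0.9, 0.95, 0.8)),
                              "exponential"),
               "non-increasing")
})

test_that("parameters are recovered from simulated KM data", {
  truth <- survival_curve("weibull", shape = 1.5, scale = 3)
  km <- generate_km_dataset(truth, n = 1000, seed = 74)
  fit <- fit_parametric(km, "weibull")
  expect_equal(fit$curve$params[["shape"]], 1.5, tolerance = 0.1)
  expect_equal(fit$curve$params[["scale"]], 3, tolerance = 0.1)
  # independent route: flexsurv maximum likelihood on the raw event times
  withr::local_seed(74)
  ml <- flexsurv::flexsurvreg(
    survival::Surv(surv_quantile(truth, runif(1000)), rep(1, 1000)) ~ 1,
    dist = "weibull")
  expect_equal(unname(fit$curve$params[["shape"]]),
               unname(ml$res["shape", "est"]), tolerance = 0.1)
  expect_equal(unname(fit$curve$params[["scale"]]),
               unname(ml$res["scale", "est"]), tolerance = 0.1)
})

test_that("stochastic parameter recovery holds across seeds", {
  shapes <- vapply(1:20, function(s) {
    km <- generate_km_dataset(survival_curve("weibull", shape = 1.5, scale = 3),
                              n = 1000, seed = s)
    fit_parametric(km, "weibull")$curve$params[["shape"]]
  }, numeric(1))
  expect_true(all(abs(shapes - 1.5) / 1.5 < 0.15))
  expect_equal(median(shapes), 1.5, tolerance = 0.05)
})

test_that("family selection ranks the generating family first", {
  tm <- seq(0.1, 10, by = 0.1)
  wb <- survival_curve("weibull", shape = 2, scale = 3)
  ranked <- select_family(km_points(tm, surv_prob(wb, tm)),
                          c("exponential", "weibull"))
  expect_equal(ranked$family[1], "weibull")
  expect_lt(ranked$aic[ranked$family == "weibull"],
            ranked$aic[ranked$family == "exponential"])
  # single candidate
  one <- select_family(km_points(tm, exp(-0.5 * tm)), "exponential")
  expect_equal(nrow(one), 1L)
  expect_equal(one$family, "exponential")
  # exponential data fits exponential and shape-1 weibull identically
  # (criterion ties at -Inf); precedence puts exponential first
  tie <- select_family(km_points(tm, exp(-0.5 * tm)),
                       c("weibull", "exponential"))
  expect_equal(tie$family[1], "exponential")
})

test_that("a failing family is skipped with a warning, all failing errors", {
  # 2 usable points cannot support a 2-parameter family
  km2 <- km_points(c(1, 2), c(0.8, 0.6))
  expect_warning(r2 <- select_family(km2, c("exponential", "weibull")),
                 "failed to fit")
  expect_equal(r2$family, "exponential")
  expect_error(suppressWarnings(select_family(km2, "weibull")),
               "all candidate families failed")
})

test_that("tidy and glance methods expose estimates and fit statistics", {
  tm <- seq(0.25, 8, by = 0.25)
  fit <- fit_parametric(km_points(tm, exp(-0.6 * tm)), "exponential")
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_equal(td$term, "rate")
  gl <- glance(fit)
  expect_named(gl, c("family", "n", "n_params", "rss", "aic"))
  expect_equal(gl$n_params, 1L)
})
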