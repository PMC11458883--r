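test_that("sequence and line-model constructors enforce their invariants", {
  expect_error(treatment_sequence(character(0)), "between 1 and 4")
  expect_error(treatment_sequence(c("A", "B", "C", "D", "E")), "between 1 and 4")
  expect_error(treatment_sequence(c("A", "A")), "duplicate")
  expect_silent(treatment_sequence(c("A", "A"), allow_repeat = TRUE))
  cv <- survival_curve("exponential", rate = 1)
  expect_error(line_model("A", cv, attrition = 1.2), "\\[0, 1\\]")
  expect_error(simulation_settings(n_cycles = 0), "positive integer")
  expect_error(simulation_settings(cycle_length = 0), "positive")
})

test_that("a zero-hazard line keeps the whole cohort alive to the horizon", {
  # gompertz with strongly negative shape plateaus near 1: effectively no events
  flat <- survival_curve("gompertz", shape = -1e3, rate = 1e-9)
  tr <- simulate_sequence(line_model("A", flat, 0.7), short_settings())
  expect_equal(tr$alive[nrow(tr)], 1, tolerance = 1e-9)
  expect_equal(tr$dead[nrow(tr)], 0, tolerance = 1e-9)
})

test_that("single exponential line matches its mean within one cycle length", {
  st <- simulation_settings() # 40-year horizon
  tr <- simulate_sequence(
    line_model("A", survival_curve("exponential", rate = 0.5), 0), st)
  expect_equal(line_expected_times(tr)$years, 2, tolerance = st$cycle_length)
})

test_that("multi-line OS converges to the exponential closed form under cycle refinement", {
  means <- c(2, 1)
  rates <- 1 / means
  oracle <- oracle_exponential_os(means, c(0.7, 0.7)) # 2.7
  expect_equal(oracle, 2.7)
  st <- simulation_settings()
  os1 <- overall_survival_years(
    simulate_sequence(exp_lines(rates, c(0.7, 0.7)), st))
  expect_equal(os1, oracle, tolerance = 0.08)
  # Richardson-style refinement: error shrinks roughly with the cycle length
  errs <- vapply(c(1, 2, 4), function(f) {
    stf <- simulation_settings(cycle_length = st$cycle_length / f,
                               n_cycles = st$n_cycles * f)
    abs(overall_survival_years(
      simulate_sequence(exp_lines(rates, c(0.7, 0.7)), stf)) - oracle)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], errs[1] / 3)
  # four lines, uneven attritions
  means4 <- c(3, 1.5, 0.8, 0.4)
  att4 <- c(0.8, 0.6, 0.5, 0)
  os4 <- overall_survival_years(
    simulate_sequence(exp_lines(1 / means4, att4), st))
  expect_equal(os4, oracle_exponential_os(means4, att4), tolerance = 0.1)
})

test_that("attrition boundaries behave as expected", {
  st <- short_settings(522L) # 20 years
  rates <- c(1, 2, 4)
  # no attrition: later lines never occupied
  tr0 <- simulate_sequence(exp_lines(rates, c(0, 0, 0)), st)
  expect_equal(max(tr0$pf_line2), 0)
  expect_equal(max(tr0$pf_line3), 0)
  # full attrition in terminal mode: OS is exactly the per-line sum
  tr1 <- simulate_sequence(exp_lines(rates, c(1, 1, 1)), st)
  expect_equal(overall_survival_years(tr1),
               sum(line_expected_times(tr1)$years), tolerance = 1e-9)
})

test_that("mass is conserved and mortality monotone for random curve libraries", {
  st <- short_settings(261L)
  withr::local_seed(2024)
  for (draw in 1:50) {
    K <- sample(1:4, 1)
    models <- purrr::map(seq_len(K), function(k) {
      line_model(paste0("L", k), random_curve(), runif(1))
    })
    tr <- simulate_sequence(models, st)
    total <- tr$alive + tr$dead
    expect_true(all(abs(total - 1) < 1e-9))
    expect_true(all(diff(tr$dead) >= -1e-12))
    expect_true(all(diff(tr$alive) <= 1e-12))
    expect_equal(tr$pf_line1[1], 1)
  }
})

test_that("order sensitivity of OS is fully captured by entry-probability weighting", {
  st <- simulation_settings()
  a <- c(0.6, 0.6, 0.6)
  rates <- c(0.4, 1.5, 2.5)
  # swapping lines re-weights their conditional means by entry probability:
  # the engine matches the closed form under either order
  os_ab <- overall_survival_years(
    simulate_sequence(exp_lines(rates, a), st))
  os_ba <- overall_survival_years(
    simulate_sequence(exp_lines(rates[c(2, 1, 3)], a), st))
  expect_equal(os_ab, oracle_exponential_os(1 / rates, a), tolerance = 0.02)
  expect_equal(os_ba, oracle_exponential_os(1 / rates[c(2, 1, 3)], a),
               tolerance = 0.02)
  # with full attrition every line is reached: OS is permutation-invariant
  os_full_1 <- overall_survival_years(
    simulate_sequence(exp_lines(rates, c(1, 1, 1)), st))
  os_full_2 <- overall_survival_years(
    simulate_sequence(exp_lines(rates[c(2, 1, 3)], c(1, 1, 1)), st))
  expect_equal(os_full_1, os_full_2, tolerance = 1e-6)
})

test_that("partitioned mode reduces to PFS-only when OS equals PFS", {
  pfs <- survival_curve("weibull", shape = 1.3, scale = 1.2)
  st <- short_settings(261L, final_line_mode = "partitioned_survival")
  m <- list(
    line_model("A", survival_curve("exponential", rate = 0.7), 0.8),
    line_model("B", pfs, 0.5, os_curve = pfs)
  )
  tr <- simulate_sequence(m, st)
  expect_equal(max(tr$post_progression), 0)
  total <- tr$alive + tr$dead
  expect_true(all(abs(total - 1) < 1e-9))
})

test_that("partitioned mode accrues post-progression time and conserves mass", {
  st <- short_settings(261L, final_line_mode = "partitioned_survival")
  m <- list(
    line_model("A", survival_curve("exponential", rate = 0.7), 0.8),
    line_model("B", survival_curve("exponential", rate = 2), 0.5,
               os_curve = survival_curve("exponential", rate = 0.8))
  )
  tr <- simulate_sequence(m, st)
  expect_gt(post_progression_years(tr), 0)
  expect_true(all(abs(tr$alive + tr$dead - 1) < 1e-9))
  out <- sequence_outcomes(tr)
  expect_equal(out$os_years,
               sum(out$per_line_years) + out$final_line_pp_years,
               tolerance = 1e-9)
  # missing OS curve is an error in this mode
  expect_error(
    simulate_sequence(list(line_model("A", survival_curve("exponential",
                                                          rate = 1), 0.5)),
                      st),
    "OS curve")
})

test_that("crossing PFS/OS curves are clamped with a warning", {
  st <- short_settings(130L, final_line_mode = "partitioned_survival")
  m <- list(line_model("A", survival_curve("exponential", rate = 0.5), 0,
                       os_curve = survival_curve("exponential", rate = 1)))
  expect_warning(tr <- simulate_sequence(m, st), "clamped")
  expect_equal(max(tr$post_progression), 0)
  st_strict <- short_settings(130L, final_line_mode = "partitioned_survival",
                              strict_curve_order = TRUE)
  expect_error(simulate_sequence(m, st_strict), "exceeds OS")
})

test_that("line models resolve from the curve library by line setting", {
  drd <- survival_curve("weibull", shape = 1.2, scale = 7)
  rd <- survival_curve("exponential", rate = 0.28)
  pd <- survival_curve("exponential", rate = 2.4)
  lib <- tibble::tibble(
    regimen = c("DRd", "Rd", "VMP", "Pd", "Kd"),
    line_setting = c("newly_diagnosed", "newly_diagnosed", "newly_diagnosed",
                     "double_refractory", "relapsed_refractory"),
    endpoint = "PFS",
    curve = list(drd, rd, NULL, pd, NULL),
    reference = c(NA, NA, "Rd", NA, NA),
    hr = c(NA, NA, 1.5, NA, NA)
  )
  lib$curve[[5]] <- survival_curve("exponential", rate = 1.4)
  seq1 <- treatment_sequence(c("DRd", "Kd", "Pd"))
  models <- build_line_models(seq1, lib, attrition_by_line = 0.7)
  expect_length(models, 3)
  expect_identical(models[[1]]$pfs_curve, drd)  # direct lookup
  expect_identical(models[[3]]$pfs_curve, pd)   # double-refractory fallback
  # reference + hr record equals apply_hazard_ratio of the reference curve
  mv <- build_line_models(treatment_sequence("VMP"), lib, 0.7)
  tt <- seq(0, 20, by = 0.25)
  expect_equal(surv_prob(mv[[1]]$pfs_curve, tt),
               surv_prob(apply_hazard_ratio(rd, 1.5), tt))
  # missing regimen errors with its name
  expect_error(build_line_models(treatment_sequence("EloRd"), lib, 0.7),
               "EloRd")
  # hazard-ratio table fallback
  hrt <- tibble::tibble(reference_regimen = "Rd", target_regimen = "VRd",
                        line_setting = "newly_diagnosed", hr = 0.8)
  mvr <- build_line_models(treatment_sequence("VRd"), lib, 0.7, hr_table = hrt)
  expect_equal(surv_prob(mvr[[1]]$pfs_curve, tt),
               surv_prob(apply_hazard_ratio(rd, 0.8), tt))
  # ambiguous double resolution
  hrt2 <- dplyr::bind_rows(hrt, tibble::tibble(
    reference_regimen = "DRd", target_regimen = "VRd",
    line_setting = "newly_diagnosed", hr = 0.9))
  expect_error(build_line_models(treatment_sequence("VRd"), lib, 0.7,
                                 hr_table = hrt2), "ambiguous")
})

test_that("eligibility validation flags off-setting regimens and notes", {
  # the optimal reference sequence is fully eligible
  expect_equal(nrow(validate_sequence(
    treatment_sequence(c("DRd", "PVd", "Kd", "Vd")))), 0L)
  # Pd is licensed only in the double-refractory setting: invalid in line 1
  f <- validate_sequence(treatment_sequence(c("Pd", "Kd")))
  expect_equal(f$severity, "violation")
  expect_match(f$message, "not licensed for line 1")
  # D in line 2 is invalid (double refractory starts at line 3)
  f2 <- validate_sequence(treatment_sequence(c("DRd", "D")))
  expect_true(any(f2$severity == "violation" & f2$line == 2))
  # VCd carries a not-approved note
  f3 <- validate_sequence(treatment_sequence(c("Rd", "VCd")))
  expect_true(any(f3$severity == "note" & f3$regimen == "VCd"))
  expect_error(validate_sequence(treatment_sequence("XYZ")), "unknown regimen")
})
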