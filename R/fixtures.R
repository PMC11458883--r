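#' Reference treatment sequences for transplant-ineligible myeloma in Portugal
#'
#' The five treatment sequences defined by the Portuguese expert panel
#' (September 2022): the four sequences most commonly used in clinical
#' practice and the panel's optimal sequence of choice.
#'
#' @return A list of [treatment_sequence()] objects with an attribute
#'   `role` (`"common"` or `"optimal"`) on each element.
#' @examples
#' purrr::map_chr(portugal_sequences(), "label")
#' @export
portugal_sequences <- function() {
  spec <- list(
    list(lines = c("VMP", "DRd", "Pd", "Kd"), role = "common"),
    list(lines = c("VMP", "DRd", "Kd", "Pd"), role = "common"),
    list(lines = c("Rd", "VCd", "D", "Pd"), role = "common"),
    list(lines = c("Rd", "VCd", "Pd", "D"), role = "common"),
    list(lines = c("DRd", "PVd", "Kd", "Vd"), role = "optimal")
  )
  purrr::map(spec, function(s) {
    seq <- treatment_sequence(s$lines)
    attr(seq, "role") <- s$role
    seq
  })
}

#' Regimen eligibility by line setting (Portugal, September 2022)
#'
#' Treatment regimens licensed in Portugal for transplant-ineligible
#' multiple myeloma patients, by the setting in which they may be used:
#' newly diagnosed (first line), relapsed/refractory (later lines), and
#' double refractory (third line onwards). VCd is listed for the
#' relapsed/refractory setting but carries a not-approved annotation.
#'
#' @return A tibble with columns `regimen`, `setting`, `approved`.
#' @export
portugal_eligibility <- function() {
  nd <- c("DRd", "DVMP", "Rd", "VRd", "VMP")
  rr <- c("DRd", "DVd", "Rd", "Vd", "VCd", "KRd", "Kd", "IRd", "PVd", "EloRd")
  dr <- c("D", "Pd", "IsaPd")
  out <- dplyr::bind_rows(
    tibble::tibble(regimen = nd, setting = "newly_diagnosed"),
    tibble::tibble(regimen = rr, setting = "relapsed_refractory"),
    tibble::tibble(regimen = dr, setting = "double_refractory")
  )
  out$approved <- !(out$regimen == "VCd" & out$setting == "relapsed_refractory")
  out
}

#' Reference per-line expected progression-free years per sequence
#'
#' The per-line expected progression-free durations (years, unconditional
#' per starting patient) and resulting overall survival reported for the
#' five Portuguese reference sequences. These are the calibration targets
#' used by [calibrate_exponential_library()]. Also shipped as
#' `inst/extdata/sequence_targets.tsv`.
#'
#' @return A tibble: `sequence`, `role`, `pfs_l1` ... `pfs_l4`, `os`.
#' @export
sequence_targets <- function() {
  tibble::tribble(
    ~sequence,          ~role,     ~pfs_l1, ~pfs_l2, ~pfs_l3, ~pfs_l4, ~os,
    "VMP+DRd+Pd+Kd",    "common",  1.97,    4.74,    0.46,    0.42,    7.59,
    "VMP+DRd+Kd+Pd",    "common",  1.97,    4.74,    0.72,    0.38,    7.81,
    "Rd+VCd+D+Pd",      "common",  4.13,    0.95,    0.71,    0.38,    6.17,
    "Rd+VCd+Pd+D",      "common",  4.13,    0.95,    0.46,    0.59,    6.13,
    "DRd+PVd+Kd+Vd",    "optimal", 7.48,    1.29,    0.71,    0.28,    9.76
  )
}

#' Calibrate an exponential curve library to per-line expected times
#'
#' Finds per-line exponential progression-free curves such that the cohort
#' engine reproduces a row of target unconditional per-line expected
#' progression-free years under given attrition fractions. The entry
#' probability of line `k` under full follow-up is
#' `e_k = prod(attrition[1..k-1])`, so the conditional mean is initialised
#' at `target_k / e_k` and rates at its reciprocal; a multiplicative
#' fixed-point iteration (at most `max_iter` engine evaluations) then
#' absorbs cycle discretization and horizon truncation until each
#' unconditional time matches its target within `tol` years.
#'
#' @param targets Numeric vector of per-line unconditional expected
#'   progression-free years (length 1-4); lines with target 0 are dropped.
#' @param attrition Per-line attrition fractions, recycled to the number of
#'   lines. Default 0.7.
#' @param settings A [simulation_settings()]; terminal-death mode is
#'   required (calibration constrains progression-free time only).
#' @param regimens Optional regimen names for the returned models.
#' @param tol Per-line absolute tolerance in years. Default 0.0025.
#' @param max_iter Maximum fixed-point iterations. Default 20.
#' @return A list of [line_model()] objects; calibration diagnostics
#'   (`achieved`, `iterations`, `residual`) are attached as attributes.
#' @examples
#' mods <- calibrate_exponential_library(c(2, 1), attrition = 0.7,
#'   settings = simulation_settings(n_cycles = 783))
#' @export
calibrate_exponential_library <- function(targets, attrition = 0.7,
                                          settings = simulation_settings(),
                                          regimens = NULL, tol = 0.0025,
                                          max_iter = 20L) {
  stopifnot(inherits(settings, "simulation_settings"))
  if (settings$final_line_mode != "terminal_death") {
    stop("calibration requires terminal-death mode", call. = FALSE)
  }
  targets <- as.numeric(targets)
  if (length(targets) < 1L || length(targets) > 4L || any(targets < 0)) {
    stop("'targets' must be 1-4 non-negative per-line times", call. = FALSE)
  }
  K <- length(targets)
  attrition <- rep_len(as.numeric(attrition), K)
  if (any(attrition < 0 | attrition > 1)) {
    stop("attrition fractions must lie in [0, 1]", call. = FALSE)
  }
  entry <- cumprod(c(1, attrition[-K]))
  if (any(targets > 0 & entry == 0)) {
    stop("infeasible targets: a line with zero entry probability has a positive target",
         call. = FALSE)
  }
  regimens <- regimens %||% paste0("line", seq_len(K))

  pos <- targets > 0
  cond_mean <- ifelse(pos, targets / entry, NA_real_)
  rates <- ifelse(pos, 1 / cond_mean, Inf)
  # a line with zero target contributes (essentially) no time: huge rate
  rates[!pos] <- 1e6

  build <- function(r) {
    purrr::map(seq_len(K), function(k) {
      line_model(regimens[k], survival_curve("exponential", rate = r[k]),
                 attrition[k])
    })
  }
  achieved <- NULL
  for (it in seq_len(max_iter)) {
    tr <- simulate_sequence(build(rates), settings)
    achieved <- line_expected_times(tr)$years
    resid <- achieved - targets
    if (all(abs(resid[pos]) <= tol)) {
      mods <- build(rates)
      attr(mods, "achieved") <- achieved
      attr(mods, "iterations") <- it
      attr(mods, "residual") <- resid
      return(mods)
    }
    # longer achieved time than targeted -> raise the hazard proportionally
    rates[pos] <- rates[pos] * (achieved[pos] / targets[pos])
  }
  stop(sprintf(
    "calibration did not converge in %d iterations; residuals: %s",
    max_iter, paste(sprintf("%.4f", achieved - targets), collapse = ", ")
  ), call. = FALSE)
}

#' Synthetic Kaplan-Meier dataset from a known curve
#'
#' Samples `n` event times from a survival curve by inversion, applies
#' independent uniform censoring calibrated so the expected censored
#' fraction equals `censor_frac` (the censoring bound `b` solves
#' `RMST(b)/b = censor_frac` for `C ~ U(0, b)`), and returns the
#' product-limit (Kaplan-Meier) estimate at event times.
#'
#' @param curve A [survival_curve()] (the generating truth).
#' @param n Number of simulated patients (>= 10).
#' @param censor_frac Target censored fraction, in `[0, 1)`. Default 0.
#' @param seed Integer seed. Default 20221101.
#' @return A [km_points()] tibble (`time_years`, `survival`, `n_at_risk`)
#'   with attributes `n_events` and `n_censored`.
#' @export
generate_km_dataset <- function(curve, n, censor_frac = 0, seed = 20221101) {
  stopifnot(inherits(curve, "survival_curve"))
  if (!is.numeric(n) || n < 10) stop("'n' must be at least 10", call. = FALSE)
  if (censor_frac < 0 || censor_frac >= 1) {
    stop("'censor_frac' must lie in [0, 1)", call. = FALSE)
  }
  n <- as.integer(n)
  withr::local_seed(as.integer(seed))
  event_times <- surv_quantile(curve, stats::runif(n))
  if (censor_frac > 0) {
    p_cens <- function(b) restricted_mean(curve, b, step = b / 2000) / b
    lo <- 1e-6
    hi <- 1
    while (p_cens(hi) > censor_frac && hi < 1e6) hi <- hi * 2
    b <- stats::uniroot(function(x) p_cens(x) - censor_frac, c(lo, hi),
                        tol = 1e-8)$root
    cens_times <- stats::runif(n, 0, b)
    obs <- pmin(event_times, cens_times)
    status <- as.integer(event_times <= cens_times)
  } else {
    obs <- event_times
    status <- rep(1L, n)
  }
  fit <- survival::survfit(survival::Surv(obs, status) ~ 1)
  sm <- summary(fit, censored = FALSE)
  keep <- sm$n.event > 0
  out <- km_points(sm$time[keep], sm$surv[keep], n_at_risk = sm$n.risk[keep])
  attr(out, "n_events") <- sum(status)
  attr(out, "n_censored") <- n - sum(status)
  out
}

#' Random curve library for property testing
#'
#' Generates a reproducible library of progression-free survival curves
#' with families sampled uniformly and parameters drawn uniformly from
#' plausible ranges. Every curve satisfies the survival-curve invariants by
#' construction.
#'
#' @param seed Integer seed.
#' @param n_regimens Number of regimens to generate.
#' @param setting Line setting assigned to the records.
#' @param param_ranges Named list of per-family parameter ranges; each entry
#'   is a named list of `c(min, max)` pairs. Defaults span means of roughly
#'   0.3-10 years.
#' @return A curve-library tibble as accepted by [build_line_models()].
#' @export
random_curve_library <- function(seed, n_regimens,
                                 setting = "newly_diagnosed",
                                 param_ranges = NULL) {
  param_ranges <- param_ranges %||% list(
    exponential = list(rate = c(0.1, 3)),
    weibull     = list(shape = c(0.6, 2.5), scale = c(0.3, 10)),
    lognormal   = list(meanlog = c(-1, 2), sdlog = c(0.3, 1.5)),
    loglogistic = list(shape = c(0.8, 3), scale = c(0.3, 10)),
    gompertz    = list(shape = c(0.01, 0.5), rate = c(0.1, 2))
  )
  if (n_regimens == 0) {
    return(tibble::tibble(regimen = character(), line_setting = character(),
                          endpoint = character(), curve = list(),
                          reference = character(), hr = numeric()))
  }
  withr::local_seed(as.integer(seed))
  fams <- sample(names(param_ranges), n_regimens, replace = TRUE)
  curves <- purrr::map(fams, function(fam) {
    rng <- param_ranges[[fam]]
    pars <- purrr::map_dbl(rng, function(r) stats::runif(1, r[1], r[2]))
    survival_curve(fam, pars)
  })
  tibble::tibble(
    regimen = sprintf("REG%02d", seq_len(n_regimens)),
    line_setting = setting,
    endpoint = "PFS",
    curve = curves,
    reference = NA_character_,
    hr = NA_real_
  )
}

#' Calibrated line models and curve library for a reference sequence
#'
#' Convenience wrappers around [calibrate_exponential_library()] for the
#' five reference sequences of [sequence_targets()]:
#' `reference_sequence_models()` returns calibrated [line_model()]s for one
#' sequence; `reference_curve_library()` returns the same calibration as a
#' curve-library tibble (one PFS record per regimen, at the line setting
#' implied by its position) suitable for [build_line_models()] or
#' [write_curve_library()].
#'
#' @param label A sequence label from [sequence_targets()].
#' @param attrition Per-line attrition fractions. Default 0.7.
#' @param settings A [simulation_settings()] (terminal-death mode).
#' @return For `reference_sequence_models()`, a list of [line_model()] with
#'   calibration diagnostics attached; for `reference_curve_library()`, a
#'   curve-library tibble.
#' @export
reference_sequence_models <- function(label, attrition = 0.7,
                                      settings = simulation_settings()) {
  tg <- sequence_targets()
  row <- tg[tg$sequence == label, ]
  if (nrow(row) != 1) {
    stop(sprintf("unknown reference sequence '%s'", label), call. = FALSE)
  }
  seqs <- portugal_sequences()
  sq <- seqs[[match(label, purrr::map_chr(seqs, "label"))]]
  calibrate_exponential_library(
    targets = unlist(row[, c("pfs_l1", "pfs_l2", "pfs_l3", "pfs_l4")]),
    attrition = attrition, settings = settings, regimens = sq$lines
  )
}

#' @rdname reference_sequence_models
#' @export
reference_curve_library <- function(label, attrition = 0.7,
                                    settings = simulation_settings()) {
  mods <- reference_sequence_models(label, attrition, settings)
  rows <- purrr::imap(mods, function(m, k) {
    allowed <- line_settings_for(k)
    elig <- portugal_eligibility()
    st <- allowed[allowed %in% elig$setting[elig$regimen == m$regimen]]
    tibble::tibble(
      regimen = m$regimen, line_setting = st[1], endpoint = "PFS",
      curve = list(m$pfs_curve), reference = NA_character_, hr = NA_real_
    )
  })
  dplyr::bind_rows(rows)
}
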