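# Shared fixtures and independent oracles.

# Closed-form expected overall survival for exponential lines under full
# follow-up: OS = sum_k (prod_{j<k} a_j) * c_k, with c_k the conditional
# (per-entrant) mean of line k. Independent of the cohort engine.
oracle_exponential_os <- function(cond_means, attritions) {
  k <- length(cond_means)
  entry <- cumprod(c(1, attritions[seq_len(k - 1)]))
  sum(entry * cond_means)
}

# Short-horizon settings for property tests (10 years of two-week cycles).
short_settings <- function(n_cycles = 261L, ...) {
  simulation_settings(n_cycles = n_cycles, ...)
}

exp_lines <- function(rates, attritions, regimens = NULL) {
  regimens <- regimens %||% paste0("L", seq_along(rates))
  purrr::map(seq_along(rates), function(k) {
    line_model(regimens[k], survival_curve("exponential", rate = rates[k]),
               attritions[k])
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# dense time grid used by curve-shape invariants
grid_80y <- seq(0, 80, length.out = 401)

random_curve <- function() {
  fam <- sample(c("exponential", "weibull", "lognormal", "loglogistic",
                  "gompertz"), 1)
  switch(fam,
    exponential = survival_curve("exponential", rate = runif(1, 0.05, 3)),
    weibull = survival_curve("weibull", shape = runif(1, 0.5, 3),
                             scale = runif(1, 0.3, 10)),
    lognormal = survival_curve("lognormal", meanlog = runif(1, -1, 2),
                               sdlog = runif(1, 0.2, 1.5)),
    loglogistic = survival_curve("loglogistic", shape = runif(1, 0.7, 3),
                                 scale = runif(1, 0.3, 10)),
    gompertz = survival_curve("gompertz", shape = runif(1, -0.2, 0.5),
                              rate = runif(1, 0.05, 2))
  )
}
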