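#' Parametric survival curves
#'
#' `survival_curve()` constructs a parametric survival function S(t) with time
#' measured in years. Five families are supported, in the parameterizations
#' used throughout health-economic survival extrapolation:
#'
#' * `exponential`: `rate` (lambda > 0), S(t) = exp(-lambda t)
#' * `weibull`: `shape` (> 0), `scale` (> 0), S(t) = exp(-(t/scale)^shape)
#' * `lognormal`: `meanlog`, `sdlog` (> 0), S(t) = 1 - Phi((log t - meanlog)/sdlog)
#' * `loglogistic`: `shape` (> 0), `scale` (> 0), S(t) = 1/(1 + (t/scale)^shape)
#' * `gompertz`: `shape` (real), `rate` (> 0),
#'   S(t) = exp(-(rate/shape) (exp(shape t) - 1)) (exponential in the
#'   shape -> 0 limit)
#'
#' A curve may carry a proportional-hazards multiplier `hr` (see
#' [apply_hazard_ratio()]); evaluation then returns the base survival raised
#' to the power `hr`.
#'
#' @param family One of `"exponential"`, `"weibull"`, `"lognormal"`,
#'   `"loglogistic"`, `"gompertz"`.
#' @param ... Named family parameters (see Details). Alternatively a single
#'   named numeric vector/list `params`.
#' @param hr Proportional-hazards multiplier applied on top of the base
#'   curve; must be positive. Default 1.
#'
#' @return An object of class `survival_curve`.
#' @examples
#' cv <- survival_curve("exponential", rate = 0.5)
#' surv_prob(cv, c(0, 1, 2))
#' @export
survival_curve <- function(family, ..., hr = 1) {
  family <- match.arg(family, curve_families())
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) &&
      (is.list(dots[[1]]) || !is.null(names(dots[[1]])))) {
    dots <- as.list(dots[[1]])
  }
  params <- vapply(dots, as.numeric, numeric(1))
  expected <- curve_param_names(family)
  if (!setequal(names(params), expected)) {
    stop(sprintf(
      "family '%s' requires parameters {%s}, got {%s}",
      family, paste(expected, collapse = ", "),
      paste(names(params), collapse = ", ")
    ), call. = FALSE)
  }
  params <- params[expected]
  check_curve_params(family, params)
  if (!is.numeric(hr) || length(hr) != 1L || !is.finite(hr) || hr <= 0) {
    stop("'hr' must be a single positive number", call. = FALSE)
  }
  structure(
    list(family = family, params = params, hr = as.numeric(hr),
         time_unit = "years"),
    class = "survival_curve"
  )
}

curve_families <- function() {
  c("exponential", "weibull", "lognormal", "loglogistic", "gompertz")
}

curve_param_names <- function(family) {
  switch(family,
    exponential = "rate",
    weibull     = c("shape", "scale"),
    lognormal   = c("meanlog", "sdlog"),
    loglogistic = c("shape", "scale"),
    gompertz    = c("shape", "rate")
  )
}

check_curve_params <- function(family, params) {
  if (any(!is.finite(params))) {
    stop("curve parameters must be finite", call. = FALSE)
  }
  bad <- switch(family,
    exponential = params[["rate"]] <= 0,
    weibull     = params[["shape"]] <= 0 || params[["scale"]] <= 0,
    lognormal   = params[["sdlog"]] <= 0,
    loglogistic = params[["shape"]] <= 0 || params[["scale"]] <= 0,
    gompertz    = params[["rate"]] <= 0
  )
  if (bad) {
    stop(sprintf("invalid parameters for family '%s'", family), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf(
    "<survival_curve> %s(%s)%s\n", x$family,
    paste(sprintf("%s = %g", names(x$params), x$params), collapse = ", "),
    if (x$hr != 1) sprintf(" ^ hr %g", x$hr) else ""
  ))
  invisible(x)
}

#' @export
format.survival_curve <- function(x, ...) {
  sprintf("%s(%s)%s", x$family,
          paste(sprintf("%s=%g", names(x$params), x$params), collapse = ","),
          if (x$hr != 1) sprintf("^%g", x$hr) else "")
}

#' Evaluate a survival curve
#'
#' Returns S(t), the probability of being event-free at time `t` (years).
#' Vectorized over `t`.
#'
#' @param curve A [survival_curve()].
#' @param t Non-negative times in years.
#' @return Survival probabilities in `[0, 1]`; `S(0) = 1`.
#' @examples
#' surv_prob(survival_curve("weibull", shape = 1, scale = 2), 2)
#' @export
surv_prob <- function(curve, t) {
  stopifnot(inherits(curve, "survival_curve"))
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  p <- curve$params
  s <- switch(curve$family,
    exponential = stats::pexp(t, rate = p[["rate"]], lower.tail = FALSE),
    weibull     = stats::pweibull(t, shape = p[["shape"]], scale = p[["scale"]],
                                  lower.tail = FALSE),
    lognormal   = stats::plnorm(t, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]],
                                lower.tail = FALSE),
    loglogistic = flexsurv::pllogis(t, shape = p[["shape"]], scale = p[["scale"]],
                                    lower.tail = FALSE),
    gompertz    = flexsurv::pgompertz(t, shape = p[["shape"]], rate = p[["rate"]],
                                      lower.tail = FALSE)
  )
  if (curve$hr != 1) s <- s^curve$hr
  pmin(pmax(s, 0), 1)
}

#' Quantile function of a survival curve
#'
#' Inverse of [surv_prob()]: the time at which survival drops to `s`.
#' Used by the synthetic Kaplan-Meier generator.
#'
#' @param curve A [survival_curve()].
#' @param s Survival probabilities in `(0, 1]`.
#' @return Times in years.
#' @export
surv_quantile <- function(curve, s) {
  stopifnot(inherits(curve, "survival_curve"))
  if (any(s <= 0 | s > 1)) stop("'s' must be in (0, 1]", call. = FALSE)
  # S_hr(t) = s  <=>  S_base(t) = s^(1/hr)
  if (curve$hr != 1) s <- s^(1 / curve$hr)
  p <- curve$params
  switch(curve$family,
    exponential = stats::qexp(s, rate = p[["rate"]], lower.tail = FALSE),
    weibull     = stats::qweibull(s, shape = p[["shape"]], scale = p[["scale"]],
                                  lower.tail = FALSE),
    lognormal   = stats::qlnorm(s, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]],
                                lower.tail = FALSE),
    loglogistic = flexsurv::qllogis(s, shape = p[["shape"]], scale = p[["scale"]],
                                    lower.tail = FALSE),
    gompertz    = flexsurv::qgompertz(s, shape = p[["shape"]], rate = p[["rate"]],
                                      lower.tail = FALSE)
  )
}

#' Apply a hazard ratio to a survival curve
#'
#' Under proportional hazards a multiplicative hazard effect `hr` transforms
#' survival as `S_target(t) = S_ref(t)^hr`. For an exponential reference the
#' result is returned exactly as an exponential with rate `hr * rate`; other
#' families carry the exponent on the curve object.
#'
#' @param curve A [survival_curve()].
#' @param hr Positive hazard ratio.
#' @return A [survival_curve()] evaluating to `S(t)^hr`.
#' @examples
#' rd <- survival_curve("exponential", rate = 0.3)
#' apply_hazard_ratio(rd, 2) # exponential(rate = 0.6)
#' @export
apply_hazard_ratio <- function(curve, hr) {
  stopifnot(inherits(curve, "survival_curve"))
  if (!is.numeric(hr) || length(hr) != 1L || !is.finite(hr) || hr <= 0) {
    stop("'hr' must be a single positive number", call. = FALSE)
  }
  if (curve$family == "exponential") {
    return(survival_curve("exponential",
                          rate = curve$params[["rate"]] * curve$hr * hr))
  }
  out <- curve
  out$hr <- curve$hr * hr
  out
}

#' Per-cycle event probability from a survival curve
#'
#' Converts a survival curve into the discrete-cycle conditional event
#' probability used by the cohort engine: for a cohort that has spent `u`
#' full cycles in a line,
#' `q(u) = 1 - S((u + 1) * cycle_length) / S(u * cycle_length)`.
#' When `S(u * cycle_length)` falls below `floor` the cohort is treated as
#' exhausted and `q(u) = 1`.
#'
#' @param curve A [survival_curve()].
#' @param u Cycle index within the line (0-based); vectorized.
#' @param cycle_length Cycle length in years (> 0).
#' @param floor Survival floor below which S is treated as 0. Default `1e-12`.
#' @return Event probabilities in `[0, 1]`.
#' @examples
#' # memoryless: identical for all u
#' cycle_event_prob(survival_curve("exponential", rate = 2), 0:3, 14 / 365.25)
#' @export
cycle_event_prob <- function(curve, u, cycle_length, floor = 1e-12) {
  stopifnot(inherits(curve, "survival_curve"))
  if (any(u < 0)) stop("'u' must be non-negative", call. = FALSE)
  if (!is.numeric(cycle_length) || cycle_length <= 0) {
    stop("'cycle_length' must be positive", call. = FALSE)
  }
  s0 <- surv_prob(curve, u * cycle_length)
  s1 <- surv_prob(curve, (u + 1) * cycle_length)
  q <- ifelse(s0 <= floor, 1, 1 - s1 / s0)
  pmin(pmax(q, 0), 1)
}

#' Restricted mean survival time
#'
#' Area under the survival curve up to `horizon`, by composite trapezoidal
#' quadrature on a uniform grid of width `step` (plus a final partial panel
#' when `horizon` is not a multiple of `step`).
#'
#' @param curve A [survival_curve()].
#' @param horizon Upper limit of integration, years (>= 0).
#' @param step Quadrature step, years (> 0). Default one day.
#' @return Restricted mean survival time in years.
#' @examples
#' restricted_mean(survival_curve("exponential", rate = 1), horizon = 40)
#' @export
restricted_mean <- function(curve, horizon, step = 1 / 365.25) {
  stopifnot(inherits(curve, "survival_curve"))
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon < 0) {
    stop("'horizon' must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(step) || step <= 0) stop("'step' must be positive", call. = FALSE)
  if (horizon == 0) return(0)
  grid <- seq(0, horizon, by = step)
  if (grid[length(grid)] < horizon) grid <- c(grid, horizon)
  s <- surv_prob(curve, grid)
  sum(diff(grid) * (s[-length(s)] + s[-1]) / 2)
}
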