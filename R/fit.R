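#' Kaplan-Meier summary points
#'
#' Validates a table of survival summary points (as read from published
#' curves or produced by [generate_km_dataset()]) and returns it as a tibble
#' of class `km_points` with columns `time_years`, `survival` and, when
#' available, `n_at_risk`.
#'
#' @param time_years Strictly ascending non-negative times (years).
#' @param survival Survival probabilities in `[0, 1]`, non-increasing.
#' @param n_at_risk Optional positive numbers at risk per point.
#' @return A tibble of class `km_points`.
#' @export
km_points <- function(time_years, survival, n_at_risk = NULL) {
  time_years <- as.numeric(time_years)
  survival <- as.numeric(survival)
  if (length(time_years) != length(survival)) {
    stop("'time_years' and 'survival' must have equal length", call. = FALSE)
  }
  if (any(time_years < 0)) stop("times must be non-negative", call. = FALSE)
  if (any(diff(time_years) <= 0)) {
    stop("times must be strictly ascending", call. = FALSE)
  }
  if (any(survival < 0 | survival > 1)) {
    stop("survival probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(diff(survival) > 0)) {
    stop("survival probabilities must be non-increasing", call. = FALSE)
  }
  out <- tibble::tibble(time_years = time_years, survival = survival)
  if (!is.null(n_at_risk)) {
    n_at_risk <- as.numeric(n_at_risk)
    if (length(n_at_risk) != length(time_years) || any(n_at_risk <= 0)) {
      stop("'n_at_risk' must be positive and match the number of points",
           call. = FALSE)
    }
    out$n_at_risk <- n_at_risk
  }
  class(out) <- c("km_points", class(out))
  out
}

as_km_points <- function(x) {
  if (inherits(x, "km_points")) return(x)
  if (is.data.frame(x)) {
    return(km_points(x$time_years, x$survival, x[["n_at_risk"]]))
  }
  stop("cannot interpret input as Kaplan-Meier summary points", call. = FALSE)
}

# points usable on the complementary log-log scale: 0 < S < 1, t > 0
cloglog_usable <- function(km) {
  km$time_years > 0 & km$survival > 0 & km$survival < 1
}

#' Fit a parametric family to Kaplan-Meier summary points
#'
#' Estimates the parameters of one survival family by weighted least squares
#' on the complementary log-log scale: the criterion is
#' `sum w_i (log(-log S_model(t_i)) - log(-log S_i))^2`, with weights
#' `w_i = n_at_risk_i` when numbers at risk are supplied and 1 otherwise.
#' This transformed-scale criterion works directly on summary points without
#' reconstructing pseudo individual-patient data, and is exactly linear for
#' the exponential and Weibull families. Points with `S = 1`, `S = 0` or
#' `t = 0` carry no information on this scale and are dropped.
#'
#' @param km A [km_points()] table (or data frame with matching columns).
#' @param family A single family name (see [survival_curve()]).
#' @return An object of class `curve_fit`: the fitted [survival_curve()]
#'   plus fit statistics (`rss`, `n`, `n_params`, and an AIC-like criterion
#'   `n * log(rss/n) + 2 * n_params`). Methods: [tidy()], [glance()].
#' @examples
#' tm <- seq(0.25, 6, by = 0.25)
#' km <- km_points(tm, exp(-0.4 * tm))
#' fit_parametric(km, "exponential")
#' @export
fit_parametric <- function(km, family) {
  km <- as_km_points(km)
  family <- match.arg(family, curve_families())
  k <- length(curve_param_names(family))
  if (all(km$survival >= 1)) {
    stop("no events in the summary points (all survival = 1)", call. = FALSE)
  }
  use <- cloglog_usable(km)
  tm <- km$time_years[use]
  sv <- km$survival[use]
  w <- if (!is.null(km[["n_at_risk"]])) km$n_at_risk[use] else rep(1, sum(use))
  if (length(tm) < k + 1L) {
    stop(sprintf(
      "too few usable points (%d) to fit a %d-parameter family", length(tm), k
    ), call. = FALSE)
  }
  y <- log(-log(sv))
  x <- log(tm)

  fit <- switch(family,
    exponential = {
      # y = log(rate) + x
      rate <- exp(stats::weighted.mean(y - x, w))
      list(params = c(rate = rate))
    },
    weibull = {
      # y = shape * (x - log(scale)): weighted simple regression
      cf <- unname(stats::lm.wfit(cbind(1, x), y, w)$coefficients)
      shape <- cf[2]
      list(params = c(shape = shape, scale = exp(-cf[1] / shape)))
    },
    lognormal = {
      # exact linearization for starts: qnorm(1 - S) = (log t - meanlog)/sdlog
      z <- stats::qnorm(1 - sv)
      cf <- stats::lm.wfit(cbind(1, x), z, w)$coefficients
      start <- c(meanlog = unname(-cf[1] / cf[2]), sdlog = max(1 / cf[2], 1e-6))
      wls_optim(family, start, tm, y, w)
    },
    loglogistic = {
      # exact linearization for starts: log((1-S)/S) = shape (log t - log scale)
      z <- log((1 - sv) / sv)
      cf <- stats::lm.wfit(cbind(1, x), z, w)$coefficients
      shape <- max(cf[2], 1e-6)
      start <- c(shape = unname(shape), scale = unname(exp(-cf[1] / shape)))
      wls_optim(family, start, tm, y, w)
    },
    gompertz = {
      rate0 <- exp(stats::weighted.mean(y - x, w)) # exponential rate as anchor
      best <- NULL
      for (sh0 in c(-0.5, -0.1, 1e-3, 0.1, 0.5)) {
        cand <- try(
          wls_optim(family, c(shape = sh0, rate = rate0), tm, y, w),
          silent = TRUE
        )
        if (inherits(cand, "try-error")) next
        if (is.null(best) || cand$rss < best$rss) best <- cand
      }
      if (is.null(best)) stop("gompertz fit failed from all starts", call. = FALSE)
      best
    }
  )

  curve <- survival_curve(family, fit$params)
  yhat <- log(-log(surv_prob(curve, tm)))
  rss <- sum(w * (y - yhat)^2)
  n <- length(tm)
  structure(
    list(curve = curve, family = family, rss = rss, n = n, n_params = k,
         aic = n * log(rss / n) + 2 * k,
         weighted = !is.null(km[["n_at_risk"]])),
    class = "curve_fit"
  )
}

# Nelder-Mead + BFGS polish of the weighted cloglog least-squares objective.
# Positive parameters are optimized on the log scale; the gompertz shape is
# left unconstrained (negative shapes give improper, plateauing survival).
wls_optim <- function(family, start, tm, y, w) {
  nm <- curve_param_names(family)
  is_pos <- switch(family,
    lognormal   = c(FALSE, TRUE),
    loglogistic = c(TRUE, TRUE),
    gompertz    = c(FALSE, TRUE)
  )
  enc <- function(p) {
    p[is_pos] <- log(p[is_pos])
    p
  }
  dec <- function(th) {
    th[is_pos] <- exp(th[is_pos])
    names(th) <- nm
    th
  }
  obj <- function(th) {
    p <- dec(th)
    s <- tryCatch(surv_prob(do.call(survival_curve, c(list(family), as.list(p))), tm),
                  error = function(e) NULL)
    if (is.null(s) || any(s <= 0) || any(s >= 1)) return(1e10)
    sum(w * (y - log(-log(s)))^2)
  }
  th0 <- enc(start[nm])
  o1 <- stats::optim(th0, obj, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-14))
  o2 <- tryCatch(
    stats::optim(o1$par, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14)),
    error = function(e) o1
  )
  best <- if (o2$value <= o1$value) o2 else o1
  list(params = dec(best$par), rss = best$value)
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf("<curve_fit> %s  rss = %.4g  aic = %.4g  (n = %d%s)\n",
              format(x$curve), x$rss, x$aic, x$n,
              if (x$weighted) ", n_at_risk weighted" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_parametric
#' @param x A `curve_fit` object.
#' @param ... Unused.
#' @method tidy curve_fit
#' @export
tidy.curve_fit <- function(x, ...) {
  tibble::tibble(term = names(x$curve$params),
                 estimate = unname(x$curve$params))
}

#' @rdname fit_parametric
#' @method glance curve_fit
#' @export
glance.curve_fit <- function(x, ...) {
  tibble::tibble(family = x$family, n = x$n, n_params = x$n_params,
                 rss = x$rss, aic = x$aic)
}

#' Fit several families and rank them by statistical fit
#'
#' Fits each candidate family with [fit_parametric()] and ranks the results
#' by the AIC-like criterion `n log(RSS/n) + 2k` (smaller is better). Ties
#' are broken by a fixed precedence order — exponential, weibull, lognormal,
#' loglogistic, gompertz — preferring the more parsimonious / conventional
#' family. A family whose fit fails is skipped with a warning. The ranking is
#' a statistical ordering only; the caller retains the final choice (e.g. on
#' clinical plausibility of the extrapolation) by picking any row.
#'
#' @param km A [km_points()] table.
#' @param families Character vector of candidate families. Default: all five.
#' @return A tibble with one row per successfully fitted family, ordered by
#'   rank: columns `rank`, `family`, `rss`, `aic`, and a list-column `fit` of
#'   `curve_fit` objects.
#' @export
select_family <- function(km, families = curve_families()) {
  if (length(families) == 0) stop("'families' must be non-empty", call. = FALSE)
  families <- match.arg(families, curve_families(), several.ok = TRUE)
  fits <- purrr::map(families, function(fam) {
    tryCatch(fit_parametric(km, fam), error = function(e) {
      warning(sprintf("family '%s' failed to fit: %s", fam, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
  })
  keep <- !purrr::map_lgl(fits, is.null)
  if (!any(keep)) stop("all candidate families failed to fit", call. = FALSE)
  fits <- fits[keep]
  out <- tibble::tibble(
    family = purrr::map_chr(fits, "family"),
    rss = purrr::map_dbl(fits, "rss"),
    aic = purrr::map_dbl(fits, "aic"),
    fit = fits
  )
  precedence <- match(out$family, curve_families())
  out <- out[order(out$aic, precedence), ]
  out$rank <- seq_len(nrow(out))
  dplyr::relocate(out, "rank")
}
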