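#' Population life-years projection
#'
#' Scales per-patient overall survival to the annual national cohort that
#' completes a full treatment sequence:
#' `n_tie = round(new_cases * tie_share)` patients are transplant-ineligible,
#' `n_fourth = round(n_tie * fourth_line_share)` of those reach a fourth
#' line, and each scenario contributes `LY = round(n_fourth * OS)` life
#' years. Life years gained is `LY(optimal) - LY(comparator)` for every
#' non-optimal scenario. Rounding at each named step is half-up to integers
#' (`rounding = "stepwise"`, the convention of the published projection); an
#' unrounded single-step variant is available with `rounding = "none"`.
#'
#' @param new_cases_per_year New diagnoses per year (>= 0).
#' @param tie_share Fraction of cases that are transplant-ineligible.
#' @param fourth_line_share Fraction of transplant-ineligible patients who
#'   reach a fourth treatment line. Default 0.175.
#' @param os_by_scenario Named numeric vector: expected overall survival in
#'   years per scenario label.
#' @param optimal Scenario label treated as the optimal sequence.
#' @param rounding `"stepwise"` (integer rounding at each step) or `"none"`.
#' @return An object of class `ly_projection`: a `cohort` tibble
#'   (`quantity`, `value`) and a `life_years` tibble (`scenario`,
#'   `os_years`, `life_years`, `ly_gained_vs_optimal`). Method: [tidy()].
#' @examples
#' project_life_years(886, 0.60, 0.175,
#'                    os_by_scenario = c(optimal = 9.76, common_worst = 6.13),
#'                    optimal = "optimal")
#' @export
project_life_years <- function(new_cases_per_year, tie_share,
                               fourth_line_share = 0.175, os_by_scenario,
                               optimal, rounding = c("stepwise", "none")) {
  rounding <- match.arg(rounding)
  if (!is.numeric(new_cases_per_year) || new_cases_per_year < 0) {
    stop("'new_cases_per_year' must be non-negative", call. = FALSE)
  }
  for (sh in c(tie_share, fourth_line_share)) {
    if (!is.numeric(sh) || sh < 0 || sh > 1) {
      stop("shares must lie in [0, 1]", call. = FALSE)
    }
  }
  if (is.null(names(os_by_scenario)) || any(!nzchar(names(os_by_scenario)))) {
    stop("'os_by_scenario' must be a named vector", call. = FALSE)
  }
  if (any(os_by_scenario < 0)) stop("OS values must be >= 0", call. = FALSE)
  if (!optimal %in% names(os_by_scenario)) {
    stop(sprintf("optimal scenario '%s' missing from 'os_by_scenario'", optimal),
         call. = FALSE)
  }
  step_round <- if (rounding == "stepwise") function(x) round_half_up(x, 0) else identity
  n_tie <- step_round(new_cases_per_year * tie_share)
  n_fourth <- step_round(n_tie * fourth_line_share)
  ly <- step_round(n_fourth * os_by_scenario)
  gained <- ly[[optimal]] - ly
  gained[optimal] <- NA_real_
  structure(
    list(
      cohort = tibble::tibble(
        quantity = c("new_cases_per_year", "transplant_ineligible",
                     "reach_fourth_line"),
        value = c(new_cases_per_year, n_tie, n_fourth)),
      life_years = tibble::tibble(
        scenario = names(os_by_scenario),
        os_years = unname(os_by_scenario),
        life_years = unname(ly),
        ly_gained_vs_optimal = unname(gained)),
      optimal = optimal, rounding = rounding),
    class = "ly_projection"
  )
}

#' @export
print.ly_projection <- function(x, ...) {
  cat(sprintf("<ly_projection> (%s rounding)\n", x$rounding))
  print(x$cohort)
  print(x$life_years)
  invisible(x)
}

#' @rdname project_life_years
#' @param x An `ly_projection` object.
#' @param ... Unused.
#' @method tidy ly_projection
#' @export
tidy.ly_projection <- function(x, ...) x$life_years
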