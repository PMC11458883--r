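#' Expected progression-free time per line
#'
#' Integrates each line's progression-free occupancy over the trace: the sum
#' of per-cycle occupancy at the start of cycles `0 .. n_cycles - 1` times
#' the cycle length (a left-Riemann sum; no half-cycle correction). Times
#' are unconditional — per member of the starting cohort — so that overall
#' survival decomposes additively across lines. Per-entrant (conditional)
#' times and entry probabilities are also reported.
#'
#' @param trace A `cohort_trace` from [simulate_sequence()].
#' @return A tibble with one row per line: `line`, `regimen`,
#'   `years` (unconditional expected progression-free years),
#'   `entry_prob` (fraction of the cohort ever entering the line), and
#'   `years_per_entrant` (`years / entry_prob`).
#' @export
line_expected_times <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  st <- attr(trace, "settings")
  K <- attr(trace, "n_lines")
  body <- trace[-nrow(trace), ] # integrate over cycle starts 0..N-1
  entry_probs <- attr(trace, "entry_prob")
  purrr::map_dfr(seq_len(K), function(k) {
    occ <- body[[paste0("pf_line", k)]]
    entry <- entry_probs[k]
    yrs <- sum(occ) * st$cycle_length
    tibble::tibble(
      line = k,
      regimen = attr(trace, "regimens")[k],
      years = yrs,
      entry_prob = entry,
      years_per_entrant = ifelse(entry > 0, yrs / entry, NA_real_)
    )
  })
}

#' Overall survival from a cohort trace
#'
#' Expected years alive: the per-cycle alive fraction (all progression-free
#' states plus any post-progression occupancy) summed over cycle starts and
#' scaled by the cycle length. Equals the sum of per-line expected
#' progression-free years plus final-line post-progression years.
#'
#' @param trace A `cohort_trace` from [simulate_sequence()].
#' @return Expected overall survival in years.
#' @export
overall_survival_years <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  st <- attr(trace, "settings")
  sum(trace$alive[-nrow(trace)]) * st$cycle_length
}

#' Post-progression years in the final line
#'
#' Zero in terminal-death mode; in partitioned-survival mode, the area of
#' the post-progression state.
#'
#' @inheritParams overall_survival_years
#' @return Years.
#' @export
post_progression_years <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  st <- attr(trace, "settings")
  sum(trace$post_progression[-nrow(trace)]) * st$cycle_length
}

#' Summarize a simulated sequence
#'
#' Collapses a cohort trace into the sequence's outcome measures: per-line
#' expected progression-free years and overall survival.
#'
#' @param trace A `cohort_trace` from [simulate_sequence()].
#' @param label Optional label override.
#' @return An object of class `sequence_outcomes` with fields `label`,
#'   `per_line_years`, `os_years`, `final_line_pp_years`, `lines`, and the
#'   simulation settings. Methods: [tidy()], [glance()].
#' @export
sequence_outcomes <- function(trace, label = NULL) {
  stopifnot(inherits(trace, "cohort_trace"))
  lt <- line_expected_times(trace)
  structure(
    list(label = label %||% attr(trace, "label"),
         lines = lt$regimen,
         per_line_years = lt$years,
         per_entrant_years = lt$years_per_entrant,
         os_years = overall_survival_years(trace),
         final_line_pp_years = post_progression_years(trace),
         settings = attr(trace, "settings")),
    class = "sequence_outcomes"
  )
}

#' @export
print.sequence_outcomes <- function(x, ...) {
  cat(sprintf("<sequence_outcomes> %s\n", x$label))
  cat(sprintf("  per-line PF years: %s\n",
              paste(sprintf("%.2f", x$per_line_years), collapse = ", ")))
  if (x$final_line_pp_years > 0) {
    cat(sprintf("  post-progression years (final line): %.2f\n",
                x$final_line_pp_years))
  }
  cat(sprintf("  overall survival: %.2f years\n", x$os_years))
  invisible(x)
}

#' @rdname sequence_outcomes
#' @param x A `sequence_outcomes` object.
#' @param ... Unused.
#' @method tidy sequence_outcomes
#' @export
tidy.sequence_outcomes <- function(x, ...) {
  tibble::tibble(label = x$label, line = seq_along(x$per_line_years),
                 regimen = x$lines, pfs_years = x$per_line_years,
                 pfs_years_per_entrant = x$per_entrant_years)
}

#' @rdname sequence_outcomes
#' @method glance sequence_outcomes
#' @export
glance.sequence_outcomes <- function(x, ...) {
  tibble::tibble(label = x$label, n_lines = length(x$per_line_years),
                 os_years = x$os_years,
                 post_progression_years = x$final_line_pp_years)
}

#' Incremental overall survival between two sequences
#'
#' Signed difference `a - b` in expected overall-survival years. Both
#' outcome objects must come from simulations run under identical settings.
#'
#' @param a,b `sequence_outcomes` objects.
#' @return Years (signed).
#' @export
incremental_os <- function(a, b) {
  stopifnot(inherits(a, "sequence_outcomes"), inherits(b, "sequence_outcomes"))
  if (!settings_compatible(a$settings, b$settings)) {
    stop("sequence outcomes were computed under different simulation settings",
         call. = FALSE)
  }
  a$os_years - b$os_years
}

#' Outcome table and aggregates for a set of sequences
#'
#' Builds the per-sequence outcome table (per-line progression-free years,
#' overall survival, and — when an optimal sequence is named — the signed OS
#' difference of each sequence against it), together with aggregate
#' statistics: the non-weighted mean OS over the non-optimal sequences and
#' the first-line progression-free fold-change of the optimal sequence over
#' each comparator.
#'
#' @param outcomes A list of `sequence_outcomes`.
#' @param optimal_label Label of the reference (optimal) sequence, or `NULL`
#'   for a table without incremental columns.
#' @return A tibble with columns `sequence`, `pfs_l1` ... `pfs_l4`, `os`,
#'   and (when `optimal_label` is given) `delta_os_vs_optimal` and
#'   `pfs_l1_fold_optimal`. The non-weighted comparator mean OS is attached
#'   as attribute `mean_comparator_os`.
#' @export
summarize_sequences <- function(outcomes, optimal_label = NULL) {
  if (inherits(outcomes, "sequence_outcomes")) outcomes <- list(outcomes)
  stopifnot(length(outcomes) >= 1,
            all(purrr::map_lgl(outcomes, inherits, "sequence_outcomes")))
  labels <- purrr::map_chr(outcomes, "label")
  tbl <- purrr::map_dfr(outcomes, function(o) {
    pl <- c(o$per_line_years, rep(NA_real_, 4 - length(o$per_line_years)))
    tibble::tibble(sequence = o$label, pfs_l1 = pl[1], pfs_l2 = pl[2],
                   pfs_l3 = pl[3], pfs_l4 = pl[4], os = o$os_years)
  })
  if (!is.null(optimal_label)) {
    if (!optimal_label %in% labels) {
      stop(sprintf("optimal sequence '%s' not among the outcomes",
                   optimal_label), call. = FALSE)
    }
    opt <- outcomes[[match(optimal_label, labels)]]
    tbl$delta_os_vs_optimal <- purrr::map_dbl(outcomes, incremental_os, opt)
    tbl$delta_os_vs_optimal[labels == optimal_label] <- NA_real_
    tbl$pfs_l1_fold_optimal <- opt$per_line_years[1] / tbl$pfs_l1
    tbl$pfs_l1_fold_optimal[labels == optimal_label] <- NA_real_
    comp <- tbl$os[labels != optimal_label]
  } else {
    comp <- tbl$os
  }
  attr(tbl, "mean_comparator_os") <- if (length(comp) > 0) mean(comp) else NA_real_
  tbl
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention of the
#' model's printed tables), unlike [round()]'s round-half-even.
#'
#' @param x Numeric.
#' @param digits Decimal places (may be 0).
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  scaled <- x * 10^digits
  # nudge by an ulp-scale epsilon so values stored just under .5 round up
  sign(scaled) * floor(abs(scaled) + 0.5 + 1e-9) / 10^digits
}

#' Render an outcome table at display precision
#'
#' Applies the display rounding used in the reported tables: two decimals
#' for per-line and OS years, one decimal for fold-changes.
#'
#' @param tbl A table from [summarize_sequences()].
#' @return A tibble with rounded values.
#' @export
format_outcome_table <- function(tbl) {
  out <- dplyr::mutate(tbl, dplyr::across(
    dplyr::any_of(c("pfs_l1", "pfs_l2", "pfs_l3", "pfs_l4", "os",
                    "delta_os_vs_optimal")),
    ~ round_half_up(.x, 2)))
  if ("pfs_l1_fold_optimal" %in% names(out)) {
    out$pfs_l1_fold_optimal <- round_half_up(out$pfs_l1_fold_optimal, 1)
  }
  out
}
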