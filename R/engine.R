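#' Treatment sequences
#'
#' An ordered list of one to four regimen identifiers, simulated as
#' consecutive treatment lines.
#'
#' @param lines Character vector of regimen identifiers, in line order
#'   (length 1-4).
#' @param label Display label; defaults to the regimens joined by `+`.
#' @param allow_repeat Permit the same regimen in more than one line.
#'   Default `FALSE`.
#' @return An object of class `treatment_sequence`.
#' @examples
#' treatment_sequence(c("DRd", "PVd", "Kd", "Vd"))
#' @export
treatment_sequence <- function(lines, label = NULL, allow_repeat = FALSE) {
  lines <- as.character(lines)
  if (length(lines) < 1L || length(lines) > 4L) {
    stop("a treatment sequence must have between 1 and 4 lines", call. = FALSE)
  }
  if (anyDuplicated(lines) && !allow_repeat) {
    stop("duplicate regimen in sequence (set allow_repeat = TRUE to permit)",
         call. = FALSE)
  }
  structure(
    list(lines = lines,
         label = label %||% paste(lines, collapse = "+"),
         allow_repeat = isTRUE(allow_repeat)),
    class = "treatment_sequence"
  )
}

#' @export
print.treatment_sequence <- function(x, ...) {
  cat(sprintf("<treatment_sequence> %s: %s\n", x$label,
              paste(x$lines, collapse = " -> ")))
  invisible(x)
}

#' One treatment line's simulation inputs
#'
#' @param regimen Regimen identifier.
#' @param pfs_curve Progression-free survival curve ([survival_curve()]).
#' @param attrition Fraction of PFS events that are progressions to the next
#'   line (the remainder are deaths), in `[0, 1]`. Ignored for the final
#'   line in terminal-death mode.
#' @param os_curve Optional overall-survival curve; required for the final
#'   line in partitioned-survival mode.
#' @return An object of class `line_model`.
#' @export
line_model <- function(regimen, pfs_curve, attrition, os_curve = NULL) {
  stopifnot(inherits(pfs_curve, "survival_curve"))
  if (!is.null(os_curve)) stopifnot(inherits(os_curve, "survival_curve"))
  if (!is.numeric(attrition) || length(attrition) != 1L ||
      attrition < 0 || attrition > 1) {
    stop("'attrition' must be a single value in [0, 1]", call. = FALSE)
  }
  structure(
    list(regimen = as.character(regimen), pfs_curve = pfs_curve,
         attrition = as.numeric(attrition), os_curve = os_curve),
    class = "line_model"
  )
}

#' Simulation settings
#'
#' Defaults follow the model's base case: two-week cycles
#' (`14/365.25` years), a 40-year lifetime horizon
#' (`ceiling(40 * 365.25 / 14)` = 1044 cycles), no half-cycle correction,
#' and terminal death on progression from the final line.
#'
#' @param cycle_length Cycle length in years.
#' @param n_cycles Number of cycles simulated.
#' @param final_line_mode `"terminal_death"` (progression from the final
#'   line is death) or `"partitioned_survival"` (final line follows its PFS
#'   and OS curves; post-progression occupancy is their difference).
#' @param survival_floor Survival value below which a curve is treated as
#'   exhausted when forming conditional event probabilities.
#' @param strict_curve_order In partitioned mode, error (rather than clamp
#'   with a warning) when `S_PFS > S_OS` somewhere on the cycle grid.
#' @return An object of class `simulation_settings`.
#' @export
simulation_settings <- function(cycle_length = 14 / 365.25,
                                n_cycles = 1044L,
                                final_line_mode = c("terminal_death",
                                                    "partitioned_survival"),
                                survival_floor = 1e-12,
                                strict_curve_order = FALSE) {
  final_line_mode <- match.arg(final_line_mode)
  if (!is.numeric(cycle_length) || cycle_length <= 0) {
    stop("'cycle_length' must be positive", call. = FALSE)
  }
  n_cycles <- as.integer(n_cycles)
  if (is.na(n_cycles) || n_cycles < 1L) {
    stop("'n_cycles' must be a positive integer", call. = FALSE)
  }
  structure(
    list(cycle_length = cycle_length, n_cycles = n_cycles,
         final_line_mode = final_line_mode, survival_floor = survival_floor,
         strict_curve_order = isTRUE(strict_curve_order)),
    class = "simulation_settings"
  )
}

settings_compatible <- function(a, b) {
  isTRUE(all.equal(a$cycle_length, b$cycle_length)) &&
    a$n_cycles == b$n_cycles && a$final_line_mode == b$final_line_mode
}

#' Resolve a sequence into line models from a curve library
#'
#' Looks each regimen up in a curve library at the setting implied by its
#' line position: line 1 in the newly-diagnosed setting, lines 2-4 in the
#' relapsed/refractory setting, falling back to the double-refractory
#' setting for lines 3-4 when the regimen is available only there. A library
#' record either carries a parametric curve directly or points at a
#' reference regimen with a hazard ratio, in which case the reference curve
#' is resolved in the same setting and the ratio applied
#' ([apply_hazard_ratio()]). Additional reference/ratio pairs may be
#' supplied in `hr_table`.
#'
#' @param seq A [treatment_sequence()].
#' @param curve_library Tibble with columns `regimen`, `line_setting`
#'   (`newly_diagnosed`, `relapsed_refractory`, `double_refractory`),
#'   `endpoint` (`PFS` or `OS`), and either `curve` (list-column of
#'   [survival_curve()]) or `reference` + `hr`. See [read_curve_library()].
#' @param attrition_by_line Numeric vector of per-line attrition fractions,
#'   recycled to the sequence length.
#' @param hr_table Optional tibble `reference_regimen`, `target_regimen`,
#'   `line_setting`, `hr` used when the library has no record for a regimen.
#' @return A list of [line_model()] objects in sequence order.
#' @export
build_line_models <- function(seq, curve_library, attrition_by_line,
                              hr_table = NULL) {
  stopifnot(inherits(seq, "treatment_sequence"))
  n <- length(seq$lines)
  attrition <- rep_len(as.numeric(attrition_by_line), n)
  purrr::imap(seq$lines, function(reg, k) {
    pfs <- resolve_curve(reg, k, "PFS", curve_library, hr_table)
    os <- tryCatch(
      resolve_curve(reg, k, "OS", curve_library, hr_table),
      error = function(e) NULL
    )
    line_model(reg, pfs, attrition[k], os_curve = os)
  })
}

line_settings_for <- function(k) {
  if (k == 1L) "newly_diagnosed"
  else if (k == 2L) "relapsed_refractory"
  else c("relapsed_refractory", "double_refractory")
}

resolve_curve <- function(regimen, k, endpoint, curve_library,
                          hr_table = NULL, depth = 0L) {
  if (depth > 1L) {
    stop(sprintf("curve for '%s' chains references beyond one hazard-ratio hop",
                 regimen), call. = FALSE)
  }
  settings <- line_settings_for(k)
  hits <- NULL
  setting <- NA_character_
  for (st in settings) {
    hits <- curve_library[curve_library$regimen == regimen &
                            curve_library$line_setting == st &
                            curve_library$endpoint == endpoint, ]
    if (nrow(hits) > 0) { setting <- st; break }
  }
  if (is.null(hits) || nrow(hits) == 0) {
    # fall back to a bare hazard-ratio table entry
    if (!is.null(hr_table)) {
      hr_hits <- hr_table[hr_table$target_regimen == regimen &
                            hr_table$line_setting %in% settings, ]
      if (nrow(hr_hits) > 1) {
        stop(sprintf("ambiguous hazard-ratio resolution for '%s' (%s, line %d)",
                     regimen, endpoint, k), call. = FALSE)
      }
      if (nrow(hr_hits) == 1) {
        ref <- resolve_curve(hr_hits$reference_regimen[1], k, endpoint,
                             curve_library, hr_table = NULL, depth = depth + 1L)
        return(apply_hazard_ratio(ref, hr_hits$hr[1]))
      }
    }
    stop(sprintf("no %s curve for regimen '%s' in settings {%s}", endpoint,
                 regimen, paste(settings, collapse = ", ")), call. = FALSE)
  }
  if (nrow(hits) > 1) {
    stop(sprintf("ambiguous library entries for '%s' (%s, setting %s)",
                 regimen, endpoint, setting), call. = FALSE)
  }
  rec <- hits[1, ]
  if (!is.null(rec$curve[[1]])) return(rec$curve[[1]])
  ref <- resolve_curve(rec$reference[[1]], k, endpoint, curve_library,
                       hr_table, depth = depth + 1L)
  apply_hazard_ratio(ref, rec$hr[[1]])
}

#' Simulate a treatment sequence as a cohort trace
#'
#' Runs the discrete-cycle semi-Markov cohort model. A cohort of mass 1
#' starts progression-free in line 1. Each cycle, the fraction that has
#' spent `u` cycles in line `k` experiences a progression-or-death event
#' with probability `q_k(u) = 1 - S_k((u+1) delta) / S_k(u delta)`
#' (time-in-line dependence makes the model semi-Markov: occupancy is
#' tracked in tunnel states indexed by `u`). Of the event mass, the line's
#' attrition fraction enters the next line at `u = 0` in the following
#' cycle; the complement dies. In `terminal_death` mode all final-line
#' events are deaths. In `partitioned_survival` mode each cohort entering
#' the final line follows its PFS and OS curves from its own entry time;
#' post-progression occupancy is `S_OS - S_PFS` (clamped at 0, with a
#' warning when the fitted curves cross). Events resolve at cycle end; no
#' half-cycle correction is applied.
#'
#' @param models A list of 1-4 [line_model()] objects (or a single one).
#' @param settings A [simulation_settings()].
#' @param label Optional sequence label stored on the trace.
#' @return A `cohort_trace`: a tibble with one row per cycle boundary
#'   (`cycle` 0 to `n_cycles`, state at the start of each cycle) and columns
#'   `time_years`, `pf_line1` ... `pf_lineK` (progression-free occupancy by
#'   line), `post_progression`, `dead`, `alive`. Settings and labels are
#'   attached as attributes.
#' @examples
#' m <- line_model("Rd", survival_curve("exponential", rate = 0.5), 0.7)
#' tr <- simulate_sequence(list(m), simulation_settings(n_cycles = 260))
#' overall_survival_years(tr)
#' @export
simulate_sequence <- function(models, settings = simulation_settings(),
                              label = NULL) {
  if (inherits(models, "line_model")) models <- list(models)
  stopifnot(inherits(settings, "simulation_settings"))
  if (length(models) < 1L || length(models) > 4L) {
    stop("between 1 and 4 line models are required", call. = FALSE)
  }
  if (!all(purrr::map_lgl(models, inherits, "line_model"))) {
    stop("'models' must be line_model objects", call. = FALSE)
  }
  K <- length(models)
  N <- settings$n_cycles
  delta <- settings$cycle_length
  partitioned <- settings$final_line_mode == "partitioned_survival"
  if (partitioned && is.null(models[[K]]$os_curve)) {
    stop("partitioned-survival mode requires an OS curve on the final line",
         call. = FALSE)
  }

  # per-line conditional event probabilities q_k(u), u = 0..N-1
  qk <- purrr::map(models, function(m) {
    cycle_event_prob(m$pfs_curve, 0:(N - 1), delta,
                     floor = settings$survival_floor)
  })
  attr_k <- purrr::map_dbl(models, "attrition")

  n_markov <- if (partitioned) K - 1L else K   # lines simulated as tunnels
  occ <- purrr::map(seq_len(max(n_markov, 1L)), function(k) numeric(N + 1))
  if (n_markov >= 1L) occ[[1]][1] <- 1
  final_entrants <- numeric(N + 1)             # partitioned-mode entry masses
  if (partitioned && K == 1L) final_entrants[1] <- 1

  pf <- matrix(0, nrow = N + 1, ncol = K)      # state at start of each cycle
  dead <- numeric(N + 1)
  dead_cum <- 0
  entry_prob <- c(1, numeric(K - 1))           # cohort mass ever entering line k

  for (t in 0:(N - 1)) {
    row <- t + 1L
    for (k in seq_len(n_markov)) pf[row, k] <- sum(occ[[k]])
    dead[row] <- dead_cum
    new_entrants <- numeric(max(n_markov, 0L))
    promote_final <- 0
    for (k in seq_len(n_markov)) {
      v <- occ[[k]]
      active <- which(v > 0)
      if (length(active) == 0) next
      ev <- v[active] * qk[[k]][active]        # active indices are u+1 <= N
      total_ev <- sum(ev)
      surv <- v[active] - ev
      v[] <- 0
      v[active + 1L] <- surv
      occ[[k]] <- v
      if (k < n_markov) {
        new_entrants[k + 1L] <- attr_k[k] * total_ev
        dead_cum <- dead_cum + (1 - attr_k[k]) * total_ev
      } else if (partitioned) {
        promote_final <- attr_k[k] * total_ev
        dead_cum <- dead_cum + (1 - attr_k[k]) * total_ev
      } else {
        dead_cum <- dead_cum + total_ev        # terminal final line
      }
    }
    for (k in seq_len(n_markov)) {
      if (k > 1L) {
        occ[[k]][1] <- occ[[k]][1] + new_entrants[k]
        entry_prob[k] <- entry_prob[k] + new_entrants[k]
      }
    }
    if (partitioned && K > 1L) {
      final_entrants[row + 1L] <- final_entrants[row + 1L] + promote_final
      entry_prob[K] <- entry_prob[K] + promote_final
    }
  }
  for (k in seq_len(n_markov)) pf[N + 1, k] <- sum(occ[[k]])
  dead[N + 1] <- dead_cum

  post_progression <- numeric(N + 1)
  if (partitioned) {
    m <- models[[K]]
    u_grid <- 0:N
    s_pfs <- surv_prob(m$pfs_curve, u_grid * delta)
    s_os <- surv_prob(m$os_curve, u_grid * delta)
    if (any(s_pfs > s_os + 1e-12)) {
      msg <- sprintf(
        "final-line PFS exceeds OS on the cycle grid for '%s'; post-progression clamped at 0",
        m$regimen)
      if (settings$strict_curve_order) stop(msg, call. = FALSE)
      warning(msg, call. = FALSE)
    }
    # convolve entry masses with the final line's survival functions
    for (row in seq_len(N + 1)) {
      e_idx <- which(final_entrants[seq_len(row)] > 0)
      if (length(e_idx) == 0) next
      lag <- row - e_idx
      e <- final_entrants[e_idx]
      pf[row, K] <- sum(e * s_pfs[lag + 1L])
      alive_k <- sum(e * s_os[lag + 1L])
      pp <- max(alive_k - pf[row, K], 0)
      post_progression[row] <- pp
      # when clamped (PFS above OS) deaths are taken against PF occupancy so
      # the cohort mass still balances
      dead[row] <- dead[row] + sum(e) - pf[row, K] - pp
    }
  }

  alive <- rowSums(pf) + post_progression
  total <- alive + dead
  off <- which(abs(total - 1) > 1e-9)
  if (length(off) > 0) {
    stop(sprintf("internal error: cohort mass %.12f != 1 at cycle %d",
                 total[off[1]], off[1] - 1L), call. = FALSE)
  }

  out <- tibble::tibble(cycle = 0:N, time_years = (0:N) * delta)
  for (k in seq_len(K)) out[[paste0("pf_line", k)]] <- pf[, k]
  out$post_progression <- post_progression
  out$dead <- dead
  out$alive <- alive
  structure(out,
            class = c("cohort_trace", class(out)),
            settings = settings,
            label = label %||% paste(purrr::map_chr(models, "regimen"),
                                     collapse = "+"),
            regimens = purrr::map_chr(models, "regimen"),
            entry_prob = entry_prob,
            n_lines = K)
}

#' Validate a sequence against a line-setting eligibility table
#'
#' Checks each regimen against the settings in which it is licensed: line 1
#' must be licensed for newly-diagnosed patients, lines 2-4 for the
#' relapsed/refractory setting, with the double-refractory setting also
#' acceptable from line 3 onwards. Repeated regimens produce a warning-level
#' finding unless the sequence allows repeats; regimens flagged as not
#' approved produce a note.
#'
#' @param seq A [treatment_sequence()].
#' @param eligibility An eligibility table as returned by
#'   [portugal_eligibility()]: columns `regimen`, `setting`, `approved`.
#' @return A tibble of findings (`line`, `regimen`, `severity`, `message`);
#'   zero rows when the sequence is fully eligible.
#' @export
validate_sequence <- function(seq, eligibility = portugal_eligibility()) {
  stopifnot(inherits(seq, "treatment_sequence"))
  unknown <- setdiff(seq$lines, unique(eligibility$regimen))
  if (length(unknown) > 0) {
    stop(sprintf("unknown regimen identifier(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  findings <- list()
  add <- function(line, regimen, severity, message) {
    findings[[length(findings) + 1L]] <<-
      tibble::tibble(line = line, regimen = regimen, severity = severity,
                     message = message)
  }
  for (k in seq_along(seq$lines)) {
    reg <- seq$lines[k]
    allowed <- line_settings_for(k)
    rows <- eligibility[eligibility$regimen == reg &
                          eligibility$setting %in% allowed, ]
    if (nrow(rows) == 0) {
      add(k, reg, "violation",
          sprintf("'%s' is not licensed for line %d (settings: %s)",
                  reg, k, paste(allowed, collapse = ", ")))
    } else if (any(!rows$approved)) {
      add(k, reg, "note", sprintf("'%s' is licensed but not approved", reg))
    }
  }
  dup <- unique(seq$lines[duplicated(seq$lines)])
  if (length(dup) > 0 && !seq$allow_repeat) {
    for (reg in dup) {
      add(NA_integer_, reg, "warning",
          sprintf("regimen '%s' appears more than once", reg))
    }
  }
  if (length(findings) == 0) {
    return(tibble::tibble(line = integer(), regimen = character(),
                          severity = character(), message = character()))
  }
  dplyr::bind_rows(findings)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
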