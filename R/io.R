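#' Read and write Kaplan-Meier summary CSV files
#'
#' The exchange format is a headed CSV with dot decimals and columns
#' `time_years,survival[,n_at_risk]`.
#'
#' @param path File path.
#' @return `read_km_csv()` returns a [km_points()] tibble.
#' @export
read_km_csv <- function(path) {
  if (!file.exists(path)) {
    abort_config(sprintf("KM file not found: %s", path))
  }
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("time_years", "survival")
  if (!all(need %in% names(df))) {
    abort_config(sprintf("KM file %s must have columns %s", path,
                         paste(need, collapse = ", ")))
  }
  km_points(df$time_years, df$survival, df[["n_at_risk"]])
}

#' @rdname read_km_csv
#' @param km A [km_points()] tibble.
#' @export
write_km_csv <- function(km, path) {
  readr::write_csv(as_km_points(km), path)
  invisible(path)
}

#' Read and write curve libraries
#'
#' A curve library is a list of records in JSON or YAML (chosen by file
#' extension). Each record carries `regimen`, `line_setting`, `endpoint`
#' (`PFS`/`OS`) and either a parametric curve (`family` + named `params`,
#' optionally `hr`) or a reference (`reference` regimen + `hr`), resolved at
#' model-build time by [build_line_models()].
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_curve_library()` returns a tibble with columns `regimen`,
#'   `line_setting`, `endpoint`, list-column `curve`, `reference`, `hr`.
#' @export
read_curve_library <- function(path) {
  records <- read_structured(path)
  if (length(records) == 0) {
    abort_config(sprintf("curve library %s is empty", path))
  }
  rows <- purrr::imap(records, function(rec, i) {
    where <- sprintf("%s, record %d", path, i)
    for (key in c("regimen", "line_setting", "endpoint")) {
      if (is.null(rec[[key]])) {
        abort_config(sprintf("missing '%s' in %s", key, where))
      }
    }
    if (!rec$line_setting %in% c("newly_diagnosed", "relapsed_refractory",
                                 "double_refractory")) {
      abort_config(sprintf("invalid line_setting '%s' in %s",
                           rec$line_setting, where))
    }
    if (!rec$endpoint %in% c("PFS", "OS")) {
      abort_config(sprintf("invalid endpoint '%s' in %s", rec$endpoint, where))
    }
    has_curve <- !is.null(rec$family)
    has_ref <- !is.null(rec$reference)
    if (has_curve == has_ref) {
      abort_config(sprintf(
        "record must have exactly one of 'family' or 'reference' in %s", where))
    }
    curve <- NULL
    if (has_curve) {
      curve <- tryCatch(
        survival_curve(rec$family, unlist(rec$params),
                       hr = rec$hr %||% 1),
        error = function(e) abort_config(sprintf("%s in %s",
                                                 conditionMessage(e), where))
      )
    } else if (is.null(rec$hr)) {
      abort_config(sprintf("'reference' record needs an 'hr' in %s", where))
    }
    tibble::tibble(
      regimen = rec$regimen, line_setting = rec$line_setting,
      endpoint = rec$endpoint, curve = list(curve),
      reference = if (has_ref) rec$reference else NA_character_,
      hr = if (has_ref) as.numeric(rec$hr) else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

#' @rdname read_curve_library
#' @param library A curve-library tibble.
#' @export
write_curve_library <- function(library, path) {
  records <- purrr::pmap(library, function(regimen, line_setting, endpoint,
                                           curve, reference, hr, ...) {
    base <- list(regimen = regimen, line_setting = line_setting,
                 endpoint = endpoint)
    if (!is.null(curve)) {
      c(base, list(family = curve$family, params = as.list(curve$params)),
        if (curve$hr != 1) list(hr = curve$hr))
    } else {
      c(base, list(reference = reference, hr = hr))
    }
  })
  write_structured(records, path)
  invisible(path)
}

#' Read treatment sequences from a structured file
#'
#' Expects a JSON/YAML list of `{label, lines}` records.
#'
#' @param path File path.
#' @return A list of [treatment_sequence()].
#' @export
read_sequences <- function(path) {
  records <- read_structured(path)
  if (length(records) == 0) abort_config("no sequences in file")
  purrr::map(records, function(rec) {
    if (is.null(rec$lines)) abort_config("sequence record missing 'lines'")
    treatment_sequence(unlist(rec$lines), label = rec$label,
                       allow_repeat = isTRUE(rec$allow_repeat))
  })
}

#' Read per-line attrition fractions
#'
#' Tab-separated file with columns `line` (1-based index) and `attrition`.
#'
#' @param path File path.
#' @return Numeric vector of attrition fractions ordered by line.
#' @export
read_attrition <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("line", "attrition") %in% names(df))) {
    abort_config("attrition file must have columns 'line' and 'attrition'")
  }
  if (any(df$attrition < 0 | df$attrition > 1)) {
    abort_config("attrition fractions must lie in [0, 1]")
  }
  df <- df[order(df$line), ]
  df$attrition
}

#' Load and validate a run configuration
#'
#' A configuration is a JSON/YAML mapping with keys `curves`, `sequences`,
#' `attrition` (file paths, resolved relative to the configuration file),
#' optional `eligibility` (defaults to the packaged Portuguese table),
#' optional `settings` (`cycle_length`, `n_cycles`, `final_line_mode`),
#' `optimal` (sequence label), `out_dir`, and `write_traces`. Unknown keys
#' are rejected. Defaults: two-week cycles, 1044 cycles, terminal-death
#' mode. Partitioned-survival mode is validated against the curve library:
#' every sequence's final-line regimen must resolve to an OS curve.
#'
#' @param path Path to the configuration file.
#' @return A validated `run_config` list with loaded inputs.
#' @export
load_run_config <- function(path) {
  cfg <- read_structured(path)
  known <- c("curves", "sequences", "attrition", "eligibility", "settings",
             "optimal", "out_dir", "write_traces")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0) {
    abort_config(sprintf("unknown configuration key(s) in %s: %s", path,
                         paste(extra, collapse = ", ")))
  }
  for (key in c("curves", "sequences", "attrition")) {
    if (is.null(cfg[[key]])) {
      abort_config(sprintf("configuration %s is missing '%s'", path, key))
    }
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  st_in <- cfg$settings %||% list()
  known_st <- c("cycle_length", "n_cycles", "final_line_mode", "survival_floor")
  extra_st <- setdiff(names(st_in), known_st)
  if (length(extra_st) > 0) {
    abort_config(sprintf("unknown settings key(s): %s",
                         paste(extra_st, collapse = ", ")))
  }
  settings <- tryCatch(
    simulation_settings(
      cycle_length = st_in$cycle_length %||% 14 / 365.25,
      n_cycles = st_in$n_cycles %||% 1044L,
      final_line_mode = st_in$final_line_mode %||% "terminal_death",
      survival_floor = st_in$survival_floor %||% 1e-12
    ),
    error = function(e) abort_config(conditionMessage(e))
  )
  library <- read_curve_library(resolve(cfg$curves))
  sequences <- read_sequences(resolve(cfg$sequences))
  attrition <- read_attrition(resolve(cfg$attrition))
  eligibility <- if (!is.null(cfg$eligibility)) {
    readr::read_tsv(resolve(cfg$eligibility), show_col_types = FALSE)
  } else {
    portugal_eligibility()
  }
  if (settings$final_line_mode == "partitioned_survival") {
    for (sq in sequences) {
      k <- length(sq$lines)
      ok <- tryCatch({
        resolve_curve(sq$lines[k], k, "OS", library)
        TRUE
      }, error = function(e) FALSE)
      if (!ok) {
        abort_config(sprintf(
          "partitioned-survival mode but no OS curve resolvable for final-line regimen '%s' of sequence '%s'",
          sq$lines[k], sq$label))
      }
    }
  }
  structure(
    list(curve_library = library, sequences = sequences,
         attrition = attrition, eligibility = eligibility,
         settings = settings, optimal = cfg$optimal,
         out_dir = cfg$out_dir %||% ".",
         write_traces = isTRUE(cfg$write_traces)),
    class = "run_config"
  )
}

#' Run the full pipeline from a configuration
#'
#' Validates every sequence against the eligibility table, resolves curves,
#' simulates each sequence, and writes an outcome table
#' (`outcomes.tsv`: `sequence, pfs_l1..pfs_l4, os[, delta_os_vs_optimal]`)
#' plus, optionally, per-sequence cycle traces. Progress and aggregates are
#' logged to standard error as `key=value` lines. Outputs are deterministic:
#' identical inputs give byte-identical files.
#'
#' @param config A `run_config` from [load_run_config()].
#' @param quiet Suppress logging.
#' @return Invisibly, a list with the outcome table, outcome objects, and
#'   written file paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log_line <- function(...) {
    if (!quiet) {
      message(sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                      paste0(...)))
    }
  }
  if (length(config$sequences) == 0) {
    abort_validation("no sequences to simulate")
  }
  log_line("stage=validate n_sequences=", length(config$sequences))
  for (sq in config$sequences) {
    findings <- validate_sequence(sq, config$eligibility)
    viol <- findings[findings$severity == "violation", ]
    if (nrow(viol) > 0) {
      abort_validation(sprintf("sequence '%s' ineligible: %s", sq$label,
                               paste(viol$message, collapse = "; ")))
    }
    for (msg in findings$message[findings$severity != "violation"]) {
      log_line("stage=validate sequence=", sq$label, " note=\"", msg, "\"")
    }
  }
  outcomes <- purrr::map(config$sequences, function(sq) {
    models <- tryCatch(
      build_line_models(sq, config$curve_library, config$attrition),
      error = function(e) abort_validation(conditionMessage(e))
    )
    tr <- tryCatch(
      simulate_sequence(models, config$settings, label = sq$label),
      error = function(e) abort_simulation(conditionMessage(e))
    )
    out <- sequence_outcomes(tr)
    log_line("stage=simulate sequence=", sq$label,
             " os_years=", sprintf("%.4f", out$os_years))
    attr(out, "trace") <- tr
    out
  })
  tbl <- summarize_sequences(outcomes, optimal_label = config$optimal)
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  out_path <- file.path(config$out_dir, "outcomes.tsv")
  readr::write_tsv(format_outcome_table(tbl), out_path)
  written <- out_path
  if (config$write_traces) {
    for (o in outcomes) {
      tr <- attr(o, "trace")
      p <- file.path(config$out_dir,
                     paste0("trace_", gsub("[^A-Za-z0-9]+", "_", o$label),
                            ".tsv"))
      readr::write_tsv(tibble::as_tibble(tr), p)
      written <- c(written, p)
    }
  }
  log_line("stage=summarize mean_comparator_os=",
           sprintf("%.4f", attr(tbl, "mean_comparator_os")))
  log_line("stage=done outputs=", length(written))
  invisible(list(table = tbl, outcomes = outcomes, files = written))
}

# -- internal: structured-text helpers and condition classes -----------------

read_structured <- function(path) {
  if (!file.exists(path)) {
    abort_config(sprintf("file not found: %s", path))
  }
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("json", "yaml", "yml")) {
    abort_config(sprintf("unsupported extension '%s' (use json/yaml)", ext))
  }
  tryCatch({
    if (ext == "json") {
      jsonlite::read_json(path, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(path)
    }
  }, error = function(e) {
    abort_config(sprintf("failed to parse %s: %s", path, conditionMessage(e)))
  })
}

write_structured <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path, precision = 15L)
  } else {
    abort_config(sprintf("unsupported extension '%s' (use json/yaml)", ext))
  }
  invisible(path)
}

abort_config <- function(msg) {
  rlang::abort(msg, class = "seqmm_config_error")
}
abort_validation <- function(msg) {
  rlang::abort(msg, class = "seqmm_validation_error")
}
abort_simulation <- function(msg) {
  rlang::abort(msg, class = "seqmm_simulation_error")
}
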