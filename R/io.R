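#' Read and write trace, event, and force files
#'
#' All files are plain delimited text. Traces are TSV with columns `time_s`,
#' `stage_nm`, `force_pN`, preceded by `#`-prefixed `key=value` metadata lines
#' carrying the trap configuration and condition. Events are CSV with columns
#' `t_bind_s, t_rupture_s, rupture_force_pN, F_start_pN, direction,
#' is_primary`. Force lists are CSV with a `force_pN` column and optional
#' `direction` / `condition`. Write-then-read round-trips reproduce values to
#' at least 6 significant digits.
#'
#' @param trace a `dyn_trace` from [simulate_pull_trace()] or [read_trace()].
#' @param path file path.
#' @return readers return tibbles (`dyn_trace` / `dyn_events`); writers return
#'   `path` invisibly.
#' @name trace_io
NULL

trap_to_meta <- function(trap, condition = NULL) {
  fields <- trap[!vapply(trap, is.null, logical(1))]
  c(
    sprintf("# %s=%.10g", names(fields), unlist(fields)),
    if (!is.null(condition)) sprintf("# condition=%s", condition)
  )
}

#' @rdname trace_io
#' @export
write_trace <- function(trace, path) {
  stopifnot(is.data.frame(trace))
  trap <- attr(trace, "trap")
  meta <- if (inherits(trap, "trap_config")) {
    trap_to_meta(trap, attr(trace, "condition"))
  } else character(0)
  writeLines(c(meta, "time_s\tstage_nm\tforce_pN"), path)
  readr::write_tsv(
    tibble(
      time_s = sprintf("%.8g", trace$time_s),
      stage_nm = sprintf("%.8g", trace$stage_nm),
      force_pN = sprintf("%.8g", trace$force_pN)
    ),
    path, col_names = FALSE, append = TRUE
  )
  invisible(path)
}

#' @rdname trace_io
#' @export
read_trace <- function(path) {
  head_lines <- readLines(path, n = 100)
  meta_lines <- grep("^#", head_lines, value = TRUE)
  kv <- strsplit(sub("^#\\s*", "", meta_lines), "=", fixed = TRUE)
  meta <- stats::setNames(
    lapply(kv, function(p) if (length(p) == 2) p[2] else NA_character_),
    vapply(kv, `[[`, character(1), 1)
  )
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  req <- c("time_s", "stage_nm", "force_pN")
  if (!all(req %in% names(out))) {
    abort(sprintf("trace file %s is missing required columns: %s",
                  path, paste(setdiff(req, names(out)), collapse = ", ")))
  }
  out <- as_tibble(out)
  class(out) <- c("dyn_trace", class(out))
  trap_fields <- intersect(
    names(meta),
    c("k_trap", "v_stage", "sweep_amplitude", "motor_stiffness", "k_on",
      "sample_rate", "noise_sd", "tau_relax_s")
  )
  if (length(trap_fields) > 0) {
    args <- lapply(meta[trap_fields], as.numeric)
    attr(out, "trap") <- do.call(trap_config, args)
  }
  if (!is.null(meta$condition)) attr(out, "condition") <- meta$condition
  out
}

#' @rdname trace_io
#' @param events a `dyn_events` tibble.
#' @param comment optional `#`-prefixed comment lines (e.g. config hash)
#'   written before the header.
#' @export
write_events <- function(events, path, comment = character(0)) {
  stopifnot(is.data.frame(events))
  write_csv_commented(as_tibble(as.data.frame(events)), path, comment)
}

# plain CSV with optional leading "# " comment lines (readr writes the body so
# number formatting is stable across runs)
write_csv_commented <- function(x, path, comment = character(0)) {
  writeLines(c(if (length(comment)) paste0("# ", comment),
               paste(names(x), collapse = ",")), path)
  readr::write_csv(x, path, col_names = FALSE, append = TRUE)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_events <- function(path) {
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  req <- c("t_bind_s", "t_rupture_s", "rupture_force_pN", "F_start_pN",
           "direction", "is_primary")
  missing_cols <- setdiff(req, names(out))
  if (length(missing_cols)) {
    abort(sprintf("events file %s is missing required columns: %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  bad <- which(!out$direction %in% c("forward", "backward"))
  if (length(bad)) {
    abort(sprintf("events file %s: unknown direction token %s on data line %d",
                  path, out$direction[bad[1]], bad[1]))
  }
  out <- as_tibble(out)
  class(out) <- c("dyn_events", class(out))
  out
}

#' @rdname trace_io
#' @export
read_forces <- function(path) {
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  if (!"force_pN" %in% names(out)) {
    abort(sprintf("forces file %s is missing required column: force_pN", path))
  }
  bad <- which(!is.finite(out$force_pN) | out$force_pN <= 0)
  if (length(bad)) {
    abort(sprintf("forces file %s: force must be a positive magnitude, violated on data line %d",
                  path, bad[1]))
  }
  as_tibble(out)
}

#' @rdname trace_io
#' @param x list or data frame to serialize.
#' @export
write_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}

#' Read a pipeline run configuration
#'
#' JSON document with `trap`, `bond`, `analysis`, `seeds`, and `condition`
#' sections. `trap` holds [trap_config()] fields; `bond` holds either a named
#' shortcut (`type` of slip/ideal/slip-ideal/slip-ideal-slip/catch plus its
#' parameters) or an explicit `segments` table; `analysis` holds `bandwidth`,
#' `f_min`, `survival_floor`, `B_ci`, `B_test`, `alpha_level`, `ci_level`;
#' `seeds` maps stage names to integers; `condition` holds construct,
#' nucleotide and terminus labels.
#'
#' @param path JSON file path.
#' @return list with parsed `trap` ([trap_config()]), `bond` ([bond_model()],
#'   if given), `analysis`, `seeds`, `condition`, and `hash`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  trap_args <- lapply(as.list(raw$trap %||% list()), function(v) {
    if (is.character(v)) as.numeric(v) else v   # "Inf" comes through as string
  })
  cfg <- list(
    trap = do.call(trap_config, trap_args),
    analysis = utils::modifyList(
      list(bandwidth = NULL, f_min = 0.5, survival_floor = 0.05,
           B_ci = 4000, B_test = 1e5, B_rate = 500, alpha_level = 0.05,
           ci_level = 0.99),
      as.list(raw$analysis %||% list())
    ),
    seeds = as.list(raw$seeds %||% list()),
    condition = as.list(raw$condition %||% list(label = "unspecified"))
  )
  if (!is.null(raw$bond)) {
    b <- as.list(raw$bond)
    cfg$bond <- if (!is.null(b$segments)) {
      bond_model(as_tibble(b$segments), label = b$label %||% "custom")
    } else {
      switch(b$type %||% "slip",
        slip  = bond_slip(b$k0, b$f_scale),
        ideal = bond_ideal(b$k0),
        catch = bond_catch(b$k0, b$f_scale),
        `slip-ideal` = bond_slip_ideal(b$k0, b$f_scale, b$f_break %||% 2),
        `slip-ideal-slip` = bond_slip_ideal_slip(
          b$k0, b$f_scale, b$f_break %||% 2, b$f_break2 %||% 5,
          b$f_scale2 %||% b$f_scale
        ),
        abort(sprintf("unknown bond type '%s' in config %s", b$type, path))
      )
    }
  }
  cfg$hash <- config_hash(raw)
  cfg
}
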