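#' Run the full unbinding-force analysis pipeline
#'
#' Glues the stages together: event detection on each trace, primary-event
#' filtering, a per-direction split, normalized histograms and rate curves
#' with bootstrap confidence bands, bootstrap CIs on the mean unbinding force,
#' and the registry call. Writes `events.csv`, `rates.csv`, `ci.json`,
#' `call.json` and `run.log` into `out_dir`; every file carries the config
#' hash so a rerun with identical config and seeds is byte-identical.
#'
#' @param config a configuration list as returned by [read_run_config()], or a
#'   path to a JSON config file.
#' @param traces list of `dyn_trace` objects (or paths to trace files);
#'   alternatively supply `forces` directly.
#' @param forces data frame with `force_pN` and `direction` columns (primary
#'   unbinding forces), used when no traces are given.
#' @param out_dir output directory (created if missing); `NULL` for no files.
#' @return invisibly, a list with `events`, `forces`, `histograms`, `rates`,
#'   `ci`, `call`, and `files`.
#' @export
run_pipeline <- function(config, traces = NULL, forces = NULL, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$trap)) abort("pipeline config must contain a `trap` section")
  if (is.null(traces) && is.null(forces)) {
    abort("run_pipeline needs at least one input: `traces` or `forces`")
  }
  an <- config$analysis
  seeds <- config$seeds
  cond <- config$condition$label %||% "unspecified"
  hash <- config$hash %||% config_hash(config[c("analysis", "condition")])
  log_lines <- c(
    sprintf("dynforce %s", as.character(utils::packageVersion("dynforce"))),
    sprintf("config_md5 %s", hash),
    sprintf("condition %s", cond)
  )
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "dynforce_pipeline_error", parent = e)
    })
  }

  events <- NULL
  if (!is.null(traces)) {
    if (is.data.frame(traces)) traces <- list(traces)
    events <- stage("detect", {
      evs <- purrr::map(traces, function(tr) {
        if (is.character(tr)) tr <- read_trace(tr)
        detect_events(tr)
      })
      bind_rows(evs, .id = "trace_id")
    })
    log_lines <- c(log_lines, sprintf("detected_events %d", nrow(events)))
    primary <- stage("filter_primary", filter_primary(events))
    log_lines <- c(log_lines, sprintf("primary_events %d", nrow(primary)))
    forces <- tibble(
      force_pN = primary$rupture_force_pN,
      direction = primary$direction,
      condition = cond
    )
  } else {
    forces <- as_tibble(forces)
    if (!"direction" %in% names(forces)) forces$direction <- "backward"
    forces$condition <- cond
    log_lines <- c(log_lines, sprintf("input_forces %d", nrow(forces)))
  }

  by_dir <- split(forces, forces$direction)
  log_lines <- c(log_lines, sprintf("events_%s %d", names(by_dir),
                                    vapply(by_dir, nrow, integer(1))))

  histograms <- stage("histogram", purrr::map(by_dir, normalized_histogram))
  rates <- stage("rate_curve", purrr::imap(by_dir, function(d, dir) {
    boot_rate_ci(
      d, config$trap, B = an$B_rate %||% 500,
      seed = seeds$rates %||% 1L,
      bandwidth = an$bandwidth, f_min = an$f_min,
      survival_floor = an$survival_floor
    )
  }))
  ci <- stage("boot_ci", purrr::imap(by_dir, function(d, dir) {
    boot_ci_mean(d, B = an$B_ci, seed = seeds$ci %||% 1L)
  }))
  call <- NULL
  if (all(c("forward", "backward") %in% names(by_dir)) &&
      nrow(by_dir$forward) >= 30 && nrow(by_dir$backward) >= 30) {
    call <- stage("classify", classify_registry(
      by_dir$forward, by_dir$backward,
      alpha_level = an$alpha_level, ci_level = an$ci_level,
      B = an$B_ci, seed = seeds$classify %||% 1L, condition = cond
    ))
    log_lines <- c(log_lines, sprintf("registry_call %s", call$summary))
  } else {
    log_lines <- c(log_lines, "registry_call skipped (need >= 30 events per direction)")
  }

  files <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files$events <- file.path(out_dir, "events.csv")
    if (!is.null(events)) {
      write_events(events, files$events, comment = sprintf("config_md5=%s", hash))
    } else {
      write_events_like_forces(forces, files$events, hash)
    }
    files$rates <- file.path(out_dir, "rates.csv")
    rates_tbl <- bind_rows(purrr::imap(rates, function(rc, dir) {
      tibble(
        force_pN = rc$force_pN, rate_per_s = rc$rate_per_s,
        ci_lo = rc$ci_lo, ci_hi = rc$ci_hi,
        direction = dir, condition = cond
      )
    }))
    write_csv_commented(rates_tbl, files$rates,
                        comment = sprintf("config_md5=%s", hash))
    files$ci <- file.path(out_dir, "ci.json")
    write_report(list(config_md5 = hash, condition = cond,
                      ci = purrr::map(ci, as.list)), files$ci)
    files$call <- file.path(out_dir, "call.json")
    if (!is.null(call)) {
      write_report(list(
        config_md5 = hash, condition = cond, summary = call$summary,
        backward = call$backward_label, forward = call$forward_label,
        mode = call$mode, details = call$details
      ), files$call)
    }
    files$log <- file.path(out_dir, "run.log")
    writeLines(log_lines, files$log)
  }

  invisible(list(
    events = events, forces = forces, histograms = histograms,
    rates = rates, ci = ci, call = call, files = files, log = log_lines
  ))
}

write_events_like_forces <- function(forces, path, hash) {
  write_csv_commented(forces, path, sprintf("config_md5=%s", hash))
}
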