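# internal helpers shared across modules

#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange select bind_rows group_by summarise ungroup
NULL

# evaluate `expr` under a local RNG seed without disturbing the caller's stream;
# seed = NULL means "use the current stream"
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# cumulative trapezoid integral of y over x, same length as x, starting at 0
cumtrapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

stopifnot_scalar_number <- function(x, name, positive = FALSE, allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (allow_inf || is.finite(x)) && (!positive || x > 0)
  if (!ok) {
    abort(sprintf(
      "`%s` must be a single %s%snumber, got %s",
      name, if (positive) "positive " else "", if (allow_inf) "(possibly infinite) " else "",
      paste(format(x), collapse = ", ")
    ), class = "dynforce_invalid_config")
  }
  invisible(x)
}

# accept either a bare numeric vector or a data frame with `column`
pull_numeric <- function(x, column = "force_pN", what = "forces") {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.data.frame(x)) {
    if (!column %in% names(x)) {
      abort(sprintf("data frame input for %s must have a `%s` column", what, column))
    }
    return(as.numeric(x[[column]]))
  }
  abort(sprintf("%s must be a numeric vector or a data frame with a `%s` column", what, column))
}

# md5 of a canonical JSON rendering; used to stamp outputs for reproducibility
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = 12, force = TRUE)
  unname(tools::md5sum(tf))
}
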