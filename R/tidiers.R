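#' Tidiers for fitted dynforce objects
#'
#' broom-style `tidy()` and `glance()` methods: `tidy()` returns the
#' per-component table (per-reference diagnostics of a registry call, the
#' fitted segments of a bond phenotype), `glance()` a one-row summary.
#'
#' @param x a `registry_call` or `bond_phenotype`.
#' @param ... unused.
#' @return a tibble.
#' @name dynforce-tidiers
NULL

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname dynforce-tidiers
#' @method tidy registry_call
#' @export
tidy.registry_call <- function(x, ...) {
  x$details
}

#' @rdname dynforce-tidiers
#' @method glance registry_call
#' @export
glance.registry_call <- function(x, ...) {
  tibble(
    condition = x$condition, summary = x$summary,
    backward_label = x$backward_label, forward_label = x$forward_label,
    n_backward = x$n_backward, n_forward = x$n_forward, mode = x$mode
  )
}

#' @rdname dynforce-tidiers
#' @method tidy bond_phenotype
#' @export
tidy.bond_phenotype <- function(x, ...) {
  x$segments
}

#' @rdname dynforce-tidiers
#' @method glance bond_phenotype
#' @export
glance.bond_phenotype <- function(x, ...) {
  tibble(
    label = x$label, pattern = x$pattern,
    n_segments = nrow(x$segments),
    breakpoints = paste(round(x$breakpoints, 3), collapse = ";")
  )
}
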