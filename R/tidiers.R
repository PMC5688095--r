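#' Tidy the per-cell calls of a pipeline result
#'
#' Broom-style accessors: `tidy()` returns the per-cell audit trail (one row
#' per cell, every gate outcome and failure reasons), `glance()` the
#' per-sample, per-population summary (`n`, `n_pos`, `pct_pla_pos`).
#'
#' @param x A `plic_result` from [run_pipeline()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy plic_result
#' @export
tidy.plic_result <- function(x, ...) x$calls

#' @rdname tidy.plic_result
#' @method glance plic_result
#' @export
glance.plic_result <- function(x, ...) x$summary

#' Tidy a group comparison
#'
#' `tidy()` returns the per-group means and s.e.m.; `glance()` the one-row
#' test summary (`t`, `df`, `p_value`, `method`).
#'
#' @param x A `plic_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy plic_comparison
#' @export
tidy.plic_comparison <- function(x, ...) x$groups

#' @rdname tidy.plic_comparison
#' @method glance plic_comparison
#' @export
glance.plic_comparison <- function(x, ...) {
  tibble::tibble(t = x$t, df = x$df, p_value = x$p_value, method = x$method)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
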