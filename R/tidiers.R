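#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the fitted variance prior
#'
#' @param x a `var_prior` from [fit_variance_prior()].
#' @param ... unused.
#' @return a tibble with one row per parameter (`d0`, `s0_sq`).
#' @export
tidy.var_prior <- function(x, ...) {
  tibble::tibble(term = c("d0", "s0_sq"), estimate = c(x$d0, x$s0_sq))
}

#' @rdname tidy.var_prior
#' @return for `glance()`: a one-row tibble with the parameters and the fit
#'   bookkeeping (`n_used`, `n_zero`, `df_mean`).
#' @export
glance.var_prior <- function(x, ...) {
  tibble::tibble(d0 = x$d0, s0_sq = x$s0_sq, n_used = x$n_used,
                 n_zero = x$n_zero, df_mean = x$df_mean)
}

#' @export
print.var_prior <- function(x, ...) {
  cat(sprintf(
    "Empirical-Bayes variance prior: d0 = %s, s0^2 = %.6g (%d genes, %d zero-variance dropped)\n",
    if (is.infinite(x$d0)) "Inf" else sprintf("%.3f", x$d0),
    x$s0_sq, x$n_used, x$n_zero))
  invisible(x)
}

#' One-row summary of an enrichment result
#'
#' @param x an `enrich_result` from [enrich()].
#' @param ... unused.
#' @return a one-row tibble: numbers of terms tested and significant, the
#'   alpha, and the adjustment procedure.
#' @export
glance.enrich_result <- function(x, ...) {
  tibble::tibble(n_terms = nrow(x), n_significant = sum(x$significant),
                 alpha = attr(x, "alpha"), adjust = attr(x, "adjust"))
}

#' Per-cell pattern-call summary
#'
#' @param x a `pattern_calls` tibble from [classify_patterns()].
#' @param ... unused.
#' @return a tibble with one row per (line, generation): gene totals,
#'   dominance-class and additivity counts.
#' @export
glance.pattern_calls <- function(x, ...) {
  x %>%
    dplyr::group_by(.data$line, .data$generation) %>%
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_parent_divergent = sum(.data$parent_divergent),
      n_dominance = sum(.data$dominance %in%
                          c("diploid_high", "diploid_low",
                            "tetraploid_high", "tetraploid_low")),
      n_excluded_mpv_bias = sum(.data$dominance == "excluded_mpv_bias"),
      n_nonadditive = sum(.data$additivity == "nonadditive"),
      n_up = sum(.data$direction == "up"),
      n_down = sum(.data$direction == "down"),
      .groups = "drop")
}
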