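#' Plot the non-additive category composition of each study cell
#'
#' Stacked bars of the non-additive expression categories per (line,
#' generation) cell.
#'
#' @param object a `pattern_calls` tibble from [classify_patterns()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pattern_calls <- function(object, ...) {
  dat <- object %>%
    dplyr::filter(.data$additivity == "nonadditive") %>%
    dplyr::count(.data$line, .data$generation, .data$nonadd_category)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$generation, y = .data$n,
                                    fill = .data$nonadd_category)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$line)) +
    ggplot2::labs(x = "generation", y = "non-additive genes",
                  fill = "category") +
    ggplot2::theme_minimal()
}

#' Plot an enrichment result
#'
#' Dot plot of the most enriched terms: fold enrichment against terms
#' ordered by adjusted p-value, sized by target hits and colored by
#' significance.
#'
#' @param object an `enrich_result` from [enrich()].
#' @param top number of terms to show.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.enrich_result <- function(object, top = 20, ...) {
  dat <- utils::head(dplyr::arrange(tibble::as_tibble(object), .data$q,
                                    .data$p), top)
  lab <- ifelse(is.na(dat$name), dat$term_id, dat$name)
  dat$label <- factor(lab, levels = rev(unique(lab)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$fold, y = .data$label,
                                    size = .data$k,
                                    color = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "fold enrichment", y = NULL, size = "target hits",
                  color = sprintf("q < %.2g", attr(object, "alpha"))) +
    ggplot2::theme_minimal()
}

#' MA-style plot of one contrast
#'
#' Log2 difference against mean log2 expression for a chosen contrast in a
#' chosen cell, colored by significance — e.g. `"H-M"` displays departure
#' from mid-parent additivity.
#'
#' @param contrasts a `contrast_tbl` from [contrast_table()].
#' @param contrast one of `"T-D"`, `"H-T"`, `"H-D"`, `"H-M"`, `"M-T"`,
#'   `"M-D"`.
#' @param line,generation the cell to plot; defaults to the first cell
#'   present.
#' @return a ggplot object.
#' @export
plot_contrast_ma <- function(contrasts, contrast = "H-M", line = NULL,
                             generation = NULL) {
  stopifnot(contrast %in% cell_contrasts())
  if (is.null(line)) line <- contrasts$line[1]
  if (is.null(generation)) generation <- contrasts$generation[1]
  ct <- contrast
  dat <- dplyr::filter(contrasts, .data$contrast == ct,
                       .data$line == !!line,
                       .data$generation == !!generation)
  ggplot2::ggplot(dat, ggplot2::aes(x = (.data$mean_a + .data$mean_b) / 2,
                                    y = .data$diff,
                                    color = .data$significant)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "mean log2 expression", y = paste("log2", contrast),
                  title = sprintf("%s, line %s, generation %s", contrast,
                                  line, generation)) +
    ggplot2::theme_minimal()
}
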