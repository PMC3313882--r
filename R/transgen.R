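#' Per-gene presence signatures over the study cells
#'
#' For a chosen pattern class (any per-row logical condition on the calls,
#' e.g. `additivity == "nonadditive"` or
#' `dominance %in% c("diploid_high", "diploid_low")`), records in which
#' (line, generation) cells each gene shows the class. Genes flagged in no
#' cell are dropped.
#'
#' @param calls a `pattern_calls` tibble (or any tibble with `gene_id`,
#'   `line`, `generation` columns).
#' @param flag a logical expression evaluated per row of `calls`.
#' @return a tibble `gene_id`, `line`, `generation` with one row per flagged
#'   cell, carrying the full line/generation universe as attributes.
#' @export
#' @examples
#' \dontrun{
#' sig <- presence_signatures(calls, additivity == "nonadditive")
#' assign_groups(sig)
#' }
presence_signatures <- function(calls, flag) {
  out <- calls %>%
    dplyr::filter({{ flag }}) %>%
    dplyr::distinct(.data$gene_id, .data$line, .data$generation)
  attr(out, "lines") <- sort(unique(calls$line))
  attr(out, "generations") <- sort(unique(calls$generation))
  out
}

#' Transgenerational group of each flagged gene
#'
#' Classifies every gene by where its pattern occurs across the line x
#' generation grid: `stochastic` (group I) — one line at one generation
#' only; `heritable` (group II) — one line at both generations;
#' `persistent` (group III) — both lines at both generations. Multi-cell
#' combinations covered by none of the three definitions (e.g. both lines
#' at a single generation) are reported explicitly as `shared_other` rather
#' than silently merged.
#'
#' @param signatures output of [presence_signatures()] (long tibble of
#'   flagged gene x cell rows).
#' @param lines,generations the cell universe; defaults to the attributes
#'   set by [presence_signatures()] or, failing that, the values present.
#' @return a tibble `gene_id`, `n_cells`, `group`.
#' @export
assign_groups <- function(signatures,
                          lines = attr(signatures, "lines"),
                          generations = attr(signatures, "generations")) {
  if (nrow(signatures) == 0) {
    stop("empty signature set.", call. = FALSE)
  }
  if (is.null(lines)) lines <- sort(unique(signatures$line))
  if (is.null(generations)) generations <- sort(unique(signatures$generation))
  n_total <- length(lines) * length(generations)
  signatures %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(n_cells = dplyr::n(),
                     n_lines = dplyr::n_distinct(.data$line),
                     n_gens = dplyr::n_distinct(.data$generation),
                     .groups = "drop") %>%
    dplyr::mutate(group = dplyr::case_when(
      .data$n_cells == 1 ~ "stochastic",
      .data$n_lines == 1 & .data$n_gens == length(generations) ~ "heritable",
      .data$n_cells == n_total ~ "persistent",
      TRUE ~ "shared_other")) %>%
    dplyr::select("gene_id", "n_cells", "group")
}

#' Set overlap (Venn) summary of two gene sets
#'
#' @param set_a,set_b character vectors of gene ids.
#' @return one-row tibble: `size_a`, `size_b`, `intersection`, `union`,
#'   `shared_percent` (100 * intersection / union, exact; round to one
#'   decimal for reporting).
#' @export
#' @examples
#' venn(letters[1:4], letters[3:6])
venn <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  i <- length(intersect(a, b))
  u <- length(union(a, b))
  venn_counts(length(a), length(b), i)
}

#' Venn summary from counts
#'
#' Builds the same summary as [venn()] from the three counts directly
#' (useful when only published set sizes are available).
#'
#' @param size_a,size_b,intersection nonnegative integers with
#'   `intersection <= min(size_a, size_b)`.
#' @return one-row tibble as in [venn()].
#' @export
#' @examples
#' venn_counts(828, 1642, 385)   # shared_percent 18.47 -> "18.5%"
venn_counts <- function(size_a, size_b, intersection) {
  stopifnot(size_a >= 0, size_b >= 0, intersection >= 0,
            intersection <= min(size_a, size_b))
  u <- size_a + size_b - intersection
  tibble::tibble(size_a = as.integer(size_a), size_b = as.integer(size_b),
                 intersection = as.integer(intersection),
                 union = as.integer(u),
                 shared_percent = if (u > 0) 100 * intersection / u else 0)
}

#' Per-cell and per-line summary of non-additive expression
#'
#' Reproduces the reporting conventions of a transgenerational
#' non-additivity table: per (line, generation) cell, the number and percent
#' (of all expressed genes) of non-additive genes, the up/down split as
#' percent of the cell's non-additive total, the per-category counts, and
#' the overlap with parent-divergent genes. The per-line `average` row
#' averages the two generations' counts but recomputes every percentage
#' from the pooled counts (so e.g. pooled up-share
#' `100 * (485 + 826) / (828 + 1642) = 53.1`).
#'
#' @param calls a `pattern_calls` tibble.
#' @param expressed_n size of the expressed-gene universe (> 0).
#' @return a tibble with one row per line x (generation or `"average"`).
#' @export
summarize_cells <- function(calls, expressed_n) {
  if (expressed_n <= 0) stop("`expressed_n` must be positive.", call. = FALSE)
  cats <- c("high_diploid_dominance", "low_diploid_dominance",
            "high_tetraploid_dominance", "low_tetraploid_dominance",
            "over_dominance", "under_dominance", "other")
  per_cell <- calls %>%
    dplyr::group_by(.data$line, .data$generation) %>%
    dplyr::summarise(
      n_expressed = dplyr::n(),
      n_nonadditive = sum(.data$additivity == "nonadditive"),
      n_up = sum(.data$direction == "up"),
      n_down = sum(.data$direction == "down"),
      n_parent_divergent_nonadd = sum(.data$additivity == "nonadditive" &
                                        .data$parent_divergent),
      .groups = "drop")
  cat_counts <- calls %>%
    dplyr::filter(.data$additivity == "nonadditive") %>%
    dplyr::count(.data$line, .data$generation, .data$nonadd_category) %>%
    tidyr::pivot_wider(names_from = "nonadd_category", values_from = "n",
                       values_fill = 0L)
  idx <- match(paste(per_cell$line, per_cell$generation),
               paste(cat_counts$line, cat_counts$generation))
  for (ct in cats) {
    cnt <- if (ct %in% names(cat_counts)) cat_counts[[ct]][idx] else
      rep(NA_integer_, nrow(per_cell))
    per_cell[[paste0("n_", ct)]] <- ifelse(is.na(cnt), 0L, cnt)
  }
  averages <- per_cell %>%
    dplyr::group_by(.data$line) %>%
    dplyr::summarise(generation = "average",
                     dplyr::across(dplyr::starts_with("n_"), sum),
                     .groups = "drop")
  n_gens <- dplyr::n_distinct(per_cell$generation)
  count_cols <- grep("^n_", names(averages), value = TRUE)
  pct <- function(tbl, pooled = FALSE) {
    denom_nonadd <- tbl$n_nonadditive
    tbl <- tbl %>% dplyr::mutate(
      pct_nonadditive = 100 * .data$n_nonadditive /
        (expressed_n * (if (pooled) n_gens else 1)),
      pct_additive = 100 - .data$pct_nonadditive,
      pct_up = ifelse(denom_nonadd > 0, 100 * .data$n_up / denom_nonadd, 0),
      pct_down = ifelse(denom_nonadd > 0, 100 * .data$n_down / denom_nonadd, 0),
      pct_parent_divergent = ifelse(denom_nonadd > 0,
        100 * .data$n_parent_divergent_nonadd / denom_nonadd, 0))
    for (ct in cats) {
      tbl[[paste0("pct_", ct)]] <-
        ifelse(denom_nonadd > 0, 100 * tbl[[paste0("n_", ct)]] / denom_nonadd, 0)
    }
    tbl
  }
  per_cell <- pct(per_cell)
  averages <- pct(averages, pooled = TRUE)
  # the average row's counts are generation means (percentages stay pooled)
  averages <- averages %>%
    dplyr::mutate(dplyr::across(dplyr::all_of(count_cols), \(x) x / n_gens))
  dplyr::bind_rows(per_cell, averages) %>%
    dplyr::arrange(.data$line,
                   factor(.data$generation,
                          c(sort(unique(per_cell$generation)), "average")))
}
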