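#' Pivot a contrast table to one row per gene and cell
#'
#' Spreads the six pairwise contrasts into per-cell columns
#' (`sig_td`, `sig_ht`, ..., `d_td`, `d_ht`, ...), the wide form consumed by
#' the pattern-classification rules. `d_xy` is the log2 difference
#' `mean(X) - mean(Y)` of the contrast `X-Y`.
#'
#' @param contrasts a `contrast_tbl` from [contrast_table()].
#' @return a tibble with one row per gene x (line, generation).
#' @export
pivot_contrasts <- function(contrasts) {
  code <- c("T-D" = "td", "H-T" = "ht", "H-D" = "hd",
            "H-M" = "hm", "M-T" = "mt", "M-D" = "md")
  missing_ct <- setdiff(names(code), unique(contrasts$contrast))
  if (length(missing_ct) > 0) {
    stop("contrast table lacks contrast(s): ",
         paste(missing_ct, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(contrasts[c("gene_id", "line", "generation",
                                "contrast")])) {
    stop("duplicated gene within a (line, generation) cell.", call. = FALSE)
  }
  wide <- contrasts %>%
    dplyr::mutate(code = code[.data$contrast]) %>%
    dplyr::select("gene_id", "line", "generation", "code", "diff",
                  "significant") %>%
    tidyr::pivot_wider(names_from = "code",
                       values_from = c("diff", "significant"),
                       names_glue = "{.value}_{code}") %>%
    dplyr::rename_with(~ sub("^diff_", "d_", .x)) %>%
    dplyr::rename_with(~ sub("^significant_", "sig_", .x))
  if (anyDuplicated(wide[c("gene_id", "line", "generation")])) {
    stop("duplicated gene within a (line, generation) cell.", call. = FALSE)
  }
  wide
}

#' Parental-dominance call with mid-parent bias exclusion
#'
#' A gene shows *parental expression dominance* in a cell when the parents
#' differ (T-D significant), the polyploid is statistically equal to exactly
#' one parent (exactly one of H-T, H-D significant), and the empirical
#' mid-parent mixture does **not** show the same bias. If the mixture also
#' sticks to the same parent the apparent dominance is attributable to
#' differential hybridization affinity of the parental transcript pools and
#' the gene is excluded (`excluded_mpv_bias`). A mixture biased toward the
#' *other* parent does not exclude. "Statistically equal" means
#' non-significance of the moderated test at the run's alpha.
#'
#' @param wide a wide per-gene-per-cell tibble from [pivot_contrasts()].
#' @return `wide` with a `dominance` column added, one of `not_divergent`,
#'   `diploid_high`, `diploid_low`, `tetraploid_high`, `tetraploid_low`,
#'   `excluded_mpv_bias`, `none`.
#' @export
dominance_call <- function(wide) {
  hex_bias <- xor(wide$sig_ht, wide$sig_hd)
  hex_parent <- ifelse(!wide$sig_hd, "D", "T")   # parent H is equal to
  mpv_bias <- xor(wide$sig_mt, wide$sig_md)
  mpv_parent <- ifelse(!wide$sig_md, "D", "T")
  d_higher <- wide$d_td < 0                      # d_td = mean(T) - mean(D)
  wide$dominance <- dplyr::case_when(
    !wide$sig_td ~ "not_divergent",
    hex_bias & mpv_bias & mpv_parent == hex_parent ~ "excluded_mpv_bias",
    hex_bias & hex_parent == "D" & d_higher ~ "diploid_high",
    hex_bias & hex_parent == "D" & !d_higher ~ "diploid_low",
    hex_bias & hex_parent == "T" & !d_higher ~ "tetraploid_high",
    hex_bias & hex_parent == "T" & d_higher ~ "tetraploid_low",
    TRUE ~ "none")
  wide
}

#' Additivity call against the empirical mid-parent value
#'
#' A gene is *non-additive* in a cell iff the polyploid differs significantly
#' from the mid-parent mixture (H-M significant; a p-value exactly at alpha
#' counts as additive). The direction is the sign of the H - M log2
#' difference.
#'
#' @inheritParams dominance_call
#' @return `wide` with `additivity` (`additive`/`nonadditive`) and
#'   `direction` (`up`/`down`/`none`) columns added.
#' @export
additivity_call <- function(wide) {
  wide$additivity <- ifelse(wide$sig_hm, "nonadditive", "additive")
  wide$direction <- dplyr::case_when(
    !wide$sig_hm ~ "none",
    wide$d_hm > 0 ~ "up",
    TRUE ~ "down")
  wide
}

#' Category of a non-additively expressed gene
#'
#' Within the non-additive set, a gene is `over_dominance` if the polyploid
#' sits significantly above both parents, `under_dominance` if significantly
#' below both, a high/low diploid (tetraploid) dominance category if it is
#' statistically equal to the diploid (tetraploid) parent, different from
#' the other, the parents themselves differ, and the matched parent is the
#' higher/lower one; everything else falls into the residual class `other`.
#' The mid-parent bias filter is *not* applied here by default
#' (non-additivity already requires H to differ from the mixture); set
#' `mpv_filter = TRUE` to divert same-parent mixture-biased genes to
#' `other`.
#'
#' @inheritParams dominance_call
#' @param mpv_filter apply the mid-parent bias exclusion inside the
#'   non-additive categories as well.
#' @return `wide` with a `nonadd_category` column added (`not_applicable`
#'   for additive rows).
#' @export
nonadditive_category <- function(wide, mpv_filter = FALSE) {
  if (!"additivity" %in% names(wide)) wide <- additivity_call(wide)
  nonadd <- wide$additivity == "nonadditive"
  d_higher <- wide$d_td < 0
  mpv_bias <- xor(wide$sig_mt, wide$sig_md)
  mpv_parent <- ifelse(!wide$sig_md, "D", "T")
  dom_ok <- function(parent) {
    if (!mpv_filter) return(TRUE)
    !(mpv_bias & mpv_parent == parent)
  }
  wide$nonadd_category <- dplyr::case_when(
    !nonadd ~ "not_applicable",
    wide$sig_ht & wide$sig_hd & wide$d_ht > 0 & wide$d_hd > 0 ~ "over_dominance",
    wide$sig_ht & wide$sig_hd & wide$d_ht < 0 & wide$d_hd < 0 ~ "under_dominance",
    wide$sig_td & !wide$sig_hd & wide$sig_ht & d_higher & dom_ok("D") ~
      "high_diploid_dominance",
    wide$sig_td & !wide$sig_hd & wide$sig_ht & !d_higher & dom_ok("D") ~
      "low_diploid_dominance",
    wide$sig_td & !wide$sig_ht & wide$sig_hd & !d_higher & dom_ok("T") ~
      "high_tetraploid_dominance",
    wide$sig_td & !wide$sig_ht & wide$sig_hd & d_higher & dom_ok("T") ~
      "low_tetraploid_dominance",
    TRUE ~ "other")
  wide
}

#' Classify every gene of every study cell
#'
#' Runs the dominance, additivity and non-additive-category rules on a
#' contrast table and returns one pattern call per gene and (line,
#' generation) cell.
#'
#' @param contrasts a `contrast_tbl` from [contrast_table()].
#' @param mpv_filter_table1 apply the mid-parent bias filter inside the
#'   non-additive categories too (off by default; the dominance call always
#'   applies it).
#' @return an object of class `pattern_calls`: a tibble with columns
#'   `gene_id`, `line`, `generation`, `parent_divergent`, `dominance`,
#'   `additivity`, `direction`, `nonadd_category`.
#' @export
classify_patterns <- function(contrasts, mpv_filter_table1 = FALSE) {
  wide <- pivot_contrasts(contrasts)
  wide <- dominance_call(wide)
  wide <- additivity_call(wide)
  wide <- nonadditive_category(wide, mpv_filter = mpv_filter_table1)
  out <- wide %>%
    dplyr::mutate(parent_divergent = .data$sig_td) %>%
    dplyr::select("gene_id", "line", "generation", "parent_divergent",
                  "dominance", "additivity", "direction", "nonadd_category") %>%
    dplyr::arrange(.data$line, .data$generation, .data$gene_id)
  attr(out, "alpha") <- attr(contrasts, "alpha")
  class(out) <- c("pattern_calls", class(out))
  out
}
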