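#' Pipeline configuration
#'
#' Bundles and validates everything [run_pipeline()] needs. Exactly one
#' input mode is active: `"simulate"` (a [sim_config()] describes the
#' study), `"panel"` (probe-level TSVs on disk), or `"expression"` (a
#' gene-level log2 TSV plus sample sheet, optionally with a precomputed
#' expressed set, in which case normalization and detection are skipped).
#'
#' @param mode input mode.
#' @param sim a [sim_config()] (simulate mode).
#' @param panel_dir directory holding `pm.tsv`, `mm.tsv`, `samples.csv`
#'   (panel mode).
#' @param expression_path,sample_sheet_path gene-level TSV and sample sheet
#'   (expression mode).
#' @param expressed optional character vector of expressed gene ids
#'   (expression mode; defaults to all genes in the table).
#' @param annotation,terms optional annotation tibbles for enrichment (see
#'   [enrich()]).
#' @param alpha significance cutoff for all moderated tests (strict `<`).
#' @param tau,alpha1,alpha2 detection parameters (see [detection_call()]).
#' @param skip_background skip background correction in [rma()].
#' @param mpv_filter_table1 apply the mid-parent bias filter inside the
#'   non-additive categories (see [nonadditive_category()]).
#' @param adjust FDR procedure for enrichment.
#' @param outdir optional output directory for TSV/JSON artifacts.
#' @param seed integer seed overriding the simulation config's seed.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("simulate", "panel", "expression"),
                            sim = NULL, panel_dir = NULL,
                            expression_path = NULL, sample_sheet_path = NULL,
                            expressed = NULL, annotation = NULL, terms = NULL,
                            alpha = 0.05, tau = 0.015, alpha1 = 0.04,
                            alpha2 = 0.06, skip_background = FALSE,
                            mpv_filter_table1 = FALSE,
                            adjust = c("BH", "hochberg"),
                            outdir = NULL, seed = NULL) {
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1).",
                                     call. = FALSE)
  if (mode == "simulate" && !inherits(sim, "sim_config")) {
    stop("simulate mode needs a `sim_config()`.", call. = FALSE)
  }
  if (mode == "panel" && is.null(panel_dir)) {
    stop("panel mode needs `panel_dir`.", call. = FALSE)
  }
  if (mode == "expression" &&
      (is.null(expression_path) || is.null(sample_sheet_path))) {
    stop("expression mode needs `expression_path` and `sample_sheet_path`.",
         call. = FALSE)
  }
  if (!is.null(seed) && mode == "simulate") {
    sim$seed <- as.integer(seed)
  }
  structure(list(mode = mode, sim = sim, panel_dir = panel_dir,
                 expression_path = expression_path,
                 sample_sheet_path = sample_sheet_path, expressed = expressed,
                 annotation = annotation, terms = terms, alpha = alpha,
                 tau = tau, alpha1 = alpha1, alpha2 = alpha2,
                 skip_background = skip_background,
                 mpv_filter_table1 = mpv_filter_table1, adjust = adjust,
                 outdir = outdir, seed = seed),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulates or loads the inputs, normalizes (RMA-style) and computes
#' detection calls where probe-level data exist, restricts to the expressed
#' universe, fits the shared variance prior and the six pairwise contrasts
#' per cell, classifies dominance and additivity patterns, derives
#' transgenerational groups and set overlaps for the non-additive and
#' dominance classes, builds the per-cell summary table, optionally runs
#' term enrichment of the non-additive union against the expressed universe,
#' and (if `outdir` is set) writes every table as TSV/JSON plus a run log
#' with per-stage gene counts. Deterministic given the seed.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly when writing to disk) a named list of results:
#'   `truth`, `design`, `expr`, `detection`, `expressed`, `prior`,
#'   `contrasts`, `contrast_counts`, `calls`, `groups_nonadditive`,
#'   `groups_dominance`, `venn_nonadditive`, `table1`, `enrichment`,
#'   `run_log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  detection <- NULL
  if (config$mode == "simulate") {
    truth <- build_truth(config$sim)
    design <- sim_design(config$sim)
    panel <- simulate_panel(truth, design)
  } else if (config$mode == "panel") {
    panel <- read_panel_tsv(config$panel_dir)
    design <- panel$design
  } else {
    expr <- read_expression_tsv(config$expression_path)
    design <- read_sample_sheet(config$sample_sheet_path)
    attr(expr, "design") <- design
    panel <- NULL
  }
  if (!is.null(panel)) {
    expr <- rma(panel, skip_background = config$skip_background)
    detection <- detect_calls(panel, tau = config$tau,
                              alpha1 = config$alpha1, alpha2 = config$alpha2)
    expressed <- expressed_set(detection, design)
  } else {
    expressed <- if (!is.null(config$expressed)) config$expressed else
      expr$gene_id
  }
  n_input <- nrow(expr)
  expr_use <- dplyr::filter(expr, .data$gene_id %in% expressed)
  attr(expr_use, "design") <- design
  contrasts <- contrast_table(expr_use, design, alpha = config$alpha)
  prior <- attr(contrasts, "prior")
  calls <- classify_patterns(contrasts,
                             mpv_filter_table1 = config$mpv_filter_table1)
  sig_nonadd <- presence_signatures(calls, .data$additivity == "nonadditive")
  sig_dom <- presence_signatures(
    calls, .data$dominance %in% c("diploid_high", "diploid_low",
                                  "tetraploid_high", "tetraploid_low"))
  groups_nonadd <- if (nrow(sig_nonadd) > 0) assign_groups(sig_nonadd) else
    tibble::tibble(gene_id = character(), n_cells = integer(),
                   group = character())
  groups_dom <- if (nrow(sig_dom) > 0) assign_groups(sig_dom) else
    tibble::tibble(gene_id = character(), n_cells = integer(),
                   group = character())
  lines <- unique(stats::na.omit(design$line))
  gens <- unique(stats::na.omit(design$generation))
  cell_sets <- function(sig) {
    lapply(stats::setNames(lines, lines), function(ln) {
      lapply(stats::setNames(gens, gens), function(gn) {
        sig$gene_id[sig$line == ln & sig$generation == gn]
      })
    })
  }
  ns <- cell_sets(sig_nonadd)
  venn_nonadd <- list()
  if (length(gens) == 2) {
    for (ln in lines) {
      venn_nonadd[[paste0(ln, "_generations")]] <-
        venn(ns[[ln]][[gens[1]]], ns[[ln]][[gens[2]]])
    }
  }
  if (length(lines) == 2) {
    for (gn in gens) {
      venn_nonadd[[paste0(gn, "_lines")]] <-
        venn(ns[[lines[1]]][[gn]], ns[[lines[2]]][[gn]])
    }
  }
  table1 <- summarize_cells(calls, expressed_n = length(expressed))
  enr <- NULL
  if (!is.null(config$annotation)) {
    target <- unique(sig_nonadd$gene_id)
    if (length(target) > 0) {
      enr <- enrich(config$annotation, target = target,
                    reference = expressed, terms = config$terms,
                    alpha = config$alpha, adjust = config$adjust)
    }
  }
  run_log <- list(
    mode = config$mode, alpha = config$alpha,
    n_genes_input = n_input, n_expressed = length(expressed),
    n_classified = dplyr::n_distinct(calls$gene_id),
    n_nonadditive_union = dplyr::n_distinct(sig_nonadd$gene_id),
    n_dominance_union = dplyr::n_distinct(sig_dom$gene_id),
    prior = list(d0 = prior$d0, s0_sq = prior$s0_sq),
    group_counts_nonadditive = as.list(table(groups_nonadd$group)),
    seed = if (!is.null(config$sim)) config$sim$seed else config$seed)
  res <- list(truth = truth, design = design, expr = expr,
              detection = detection, expressed = expressed, prior = prior,
              contrasts = contrasts,
              contrast_counts = contrast_summary(contrasts), calls = calls,
              groups_nonadditive = groups_nonadd,
              groups_dominance = groups_dom,
              venn_nonadditive = dplyr::bind_rows(venn_nonadd,
                                                  .id = "comparison"),
              table1 = table1, enrichment = enr, run_log = run_log)
  if (!is.null(config$outdir)) {
    write_pipeline_outputs(res, config$outdir)
    return(invisible(res))
  }
  res
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(outdir, "INCOMPLETE")
  file.create(marker)
  write_expression_tsv(res$expr, file.path(outdir, "expression.tsv"))
  write_sample_sheet(res$design, file.path(outdir, "samples.csv"))
  if (!is.null(res$detection)) {
    readr::write_tsv(res$detection$calls,
                     file.path(outdir, "detection_calls.tsv"),
                     progress = FALSE)
    readr::write_tsv(res$detection$pvals,
                     file.path(outdir, "detection_pvalues.tsv"),
                     progress = FALSE)
  }
  writeLines(res$expressed, file.path(outdir, "expressed_genes.txt"))
  readr::write_tsv(tibble::as_tibble(res$contrasts),
                   file.path(outdir, "contrasts.tsv"), progress = FALSE)
  readr::write_tsv(tibble::as_tibble(res$calls),
                   file.path(outdir, "pattern_calls.tsv"), progress = FALSE)
  readr::write_tsv(res$groups_nonadditive,
                   file.path(outdir, "groups_nonadditive.tsv"),
                   progress = FALSE)
  readr::write_tsv(res$groups_dominance,
                   file.path(outdir, "groups_dominance.tsv"),
                   progress = FALSE)
  readr::write_tsv(res$table1, file.path(outdir, "cell_summary.tsv"),
                   progress = FALSE)
  jsonlite::write_json(res$venn_nonadditive,
                       file.path(outdir, "venn_nonadditive.json"),
                       dataframe = "rows", digits = NA)
  if (!is.null(res$enrichment)) {
    readr::write_tsv(tibble::as_tibble(res$enrichment),
                     file.path(outdir, "enrichment.tsv"), progress = FALSE)
  }
  jsonlite::write_json(res$run_log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  file.remove(marker)
  invisible(outdir)
}
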