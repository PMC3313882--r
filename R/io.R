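#' Read / write a gene x sample log2 expression table
#'
#' Tab-separated, header row of sample ids, first column `gene_id`. Writing
#' then reading reproduces values to full double precision and preserves
#' row and column order; both LF and CRLF files parse identically.
#'
#' @param path file path.
#' @return [read_expression_tsv()]: an expression tibble (`gene_id` + one
#'   numeric column per sample).
#' @export
read_expression_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(out)[1] != "gene_id") {
    names(out)[1] <- "gene_id"
  }
  dup <- which(duplicated(out$gene_id))
  if (length(dup) > 0) {
    stop("duplicated gene id(s) at data line(s) ",
         paste(dup, collapse = ", "), ": ",
         paste(unique(out$gene_id[dup]), collapse = ", "), call. = FALSE)
  }
  vals <- out[-1]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) {
    stop("non-numeric expression column(s): ",
         paste(names(vals)[bad], collapse = ", "), call. = FALSE)
  }
  class(out) <- c("expr_tbl", class(out))
  out
}

#' @rdname read_expression_tsv
#' @param expr expression tibble (`gene_id` + sample columns).
#' @export
write_expression_tsv <- function(expr, path) {
  stopifnot("gene_id" %in% names(expr))
  readr::write_tsv(tibble::as_tibble(expr), path, progress = FALSE)
  invisible(path)
}

#' Read / write the sample sheet
#'
#' Comma-separated with columns `sample_id`, `role`, `line`, `generation`,
#' `replicate`; extra columns are preserved as opaque metadata. Roles are
#' restricted to `tetraploid_parent`, `diploid_parent`, `mpv`,
#' `allohexaploid`; mixture and polyploid samples must carry a line id.
#'
#' @param path file path.
#' @return a validated design tibble.
#' @export
read_sample_sheet <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("sample_id", "role", "line", "generation", "replicate")
  miss <- setdiff(req, names(out))
  if (length(miss) > 0) {
    stop("sample sheet is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::mutate(out,
                       line = as.character(.data$line),
                       generation = as.character(.data$generation),
                       replicate = as.integer(.data$replicate))
  validate_design(out)
}

#' @rdname read_sample_sheet
#' @param design design tibble.
#' @export
write_sample_sheet <- function(design, path) {
  validate_design(design)
  readr::write_csv(design, path, progress = FALSE)
  invisible(path)
}

#' Write / read a probe panel as TSV files
#'
#' The perfect-match and mismatch matrices are written as separate TSVs with
#' columns `probe_id`, `set_id`, `gene_id`, then one column per sample; the
#' design goes to a CSV sample sheet.
#'
#' @param panel a `probe_panel`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_panel_tsv <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- panel$probes[c("probe_id", "set_id", "gene_id")]
  pm_path <- file.path(dir, "pm.tsv")
  mm_path <- file.path(dir, "mm.tsv")
  sheet <- file.path(dir, "samples.csv")
  readr::write_tsv(dplyr::bind_cols(meta, tibble::as_tibble(panel$pm)),
                   pm_path, progress = FALSE)
  readr::write_tsv(dplyr::bind_cols(meta, tibble::as_tibble(panel$mm)),
                   mm_path, progress = FALSE)
  write_sample_sheet(panel$design, sheet)
  invisible(c(pm = pm_path, mm = mm_path, samples = sheet))
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(dir) {
  read_mat <- function(path) {
    tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    meta <- tb[c("probe_id", "set_id", "gene_id")]
    m <- as.matrix(tb[setdiff(names(tb), names(meta))])
    rownames(m) <- meta$probe_id
    list(meta = meta, m = m)
  }
  pm <- read_mat(file.path(dir, "pm.tsv"))
  mm_path <- file.path(dir, "mm.tsv")
  mm <- if (file.exists(mm_path)) read_mat(mm_path)$m else NULL
  design <- read_sample_sheet(file.path(dir, "samples.csv"))
  structure(list(pm = pm$m, mm = mm, probes = pm$meta, design = design,
                 config = NULL), class = "probe_panel")
}

#' Read a gene-term annotation table
#'
#' Two-column TSV `gene_id`, `term_id`, plus an optional term-metadata TSV
#' `term_id`, `name`, `namespace`.
#'
#' @param path annotation TSV path.
#' @param terms_path optional term metadata TSV path.
#' @return list with tibbles `annotation` and `terms` (possibly `NULL`).
#' @export
read_annotation_tsv <- function(path, terms_path = NULL) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("gene_id", "term_id") %in% names(ann)))
  trm <- NULL
  if (!is.null(terms_path)) {
    trm <- readr::read_tsv(terms_path, show_col_types = FALSE,
                           progress = FALSE)
    stopifnot("term_id" %in% names(trm))
    orphan <- setdiff(ann$term_id, trm$term_id)
    if (length(orphan) > 0) {
      stop("annotation references term(s) absent from the term table: ",
           paste(utils::head(orphan, 10), collapse = ", "), call. = FALSE)
    }
  }
  list(annotation = ann, terms = trm)
}
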