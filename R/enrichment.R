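#' One-sided (upper-tail) Fisher exact p-value
#'
#' Probability of observing `k` or more annotated genes in a target list of
#' size `K` drawn from a reference of size `N` containing `m` annotated
#' genes: the hypergeometric upper tail `P(X >= k)`, evaluated on the
#' log scale for stability. Vectorized over all arguments.
#'
#' @param k target genes carrying the term.
#' @param K target-list size.
#' @param m reference genes carrying the term.
#' @param N reference-list size.
#' @return numeric vector of p-values.
#' @export
#' @examples
#' fisher_upper(4, 10, 10, 100)
fisher_upper <- function(k, K, m, N) {
  if (any(k < 0) || any(k > K) || any(K > N) || any(m > N) || any(k > m) ||
      any(K - k > N - m)) {
    stop("inconsistent contingency counts.", call. = FALSE)
  }
  stats::phyper(k - 1, m, N - m, K, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_(i) = min_{j >= i} (n * p_(j) / j)`, clipped at 1, returned in input
#' order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` (false-discovery-rate step-up, the default) or
#'   `"hochberg"` (the Hochberg step-up family-wise procedure).
#' @return numeric vector of adjusted p-values.
#' @export
bh_fdr <- function(p, method = c("BH", "hochberg")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1].", call. = FALSE)
  }
  stats::p.adjust(p, method = method)
}

#' Term enrichment of a target gene list against a reference
#'
#' Singular enrichment analysis: for every term annotated to at least one
#' reference gene, tests over-representation in the target by the one-sided
#' Fisher exact test and controls the FDR by Benjamini-Hochberg (the
#' Hochberg step-up procedure is available via `adjust`). Unannotated genes
#' count in the list sizes `N` and `K` but belong to no term. When term
#' namespaces are supplied, adjustment is stratified per namespace
#' (`biological_process` / `molecular_function` / `cellular_component`),
#' matching ontology practice; `stratify = FALSE` pools. Terms with fewer
#' than 5 reference genes are tested but flagged `low_support`.
#'
#' @param annotation tibble with columns `gene_id`, `term_id` (one row per
#'   gene-term link; taken as already propagated).
#' @param target,reference character vectors of gene ids with
#'   `target` a subset of `reference`.
#' @param terms optional tibble with `term_id`, `name`, `namespace`.
#' @param alpha FDR significance cutoff.
#' @param stratify adjust per namespace (ignored without `terms`).
#' @param adjust `"BH"` or `"hochberg"`.
#' @return an object of class `enrich_result`: tibble with one row per term
#'   (`term_id`, `name`, `namespace`, `k`, `K`, `m`, `N`, `fold`, `p`, `q`,
#'   `significant`, `low_support`), sorted by `q` then `p`.
#' @export
enrich <- function(annotation, target, reference, terms = NULL, alpha = 0.05,
                   stratify = TRUE, adjust = c("BH", "hochberg")) {
  adjust <- match.arg(adjust)
  stopifnot(alpha > 0, alpha < 1)
  target <- unique(target)
  reference <- unique(reference)
  if (length(reference) == 0) stop("empty reference list.", call. = FALSE)
  stray <- setdiff(target, reference)
  if (length(stray) > 0) {
    stop("target genes missing from the reference: ",
         paste(utils::head(stray, 10), collapse = ", "),
         if (length(stray) > 10) sprintf(" (and %d more)", length(stray) - 10),
         call. = FALSE)
  }
  stopifnot(all(c("gene_id", "term_id") %in% names(annotation)))
  ann <- annotation %>%
    dplyr::distinct(.data$gene_id, .data$term_id) %>%
    dplyr::filter(.data$gene_id %in% reference)
  N <- length(reference)
  K <- length(target)
  counts <- ann %>%
    dplyr::group_by(.data$term_id) %>%
    dplyr::summarise(m = dplyr::n(),
                     k = sum(.data$gene_id %in% target), .groups = "drop")
  out <- counts %>%
    dplyr::mutate(K = K, N = N,
                  fold = ifelse(K > 0, (.data$k / K) / (.data$m / N), NA_real_),
                  p = fisher_upper(.data$k, K, .data$m, N),
                  low_support = .data$m < 5)
  if (!is.null(terms)) {
    out <- dplyr::left_join(out,
                            dplyr::distinct(terms, .data$term_id,
                                            .keep_all = TRUE),
                            by = "term_id")
  }
  if (!"namespace" %in% names(out)) out$namespace <- NA_character_
  if (!"name" %in% names(out)) out$name <- NA_character_
  strat <- if (stratify && !all(is.na(out$namespace))) {
    ifelse(is.na(out$namespace), "unannotated", out$namespace)
  } else rep("all", nrow(out))
  out <- out %>%
    dplyr::mutate(.strat = strat) %>%
    dplyr::group_by(.data$.strat) %>%
    dplyr::mutate(q = bh_fdr(.data$p, method = adjust)) %>%
    dplyr::ungroup() %>%
    dplyr::select(-".strat") %>%
    dplyr::mutate(significant = .data$q < alpha) %>%
    dplyr::select("term_id", "name", "namespace", "k", "K", "m", "N",
                  "fold", "p", "q", "significant", "low_support") %>%
    dplyr::arrange(.data$q, .data$p)
  attr(out, "alpha") <- alpha
  attr(out, "adjust") <- adjust
  class(out) <- c("enrich_result", class(out))
  out
}
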