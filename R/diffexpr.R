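#' Fit the empirical-Bayes variance prior
#'
#' Models the ensemble of per-gene sample variances as scaled F draws around
#' a common prior variance `s0_sq` with `d0` prior degrees of freedom, and
#' fits both by matching the mean and variance of `log(s_sq)` through
#' digamma/trigamma identities. Genes with zero variance are excluded from
#' the fit (counted in the result). If the trigamma equation has no positive
#' solution the ensemble is effectively homoscedastic: `d0` is unbounded
#' (`Inf`) and `s0_sq` is the mean variance.
#'
#' @param s_sq numeric vector of per-gene pooled sample variances (>= 0).
#' @param df residual degrees of freedom: a scalar, or one value per gene.
#' @return an object of class `var_prior`: list with `d0`, `s0_sq`,
#'   `n_used`, `n_zero`, `df_mean`. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
fit_variance_prior <- function(s_sq, df) {
  stopifnot(length(df) == 1 || length(df) == length(s_sq))
  if (any(s_sq < 0, na.rm = TRUE)) {
    stop("sample variances must be nonnegative.", call. = FALSE)
  }
  if (any(df < 1)) stop("residual degrees of freedom must be >= 1.",
                        call. = FALSE)
  if (length(df) == 1) df <- rep(df, length(s_sq))
  keep <- is.finite(s_sq) & s_sq > 0
  n_zero <- sum(!keep)
  s2 <- s_sq[keep]
  d <- df[keep]
  if (length(s2) < 10) {
    stop("fewer than 10 positive finite variances: prior unfittable.",
         call. = FALSE)
  }
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  # Var(log s2) = trigamma(d/2) + trigamma(d0/2)
  excess <- mean((e - ebar)^2) * length(e) / (length(e) - 1) -
    mean(trigamma(d / 2))
  if (is.finite(excess) && excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- mean(s2)
  }
  structure(list(d0 = d0, s0_sq = s0_sq, n_used = length(s2),
                 n_zero = n_zero, df_mean = mean(d)),
            class = "var_prior")
}

# Newton inversion of the trigamma function on (0, Inf)
trigamma_inverse <- function(y) {
  stopifnot(length(y) == 1, y > 0)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (x <= 0) x <- .Machine$double.eps
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Moderated two-group t-test
#'
#' The gene's pooled variance is shrunk toward the prior:
#' `s2_tilde = (d0 * s0_sq + d * s_sq) / (d0 + d)`, the statistic is the mean
#' difference over `sqrt(s2_tilde * (1/n_a + 1/n_b))`, and the two-sided
#' p-value comes from a t distribution on `d0 + d` degrees of freedom
#' (standard normal when `d0` is unbounded). All arguments are vectorized
#' over genes.
#'
#' @param mean_a,mean_b group means (log2 scale).
#' @param s_sq_pooled pooled within-group sample variance.
#' @param n_a,n_b group sizes.
#' @param prior a `var_prior` from [fit_variance_prior()].
#' @param df residual degrees of freedom behind `s_sq_pooled`.
#' @return a tibble with columns `diff`, `t`, `df_total`, `p`.
#' @export
#' @examples
#' pr <- structure(list(d0 = 4, s0_sq = 0.05), class = "var_prior")
#' moderated_t(1, 0, 0.04, 2, 2, pr, 2)  # t = 4.629 on 6 df
moderated_t <- function(mean_a, mean_b, s_sq_pooled, n_a, n_b, prior, df) {
  stopifnot(inherits(prior, "var_prior"))
  if (any(s_sq_pooled < 0)) stop("pooled variance must be nonnegative.",
                                 call. = FALSE)
  d0 <- prior$d0
  s0 <- prior$s0_sq
  n_out <- max(length(mean_a), length(mean_b), length(s_sq_pooled))
  if (is.infinite(d0)) {
    s2_tilde <- rep_len(s0, n_out)
    df_total <- rep_len(Inf, n_out)
  } else {
    s2_tilde <- rep_len((d0 * s0 + df * s_sq_pooled) / (d0 + df), n_out)
    df_total <- rep_len(d0 + df, n_out)
  }
  if (any(s2_tilde == 0)) stop("moderated variance collapsed to zero.",
                               call. = FALSE)
  diff <- mean_a - mean_b
  t <- diff / sqrt(s2_tilde * (1 / n_a + 1 / n_b))
  p <- ifelse(is.infinite(df_total),
              2 * stats::pnorm(-abs(t)),
              2 * stats::pt(-abs(t), df_total))
  tibble::tibble(diff = diff, t = t, df_total = df_total, p = p)
}

cell_contrasts <- function() c("T-D", "H-T", "H-D", "H-M", "M-T", "M-D")

#' Six pairwise moderated contrasts per gene and study cell
#'
#' For every (line, generation) cell, tests all six pairs among the
#' tetraploid parent (T), diploid parent (D), mid-parent mixture of the
#' line (M), and the polyploid of the cell (H). One variance prior is fitted
#' per run from the pooled within-group variances of *all* sample groups;
#' within a cell, each gene's variance is pooled across the cell's four
#' groups (common-variance design, `df = sum(n_g - 1)`) and moderated by the
#' shared prior. No fold-change threshold and no multiple-testing correction
#' enter the significance flag (raw `p < alpha`); BH-adjusted p-values are
#' emitted alongside for reference.
#'
#' @param expr expression tibble (`gene_id` + one column per sample),
#'   typically restricted to the expressed universe.
#' @param design sample design tibble; defaults to `attr(expr, "design")`.
#' @param alpha significance cutoff (strict `<`).
#' @param prior optional pre-fitted `var_prior`; fitted from the data when
#'   `NULL`.
#' @return an object of class `contrast_tbl`: a tibble with one row per
#'   gene x cell x contrast (`gene_id`, `line`, `generation`, `contrast`,
#'   `mean_a`, `mean_b`, `diff`, `t`, `df_total`, `p`, `p_bh`,
#'   `significant`), with the prior and alpha attached as attributes.
#' @export
contrast_table <- function(expr, design = attr(expr, "design"), alpha = 0.05,
                           prior = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  validate_design(design)
  m <- expr_matrix(expr)
  design <- design[match(colnames(m), design$sample_id), ]
  if (anyNA(design$sample_id)) {
    stop("expression columns and design sample ids do not match.",
         call. = FALSE)
  }
  gkey <- group_key(design$role, design$line, design$generation)
  groups <- split(seq_len(ncol(m)), gkey)
  if (any(lengths(groups) < 2)) {
    stop("every sample group needs >= 2 replicates: ",
         paste(names(groups)[lengths(groups) < 2], collapse = ", "),
         call. = FALSE)
  }
  group_mean <- vapply(groups, function(j) rowMeans(m[, j, drop = FALSE]),
                       numeric(nrow(m)))
  group_rss <- vapply(groups, function(j) {
    x <- m[, j, drop = FALSE]
    rowSums((x - rowMeans(x))^2)
  }, numeric(nrow(m)))
  group_n <- lengths(groups)

  if (is.null(prior)) {
    d_all <- sum(group_n - 1)
    s2_all <- rowSums(group_rss) / d_all
    prior <- fit_variance_prior(s2_all, d_all)
  }
  stopifnot(inherits(prior, "var_prior"))

  lines <- unique(stats::na.omit(design$line))
  gens <- unique(stats::na.omit(design$generation))
  need <- function(key) {
    if (!key %in% names(groups)) {
      stop("missing sample group: ", key, call. = FALSE)
    }
    key
  }
  out <- purrr::map_dfr(lines, function(ln) {
    purrr::map_dfr(gens, function(gn) {
      keys <- c(T = need(group_key("tetraploid_parent", NA, NA)),
                D = need(group_key("diploid_parent", NA, NA)),
                M = need(group_key("mpv", ln, NA)),
                H = need(group_key("allohexaploid", ln, gn)))
      d_cell <- sum(group_n[keys] - 1)
      s2_cell <- rowSums(group_rss[, keys, drop = FALSE]) / d_cell
      purrr::map_dfr(cell_contrasts(), function(ct) {
        ab <- strsplit(ct, "-", fixed = TRUE)[[1]]
        ka <- keys[ab[1]]
        kb <- keys[ab[2]]
        mt <- moderated_t(group_mean[, ka], group_mean[, kb], s2_cell,
                          group_n[ka], group_n[kb], prior, d_cell)
        tibble::tibble(gene_id = rownames(m), line = ln, generation = gn,
                       contrast = ct, mean_a = group_mean[, ka],
                       mean_b = group_mean[, kb], diff = mt$diff, t = mt$t,
                       df_total = mt$df_total, p = mt$p)
      })
    })
  })
  out <- out %>%
    dplyr::group_by(.data$line, .data$generation, .data$contrast) %>%
    dplyr::mutate(p_bh = stats::p.adjust(.data$p, method = "BH")) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(significant = .data$p < alpha)
  attr(out, "alpha") <- alpha
  attr(out, "prior") <- prior
  class(out) <- c("contrast_tbl", class(out))
  out
}

#' Per-contrast significant-gene counts with up/down split
#'
#' @param contrasts a `contrast_tbl`.
#' @return a tibble per (line, generation, contrast): `n_significant`,
#'   `n_up`, `n_down` (sign of the log2 difference among significant genes).
#' @export
contrast_summary <- function(contrasts) {
  contrasts %>%
    dplyr::group_by(.data$line, .data$generation, .data$contrast) %>%
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_significant = sum(.data$significant),
      n_up = sum(.data$significant & .data$diff > 0),
      n_down = sum(.data$significant & .data$diff < 0),
      .groups = "drop")
}
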