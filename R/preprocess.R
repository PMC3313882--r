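#' Normexp background correction of probe intensities
#'
#' Fits, per sample, a normal + exponential convolution to the observed
#' intensities by the method of moments: the mode of the empirical density is
#' the normal (background) mean, the spread below the mode estimates its sd,
#' and the decay of intensities above the mode estimates the exponential
#' signal rate. Returns the posterior expected signal, which is strictly
#' positive and strictly increasing in the observed intensity within a
#' sample.
#'
#' @param pm matrix of positive intensities (probes x samples).
#' @return matrix of background-corrected intensities, same shape.
#' @export
background_correct <- function(pm) {
  pm <- as.matrix(pm)
  if (any(pm <= 0)) stop("all intensities must be > 0.", call. = FALSE)
  out <- pm
  for (j in seq_len(ncol(pm))) {
    x <- pm[, j]
    if (stats::sd(x) == 0) {
      warning(sprintf("sample %d has zero variance; returning floored input.",
                      j), call. = FALSE)
      out[, j] <- pmax(x - x[1], 0) + 1e-3
      next
    }
    par <- normexp_mom(x)
    out[, j] <- normexp_signal(par$mu, par$sigma, par$alpha, x)
  }
  out
}

# method-of-moments normal+exponential parameters for one sample. The
# background mode is located on the lower half of the intensities (where the
# background component lives) with a fine grid, so the spike is not smeared
# by the heavy signal tail. Under the convolution model the density mode sits
# above the normal mean by sigma^2*alpha + sigma*z*, where z* solves
# dnorm(z)/pnorm(z) = alpha*sigma; the fit iterates that correction so the
# implied model mode matches the observed one.
normexp_mom <- function(x) {
  low <- x[x <= stats::quantile(x, 0.5)]
  d <- stats::density(low, n = 2^14)
  mode_x <- d$x[which.max(d$y)]
  # density of the full sample at the mode (d is normalized to the subset)
  f_mode <- max(d$y) * length(low) / length(x)
  mu <- mode_x
  sigma_of <- function(mu) {
    lower <- x[x <= mu]
    if (length(lower) < 50) return(NA_real_)
    sqrt(mean((lower - mu)^2))
  }
  sigma <- sigma_of(mu)
  if (!is.finite(sigma) || sigma <= 0) sigma <- stats::sd(x) / 10
  alpha <- 1 / max(mean(x) - mu, .Machine$double.eps)
  for (it in 1:20) {
    # under the pure convolution the density at the mode is at most alpha;
    # a much larger observed density marks a background-dominated spike
    # whose peak already sits at the normal mean, so no mode shift applies
    spike <- f_mode > 2 * alpha
    z_star <- if (spike) NULL else mills_inverse(min(alpha * sigma, 5))
    mu_new <- if (spike) mode_x - sigma^2 * alpha else
      mode_x - sigma^2 * alpha - sigma * z_star
    mu_new <- max(mu_new, min(x))
    s_new <- sigma_of(mu_new)
    if (is.finite(s_new) && s_new > 0) sigma <- s_new
    alpha <- 1 / max(mean(x) - mu_new, sigma / 10)
    if (abs(mu_new - mu) < 1e-8 * (abs(mu) + 1)) {
      mu <- mu_new
      break
    }
    mu <- mu_new
  }
  list(mu = mu, sigma = sigma, alpha = alpha)
}

# z solving dnorm(z)/pnorm(z) = c (the inverse Mills ratio), c > 0
mills_inverse <- function(c) {
  f <- function(z) exp(stats::dnorm(z, log = TRUE) -
                         stats::pnorm(z, log.p = TRUE)) - c
  stats::uniroot(f, lower = -8, upper = 40, tol = 1e-10)$root
}

# posterior mean E[signal | observed] under the normal+exponential model,
# computed with log-scale Mills ratios for numerical stability
normexp_signal <- function(mu, sigma, alpha, x) {
  mu_sf <- x - mu - sigma^2 * alpha
  z <- mu_sf / sigma
  out <- mu_sf + sigma * exp(stats::dnorm(z, log = TRUE) -
                             stats::pnorm(z, log.p = TRUE))
  pmax(out, 1e-9)
}

#' Quantile normalization
#'
#' Forces every column to share the same empirical distribution: the sorted
#' values of each column are replaced by the across-column mean of sorted
#' values. Ties within a column receive the mean of the reference values at
#' their rank positions, so permuting rows commutes with normalization.
#' A single-column input is returned unchanged.
#'
#' @param x numeric matrix with no missing entries.
#' @return matrix of the same shape.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing entries are not allowed.", call. = FALSE)
  if (ncol(x) <= 1) return(x)
  ref <- rowMeans(apply(x, 2, sort, method = "quick"))
  out <- x
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j])
    xs <- x[o, j]
    # equal values are adjacent after sorting: average ref within tie runs
    grp <- cumsum(c(TRUE, xs[-1] != xs[-length(xs)]))
    out[o, j] <- stats::ave(ref, grp, FUN = mean)
  }
  out
}

#' Median-polish summarization of a probe-set block
#'
#' Fits the additive model `log2 intensity = overall + probe effect +
#' sample effect` by alternating median sweeps ([stats::medpolish()]) and
#' returns the fitted per-sample values `overall + sample effect`.
#'
#' @param block numeric matrix (probes x samples) of log2 intensities.
#' @param eps convergence tolerance on the total absolute residual change.
#' @param maxiter maximum number of sweep pairs.
#' @return named numeric vector, one summarized value per sample.
#' @export
medianpolish_summarize <- function(block, eps = 1e-4, maxiter = 20L) {
  block <- as.matrix(block)
  if (!all(is.finite(block))) {
    bad <- which(!is.finite(block), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite intensity at probe %d, sample %d.",
                 bad[1], bad[2]), call. = FALSE)
  }
  if (nrow(block) == 1) {
    return(stats::setNames(drop(block), colnames(block)))
  }
  fit <- suppressWarnings(
    stats::medpolish(block, eps = eps, maxiter = maxiter, trace.iter = FALSE))
  stats::setNames(fit$overall + fit$col, colnames(block))
}

#' RMA-style normalization of a probe panel
#'
#' Background-corrects perfect-match intensities (normexp posterior mean),
#' log2-transforms, quantile-normalizes across samples, summarizes each
#' probe-set by median polish, and averages the log2 values of probe-sets
#' mapping to the same gene (arrays carry more probe-sets than genes).
#'
#' @param panel a `probe_panel` (see [simulate_panel()]), or any list with a
#'   positive `pm` matrix, a `probes` tibble (`probe_id`, `set_id`,
#'   `gene_id`) aligned with its rows, and a `design` tibble.
#' @param skip_background skip background correction (for panels that are
#'   already corrected).
#' @return a gene x sample log2 expression tibble (`gene_id` + one column
#'   per sample) with the design attached as attribute `"design"`.
#' @export
rma <- function(panel, skip_background = FALSE) {
  pm <- panel$pm
  probes <- panel$probes
  stopifnot(nrow(pm) == nrow(probes))
  if (any(table(probes$set_id) < 1)) {
    stop("every probe-set needs at least one probe.", call. = FALSE)
  }
  if (!skip_background) pm <- background_correct(pm)
  lg <- quantile_normalize(log2(pm))
  set_rows <- split(seq_len(nrow(lg)), probes$set_id)
  set_vals <- vapply(set_rows,
                     function(i) medianpolish_summarize(lg[i, , drop = FALSE]),
                     numeric(ncol(lg)))
  set_vals <- t(set_vals)   # sets x samples
  set_gene <- probes$gene_id[match(rownames(set_vals),
                                   probes$set_id)]
  gene_vals <- rowsum(set_vals, set_gene) /
    as.vector(table(set_gene)[sort(unique(set_gene))])
  colnames(gene_vals) <- colnames(pm)
  expr_tbl(gene_vals[order(rownames(gene_vals)), , drop = FALSE],
           panel$design)
}

# exact one-sided signed-rank tail P(W >= w) allowing midrank ties, via a
# generating-function convolution over doubled ranks (equivalent to
# enumerating all 2^n sign assignments)
signed_rank_tail_exact <- function(ranks2, w2) {
  total <- sum(ranks2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (d in ranks2) {
    if (d > 0) {
      g <- f
      g[(d + 1):(total + 1)] <- g[(d + 1):(total + 1)] + f[1:(total + 1 - d)]
      f <- g
    }
  }
  f <- f / 2^length(ranks2)
  if (w2 <= 0) return(1)
  sum(f[(w2 + 1):(total + 1)])
}

# one-sided exact/approximate signed-rank p for scores x (already tau-shifted);
# zeros are dropped as in the standard signed-rank convention
signed_rank_p <- function(x, exact_n = 25L) {
  x <- x[x != 0]
  n <- length(x)
  if (n == 0) return(1)
  r <- rank(abs(x))
  w <- sum(r[x > 0])
  if (n <= exact_n) {
    r2 <- as.integer(round(2 * r))
    return(signed_rank_tail_exact(r2, as.integer(round(2 * w))))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  stats::pnorm((w - mu - 0.5) / sqrt(sig2), lower.tail = FALSE)
}

#' MAS5-style detection call for one probe-set
#'
#' Computes discrimination scores `R = (PM - MM) / (PM + MM)` and tests, per
#' sample, whether their median exceeds `tau` by a one-sided Wilcoxon
#' signed-rank test. The null tail is exact (enumeration-equivalent, midrank
#' ties handled) for up to 25 informative probes and a continuity-corrected
#' normal approximation beyond. Calls: `P` if `p < alpha1`, `M` if
#' `alpha1 <= p < alpha2`, `A` otherwise. Probe pairs with `PM + MM = 0` are
#' dropped from the test.
#'
#' @param pm,mm numeric matrices (probes x samples) or vectors (one sample)
#'   of raw intensities for one probe-set.
#' @param tau discrimination threshold (default 0.015).
#' @param alpha1,alpha2 detection p-value cutoffs (defaults 0.04 and 0.06).
#' @return a tibble with one row per sample: `sample`, `p`, `call`.
#' @export
#' @examples
#' pm <- matrix(rep(100, 11), ncol = 1)
#' detection_call(pm, pm / 10)   # all probes discriminate: p = 1/2^11
detection_call <- function(pm, mm, tau = 0.015, alpha1 = 0.04, alpha2 = 0.06) {
  if (is.null(dim(pm))) pm <- matrix(pm, ncol = 1)
  if (is.null(dim(mm))) mm <- matrix(mm, ncol = 1)
  stopifnot(all(dim(pm) == dim(mm)), tau >= 0,
            alpha1 > 0, alpha1 < alpha2, alpha2 < 1)
  samples <- colnames(pm)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(pm)))
  p <- vapply(seq_len(ncol(pm)), function(j) {
    denom <- pm[, j] + mm[, j]
    keep <- denom != 0
    r <- (pm[keep, j] - mm[keep, j]) / denom[keep]
    signed_rank_p(r - tau)
  }, numeric(1))
  tibble::tibble(sample = samples, p = p,
                 call = ifelse(p < alpha1, "P",
                               ifelse(p < alpha2, "M", "A")))
}

#' Detection calls for every probe-set of a panel
#'
#' Runs [detection_call()] on the raw (un-normalized) PM/MM intensities of
#' each probe-set, following the MAS5 convention that detection and
#' normalization are independent paths from the probe level.
#'
#' @param panel a `probe_panel`.
#' @inheritParams detection_call
#' @return an object of class `detection_tbl`: list with tibbles `calls` and
#'   `pvals` (one row per probe-set: `set_id`, `gene_id`, one column per
#'   sample), the `design`, and `params`.
#' @export
detect_calls <- function(panel, tau = 0.015, alpha1 = 0.04, alpha2 = 0.06) {
  stopifnot(alpha1 > 0, alpha1 < alpha2, alpha2 < 1, tau >= 0)
  pm <- panel$pm
  mm <- panel$mm
  probes <- panel$probes
  denom <- pm + mm
  r <- (pm - mm) / ifelse(denom == 0, NA, denom) - tau
  set_rows <- split(seq_len(nrow(r)), probes$set_id)
  set_ids <- names(set_rows)
  pmat <- matrix(NA_real_, length(set_rows), ncol(pm),
                 dimnames = list(set_ids, colnames(pm)))
  for (s in seq_along(set_rows)) {
    block <- r[set_rows[[s]], , drop = FALSE]
    pmat[s, ] <- apply(block, 2, function(x) signed_rank_p(x[!is.na(x)]))
  }
  calls <- matrix(ifelse(pmat < alpha1, "P",
                         ifelse(pmat < alpha2, "M", "A")),
                  nrow(pmat), ncol(pmat), dimnames = dimnames(pmat))
  gene_of_set <- probes$gene_id[match(set_ids, probes$set_id)]
  to_tbl <- function(m) {
    out <- tibble::as_tibble(m)
    dplyr::bind_cols(tibble::tibble(set_id = set_ids, gene_id = gene_of_set),
                     out)
  }
  structure(list(calls = to_tbl(calls), pvals = to_tbl(pmat),
                 design = panel$design,
                 params = list(tau = tau, alpha1 = alpha1, alpha2 = alpha2)),
            class = "detection_tbl")
}

#' Expressed-gene universe from detection calls
#'
#' A gene is expressed if at least one of its probe-sets is called present
#' (`P`) in *all* replicates of *at least one* sample group in scope.
#' Marginal calls count as not present. The global expressed universe uses
#' every sample group as scope.
#'
#' @param detection a `detection_tbl` from [detect_calls()].
#' @param design sample design; defaults to the detection table's design.
#' @param scope optional character vector of group keys
#'   (`"role|line|generation"`, `NA` rendered as `"."`) to restrict the rule
#'   to; defaults to all groups.
#' @return sorted character vector of expressed gene ids.
#' @export
expressed_set <- function(detection, design = detection$design, scope = NULL) {
  stopifnot(inherits(detection, "detection_tbl"))
  validate_design(design)
  design <- dplyr::mutate(design, .group = group_key(.data$role, .data$line,
                                                     .data$generation))
  groups <- split(design$sample_id, design$.group)
  if (!is.null(scope)) {
    if (length(scope) == 0) stop("empty scope.", call. = FALSE)
    missing_groups <- setdiff(scope, names(groups))
    if (length(missing_groups) > 0) {
      stop("unknown group(s) in scope: ",
           paste(missing_groups, collapse = ", "), call. = FALSE)
    }
    groups <- groups[scope]
  }
  calls <- detection$calls
  m <- as.matrix(calls[setdiff(names(calls), c("set_id", "gene_id"))])
  present_any <- rep(FALSE, nrow(m))
  for (g in groups) {
    present_any <- present_any | rowSums(m[, g, drop = FALSE] == "P") == length(g)
  }
  sort(unique(calls$gene_id[present_any]))
}

# canonical key for a sample group
group_key <- function(role, line, generation) {
  paste(role, ifelse(is.na(line), ".", line),
        ifelse(is.na(generation), ".", generation), sep = "|")
}
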