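# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# quantile normalization by explicit rank bookkeeping
oracle_quantile_normalize <- function(x) {
  if (ncol(x) <= 1) return(x)
  sorted <- sapply(seq_len(ncol(x)), function(j) sort(x[, j]))
  ref <- rowMeans(sorted)
  out <- x
  for (j in seq_len(ncol(x))) {
    for (v in unique(x[, j])) {
      pos <- which(sort(x[, j]) == v)
      out[x[, j] == v, j] <- mean(ref[pos])
    }
  }
  out
}

# median polish by explicit alternating sweeps, run to tight convergence
oracle_medpolish_summary <- function(block, iter = 500, tol = 1e-10) {
  overall <- 0
  row_eff <- rep(0, nrow(block))
  col_eff <- rep(0, ncol(block))
  res <- block
  for (i in seq_len(iter)) {
    rm_ <- apply(res, 1, median)
    res <- sweep(res, 1, rm_)
    row_eff <- row_eff + rm_
    cm <- median(col_eff)
    overall <- overall + cm
    col_eff <- col_eff - cm
    cm2 <- apply(res, 2, median)
    res <- sweep(res, 2, cm2)
    col_eff <- col_eff + cm2
    rm2 <- median(row_eff)
    overall <- overall + rm2
    row_eff <- row_eff - rm2
    if (max(abs(rm_)) < tol && max(abs(cm2)) < tol) break
  }
  overall + col_eff
}

# one-sided signed-rank p by enumerating all 2^n sign assignments (midranks)
oracle_signed_rank_p <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  if (n == 0) return(1)
  r <- rank(abs(x))
  w_obs <- sum(r[x > 0])
  total <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- as.logical(bitwAnd(bitwShiftL(1L, 0:(n - 1)), mask))
    if (sum(r[signs]) >= w_obs - 1e-9) total <- total + 1L
  }
  total / 2^n
}

# hypergeometric upper tail via explicit log-binomial summation
oracle_hyper_tail <- function(k, K, m, N) {
  if (k <= 0) return(1)
  i <- k:min(K, m)
  lp <- lchoose(m, i) + lchoose(N - m, K - i) - lchoose(N, K)
  sum(exp(lp))
}

# BH step-up by the textbook recursion
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) {
    if (n > 1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# the expressed-gene rule by direct scanning
oracle_expressed <- function(call_mat, gene_of_row, groups) {
  ok <- character(0)
  for (g in unique(gene_of_row)) {
    rows <- which(gene_of_row == g)
    hit <- FALSE
    for (grp in groups) {
      for (r in rows) {
        if (all(call_mat[r, grp] == "P")) hit <- TRUE
      }
    }
    if (hit) ok <- c(ok, g)
  }
  sort(ok)
}

# guard against R's sample(x, 1) scalar expansion when a range collapses
pick1 <- function(v) if (length(v) == 1) v else sample(v, 1)
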