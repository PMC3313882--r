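test_that("background correction is positive, order-preserving, and handles
           degenerate samples", {
  x <- matrix(c(rexp(2000, 1 / 200) + rnorm(2000, 50, 10)), ncol = 2)
  x <- pmax(x, 1)
  out <- background_correct(x)
  expect_true(all(out > 0))
  for (j in 1:2) {
    o <- order(x[, j])
    expect_true(all(diff(out[o, j]) > 0))
  }
  const <- matrix(100, 50, 1)
  expect_warning(outc <- background_correct(const), "zero variance")
  expect_true(all(outc > 0))
  expect_equal(length(unique(as.vector(outc))), 1)
  expect_error(background_correct(matrix(c(-1, 2, 3, 4), 2)), "> 0")
})

test_that("the normexp moment fit recovers a planted exponential signal", {
  set.seed(401)
  n <- 50000
  x <- matrix(rexp(n, 1 / 200) + rnorm(n, 50, 10), ncol = 1)
  x <- pmax(x, 1)
  out <- background_correct(x)
  expect_lt(abs(mean(out) - 200) / 200, 0.1)
})

test_that("the posterior signal formula agrees with the limma reference", {
  x <- seq(20, 500, by = 7)
  ours <- alloexpr:::normexp_signal(mu = 48, sigma = 11, alpha = 1 / 180, x)
  theirs <- limma::normexp.signal(c(48, log(11), log(1 / (1 / 180))), x)
  expect_equal(ours, theirs, tolerance = 1e-6)
})

test_that("quantile normalization matches the hand examples and tie rule", {
  x <- cbind(c(1, 2, 3), c(4, 5, 6))
  out <- quantile_normalize(x)
  expect_equal(out, cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))
  same <- cbind(c(2, 7, 5), c(2, 7, 5))
  expect_equal(quantile_normalize(same), same)
  # ties receive the mean of reference values at their rank positions
  xt <- cbind(c(1, 1, 3), c(2, 5, 6))
  outt <- quantile_normalize(xt)
  expect_equal(outt[, 1], c(2.25, 2.25, 4.5))
  one <- matrix(c(3, 1, 2), ncol = 1)
  expect_identical(quantile_normalize(one), one)
  expect_error(quantile_normalize(cbind(c(1, NA), c(2, 3))), "missing")
})

test_that("quantile normalization equalizes columns, is idempotent, and
           matches the brute-force oracle", {
  set.seed(402)
  for (i in 1:100) {
    nr <- sample(3:12, 1)
    nc <- sample(2:5, 1)
    x <- matrix(sample(1:8, nr * nc, replace = TRUE) + rnorm(nr * nc, 0, 0.1),
                nr, nc)
    if (i %% 3 == 0) x <- matrix(sample(1:5, nr * nc, replace = TRUE), nr, nc)
    out <- quantile_normalize(x)
    expect_equal(out, oracle_quantile_normalize(x), tolerance = 1e-12)
    if (!any(duplicated(as.vector(x)))) {
      # tie-free: all columns share the reference multiset, and a second
      # pass changes nothing (the tie rule intentionally trades these exact
      # properties for permutation stability on tied data)
      sorted <- apply(out, 2, sort)
      expect_equal(max(apply(sorted, 1, function(r) diff(range(r)))), 0,
                   tolerance = 1e-12)
      expect_equal(quantile_normalize(out), out, tolerance = 1e-12)
    }
  }
  set.seed(412)
  for (i in 1:20) {
    x <- matrix(rnorm(40), 10, 4)   # continuous, ties absent a.s.
    out <- quantile_normalize(x)
    sorted <- apply(out, 2, sort)
    expect_equal(max(apply(sorted, 1, function(r) diff(range(r)))), 0,
                 tolerance = 1e-12)
    expect_equal(quantile_normalize(out), out, tolerance = 1e-12)
  }
  # tie-free instances also agree with the limma implementation
  set.seed(403)
  y <- matrix(rnorm(60), 15, 4)
  expect_equal(quantile_normalize(y),
               unname(as.matrix(limma::normalizeQuantiles(y))),
               tolerance = 1e-10)
})

test_that("median polish reproduces additive structure exactly", {
  r <- c(0, 1, -1, 2)
  cl <- c(5, 6, 7)
  block <- outer(r, rep(1, 3)) * 0 + outer(r, cl, "+")
  out <- medianpolish_summarize(block)
  expect_equal(unname(out - cl), rep(out[1] - cl[1], 3), tolerance = 1e-12)
  fitted_shift <- out[1] - cl[1]
  expect_equal(unname(out), cl + fitted_shift, tolerance = 1e-12)
  single <- matrix(c(1.5, 2.5, 3.5), 1)
  expect_equal(unname(medianpolish_summarize(single)), c(1.5, 2.5, 3.5))
  bad <- block
  bad[2, 2] <- NA
  expect_error(medianpolish_summarize(bad), "probe 2, sample 2")
})

test_that("median polish is outlier-robust and matches a converged oracle", {
  r <- c(0, 0.5, -0.5)
  cl <- c(8, 9, 10)
  clean <- outer(r, cl, "+")
  block <- clean
  block[2, 3] <- block[2, 3] + 10
  out <- medianpolish_summarize(block)
  ref <- medianpolish_summarize(clean)
  expect_lt(max(abs(out - ref)), 0.05)
  # with odd probe and sample counts the median-polish fixed point is unique
  # and the sweeps must agree exactly with the independent oracle
  set.seed(404)
  for (i in 1:100) {
    nr <- sample(c(3, 5, 7), 1)
    nc <- sample(c(3, 5), 1)
    b <- matrix(rnorm(nr * nc, 8), nr, nc)
    ours <- medianpolish_summarize(b, eps = 1e-9, maxiter = 300)
    expect_equal(unname(ours), unname(oracle_medpolish_summary(b)),
                 tolerance = 1e-6)
  }
  # even-count medians are averages and the decomposition is not unique;
  # both paths must still fit equally well and agree closely
  for (i in 1:20) {
    b <- matrix(rnorm(24, 8), sample(c(4, 6), 1))
    ours <- medianpolish_summarize(b, eps = 1e-9, maxiter = 300)
    orc <- oracle_medpolish_summary(b)
    expect_lt(max(abs(ours - orc)), 0.25)
  }
})

test_that("detection calls match the exact examples", {
  pm <- matrix(rep(100, 11), ncol = 1)
  res <- detection_call(pm, pm / 10)
  expect_equal(res$p, 1 / 2^11, tolerance = 1e-12)
  expect_equal(res$call, "P")
  res0 <- detection_call(pm, pm)
  expect_gte(res0$p, 0.5)
  expect_equal(res0$call, "A")
  # a signed-rank statistic of 19 on n = 6 sits in the marginal band:
  # p = 3/64 = 0.0469, between alpha1 = 0.04 and alpha2 = 0.06
  scores <- c(0.1, -0.15, 0.2, 0.3, 0.4, 0.5) + 0.015
  res_m <- detection_call(matrix(1 + scores, ncol = 1),
                          matrix(1 - scores, ncol = 1))
  expect_equal(res_m$p, 3 / 64, tolerance = 1e-9)
  expect_equal(res_m$call, "M")
})

test_that("exact signed-rank p equals exhaustive enumeration, ties included", {
  set.seed(405)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    pm <- sample(5:40, n, replace = TRUE)
    mm <- sample(5:40, n, replace = TRUE)
    res <- detection_call(matrix(pm, ncol = 1), matrix(mm, ncol = 1),
                          tau = 0.015)
    r <- (pm - mm) / (pm + mm) - 0.015
    expect_equal(res$p, oracle_signed_rank_p(r), tolerance = 1e-12,
                 label = sprintf("instance %d", i))
  }
})

test_that("large probe-sets fall back to a sane normal approximation", {
  set.seed(406)
  pm <- rexp(40, 1 / 300) + 50
  mm <- rexp(40, 1 / 60) + 50
  res <- detection_call(matrix(pm, ncol = 1), matrix(mm, ncol = 1))
  expect_true(res$p > 0 && res$p < 1)
  r <- (pm - mm) / (pm + mm) - 0.015
  w <- stats::wilcox.test(r, alternative = "greater", exact = FALSE,
                          correct = TRUE)
  expect_equal(res$p, w$p.value, tolerance = 0.02)
})

test_that("the expressed-gene rule matches a brute-force scan and is
           monotone in scope", {
  cfg <- sim_config(80, seed = 31)
  truth <- build_truth(cfg)
  panel <- simulate_panel(truth)
  det <- detect_calls(panel)
  design <- panel$design
  keys <- alloexpr:::group_key(design$role, design$line, design$generation)
  groups <- split(design$sample_id, keys)
  m <- as.matrix(det$calls[setdiff(names(det$calls), c("set_id", "gene_id"))])
  expect_identical(expressed_set(det),
                   oracle_expressed(m, det$calls$gene_id, groups))
  # the rule: present in all replicates of at least one group in scope
  sub1 <- expressed_set(det, scope = names(groups)[1])
  sub2 <- expressed_set(det, scope = names(groups)[1:3])
  expect_true(all(sub1 %in% sub2))
  expect_true(all(sub2 %in% expressed_set(det)))
  expect_error(expressed_set(det, scope = character(0)), "empty")
  expect_error(expressed_set(det, scope = "no|such|group"), "unknown")
})

test_that("rma output is invariant to probe order and tracks planted levels", {
  cfg <- sim_config(120, seed = 41, frac_absent = 0)
  truth <- build_truth(cfg)
  panel <- simulate_panel(truth)
  expr <- rma(panel)
  perm <- sample(nrow(panel$pm))
  panel_perm <- panel
  panel_perm$pm <- panel$pm[perm, ]
  panel_perm$mm <- panel$mm[perm, ]
  panel_perm$probes <- panel$probes[perm, ]
  expr_perm <- rma(panel_perm)
  expect_equal(expr, expr_perm, tolerance = 1e-12, ignore_attr = TRUE)
  # monotone recovery of true levels within a sample
  m <- expr_matrix(expr)
  d <- panel$design
  tcol <- d$sample_id[d$role == "tetraploid_parent"][1]
  truth_lev <- truth$genes$t_level_log2[match(rownames(m),
                                              truth$genes$gene_id)]
  expect_gt(cor(m[, tcol], truth_lev, method = "spearman"), 0.95)
})

test_that("rma recovers planted gene levels to 0.2 log2 for >= 90% of genes", {
  cfg <- sim_config(2000, seed = 7, frac_parent_divergent = 0)
  truth <- build_truth(cfg)
  panel <- simulate_panel(truth)
  expr <- rma(panel)
  m <- expr_matrix(expr)
  d <- panel$design
  tcols <- d$sample_id[d$role == "tetraploid_parent"]
  tg <- truth$genes[!truth$genes$absent, ]
  err <- rowMeans(m[tg$gene_id, tcols]) - tg$t_level_log2
  err <- err - median(err)   # the log2 scale anchor is arbitrary
  expect_gte(mean(abs(err) <= 0.2), 0.9)
})

test_that("probe-sets sharing a gene are summarized separately then averaged", {
  set.seed(407)
  probes <- tibble::tibble(
    probe_id = paste0("p", 1:12),
    set_id = rep(c("psA", "psB", "psC"), each = 4),
    gene_id = c(rep("g1", 8), rep("g2", 4)))
  pm <- matrix(2^rnorm(12 * 4, 8, 0.3), 12, 4,
               dimnames = list(probes$probe_id, paste0("s", 1:4)))
  design <- tibble::tibble(sample_id = paste0("s", 1:4),
                           role = c("tetraploid_parent", "tetraploid_parent",
                                    "diploid_parent", "diploid_parent"),
                           line = NA_character_, generation = NA_character_,
                           replicate = c(1L, 2L, 1L, 2L))
  panel <- list(pm = pm, mm = pm / 10, probes = probes, design = design)
  expr <- rma(panel, skip_background = TRUE)
  lg <- quantile_normalize(log2(pm))
  sa <- medianpolish_summarize(lg[1:4, ])
  sb <- medianpolish_summarize(lg[5:8, ])
  sc <- medianpolish_summarize(lg[9:12, ])
  m <- expr_matrix(expr)
  expect_equal(unname(m["g1", ]), unname((sa + sb) / 2), tolerance = 1e-12)
  expect_equal(unname(m["g2", ]), unname(sc), tolerance = 1e-12)
})

test_that("noise-free additive panels give polyploid equal to mid-parent
           after the full normalization path", {
  cfg <- sim_config(150, seed = 3, noise_sd_log2 = 0, background_sd = 0,
                    affinity_artifact_frac = 0, frac_absent = 0,
                    pattern_rates = c(additive = 1))
  truth <- build_truth(cfg)
  panel <- simulate_panel(truth)
  expr <- rma(panel)
  m <- expr_matrix(expr)
  d <- panel$design
  h <- rowMeans(m[, d$sample_id[d$role == "allohexaploid" & d$line == "AT5" &
                                  d$generation == "S4"]])
  mp <- rowMeans(m[, d$sample_id[d$role == "mpv" & d$line == "AT5"]])
  expect_equal(h, mp, tolerance = 1e-9)
})
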