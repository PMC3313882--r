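test_that("dominance calls follow the decision rules of the study", {
  # parents differ with D higher, polyploid sticks to D, mixture does not
  w <- wide_row(sig_td = TRUE, d_td = -2, sig_ht = TRUE, d_ht = 1,
                sig_hd = FALSE, sig_mt = TRUE, sig_md = TRUE)
  expect_equal(dominance_call(w)$dominance, "diploid_high")
  # same but the mixture also sticks to the diploid: affinity artifact
  w2 <- wide_row(sig_td = TRUE, d_td = -2, sig_ht = TRUE, sig_hd = FALSE,
                 sig_mt = TRUE, sig_md = FALSE)
  expect_equal(dominance_call(w2)$dominance, "excluded_mpv_bias")
  # mixture biased toward the *other* parent does not exclude
  w3 <- wide_row(sig_td = TRUE, d_td = -2, sig_ht = TRUE, sig_hd = FALSE,
                 sig_mt = FALSE, sig_md = TRUE)
  expect_equal(dominance_call(w3)$dominance, "diploid_high")
  # no test significant anywhere: not parent-divergent
  expect_equal(dominance_call(wide_row())$dominance, "not_divergent")
  # polyploid differs from both parents: no dominance
  w4 <- wide_row(sig_td = TRUE, d_td = -2, sig_ht = TRUE, sig_hd = TRUE)
  expect_equal(dominance_call(w4)$dominance, "none")
  # remaining orientations
  expect_equal(dominance_call(wide_row(sig_td = TRUE, d_td = 2,
                                       sig_ht = TRUE, sig_hd = FALSE,
                                       sig_mt = TRUE, sig_md = TRUE))$dominance,
               "diploid_low")
  expect_equal(dominance_call(wide_row(sig_td = TRUE, d_td = 2,
                                       sig_ht = FALSE, sig_hd = TRUE,
                                       sig_mt = TRUE, sig_md = TRUE))$dominance,
               "tetraploid_high")
  expect_equal(dominance_call(wide_row(sig_td = TRUE, d_td = -2,
                                       sig_ht = FALSE, sig_hd = TRUE,
                                       sig_mt = TRUE, sig_md = TRUE))$dominance,
               "tetraploid_low")
})

test_that("additivity is the polyploid-vs-mixture test with direction", {
  add <- additivity_call(wide_row(sig_hm = FALSE, d_hm = 0.4))
  expect_equal(add$additivity, "additive")
  expect_equal(add$direction, "none")
  up <- additivity_call(wide_row(sig_hm = TRUE, d_hm = 0.4))
  expect_equal(up$additivity, "nonadditive")
  expect_equal(up$direction, "up")
  dn <- additivity_call(wide_row(sig_hm = TRUE, d_hm = -0.4))
  expect_equal(dn$direction, "down")
})

test_that("non-additive categories cover the taxonomy with a residual class", {
  ov <- nonadditive_category(additivity_call(
    wide_row(sig_hm = TRUE, d_hm = 1, sig_ht = TRUE, d_ht = 1,
             sig_hd = TRUE, d_hd = 1)))
  expect_equal(ov$nonadd_category, "over_dominance")
  un <- nonadditive_category(additivity_call(
    wide_row(sig_hm = TRUE, d_hm = -1, sig_ht = TRUE, d_ht = -1,
             sig_hd = TRUE, d_hd = -1)))
  expect_equal(un$nonadd_category, "under_dominance")
  hd <- nonadditive_category(additivity_call(
    wide_row(sig_td = TRUE, d_td = -2, sig_hm = TRUE, d_hm = 0.5,
             sig_ht = TRUE, d_ht = 1, sig_hd = FALSE)))
  expect_equal(hd$nonadd_category, "high_diploid_dominance")
  lt <- nonadditive_category(additivity_call(
    wide_row(sig_td = TRUE, d_td = -2, sig_hm = TRUE, d_hm = -0.5,
             sig_ht = FALSE, sig_hd = TRUE, d_hd = -1)))
  expect_equal(lt$nonadd_category, "low_tetraploid_dominance")
  # between the parents, different from mixture, equal to neither parent
  other <- nonadditive_category(additivity_call(
    wide_row(sig_td = TRUE, d_td = -2, sig_hm = TRUE, d_hm = 0.3,
             sig_ht = TRUE, d_ht = 1, sig_hd = TRUE, d_hd = -1)))
  expect_equal(other$nonadd_category, "other")
  # additive rows carry the sentinel
  expect_equal(nonadditive_category(additivity_call(
    wide_row()))$nonadd_category, "not_applicable")
  # optional mid-parent filter inside the taxonomy diverts to the residual
  art <- additivity_call(
    wide_row(sig_td = TRUE, d_td = -2, sig_hm = TRUE, d_hm = 0.5,
             sig_ht = TRUE, d_ht = 1, sig_hd = FALSE,
             sig_mt = TRUE, sig_md = FALSE))
  expect_equal(nonadditive_category(art)$nonadd_category,
               "high_diploid_dominance")
  expect_equal(nonadditive_category(art, mpv_filter = TRUE)$nonadd_category,
               "other")
})

test_that("classification is a partition with consistent flags", {
  cfg <- sim_config(800, seed = 61)
  truth <- build_truth(cfg)
  expr <- simulate_expression(truth)
  ct <- contrast_table(expr)
  calls <- classify_patterns(ct)
  expect_equal(nrow(calls), 800 * 4)
  expect_false(anyDuplicated(calls[c("gene_id", "line", "generation")]) > 0)
  expect_true(all((calls$nonadd_category != "not_applicable") ==
                    (calls$additivity == "nonadditive")))
  expect_true(all((calls$direction != "none") ==
                    (calls$additivity == "nonadditive")))
  dom <- calls$dominance %in% c("diploid_high", "diploid_low",
                                "tetraploid_high", "tetraploid_low")
  expect_true(all(calls$parent_divergent[dom]))
  # shuffling gene order in the contrast table leaves calls unchanged
  ct_shuf <- ct[sample(nrow(ct)), ]
  attr(ct_shuf, "alpha") <- attr(ct, "alpha")
  class(ct_shuf) <- class(ct)
  calls2 <- classify_patterns(ct_shuf)
  expect_equal(tibble::as_tibble(calls), tibble::as_tibble(calls2))
  # duplicated gene in a cell is a structural error
  ct_dup <- rbind(tibble::as_tibble(ct), tibble::as_tibble(ct)[1:6, ])
  expect_error(pivot_contrasts(ct_dup))
})

test_that("noise-free planted labels are recovered exactly", {
  cfg <- sim_config(400, seed = 63, noise_sd_log2 = 0,
                    affinity_artifact_frac = 0, frac_absent = 0)
  truth <- build_truth(cfg)
  expr <- simulate_expression(truth)
  ct <- contrast_table(expr, prior = structure(
    list(d0 = 4, s0_sq = 1e-4), class = "var_prior"))
  calls <- classify_patterns(ct)
  planted <- dplyr::rename(truth$cells, planted = pattern)
  j <- dplyr::inner_join(tibble::as_tibble(calls), planted,
                         by = c("gene_id", "line", "generation"))
  jd <- j[j$planted %in% names(planted_dominance_map), ]
  expect_true(all(jd$dominance == planted_dominance_map[jd$planted]))
  jo <- j[j$planted %in% c("over_dominance", "under_dominance"), ]
  expect_true(all(jo$nonadd_category == jo$planted))
  ja <- j[j$planted == "additive", ]
  expect_true(all(ja$additivity == "additive"))
})

test_that("planted patterns are recovered under study noise and dominance
           genes are mostly additive against the mixture", {
  cfg <- sim_config(3000, seed = 65, frac_absent = 0)
  res <- run_gene_level_study(cfg)
  j <- res$joined
  jd <- j[j$planted %in% names(planted_dominance_map), ]
  expect_gte(mean(jd$dominance == planted_dominance_map[jd$planted]), 0.8)
  ja <- j[j$planted == "additive" &
            !j$gene_id %in%
              res$truth$genes$gene_id[res$truth$genes$affinity_artifact], ]
  expect_lte(mean(ja$additivity == "nonadditive"), 0.07)
})

test_that("with modest parental divergence, called dominance genes are
           mostly additive against the mixture", {
  # a dominant parent close to the mixture keeps |H - M| near the noise
  # floor: dominance then usually coexists with statistical additivity
  cfg <- sim_config(3000, seed = 67, divergence_effect_log2 = 0.8,
                    frac_absent = 0, affinity_artifact_frac = 0,
                    pattern_rates = c(dominance_tetraploid_high = 0.25,
                                      dominance_tetraploid_low = 0.25,
                                      additive = 0.5))
  res <- run_gene_level_study(cfg)
  called_dom <- res$joined[res$joined$dominance %in% planted_dominance_map, ]
  expect_gt(nrow(called_dom), 100)
  expect_lt(mean(called_dom$additivity == "nonadditive"), 0.5)
})
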