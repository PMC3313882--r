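# shared fixtures for classification tests: a wide per-gene-per-cell row in
# the form pivot_contrasts() emits
wide_row <- function(sig_td = FALSE, sig_ht = FALSE, sig_hd = FALSE,
                     sig_hm = FALSE, sig_mt = FALSE, sig_md = FALSE,
                     d_td = 0, d_ht = 0, d_hd = 0, d_hm = 0, d_mt = 0,
                     d_md = 0, gene_id = "g1", line = "AT5",
                     generation = "S4") {
  tibble::tibble(gene_id = gene_id, line = line, generation = generation,
                 d_td = d_td, d_ht = d_ht, d_hd = d_hd, d_hm = d_hm,
                 d_mt = d_mt, d_md = d_md,
                 sig_td = sig_td, sig_ht = sig_ht, sig_hd = sig_hd,
                 sig_hm = sig_hm, sig_mt = sig_mt, sig_md = sig_md)
}

# map from planted pattern labels to the dominance enumeration
planted_dominance_map <- c(
  dominance_diploid_high = "diploid_high",
  dominance_diploid_low = "diploid_low",
  dominance_tetraploid_high = "tetraploid_high",
  dominance_tetraploid_low = "tetraploid_low")

# gene-level study: simulate, test, classify; returns calls joined to truth
run_gene_level_study <- function(cfg) {
  truth <- build_truth(cfg)
  expr <- simulate_expression(truth)
  ct <- contrast_table(expr)
  calls <- classify_patterns(ct)
  planted <- dplyr::rename(truth$cells, planted = pattern)
  joined <- dplyr::inner_join(tibble::as_tibble(calls), planted,
                              by = c("gene_id", "line", "generation"))
  list(truth = truth, contrasts = ct, calls = calls, joined = joined)
}
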