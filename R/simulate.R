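#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data :=
#' @importFrom dplyr %>%
NULL

# Planted-pattern vocabulary shared by the simulator and the recovery tests.
sim_patterns <- function() {
  c("dominance_diploid_high", "dominance_diploid_low",
    "dominance_tetraploid_high", "dominance_tetraploid_low",
    "over_dominance", "under_dominance",
    "nonadditive_other", "additive")
}

sim_persistence_groups <- function() c("stochastic", "heritable", "persistent")

default_pattern_rates <- function() {
  c(dominance_diploid_high    = 0.02,
    dominance_diploid_low     = 0.02,
    dominance_tetraploid_high = 0.06,
    dominance_tetraploid_low  = 0.04,
    over_dominance            = 0.010,
    under_dominance           = 0.005,
    nonadditive_other         = 0.015,
    additive                  = 0.830)
}

#' Simulation configuration for a synthetic allopolyploidy study
#'
#' Describes a study with two parental species of unequal ploidy (a tetraploid
#' "T" and a diploid "D"), an empirical mid-parent RNA mixture ("M", default
#' 2:1 T:D by transcript abundance), and two independent allopolyploid lines
#' sampled at two successive selfed generations, each group with biological
#' replicates. Expression patterns (parental dominance, over-/under-dominance,
#' other non-additivity, additivity) are planted per gene together with a
#' transgenerational persistence label, and a configurable fraction of genes
#' carries a hybridization-affinity artifact that mimics parental dominance in
#' both the mixture and the polyploid.
#'
#' @param n_genes number of genes on the simulated array.
#' @param probes_per_set perfect-match probes per probe-set (>= 3; the
#'   detection call needs ranks).
#' @param n_replicates biological replicates per sample group.
#' @param frac_parent_divergent fraction of genes differentially expressed
#'   between the parents; exactly `round(n_genes * frac_parent_divergent)`
#'   genes are flagged divergent.
#' @param divergence_effect_log2 absolute parental log2 difference planted for
#'   divergent genes (also the margin used for over-/under-dominance).
#' @param pattern_rates named probabilities over the planted patterns
#'   (see [sim_patterns()]); applies to divergent genes, non-divergent genes
#'   are always additive. Must sum to 1.
#' @param persistence_rates named probabilities over
#'   `c("stochastic", "heritable", "persistent")`; must sum to 1. A stochastic
#'   gene expresses its planted pattern in one random (line, generation) cell,
#'   a heritable gene in both generations of one random line, a persistent
#'   gene in all four cells; inactive cells are additive.
#' @param noise_sd_log2 per-probe log2 measurement noise standard deviation.
#' @param bio_sd_log2 replicate-level biological log2 noise, shared by all
#'   probes of a gene within one sample (defaults to `noise_sd_log2`);
#'   this is what the within-group variance of the summarized data sees.
#' @param frac_absent fraction of genes not expressed in the sampled tissue
#'   (background-only probes; drawn among non-divergent genes).
#' @param affinity_artifact_frac fraction of genes given a differential
#'   hybridization-affinity artifact. Artifact genes are truly additive and
#'   parent-divergent, but one parental transcript pool hybridizes more or
#'   less efficiently so that the mixture and the polyploid both appear equal
#'   to one parent.
#' @param affinity_sd_log2 log2 jitter of the affinity multiplier around the
#'   exact dominance-mimicking value.
#' @param probe_affinity_sd_log2 sd of per-probe log2 affinity multipliers.
#' @param mm_crosshyb fraction of the true signal leaking into mismatch
#'   probes.
#' @param background_mean,background_sd optical background intensity
#'   parameters (linear scale).
#' @param baseline_mean_log2,baseline_sd_log2 distribution of gene baseline
#'   log2 expression levels.
#' @param mix_ratio length-2 nonnegative weights of the tetraploid and
#'   diploid RNA pools in the mid-parent mixture (default 2:1).
#' @param lines,generations labels of the polyploid lines and selfed
#'   generations.
#' @param seed integer seed; all randomness in [build_truth()] and
#'   [simulate_panel()] derives from it.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 200, seed = 1)
#' truth <- build_truth(cfg)
#' panel <- simulate_panel(truth)
sim_config <- function(n_genes,
                       probes_per_set = 11,
                       n_replicates = 2,
                       frac_parent_divergent = 0.4,
                       divergence_effect_log2 = 2,
                       pattern_rates = default_pattern_rates(),
                       persistence_rates = c(stochastic = 0.7,
                                             heritable = 0.2,
                                             persistent = 0.1),
                       noise_sd_log2 = 0.1,
                       bio_sd_log2 = noise_sd_log2,
                       frac_absent = 0.3,
                       affinity_artifact_frac = 0.02,
                       affinity_sd_log2 = 0.1,
                       probe_affinity_sd_log2 = 0.5,
                       mm_crosshyb = 0.05,
                       background_mean = 50,
                       background_sd = 10,
                       baseline_mean_log2 = 8,
                       baseline_sd_log2 = 1.5,
                       mix_ratio = c(2, 1),
                       lines = c("AT5", "AT9"),
                       generations = c("S4", "S5"),
                       seed = 1L) {
  stopifnot(length(n_genes) == 1, n_genes >= 1,
            length(probes_per_set) == 1, length(n_replicates) == 1,
            n_replicates >= 1, noise_sd_log2 >= 0, bio_sd_log2 >= 0,
            frac_absent >= 0,
            frac_absent <= 1, affinity_sd_log2 >= 0,
            probe_affinity_sd_log2 >= 0, background_mean > 0,
            length(mix_ratio) == 2, all(mix_ratio >= 0), sum(mix_ratio) > 0,
            length(lines) >= 1, length(generations) >= 1)
  if (probes_per_set < 3) {
    stop("`probes_per_set` must be >= 3: the detection call ranks probe scores.",
         call. = FALSE)
  }
  if (frac_parent_divergent < 0 || frac_parent_divergent > 1) {
    stop("`frac_parent_divergent` must lie in [0, 1].", call. = FALSE)
  }
  check_rates <- function(r, expect, what) {
    if (!all(names(r) %in% expect) || anyNA(r) || any(r < 0)) {
      stop(sprintf("`%s` must be named nonnegative probabilities over {%s}.",
                   what, paste(expect, collapse = ", ")), call. = FALSE)
    }
    if (abs(sum(r) - 1) > 1e-9) {
      stop(sprintf("`%s` must sum to 1 (got %.12g).", what, sum(r)),
           call. = FALSE)
    }
    out <- stats::setNames(rep(0, length(expect)), expect)
    out[names(r)] <- r
    out
  }
  pattern_rates <- check_rates(pattern_rates, sim_patterns(), "pattern_rates")
  persistence_rates <- check_rates(persistence_rates, sim_persistence_groups(),
                                   "persistence_rates")
  structure(list(
    n_genes = as.integer(n_genes), probes_per_set = as.integer(probes_per_set),
    n_replicates = as.integer(n_replicates),
    frac_parent_divergent = frac_parent_divergent,
    divergence_effect_log2 = divergence_effect_log2,
    pattern_rates = pattern_rates, persistence_rates = persistence_rates,
    noise_sd_log2 = noise_sd_log2, bio_sd_log2 = bio_sd_log2,
    frac_absent = frac_absent,
    affinity_artifact_frac = affinity_artifact_frac,
    affinity_sd_log2 = affinity_sd_log2,
    probe_affinity_sd_log2 = probe_affinity_sd_log2,
    mm_crosshyb = mm_crosshyb, background_mean = background_mean,
    background_sd = background_sd, baseline_mean_log2 = baseline_mean_log2,
    baseline_sd_log2 = baseline_sd_log2, mix_ratio = as.numeric(mix_ratio),
    lines = as.character(lines), generations = as.character(generations),
    seed = as.integer(seed)), class = "sim_config")
}

#' Expected mid-parent intensity on the linear scale
#'
#' The mid-parent mixture is modeled on the linear transcript-abundance scale
#' (the RNAs are physically mixed before hybridization): the expectation is
#' the mix-ratio-weighted mean of the parental linear levels, each scaled by
#' the hybridization affinity of that parent's transcript pool on the array.
#' With both affinities equal to 1 this is the pure mixture expectation.
#'
#' @param t_linear,d_linear parental expression levels, linear scale (> 0).
#' @param mix_ratio length-2 nonnegative weights (tetraploid, diploid).
#' @param affinity_t,affinity_d positive relative hybridization affinities.
#' @return numeric vector of expected mixture intensities.
#' @export
#' @examples
#' expected_mpv_linear(300, 30)            # (2/3)*300 + (1/3)*30 = 210
#' expected_mpv_linear(300, 30, affinity_d = 3)  # 230
expected_mpv_linear <- function(t_linear, d_linear, mix_ratio = c(2, 1),
                                affinity_t = 1, affinity_d = 1) {
  if (any(t_linear <= 0) || any(d_linear <= 0) ||
      any(affinity_t <= 0) || any(affinity_d <= 0)) {
    stop("parental levels and affinities must be strictly positive.",
         call. = FALSE)
  }
  if (length(mix_ratio) != 2 || any(mix_ratio < 0) || sum(mix_ratio) <= 0) {
    stop("`mix_ratio` must be two nonnegative weights with positive sum.",
         call. = FALSE)
  }
  w <- mix_ratio / sum(mix_ratio)
  w[1] * affinity_t * t_linear + w[2] * affinity_d * d_linear
}

#' Plant the per-gene truth of a synthetic study
#'
#' Draws, for every gene, the parental log2 levels, the divergence flag
#' (exactly `round(n_genes * frac_parent_divergent)` genes), the planted
#' expression pattern, its transgenerational persistence, hybridization
#' affinity factors, and per-probe affinities; then realizes the pattern in
#' each (line, generation) cell according to the persistence label.
#'
#' For a planted dominance pattern the polyploid's true level equals the
#' dominant parent's level exactly; over-/under-dominance sits
#' `divergence_effect_log2` above the higher (below the lower) parent; the
#' residual non-additive pattern sits at the parental log2 midpoint; additive
#' cells sit at the linear-scale mixture expectation.
#'
#' @param config a [sim_config()].
#' @return an object of class `truth_table`: a list with tibbles `genes`
#'   (per-gene latent state), `cells` (per gene x line x generation pattern
#'   and true polyploid log2 level), `probes` (probe map with affinities),
#'   and the `config`.
#' @export
build_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  eff <- config$divergence_effect_log2
  gene_id <- sprintf("g%05d", seq_len(n))
  baseline <- stats::rnorm(n, config$baseline_mean_log2, config$baseline_sd_log2)

  n_div <- round(n * config$frac_parent_divergent)
  divergent <- logical(n)
  divergent[sample.int(n, n_div)] <- TRUE

  # absent (tissue-silent) genes: drawn among non-divergent genes so pattern
  # planting and the exact divergent count stay unconfounded
  absent <- logical(n)
  nd_idx <- which(!divergent)
  n_abs <- min(round(n * config$frac_absent), length(nd_idx))
  if (n_abs > 0) absent[sample(nd_idx, n_abs)] <- TRUE

  pattern <- rep("additive", n)
  if (n_div > 0) {
    pattern[divergent] <- sample(names(config$pattern_rates), n_div,
                                 replace = TRUE, prob = config$pattern_rates)
  }

  # parental levels: which parent is higher is dictated by dominance labels;
  # the free genes are assigned so the two directions balance exactly among
  # divergent genes (real parental transcriptomes split up/down about evenly,
  # and imbalance would propagate a global shift through normalization)
  d_higher <- logical(n)
  forced_d <- pattern %in% c("dominance_diploid_high", "dominance_tetraploid_low")
  forced_t <- pattern %in% c("dominance_diploid_low", "dominance_tetraploid_high")
  d_higher[forced_d] <- TRUE
  free <- which(divergent & !forced_d & !forced_t)
  need_d <- min(max(round(n_div / 2) - sum(forced_d), 0), length(free))
  if (length(free) > 0 && need_d > 0) {
    d_higher[sample(free, need_d)] <- TRUE
  }
  t_level <- ifelse(divergent, baseline - ifelse(d_higher, eff / 2, -eff / 2),
                    baseline)
  d_level <- ifelse(divergent, baseline + ifelse(d_higher, eff / 2, -eff / 2),
                    baseline)

  persistence <- rep(NA_character_, n)
  patterned <- which(pattern != "additive")
  if (length(patterned) > 0) {
    persistence[patterned] <- sample(names(config$persistence_rates),
                                     length(patterned), replace = TRUE,
                                     prob = config$persistence_rates)
  }

  # hybridization-affinity artifacts among divergent, truly additive genes:
  # scale the non-target pool by (target/other) so the mixture (and hence the
  # additive polyploid) sits exactly at the target parent's level
  affinity_t <- rep(1, n)
  affinity_d <- rep(1, n)
  art_pool <- which(divergent & pattern == "additive" & !absent)
  n_art <- min(round(n * config$affinity_artifact_frac), length(art_pool))
  artifact <- logical(n)
  if (n_art > 0) {
    idx <- sample(art_pool, n_art)
    artifact[idx] <- TRUE
    to_diploid <- stats::runif(n_art) < 0.5   # which parent the mixture mimics
    jit <- 2^stats::rnorm(n_art, 0, config$affinity_sd_log2)
    fac <- 2^(ifelse(to_diploid, d_level[idx] - t_level[idx],
                     t_level[idx] - d_level[idx])) * jit
    affinity_t[idx] <- ifelse(to_diploid, fac, 1)
    affinity_d[idx] <- ifelse(to_diploid, 1, fac)
  }

  genes <- tibble::tibble(
    gene_id = gene_id, baseline_log2 = baseline, divergent = divergent,
    absent = absent, t_level_log2 = t_level, d_level_log2 = d_level,
    pattern = pattern, persistence = persistence,
    affinity_artifact = artifact,
    affinity_factor_t = affinity_t, affinity_factor_d = affinity_d)

  # realize the pattern over the four cells
  cells_grid <- tidyr::expand_grid(line = config$lines,
                                   generation = config$generations)
  n_cells <- nrow(cells_grid)
  active <- matrix(FALSE, n, n_cells)
  if (length(patterned) > 0) {
    pick_line <- sample(seq_along(config$lines), n, replace = TRUE)
    pick_cell <- sample.int(n_cells, n, replace = TRUE)
    for (i in patterned) {
      active[i, ] <- switch(persistence[i],
        stochastic = seq_len(n_cells) == pick_cell[i],
        heritable  = cells_grid$line == config$lines[pick_line[i]],
        persistent = rep(TRUE, n_cells))
    }
  }

  mpv_log2 <- log2(expected_mpv_linear(2^t_level, 2^d_level, config$mix_ratio))
  h_for_pattern <- function(pat) {
    ifelse(pat %in% c("dominance_diploid_high", "dominance_diploid_low"),
           d_level,
    ifelse(pat %in% c("dominance_tetraploid_high", "dominance_tetraploid_low"),
           t_level,
    ifelse(pat == "over_dominance", pmax(t_level, d_level) + eff,
    ifelse(pat == "under_dominance", pmin(t_level, d_level) - eff,
    ifelse(pat == "nonadditive_other", (t_level + d_level) / 2, mpv_log2)))))
  }

  cells <- purrr::pmap_dfr(
    list(seq_len(n_cells), cells_grid$line, cells_grid$generation),
    function(ci, ln, gn) {
      pat <- ifelse(active[, ci], pattern, "additive")
      tibble::tibble(gene_id = gene_id, line = ln, generation = gn,
                     pattern = pat, h_level_log2 = h_for_pattern(pat))
    })

  # probe affinities are median-centered within each probe-set: a common
  # shift of a set's probes is indistinguishable from the gene's level, and
  # median polish estimates the level under exactly this constraint
  aff <- matrix(stats::rnorm(n * config$probes_per_set, 0,
                             config$probe_affinity_sd_log2),
                nrow = config$probes_per_set)
  aff <- sweep(aff, 2, apply(aff, 2, stats::median))
  probes <- tibble::tibble(
    probe_id = sprintf("%s_p%02d", rep(gene_id, each = config$probes_per_set),
                       rep(seq_len(config$probes_per_set), n)),
    set_id = paste0("ps_", rep(gene_id, each = config$probes_per_set)),
    gene_id = rep(gene_id, each = config$probes_per_set),
    affinity_log2 = as.vector(aff))

  structure(list(genes = genes, cells = cells, probes = probes,
                 config = config), class = "truth_table")
}

#' Sample design of the synthetic study
#'
#' One tetraploid-parent group, one diploid-parent group, one mid-parent
#' mixture group per polyploid line, and one polyploid group per line and
#' generation, each with `n_replicates` biological replicates.
#'
#' @param config a [sim_config()].
#' @return a tibble with columns `sample_id`, `role` (one of
#'   `tetraploid_parent`, `diploid_parent`, `mpv`, `allohexaploid`), `line`,
#'   `generation`, `replicate`.
#' @export
sim_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  reps <- seq_len(config$n_replicates)
  base <- dplyr::bind_rows(
    tibble::tibble(role = "tetraploid_parent", line = NA_character_,
                   generation = NA_character_),
    tibble::tibble(role = "diploid_parent", line = NA_character_,
                   generation = NA_character_),
    tibble::tibble(role = "mpv", line = config$lines,
                   generation = NA_character_),
    tidyr::expand_grid(role = "allohexaploid", line = config$lines,
                       generation = config$generations))
  design <- tidyr::expand_grid(base, replicate = reps)
  design$sample_id <- paste0(
    dplyr::case_when(design$role == "tetraploid_parent" ~ "T",
                     design$role == "diploid_parent" ~ "D",
                     design$role == "mpv" ~ paste0("MPV_", design$line),
                     TRUE ~ paste0("HEX_", design$line, "_", design$generation)),
    "_r", design$replicate)
  dplyr::select(design, "sample_id", "role", "line", "generation", "replicate")
}

# true measured log2 level of every gene in every sample group (affinity
# artifacts act on the mixture and the polyploid, never on pure parents)
truth_group_levels <- function(truth) {
  cfg <- truth$config
  g <- truth$genes
  mpv_measured <- log2(expected_mpv_linear(
    2^g$t_level_log2, 2^g$d_level_log2, cfg$mix_ratio,
    g$affinity_factor_t, g$affinity_factor_d))
  hex <- truth$cells %>%
    dplyr::left_join(dplyr::select(g, "gene_id", "affinity_factor_t",
                                   "affinity_factor_d"), by = "gene_id") %>%
    dplyr::mutate(level_log2 = ifelse(
      .data$pattern == "additive",
      mpv_measured[match(.data$gene_id, g$gene_id)],
      .data$h_level_log2),
      role = "allohexaploid") %>%
    dplyr::select("gene_id", "role", "line", "generation", "level_log2")
  mpv <- tidyr::expand_grid(gene_id = g$gene_id, line = cfg$lines) %>%
    dplyr::mutate(role = "mpv", generation = NA_character_,
                  level_log2 = mpv_measured[match(.data$gene_id, g$gene_id)])
  parents <- dplyr::bind_rows(
    tibble::tibble(gene_id = g$gene_id, role = "tetraploid_parent",
                   line = NA_character_, generation = NA_character_,
                   level_log2 = g$t_level_log2),
    tibble::tibble(gene_id = g$gene_id, role = "diploid_parent",
                   line = NA_character_, generation = NA_character_,
                   level_log2 = g$d_level_log2))
  dplyr::bind_rows(parents, mpv, hex)
}

#' Simulate a probe-level intensity panel
#'
#' For every expressed gene and sample, the perfect-match signal is
#' `2^(true level + probe affinity + Normal(0, noise_sd_log2))` plus an
#' optical background; mismatch probes see background plus a small
#' cross-hybridization fraction of the signal. Tissue-silent genes yield
#' background on both probe types. The mid-parent samples follow
#' [expected_mpv_linear()] including any planted affinity artifact.
#'
#' @param truth a `truth_table` from [build_truth()].
#' @param design a sample design tibble; defaults to [sim_design()] of the
#'   truth's config.
#' @param config defaults to the truth's config.
#' @return an object of class `probe_panel`: list with matrices `pm`, `mm`
#'   (probes x samples, linear scale), the `probes` map, the `design`, and
#'   the `config`.
#' @export
simulate_panel <- function(truth, design = NULL, config = truth$config) {
  stopifnot(inherits(truth, "truth_table"))
  if (is.null(design)) design <- sim_design(config)
  validate_design(design)
  set.seed(config$seed + 1000003L)
  g <- truth$genes
  levels_tbl <- truth_group_levels(truth)
  key <- function(role, line, generation) {
    paste(role, ifelse(is.na(line), ".", line),
          ifelse(is.na(generation), ".", generation))
  }
  lvl_key <- key(levels_tbl$role, levels_tbl$line, levels_tbl$generation)
  n_probe <- nrow(truth$probes)
  n_samp <- nrow(design)
  gi <- match(truth$probes$gene_id, g$gene_id)
  if (anyNA(gi)) stop("probe map references genes absent from the truth table.",
                      call. = FALSE)
  pm <- matrix(0, n_probe, n_samp,
               dimnames = list(truth$probes$probe_id, design$sample_id))
  mm <- pm
  for (j in seq_len(n_samp)) {
    sk <- key(design$role[j], design$line[j], design$generation[j])
    rows <- which(lvl_key == sk)
    if (length(rows) != nrow(g)) {
      stop(sprintf("design/truth mismatch for sample group '%s'.", sk),
           call. = FALSE)
    }
    lev <- levels_tbl$level_log2[rows][match(truth$probes$gene_id,
                                             levels_tbl$gene_id[rows])]
    bio <- stats::rnorm(nrow(g), 0, config$bio_sd_log2)
    signal <- ifelse(g$absent[gi], 0,
                     2^(lev + bio[gi] + truth$probes$affinity_log2 +
                        stats::rnorm(n_probe, 0, config$noise_sd_log2)))
    pm[, j] <- signal + pmax(stats::rnorm(n_probe, config$background_mean,
                                          config$background_sd), 1)
    mm[, j] <- config$mm_crosshyb * signal +
      pmax(stats::rnorm(n_probe, config$background_mean,
                        config$background_sd), 1)
  }
  structure(list(pm = pm, mm = mm, probes = truth$probes, design = design,
                 config = config), class = "probe_panel")
}

#' Simulate a gene-level log2 expression matrix directly
#'
#' Bypasses the probe level: each sample measures the gene's true log2 level
#' in its group plus Normal noise with variance `bio_sd_log2^2 +
#' noise_sd_log2^2 / probes_per_set` (biological replicate variation plus
#' the averaged-down probe noise). Useful for studying the testing and
#' classification stages in isolation.
#'
#' @inheritParams simulate_panel
#' @return a tibble with `gene_id` and one column per sample; the design is
#'   attached as attribute `"design"`.
#' @export
simulate_expression <- function(truth, design = NULL, config = truth$config) {
  stopifnot(inherits(truth, "truth_table"))
  if (is.null(design)) design <- sim_design(config)
  validate_design(design)
  set.seed(config$seed + 2000003L)
  g <- truth$genes
  levels_tbl <- truth_group_levels(truth)
  key <- function(role, line, generation) {
    paste(role, ifelse(is.na(line), ".", line),
          ifelse(is.na(generation), ".", generation))
  }
  lvl_key <- key(levels_tbl$role, levels_tbl$line, levels_tbl$generation)
  sd_gene <- sqrt(config$bio_sd_log2^2 +
                  config$noise_sd_log2^2 / config$probes_per_set)
  m <- matrix(NA_real_, nrow(g), nrow(design),
              dimnames = list(g$gene_id, design$sample_id))
  for (j in seq_len(nrow(design))) {
    sk <- key(design$role[j], design$line[j], design$generation[j])
    rows <- which(lvl_key == sk)
    lev <- levels_tbl$level_log2[rows][match(g$gene_id,
                                             levels_tbl$gene_id[rows])]
    m[, j] <- lev + stats::rnorm(nrow(g), 0, sd_gene)
  }
  expr_tbl(m, design)
}

validate_design <- function(design) {
  req <- c("sample_id", "role", "line", "generation", "replicate")
  miss <- setdiff(req, names(design))
  if (length(miss) > 0) {
    stop("sample design is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  roles <- c("tetraploid_parent", "diploid_parent", "mpv", "allohexaploid")
  bad <- setdiff(unique(design$role), roles)
  if (length(bad) > 0) {
    stop("unknown sample role(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(design$role %in% c("mpv", "allohexaploid") & is.na(design$line))) {
    stop("mpv and allohexaploid samples must carry a line id.", call. = FALSE)
  }
  if (anyDuplicated(design$sample_id)) {
    stop("duplicated sample ids in design.", call. = FALSE)
  }
  invisible(design)
}

# build an expression tibble (gene_id + one column per sample) from a matrix
expr_tbl <- function(m, design) {
  out <- tibble::as_tibble(m, rownames = "gene_id")
  attr(out, "design") <- design
  class(out) <- c("expr_tbl", class(out))
  out
}

#' Extract the numeric matrix from an expression tibble
#' @param expr a tibble with `gene_id` and one numeric column per sample.
#' @return numeric matrix with gene ids as rownames.
#' @export
expr_matrix <- function(expr) {
  stopifnot("gene_id" %in% names(expr))
  if (anyDuplicated(expr$gene_id)) {
    stop("duplicated gene ids in expression table.", call. = FALSE)
  }
  m <- as.matrix(expr[setdiff(names(expr), "gene_id")])
  if (!is.numeric(m)) stop("expression values must be numeric.", call. = FALSE)
  rownames(m) <- expr$gene_id
  m
}
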