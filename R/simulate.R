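#' Configuration for the synthetic EV-miRNA study generator
#'
#' Builds the parameter list consumed by [simulate_bundle()] and the stage
#' generators. Defaults emulate the study design the pipeline is meant for:
#' two EV sources sequenced in triplicate (3 vs 3 libraries), a majority of
#' miRNAs shared between sources, 11 miRNAs exclusive to source A and 2
#' exclusive to source B, a ~15,000-gene recipient transcriptome, and ~100
#' true high-confidence gene targets per source-specific miRNA.
#'
#' @param n_shared Number of miRNAs expressed in both groups (default 150).
#' @param n_specific_a,n_specific_b Numbers of group-exclusive miRNAs
#'   (defaults 11 and 2). Exclusive miRNAs are structural zeros in the other
#'   group unless `leaky_rate > 0`.
#' @param group_labels Labels of the two EV sources (default `c("A", "B")`);
#'   group A is the silencing source whose miRNA cargo shifts its targets in
#'   the DE table.
#' @param libraries_per_group Replicate libraries per group (default 3).
#' @param mean_depth Expected miRNA-assigned counts per library (default
#'   5e5); realized depths are jittered uniformly by `+/- depth_jitter`.
#' @param depth_jitter Relative depth jitter (default 0.2).
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`;
#'   default 0.15, a typical small-RNA replicate dispersion).
#' @param shared_meanlog,shared_sdlog,specific_meanlog,specific_sdlog
#'   Log-normal parameters of relative miRNA expression levels; the specific
#'   miRNAs are drawn well above the detection threshold.
#' @param leaky_rate Expected stray counts (Poisson) of an exclusive miRNA
#'   in the *other* group's libraries; 0 (default) keeps structural zeros.
#' @param n_genes Recipient-transcriptome size (default 15000).
#' @param targets_per_mirna True high-confidence gene targets per specific
#'   miRNA (default 100).
#' @param decoys_per_mirna Decoy (non-silenced) predicted targets per
#'   specific miRNA with scores spanning `decoy_score_range` (default 150).
#' @param true_score_range,decoy_score_range Target-score ranges (uniform)
#'   for true and decoy predictions; defaults `c(90, 100)` and `c(50, 100)`.
#' @param multi_transcript_fraction Fraction of predictions that list a
#'   second transcript isoform of the same gene (default 0.1).
#' @param unmapped_fraction Fraction of extra prediction rows pointing at
#'   transcripts absent from the gene map (default 0.02), exercising the
#'   unmapped-transcript path.
#' @param silencing_beta Expected decrease in a true target's log2 fold
#'   change per unit mean log2 CPM of its targeting miRNA (default 1; 0
#'   plants no silencing signal).
#' @param log2fc_sd Standard deviation of log2 fold-change noise
#'   (default 0.5).
#' @param frac_background_de Fraction of genes (targets included) with
#'   genuine miRNA-independent differential expression (default 0.1).
#' @param background_effect Absolute log2FC of background DE genes
#'   (default 2).
#' @param frac_genes_expressed Fraction of the gene universe present in the
#'   recipient DE table (default 0.65): target prediction spans the whole
#'   transcriptome but differential expression is only testable for
#'   expressed genes, so a matching share of predicted targets is absent
#'   from the DE table.
#' @param seed Integer seed making the bundle reproducible bit-for-bit.
#' @return A list of class `evlink_sim_config`.
#' @export
sim_config <- function(n_shared = 150, n_specific_a = 11, n_specific_b = 2,
                       group_labels = c("A", "B"), libraries_per_group = 3,
                       mean_depth = 5e5, depth_jitter = 0.2, dispersion = 0.15,
                       shared_meanlog = log(100), shared_sdlog = 1.5,
                       specific_meanlog = log(200), specific_sdlog = 1,
                       leaky_rate = 0,
                       n_genes = 15000, targets_per_mirna = 100,
                       decoys_per_mirna = 150,
                       true_score_range = c(90, 100),
                       decoy_score_range = c(50, 100),
                       multi_transcript_fraction = 0.1,
                       unmapped_fraction = 0.02,
                       silencing_beta = 1, log2fc_sd = 0.5,
                       frac_background_de = 0.1, background_effect = 2,
                       frac_genes_expressed = 0.65,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(length(cfg$group_labels) == 2, !anyDuplicated(cfg$group_labels))
  num_nonneg <- c("n_shared", "n_specific_a", "n_specific_b", "mean_depth",
                  "dispersion", "n_genes", "targets_per_mirna",
                  "decoys_per_mirna", "silencing_beta", "log2fc_sd",
                  "frac_background_de", "leaky_rate")
  for (f in num_nonneg) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 0) {
      stop_config(sprintf("sim_config field '%s' must be a single non-negative number", f))
    }
  }
  if (cfg$libraries_per_group < 1) stop_config("libraries_per_group must be >= 1")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = c("evlink_sim_config", "list"))
}

sim_gene_universe <- function(cfg) sprintf("SYNG%05d", seq_len(cfg$n_genes))

#' Simulate a grouped miRNA count matrix with planted exclusive miRNAs
#'
#' Shared miRNAs receive a common expected relative abundance in both
#' groups; group-exclusive miRNAs have expectation zero (structural zeros,
#' or low Poisson leakage when `leaky_rate > 0`) in the other group and a
#' log-normal expectation well above the detection threshold in their own.
#' Counts are negative-binomial with the configured dispersion around
#' library depths jittered by `+/- depth_jitter`.
#'
#' Uses the current RNG state; call via [simulate_bundle()] (which seeds
#' from `cfg$seed`) for bit-reproducible bundles.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `counts` (a [mirna_counts()]) and `truth`
#'   (planted specific miRNA IDs per group and expression expectations).
#' @export
simulate_counts <- function(cfg) {
  la <- cfg$group_labels[1]; lb <- cfg$group_labels[2]
  ids_shared <- sprintf("syn-miR-s%03d", seq_len(cfg$n_shared))
  ids_a <- sprintf("syn-miR-%s%02d", la, seq_len(cfg$n_specific_a))
  ids_b <- sprintf("syn-miR-%s%02d", lb, seq_len(cfg$n_specific_b))
  ids <- c(ids_shared, ids_a, ids_b)
  expr_shared <- rlnorm(cfg$n_shared, cfg$shared_meanlog, cfg$shared_sdlog)
  expr_a <- rlnorm(cfg$n_specific_a, cfg$specific_meanlog, cfg$specific_sdlog)
  expr_b <- rlnorm(cfg$n_specific_b, cfg$specific_meanlog, cfg$specific_sdlog)
  expected <- cbind(c(expr_shared, expr_a, rep(0, cfg$n_specific_b)),
                    c(expr_shared, rep(0, cfg$n_specific_a), expr_b))
  colnames(expected) <- c(la, lb)
  nlib <- cfg$libraries_per_group
  libs <- c(sprintf("%s_L%d", la, seq_len(nlib)), sprintf("%s_L%d", lb, seq_len(nlib)))
  groups <- setNames(rep(c(la, lb), each = nlib), libs)
  size <- if (cfg$dispersion > 0) 1 / cfg$dispersion else Inf
  counts <- matrix(0L, nrow = length(ids), ncol = length(libs),
                   dimnames = list(NULL, libs))
  for (j in seq_along(libs)) {
    g <- groups[j]
    depth <- cfg$mean_depth * runif(1, 1 - cfg$depth_jitter, 1 + cfg$depth_jitter)
    mu <- expected[, g] / sum(expected[, g]) * depth
    counts[, j] <- rnbinom(length(ids), mu = mu, size = size)
    if (cfg$leaky_rate > 0) {
      absent <- expected[, g] == 0
      counts[absent, j] <- counts[absent, j] + stats::rpois(sum(absent), cfg$leaky_rate)
    }
  }
  m <- mirna_counts(tibble(mirna_id = ids) %>% dplyr::bind_cols(as_tibble(counts)),
                    groups)
  truth <- list(specific = setNames(list(ids_a, ids_b), c(la, lb)),
                shared = ids_shared,
                expected_expression = tibble(mirna_id = ids,
                                             expected_a = expected[, la],
                                             expected_b = expected[, lb]))
  list(counts = m, truth = truth)
}

sample_scores <- function(n, range) round(runif(n, range[1], range[2]), 1)

#' Simulate a scored target-prediction table and transcript-to-gene map
#'
#' Each planted specific miRNA receives its true gene targets with scores in
#' the high-confidence range, plus decoy predictions (non-silenced genes)
#' with scores spanning the decoy range, so only a predictable tail of
#' decoys survives the score cutoff. Genes carry 1-3 transcript isoforms; a
#' fraction of predictions list two isoforms of the same gene (collapsed by
#' [targets_to_genes()]) and a small set of extra rows points at transcripts
#' deliberately absent from the map.
#'
#' @param cfg A [sim_config()].
#' @param truth Truth object from [simulate_counts()].
#' @return List with `predictions`, `gene_map`, and `truth` extended with
#'   `target_sets` (named list: true gene targets per specific miRNA).
#' @export
simulate_predictions <- function(cfg, truth) {
  genes <- sim_gene_universe(cfg)
  specific <- unlist(truth$specific, use.names = FALSE)
  target_sets <- setNames(
    lapply(specific, function(m) sample(genes, min(cfg$targets_per_mirna, length(genes)))),
    specific)
  rows <- purrr::map_dfr(specific, function(m) {
    true_g <- target_sets[[m]]
    decoy_pool <- setdiff(genes, true_g)
    decoy_g <- sample(decoy_pool, min(cfg$decoys_per_mirna, length(decoy_pool)))
    tibble(mirna_id = m,
           gene_id = c(true_g, decoy_g),
           target_score = c(sample_scores(length(true_g), cfg$true_score_range),
                            sample_scores(length(decoy_g), cfg$decoy_score_range)))
  })
  pred_genes <- sort(unique(rows$gene_id))
  n_tx <- sample(1:3, length(pred_genes), replace = TRUE)
  gene_map <- tibble(
    gene_id = rep(pred_genes, n_tx),
    transcript_id = sprintf("SYNT%06d", seq_len(sum(n_tx)))) %>%
    select("transcript_id", "gene_id")
  tx_of <- split(gene_map$transcript_id, gene_map$gene_id)
  pick1 <- map_chr(tx_of[rows$gene_id], function(tx) tx[sample.int(length(tx), 1)])
  pred <- tibble(mirna_id = rows$mirna_id, transcript_id = unname(pick1),
                 target_score = rows$target_score)
  # second isoform for a fraction of multi-transcript predictions
  multi <- which(runif(nrow(rows)) < cfg$multi_transcript_fraction &
                   lengths(tx_of[rows$gene_id]) > 1)
  if (length(multi) > 0) {
    second <- map_chr(multi, function(i) {
      tx <- setdiff(tx_of[[rows$gene_id[i]]], pred$transcript_id[i])
      tx[sample.int(length(tx), 1)]
    })
    pred <- bind_rows(pred, tibble(mirna_id = rows$mirna_id[multi],
                                   transcript_id = second,
                                   target_score = rows$target_score[multi]))
  }
  n_unmapped <- round(cfg$unmapped_fraction * nrow(pred))
  if (n_unmapped > 0) {
    pred <- bind_rows(pred, tibble(
      mirna_id = sample(specific, n_unmapped, replace = TRUE),
      transcript_id = sprintf("SYNTU%04d", seq_len(n_unmapped)),
      target_score = sample_scores(n_unmapped, cfg$decoy_score_range)))
  }
  pred <- pred %>% distinct(.data$mirna_id, .data$transcript_id, .keep_all = TRUE)
  truth$target_sets <- target_sets
  list(predictions = validate_predictions(pred), gene_map = gene_map, truth = truth)
}

#' Simulate a recipient-cell DE table with planted miRNA silencing
#'
#' Every gene can carry background (miRNA-independent) differential
#' expression: with probability `frac_background_de` its mean log2FC is
#' shifted by `+/- background_effect` with equal sign probability. True
#' targets of the silencing group's exclusive miRNAs receive an additional
#' shift of `-silencing_beta * mean_log2_cpm` of the targeting miRNA (the
#' maximum-abundance miRNA when several target the same gene). Observed
#' log2FC adds Normal(0, `log2fc_sd`) noise; p-values are the matching
#' two-sided z-test of the observed log2FC against the noise SD, and FDR is
#' Benjamini-Hochberg across all genes.
#'
#' @param cfg A [sim_config()].
#' @param truth Truth object from [simulate_predictions()] (needs
#'   `target_sets`).
#' @param abundance Abundance summary ([abundance_summary()]) of the
#'   silencing group computed from the simulated counts.
#' @return List with `de` (the DE tibble) and `truth` extended with
#'   `gene_effects` (per-gene background and silencing shifts).
#' @export
simulate_de <- function(cfg, truth, abundance) {
  universe <- sim_gene_universe(cfg)
  genes <- sort(sample(universe, round(cfg$frac_genes_expressed * length(universe))))
  n <- length(genes)
  bg_de <- runif(n) < cfg$frac_background_de
  bg_shift <- ifelse(bg_de, ifelse(runif(n) < 0.5, -1, 1) * cfg$background_effect, 0)
  sil_shift <- rep(0, n)
  sil_mirnas <- truth$specific[[cfg$group_labels[1]]]
  if (cfg$silencing_beta > 0 && length(sil_mirnas) > 0) {
    ab <- setNames(abundance$mean_log2_cpm, abundance$mirna_id)
    gene_idx <- setNames(seq_len(n), genes)
    for (m in sil_mirnas) {
      a <- ab[[m]]
      if (is.null(a) || is.na(a)) next
      idx <- unname(gene_idx[intersect(truth$target_sets[[m]], genes)])
      sil_shift[idx] <- pmin(sil_shift[idx], -cfg$silencing_beta * a)
    }
  }
  log2fc <- bg_shift + sil_shift + rnorm(n, 0, cfg$log2fc_sd)
  pvalue <- 2 * pnorm(-abs(log2fc) / cfg$log2fc_sd)
  de <- tibble(gene_id = genes, log2fc = log2fc, pvalue = pvalue,
               fdr = p.adjust(pvalue, method = "BH"))
  truth$expressed_genes <- genes
  truth$gene_effects <- tibble(gene_id = genes, background_shift = bg_shift,
                               silencing_shift = sil_shift)
  list(de = de, truth = truth)
}

#' Simulate a complete input bundle with ground truth
#'
#' Seeds the RNG from `cfg$seed` and runs [simulate_counts()],
#' [abundance_summary()] (silencing group), [simulate_predictions()] and
#' [simulate_de()] in a fixed order, so identical configurations yield
#' bit-identical bundles.
#'
#' @param cfg A [sim_config()].
#' @return List with `counts`, `groups`, `abundance`, `predictions`,
#'   `gene_map`, `de`, `truth`, `config`.
#' @export
#' @examples
#' b <- simulate_bundle(sim_config(n_shared = 30, n_genes = 500,
#'                                 targets_per_mirna = 10, seed = 7))
#' call_specific_mirnas(b$counts)
simulate_bundle <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  sc <- simulate_counts(cfg)
  ab <- abundance_summary(sc$counts, cfg$group_labels[1])
  sp <- simulate_predictions(cfg, sc$truth)
  sd_ <- simulate_de(cfg, sp$truth, ab)
  list(counts = sc$counts, groups = library_groups(sc$counts), abundance = ab,
       predictions = sp$predictions, gene_map = sp$gene_map,
       de = sd_$de, truth = sd_$truth, config = cfg)
}

#' Write a simulated bundle to disk as a pipeline-ready fixture
#'
#' Emits the four input tables (`counts.tsv`, `groups.tsv`,
#' `predictions.tsv`, `gene_map.tsv`, `de.tsv`) plus `truth.json` holding
#' the planted specific miRNAs, true target sets and silencing coefficient.
#' Every file passes the corresponding reader's validation.
#'
#' @param dir Output directory (created if missing).
#' @param cfg A [sim_config()]; set `seed` there for reproducibility.
#' @return Named character vector of file paths, invisibly.
#' @export
make_fixture <- function(dir, cfg = sim_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  b <- simulate_bundle(cfg)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             groups = file.path(dir, "groups.tsv"),
             predictions = file.path(dir, "predictions.tsv"),
             gene_map = file.path(dir, "gene_map.tsv"),
             de = file.path(dir, "de.tsv"),
             truth = file.path(dir, "truth.json"))
  write_count_matrix(b$counts, paths["counts"])
  write_library_groups(b$groups, paths["groups"])
  write_predictions(b$predictions, paths["predictions"])
  write_gene_map(b$gene_map, paths["gene_map"])
  write_de_table(b$de %>% mutate(log2fc = round(.data$log2fc, 6),
                                 pvalue = signif(.data$pvalue, 6),
                                 fdr = signif(.data$fdr, 6)),
                 paths["de"])
  truth_json <- list(specific = b$truth$specific,
                     target_sets = b$truth$target_sets,
                     silencing_beta = b$config$silencing_beta,
                     seed = b$config$seed)
  jsonlite::write_json(truth_json, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
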