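make_pred <- function(mirna, tx, score) {
  tibble::tibble(mirna_id = mirna, transcript_id = tx, target_score = score)
}

test_that("high-confidence filter is inclusive at the cutoff and monotone", {
  pred <- make_pred("m1", c("t1", "t2", "t3"), c(90, 89.99, 100))
  expect_equal(filter_high_confidence(pred)$transcript_id, c("t1", "t3"))
  expect_equal(filter_high_confidence(pred, 0), pred)
  set.seed(2)
  rnd <- make_pred("m1", sprintf("t%03d", 1:200), runif(200, 0, 100))
  ns <- sapply(c(0, 30, 60, 90, 100), function(ct)
    nrow(filter_high_confidence(rnd, ct)))
  expect_true(all(diff(ns) <= 0))
  expect_error(filter_high_confidence(pred, 101), class = "evlink_config_error")
})

test_that("gene mapping deduplicates isoforms and drops unmapped transcripts", {
  pred <- make_pred("m1", c("t1a", "t1b", "t2", "tX"), c(95, 96, 92, 99))
  map <- tibble::tibble(transcript_id = c("t1a", "t1b", "t2"),
                        gene_id = c("g1", "g1", "g2"))
  expect_message(out <- targets_to_genes(pred, map), "1 prediction")
  expect_equal(nrow(out), 2)  # two isoforms of g1 collapse to one gene target
  expect_setequal(out$gene_id, c("g1", "g2"))
  expect_equal(attr(out, "n_unmapped"), 1L)
})

test_that("DE classification partitions genes under both cutoff styles", {
  de <- tibble::tibble(gene_id = c("g1", "g2", "g3", "g4"),
                       log2fc = c(-2, 1.5, 0.5, 3),
                       pvalue = c(1e-5, 0.1, 1e-4, 1e-6),
                       fdr = c(0.01, 0.2, 0.01, 0.001))
  cls <- classify_de(de)
  expect_equal(as.character(cls$class), c("DOWN", "NON_DE", "UP", "UP"))
  cls1 <- classify_de(de, abs_log2fc_cutoff = 1)
  expect_equal(as.character(cls1$class), c("DOWN", "NON_DE", "NON_DE", "UP"))
  expect_equal(sort(unique(levels(cls$class))), sort(c("DOWN", "UP", "NON_DE")))
})

test_that("target classification conserves counts per miRNA and at union level", {
  de <- tibble::tibble(gene_id = sprintf("g%02d", 1:12),
                       log2fc = rep(c(-2, 2, 0.1), each = 4),
                       pvalue = rep(c(1e-5, 1e-5, 0.8), each = 4),
                       fdr = rep(c(0.01, 0.01, 0.9), each = 4))
  cls <- classify_de(de)
  # disjoint target sets: per-miRNA counts must sum to union counts
  tg <- tibble::tibble(mirna_id = rep(c("m1", "m2"), each = 4),
                       gene_id = c("g01", "g02", "g05", "g09",
                                   "g03", "g06", "g10", "gABSENT"))
  rec <- classify_targets(tg, cls)
  expect_equal(rec$n_present, rec$n_down + rec$n_up + rec$n_nonde)
  tot <- linkage_totals(rec)
  expect_equal(tot$n_down, sum(rec$n_down))
  expect_equal(tot$n_up, sum(rec$n_up))
  expect_equal(tot$n_nonde, sum(rec$n_nonde))
  expect_equal(attr(rec, "n_absent"), 1L)
  m1 <- rec[rec$mirna_id == "m1", ]
  expect_equal(m1$mean_log2fc_down, mean(c(-2, -2)))
  # empty target set yields all zeros
  rec0 <- classify_targets(tibble::tibble(mirna_id = character(),
                                          gene_id = character()), cls)
  expect_equal(nrow(rec0), 0)
  expect_equal(linkage_totals(rec0)$n_present, 0L)
})

test_that("target proportions divide by class size and flag empty classes", {
  de <- tibble::tibble(gene_id = sprintf("g%02d", 1:10),
                       log2fc = c(rep(-2, 4), rep(2, 6)),
                       pvalue = 1e-5, fdr = 0.01)
  cls <- classify_de(de)
  pr <- target_proportions(cls, c("g01", "g02", "g05"))
  expect_equal(pr$proportion[pr$class == "DOWN"], 2 / 4)
  expect_equal(pr$proportion[pr$class == "UP"], 1 / 6)
  expect_true(is.na(pr$proportion[pr$class == "NON_DE"]))  # empty class undefined
  all_t <- target_proportions(cls, de$gene_id)
  expect_equal(all_t$percent[!is.na(all_t$percent)], c(100, 100))
})

test_that("multi-miRNA convergence nests over k and lists contributors", {
  de <- tibble::tibble(gene_id = c("gA", "gB", "gC"),
                       log2fc = c(-2, -2, 2), pvalue = 1e-5, fdr = 0.01)
  cls <- classify_de(de)
  tg <- tibble::tibble(mirna_id = c("m1", "m2", "m3", "m1", "m1"),
                       gene_id = c("gA", "gA", "gA", "gB", "gC"))
  hit3 <- multi_mirna_down_targets(tg, cls, k = 3)
  expect_equal(hit3$gene_id, "gA")
  expect_equal(hit3$mirna_ids[[1]], c("m1", "m2", "m3"))
  hit1 <- multi_mirna_down_targets(tg, cls, k = 1)
  expect_setequal(hit1$gene_id, c("gA", "gB"))  # gC is UP, never listed
  for (k in 1:3) {
    expect_true(all(multi_mirna_down_targets(tg, cls, k + 1)$gene_id %in%
                      multi_mirna_down_targets(tg, cls, k)$gene_id))
  }
})

test_that("GSEA ranking scores by signed log significance and clamps p = 0", {
  de <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                       log2fc = c(2, -2, 1),
                       pvalue = c(0.01, 0.01, 0), fdr = c(0.02, 0.02, 0))
  expect_warning(rk <- gsea_ranking(de), "clamped")
  expect_equal(rk$score[rk$gene_id == "g1"], 4)
  expect_equal(rk$score[rk$gene_id == "g2"], -4)
  expect_equal(rk$gene_id[1], "g3")  # clamped p gives the top finite score
  expect_true(all(is.finite(rk$score)))
  expect_true(all(diff(rk$score) <= 0))
  # ranking is not invariant under monotone p rescaling: dividing every p by
  # 10 adds one -log10 unit, which favours large fold changes and flips g1/g4
  de2 <- tibble::tibble(gene_id = c("g1", "g4"), log2fc = c(1, 3.5),
                        pvalue = c(1e-4, 0.1), fdr = c(1e-3, 0.1))
  r_orig <- gsea_ranking(de2)       # scores 4 vs 3.5: g1 first
  r_resc <- gsea_ranking(dplyr::mutate(de2, pvalue = pvalue / 10))
  expect_false(identical(r_orig$gene_id, r_resc$gene_id))
})

test_that("sensitivity grid covers the cross-product and agrees with single runs", {
  b <- simulate_bundle(sim_config(n_shared = 40, n_genes = 2000,
                                  targets_per_mirna = 40, decoys_per_mirna = 40,
                                  mean_depth = 5e4, seed = 21))
  specific <- b$truth$specific$A
  grid <- suppressMessages(
    sensitivity_grid(specific, b$abundance, b$predictions, b$gene_map, b$de))
  expect_equal(nrow(grid), 9)
  expect_equal(nrow(dplyr::distinct(grid, score_cutoff, fdr_cutoff)), 9)
  rec <- suppressMessages(
    build_linkage_records(specific, b$abundance, b$predictions, b$gene_map, b$de))
  fit <- abundance_repression_correlation(rec)
  cell <- grid[grid$score_cutoff == 90 & grid$fdr_cutoff == 0.05, ]
  expect_equal(cell$r, fit$estimate)
  expect_equal(cell$p, fit$p.value)
  expect_equal(cell$n_used, fit$n_used)
})
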