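# Small configuration keeping simulation tests fast.
small_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_shared = 40, n_genes = 2000, targets_per_mirna = 40,
         decoys_per_mirna = 40, mean_depth = 5e4, seed = seed),
    list(...))
  do.call(sim_config, args)
}

test_that("bundles are bit-reproducible under a fixed seed and differ across seeds", {
  b1 <- simulate_bundle(small_cfg(seed = 4))
  b2 <- simulate_bundle(small_cfg(seed = 4))
  expect_identical(as.data.frame(b1$counts), as.data.frame(b2$counts))
  expect_identical(b1$de, b2$de)
  expect_identical(b1$predictions, b2$predictions)
  b3 <- simulate_bundle(small_cfg(seed = 5))
  expect_false(identical(as.data.frame(b1$counts), as.data.frame(b3$counts)))
  expect_identical(names(b1$de), names(b3$de))
})

test_that("planted exclusive miRNAs are structural zeros and fully recovered", {
  b <- simulate_bundle(small_cfg(seed = 8))
  m <- as.data.frame(b$counts)
  a_libs <- library_groups(b$counts)$library[library_groups(b$counts)$group == "A"]
  b_libs <- setdiff(names(m), c("mirna_id", a_libs))
  for (id in b$truth$specific$A) {
    expect_true(all(m[m$mirna_id == id, b_libs] == 0))
  }
  calls <- call_specific_mirnas(b$counts, threshold = 5)
  called_a <- calls$mirna_id[!is.na(calls$unique_to) & calls$unique_to == "A"]
  called_b <- calls$mirna_id[!is.na(calls$unique_to) & calls$unique_to == "B"]
  expect_setequal(called_a, b$truth$specific$A)  # recall and precision both 1
  expect_setequal(called_b, b$truth$specific$B)
})

test_that("doubling mean depth approximately doubles library totals", {
  totals <- function(depth, seed) {
    cfg <- small_cfg(seed = seed, mean_depth = depth)
    set.seed(cfg$seed)
    colSums(as.matrix(as.data.frame(simulate_counts(cfg)$counts)[-1]))
  }
  t1 <- rowMeans(sapply(1:10, function(s) totals(5e4, s)))
  t2 <- rowMeans(sapply(1:10, function(s) totals(1e5, s)))
  expect_equal(unname(t2 / t1), rep(2, 6), tolerance = 0.25)
})

test_that("true targets survive the high-confidence filter; decoy tail matches", {
  b <- simulate_bundle(small_cfg(seed = 12))
  hc <- filter_high_confidence(b$predictions, 90)
  tg <- suppressMessages(targets_to_genes(hc, b$gene_map))
  for (m in b$truth$specific$A) {
    expect_true(all(b$truth$target_sets[[m]] %in% tg$gene_id[tg$mirna_id == m]))
  }
  # union of recovered gene targets at the true-score cutoff contains the
  # planted union exactly when decoys are removed
  planted_union <- sort(unique(unlist(b$truth$target_sets[b$truth$specific$A])))
  expect_true(all(planted_union %in% tg$gene_id))

  # decoy scores are Uniform(50, 100): the fraction at >= 90 concentrates on
  # the analytic tail probability 0.2
  set.seed(99)
  tail_frac <- replicate(20, {
    cfg <- small_cfg(seed = sample.int(1e6, 1), decoys_per_mirna = 200)
    bb <- simulate_bundle(cfg)
    pg <- dplyr::left_join(bb$predictions, bb$gene_map, by = "transcript_id")
    is_true <- mapply(function(m, g) !is.na(g) && g %in% bb$truth$target_sets[[m]],
                      pg$mirna_id, pg$gene_id)
    mean(pg$target_score[!is_true] >= 90)
  })
  expect_equal(mean(tail_frac), 0.2, tolerance = 0.03)
})

test_that("multi-transcript predictions collapse and BH matches a hand-computed example", {
  b <- simulate_bundle(small_cfg(seed = 3))
  tg <- suppressMessages(targets_to_genes(b$predictions, b$gene_map))
  expect_lt(nrow(tg), nrow(b$predictions))  # isoforms + unmapped rows collapse
  # Benjamini-Hochberg oracle, worked by hand for five p-values:
  # sorted p (m = 5): 0.005, 0.009, 0.05, 0.3, 0.9
  # p * m / rank:     0.025, 0.0225, 0.08333..., 0.375, 0.9
  # step-up cummin:   0.0225, 0.0225, 0.08333..., 0.375, 0.9
  p <- c(0.05, 0.005, 0.9, 0.009, 0.3)
  expect_equal(p.adjust(p, method = "BH"),
               c(0.25 / 3, 0.0225, 0.9, 0.0225, 0.375))
  # and within a bundle the FDR column is a monotone transform of p
  ord <- order(b$de$pvalue)
  expect_true(all(diff(b$de$fdr[ord]) >= -1e-12))
})

test_that("silencing shifts scale with miRNA abundance; beta = 0 plants none", {
  b0 <- simulate_bundle(small_cfg(seed = 6, silencing_beta = 0))
  eff <- b0$truth$gene_effects
  expect_true(all(eff$silencing_shift == 0))
  # with no silencing, target and non-target log2FC are exchangeable
  targ <- unique(unlist(b0$truth$target_sets[b0$truth$specific$A]))
  in_t <- b0$de$gene_id %in% targ
  wt <- stats::wilcox.test(b0$de$log2fc[in_t], b0$de$log2fc[!in_t])
  expect_gt(wt$p.value, 0.001)

  b1 <- simulate_bundle(small_cfg(seed = 6, silencing_beta = 1, log2fc_sd = 0.05))
  rec <- suppressMessages(build_linkage_records(
    b1$truth$specific$A, b1$abundance, b1$predictions, b1$gene_map, b1$de))
  fit <- abundance_repression_correlation(rec)
  expect_lt(fit$estimate, -0.95)  # construction limit: r near -1 at low noise
})

test_that("written fixtures pass every reader's validation and round-trip", {
  dir <- withr::local_tempdir()
  paths <- make_fixture(dir, small_cfg(seed = 10))
  groups <- read_library_groups(paths["groups"])
  counts <- read_count_matrix(paths["counts"], groups)
  de <- read_de_table(paths["de"])
  pred <- read_predictions(paths["predictions"])
  map <- read_gene_map(paths["gene_map"])
  truth <- jsonlite::read_json(paths["truth"])
  expect_equal(nrow(counts), 40 + 11 + 2)
  expect_equal(length(truth$specific$A), 11)
  expect_equal(length(truth$specific$B), 2)
  b <- simulate_bundle(small_cfg(seed = 10))
  expect_identical(as.data.frame(counts), as.data.frame(b$counts))
  dir2 <- withr::local_tempdir()
  make_fixture(dir2, small_cfg(seed = 11))
  expect_false(identical(readLines(file.path(dir, "counts.tsv")),
                         readLines(file.path(dir2, "counts.tsv"))))
})
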