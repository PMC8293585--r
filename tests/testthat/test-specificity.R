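test_that("replicate detection applies the count-and-membership rule", {
  m <- toy_counts(list(c(5L, 5L, 0L, 0L, 0L, 0L),
                       c(4L, 4L, 4L, 0L, 0L, 0L),
                       c(10L, 0L, 0L, 0L, 0L, 0L)))
  det5 <- detected_in_group(m, "A", threshold = 5, min_libraries = 2)
  expect_equal(det5$detected, c(TRUE, FALSE, FALSE))
  det1 <- detected_in_group(m, "A", threshold = 1, min_libraries = 1)
  expect_true(det1$detected[3])
  expect_error(detected_in_group(m, "C"), class = "evlink_config_error")
  expect_error(detected_in_group(m, "A", min_libraries = 4),
               class = "evlink_config_error")
})

test_that("exclusivity requires literal zero counts in every other library", {
  m <- toy_counts(list(c(7L, 6L, 0L, 0L, 0L, 0L),
                       c(7L, 6L, 0L, 1L, 0L, 0L)))
  calls <- call_specific_mirnas(m, threshold = 5, min_libraries = 2)
  expect_equal(calls$unique_to, c("A", NA))
  single <- mirna_counts(data.frame(mirna_id = "m", L1 = 5L), c(L1 = "A"))
  expect_error(call_specific_mirnas(single), class = "evlink_config_error")
})

test_that("detection sweep matches hand enumeration on the toy matrix", {
  m <- toy_counts(list(c(5L, 5L, 5L, 0L, 0L, 0L),
                       c(1L, 1L, 0L, 1L, 1L, 0L),
                       c(0L, 0L, 0L, 10L, 10L, 10L),
                       c(2L, 0L, 0L, 0L, 0L, 0L)))
  sweep <- detection_sweep(m, thresholds = c(1, 3, 5, 10), min_libraries = 2)
  get <- function(thr, grp, col) sweep[[col]][sweep$threshold == thr & sweep$group == grp]
  # threshold 5 is the spec'd worked case: one detected + unique per group
  expect_equal(get(5, "A", "n_detected"), 1L)
  expect_equal(get(5, "B", "n_detected"), 1L)
  expect_equal(get(5, "A", "n_unique"), 1L)
  expect_equal(get(5, "B", "n_unique"), 1L)
  # full hand enumeration of the remaining thresholds
  expect_equal(get(1, "A", "n_detected"), 2L)
  expect_equal(get(1, "B", "n_detected"), 2L)
  expect_equal(get(1, "A", "n_unique"), 1L)
  expect_equal(get(10, "A", "n_detected"), 0L)
  expect_equal(get(10, "B", "n_unique"), 1L)

  all_zero <- toy_counts(list(rep(0L, 6), rep(0L, 6)))
  sw0 <- detection_sweep(all_zero, min_libraries = 2)
  expect_true(all(sw0$n_detected == 0) && all(sw0$n_unique == 0))
  expect_error(detection_sweep(m, thresholds = c(5, 3)),
               class = "evlink_config_error")
})

test_that("detected and unique counts are monotone and groups disjoint", {
  set.seed(11)
  for (i in 1:20) {
    m <- random_counts(n_mirna = 30, lambda = 4)
    sweep <- detection_sweep(m, thresholds = c(1, 2, 3, 5, 8))
    by_group <- split(sweep, sweep$group)
    for (g in by_group) {
      expect_true(all(diff(g$n_detected) <= 0))
      expect_true(all(diff(g$n_unique) <= 0))
      expect_true(all(g$n_unique <= g$n_detected))
    }
    calls <- call_specific_mirnas(m, threshold = 1, min_libraries = 1)
    expect_lte(sum(calls$unique_to == "A", na.rm = TRUE) +
                 sum(calls$unique_to == "B", na.rm = TRUE),
               sum(!is.na(calls$unique_to)))
  }
})

test_that("specificity calls are invariant to library permutation within groups", {
  set.seed(5)
  m <- random_counts(n_mirna = 25, lambda = 3)
  df <- as.data.frame(m)
  perm <- df[c("mirna_id", "A3", "A1", "A2", "B2", "B3", "B1")]
  mp <- mirna_counts(perm, stats::setNames(rep(c("A", "B"), each = 3),
                                           c("A3", "A1", "A2", "B2", "B3", "B1")))
  c1 <- call_specific_mirnas(m, threshold = 3, min_libraries = 2)
  c2 <- call_specific_mirnas(mp, threshold = 3, min_libraries = 2)
  expect_equal(c1$unique_to, c2$unique_to)
  expect_equal(c1$detected_A, c2$detected_A)
})

test_that("CPM normalizes per library and is scale invariant", {
  m <- mirna_counts(data.frame(mirna_id = c("a", "b"), L1 = c(1L, 3L)),
                    c(L1 = "G"))
  cpm <- mirna_cpm(m)
  expect_equal(cpm$cpm, c(250000, 750000))

  set.seed(3)
  r <- random_counts()
  cpm_r <- mirna_cpm(r)
  sums <- tapply(cpm_r$cpm, cpm_r$library, sum)
  expect_equal(as.numeric(sums), rep(1e6, 6))

  # uniform scaling of one library's counts leaves CPM (hence mean CPM) unchanged
  df <- as.data.frame(r)
  df$A1 <- df$A1 * 7L
  r2 <- mirna_counts(df, library_groups(r))
  expect_equal(abundance_summary(r2, "A"), abundance_summary(r, "A"))

  zero <- toy_counts(list(c(0L, 1L, 1L, 1L, 1L, 1L)))
  expect_error(mirna_cpm(zero), class = "evlink_data_error")
})

test_that("abundance summary offers both log2 conventions and handles zeros", {
  m <- toy_counts(list(c(2L, 4L, 6L, 1L, 1L, 1L),
                       c(8L, 6L, 4L, 1L, 1L, 1L),
                       c(0L, 0L, 0L, 8L, 8L, 8L)))
  ab <- abundance_summary(m, "A")
  cpm_a <- matrix(c(2, 4, 6, 8, 6, 4, 0, 0, 0), nrow = 3, byrow = TRUE)
  cpm_a <- sweep(cpm_a, 2, colSums(cpm_a), "/") * 1e6
  expect_equal(ab$mean_cpm, rowMeans(cpm_a))
  expect_equal(ab$mean_log2_cpm[1:2], log2(rowMeans(cpm_a))[1:2])
  expect_true(is.na(ab$mean_log2_cpm[3]))  # zero mean CPM: undefined, no pseudocount
  ab2 <- abundance_summary(m, "A", log2_method = "mean_of_log2")
  expect_equal(ab2$mean_log2_cpm[1], mean(log2(cpm_a[1, ])))
})

test_that("expressed-gene filter requires a fully covered group", {
  gc <- data.frame(gene_id = c("g1", "g2"),
                   a1 = c(10L, 9L), a2 = c(10L, 10L), a3 = c(10L, 10L),
                   b1 = c(0L, 9L), b2 = c(0L, 10L), b3 = c(0L, 10L))
  groups <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B", b3 = "B")
  expect_equal(filter_expressed_genes(gc, groups), "g1")
  set.seed(9)
  big <- data.frame(gene_id = sprintf("g%03d", 1:50),
                    matrix(rpois(300, 12), nrow = 50,
                           dimnames = list(NULL, names(groups))))
  kept <- lapply(c(5, 10, 15, 20), function(k)
    filter_expressed_genes(big, groups, min_count = k))
  for (i in 2:4) expect_true(all(kept[[i]] %in% kept[[i - 1]]))
})
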