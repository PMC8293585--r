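default_min_libraries <- function(n_libraries) as.integer(ceiling(2 / 3 * n_libraries))

#' Replicate-based miRNA detection within one library group
#'
#' A miRNA counts as detected in a group when its raw count reaches
#' `threshold` in at least `min_libraries` of the group's libraries — the
#' presence/absence rule used to filter EV small-RNA libraries, where
#' requiring agreement across replicates guards against one-library
#' artefacts. The default `min_libraries` is `ceiling(2/3 * group size)`,
#' which reproduces the 2-of-3 rule for triplicate designs.
#'
#' @param x A [mirna_counts()] object.
#' @param group Group label to test.
#' @param threshold Minimum raw count (inclusive), >= 1.
#' @param min_libraries Minimum number of libraries in the group meeting
#'   `threshold`; defaults to `ceiling(2/3 * group size)`.
#' @return Tibble with columns `mirna_id`, `detected` (logical).
#' @export
#' @examples
#' m <- mirna_counts(
#'   data.frame(mirna_id = "miR-1", L1 = 5L, L2 = 5L, L3 = 0L),
#'   c(L1 = "A", L2 = "A", L3 = "A"))
#' detected_in_group(m, "A", threshold = 5, min_libraries = 2)
detected_in_group <- function(x, group, threshold = 5, min_libraries = NULL) {
  libs <- group_library_names(x, group)
  min_libraries <- min_libraries %||% default_min_libraries(length(libs))
  if (threshold < 1) stop_config("`threshold` must be >= 1")
  if (min_libraries < 1 || min_libraries > length(libs)) {
    stop_config(sprintf("`min_libraries` must lie in [1, %d] for group '%s'",
                        length(libs), group))
  }
  m <- count_matrix(x)[, libs, drop = FALSE]
  tibble(mirna_id = x$mirna_id,
         detected = unname(rowSums(m >= threshold) >= min_libraries))
}

#' Call miRNAs exclusive to one library group
#'
#' A miRNA is called specific (unique) to group *g* when it passes the
#' replicate detection rule in *g* ([detected_in_group()]) **and** has a raw
#' count of exactly zero in every library of every other group — "not
#' detected at all" is read literally, with no threshold on the other side.
#'
#' @inheritParams detected_in_group
#' @return Tibble with one row per miRNA: `mirna_id`, one logical column
#'   `detected_<group>` per group, and `unique_to` (group label or `NA`).
#' @export
call_specific_mirnas <- function(x, threshold = 5, min_libraries = NULL) {
  g <- library_groups(x)
  groups <- unique(g$group)
  if (length(groups) < 2) {
    stop_config("specificity calling needs at least two groups")
  }
  det <- lapply(groups, function(gr) {
    detected_in_group(x, gr, threshold = threshold,
                      min_libraries = min_libraries)$detected
  })
  names(det) <- groups
  m <- count_matrix(x)
  zero_elsewhere <- sapply(groups, function(gr) {
    other_libs <- g$library[g$group != gr]
    rowSums(m[, other_libs, drop = FALSE] > 0) == 0
  })
  unique_to <- rep(NA_character_, nrow(x))
  for (gr in groups) {
    hit <- det[[gr]] & zero_elsewhere[, gr]
    unique_to[hit] <- gr  # groups are mutually exclusive by the zero rule
  }
  out <- tibble(mirna_id = x$mirna_id)
  for (gr in groups) out[[paste0("detected_", gr)]] <- det[[gr]]
  out$unique_to <- unique_to
  out
}

#' Detection and uniqueness counts over a sweep of raw-count thresholds
#'
#' For each threshold (default sweep 1, 3, 5, 10) counts, per group, the
#' miRNAs passing the replicate detection rule and the subset additionally
#' exclusive to that group — a summary of how sensitive the detected and
#' group-unique miRNA sets are to the raw-count cutoff.
#'
#' @inheritParams detected_in_group
#' @param thresholds Strictly increasing integer thresholds.
#' @return Tibble with columns `threshold`, `group`, `n_detected`, `n_unique`.
#' @export
detection_sweep <- function(x, thresholds = c(1, 3, 5, 10), min_libraries = NULL) {
  if (length(thresholds) == 0 || is.unsorted(thresholds, strictly = TRUE)) {
    stop_config("`thresholds` must be non-empty and strictly increasing")
  }
  purrr::map_dfr(thresholds, function(thr) {
    calls <- call_specific_mirnas(x, threshold = thr, min_libraries = min_libraries)
    groups <- unique(library_groups(x)$group)
    tibble(threshold = as.integer(thr), group = groups,
           n_detected = vapply(groups, function(gr) sum(calls[[paste0("detected_", gr)]]),
                               integer(1), USE.NAMES = FALSE),
           n_unique = vapply(groups, function(gr) sum(calls$unique_to == gr, na.rm = TRUE),
                             integer(1), USE.NAMES = FALSE))
  })
}

#' Per-library counts-per-million for a grouped count matrix
#'
#' CPM is computed per library as `count / library total * 1e6`, where the
#' denominator is that library's total miRNA-assigned counts (the only total
#' this table carries; substitute custom totals upstream if genome-wide
#' denominators are wanted).
#'
#' @param x A [mirna_counts()] object.
#' @return Long tibble with columns `mirna_id`, `library`, `group`, `cpm`.
#' @export
mirna_cpm <- function(x) {
  g <- library_groups(x)
  m <- count_matrix(x)
  totals <- colSums(m)
  zero <- names(totals)[totals == 0]
  if (length(zero) > 0) {
    stop_data(sprintf("library(ies) with zero total counts: %s",
                      paste(zero, collapse = ", ")))
  }
  cpm <- sweep(m, 2, totals, "/") * 1e6
  as_tibble(cpm, rownames = "mirna_id") %>%
    tidyr::pivot_longer(-"mirna_id", names_to = "library", values_to = "cpm") %>%
    left_join(g, by = "library") %>%
    select("mirna_id", "library", "group", "cpm")
}

#' Per-miRNA abundance summary for one group
#'
#' Summarizes library-wise CPM within a group as the arithmetic mean CPM and
#' its log2. By default `mean_log2_cpm = log2(mean CPM)` (undefined — `NA` —
#' when the mean CPM is zero, rather than pseudocounted);
#' `log2_method = "mean_of_log2"` instead averages per-library log2 CPM and
#' is defined only for miRNAs with non-zero CPM in every library.
#'
#' @inheritParams detected_in_group
#' @param log2_method `"log2_of_mean"` (default) or `"mean_of_log2"`.
#' @return Tibble with columns `mirna_id`, `mean_cpm`, `mean_log2_cpm`.
#' @export
abundance_summary <- function(x, group,
                              log2_method = c("log2_of_mean", "mean_of_log2")) {
  log2_method <- match.arg(log2_method)
  libs <- group_library_names(x, group)
  cpm_long <- mirna_cpm(x) %>% filter(.data$library %in% libs)
  out <- cpm_long %>%
    group_by(.data$mirna_id) %>%
    summarise(mean_cpm = mean(.data$cpm),
              .log2_of_mean = ifelse(mean(.data$cpm) > 0, log2(mean(.data$cpm)), NA_real_),
              .mean_of_log2 = ifelse(all(.data$cpm > 0), mean(log2(.data$cpm)), NA_real_),
              .groups = "drop")
  out$mean_log2_cpm <- if (log2_method == "log2_of_mean") out$.log2_of_mean else out$.mean_of_log2
  out %>%
    select("mirna_id", "mean_cpm", "mean_log2_cpm") %>%
    arrange(match(.data$mirna_id, x$mirna_id))
}

#' Retain genes expressed across all replicates of some group
#'
#' A gene is retained when there exists at least one group in which **every**
#' sample has at least `min_count` counts — the expressed-gene filter applied
#' before differential-expression testing.
#'
#' @param gene_counts Data frame: `gene_id` column plus one integer count
#'   column per sample.
#' @param groups Sample-to-group assignment: data frame (`library`/`group`)
#'   or named character vector; every count column must be assigned.
#' @param min_count Minimum per-sample count (default 10).
#' @return Character vector of retained gene IDs, in input order.
#' @export
filter_expressed_genes <- function(gene_counts, groups, min_count = 10) {
  gene_counts <- as_tibble(gene_counts)
  require_columns(gene_counts, "gene_id", "gene count table")
  groups <- normalize_groups(groups)
  samples <- setdiff(names(gene_counts), "gene_id")
  unassigned <- setdiff(samples, groups$library)
  if (length(unassigned) > 0) {
    stop_config(sprintf("no group assigned for sample(s): %s",
                        paste(unassigned, collapse = ", ")))
  }
  m <- as.matrix(gene_counts[samples])
  keep <- rep(FALSE, nrow(m))
  for (gr in unique(groups$group)) {
    cols <- groups$library[groups$group == gr]
    keep <- keep | rowSums(m[, cols, drop = FALSE] >= min_count) == length(cols)
  }
  gene_counts$gene_id[keep]
}
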