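#' Filter predicted targets to high confidence
#'
#' Retains predictions with `target_score >= score_cutoff` (inclusive;
#' a score of exactly 90 survives the default cutoff).
#'
#' @param pred Prediction table (`mirna_id`, `transcript_id`, `target_score`).
#' @param score_cutoff Score cutoff in \[0, 100\]; default 90, the
#'   conventional high-confidence boundary for miRDB-style scores.
#' @return The filtered prediction tibble.
#' @export
filter_high_confidence <- function(pred, score_cutoff = 90) {
  if (score_cutoff < 0 || score_cutoff > 100) {
    stop_config("`score_cutoff` must lie in [0, 100]")
  }
  filter(as_tibble(pred), .data$target_score >= score_cutoff)
}

#' Collapse transcript-level predictions to gene-level target sets
#'
#' Maps each predicted transcript through the transcript-to-gene table and
#' deduplicates, so that two transcript isoforms of one gene yield a single
#' gene-level target. Transcripts absent from the map are dropped with a
#' message; their number is recorded in attribute `"n_unmapped"`.
#'
#' @param pred Prediction table (typically already filtered with
#'   [filter_high_confidence()]).
#' @param map Transcript-to-gene map (`transcript_id`, `gene_id`).
#' @return Tibble with columns `mirna_id`, `gene_id` (distinct pairs),
#'   attribute `n_unmapped` = number of dropped prediction rows.
#' @export
targets_to_genes <- function(pred, map) {
  pred <- as_tibble(pred)
  require_columns(pred, c("mirna_id", "transcript_id"), "prediction table")
  map <- validate_gene_map(map)
  joined <- left_join(pred, map, by = "transcript_id")
  n_unmapped <- sum(is.na(joined$gene_id))
  if (n_unmapped > 0) {
    inform(sprintf("targets_to_genes: dropped %d prediction(s) with unmapped transcripts",
                   n_unmapped))
  }
  out <- joined %>%
    filter(!is.na(.data$gene_id)) %>%
    distinct(.data$mirna_id, .data$gene_id)
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Partition genes into DOWN / UP / NON_DE classes
#'
#' A gene is DOWN when `fdr <= fdr_cutoff` and `log2fc < 0`, UP when
#' `fdr <= fdr_cutoff` and `log2fc > 0`, otherwise NON_DE; the three classes
#' partition the gene set. With `abs_log2fc_cutoff` set (e.g. 1 for
#' cargo enrichment/depletion contrasts), significance additionally requires
#' `|log2fc| > abs_log2fc_cutoff` (strict). For recipient-cell DE the default
#' applies no fold-change magnitude requirement.
#'
#' @param de DE table (`gene_id`, `log2fc`, `pvalue`, `fdr`).
#' @param fdr_cutoff FDR significance cutoff (inclusive), default 0.05.
#' @param abs_log2fc_cutoff Optional strict absolute log2FC cutoff; `NULL`
#'   (default) disables it.
#' @return The DE tibble with an added factor column `class` with levels
#'   `DOWN`, `UP`, `NON_DE`.
#' @export
classify_de <- function(de, fdr_cutoff = 0.05, abs_log2fc_cutoff = NULL) {
  de <- validate_de_table(de)
  sig <- de$fdr <= fdr_cutoff
  if (!is.null(abs_log2fc_cutoff)) {
    sig <- sig & abs(de$log2fc) > abs_log2fc_cutoff
  }
  cls <- ifelse(sig & de$log2fc < 0, "DOWN",
                ifelse(sig & de$log2fc > 0, "UP", "NON_DE"))
  de$class <- factor(cls, levels = c("DOWN", "UP", "NON_DE"))
  de
}

#' Count each miRNA's gene targets by differential-expression class
#'
#' Restricts every miRNA's gene-level target set to genes present in the
#' classified DE table and counts them per class, recording also the mean
#' log2 fold change of the DOWN targets (`NA` when a miRNA has none).
#' Union-level totals over all listed miRNAs' targets are attached as
#' attribute `"totals"` (retrieve with [linkage_totals()]), together with
#' `"n_absent"`, the number of union target genes missing from the DE table.
#'
#' @param target_genes Gene-level target sets from [targets_to_genes()]
#'   (`mirna_id`, `gene_id`).
#' @param de_class Classified DE table from [classify_de()].
#' @return Tibble with one row per miRNA: `mirna_id`, `n_present`, `n_down`,
#'   `n_up`, `n_nonde`, `mean_log2fc_down`.
#' @export
classify_targets <- function(target_genes, de_class) {
  target_genes <- as_tibble(target_genes)
  require_columns(target_genes, c("mirna_id", "gene_id"), "target sets")
  require_columns(de_class, c("gene_id", "log2fc", "class"), "classified DE table")
  mirnas <- unique(target_genes$mirna_id)
  joined <- inner_join(target_genes, de_class[c("gene_id", "log2fc", "class")],
                       by = "gene_id")
  per_mirna <- joined %>%
    group_by(.data$mirna_id) %>%
    summarise(n_present = dplyr::n(),
              n_down = sum(.data$class == "DOWN"),
              n_up = sum(.data$class == "UP"),
              n_nonde = sum(.data$class == "NON_DE"),
              mean_log2fc_down = ifelse(any(.data$class == "DOWN"),
                                        mean(.data$log2fc[.data$class == "DOWN"]),
                                        NA_real_),
              .groups = "drop")
  out <- tibble(mirna_id = mirnas) %>%
    left_join(per_mirna, by = "mirna_id") %>%
    mutate(across(c("n_present", "n_down", "n_up", "n_nonde"),
                  ~ tidyr::replace_na(as.integer(.x), 0L)))
  union_genes <- unique(target_genes$gene_id)
  union_present <- de_class %>% filter(.data$gene_id %in% union_genes)
  totals <- tibble(
    n_targets = length(union_genes),
    n_present = nrow(union_present),
    n_down = sum(union_present$class == "DOWN"),
    n_up = sum(union_present$class == "UP"),
    n_nonde = sum(union_present$class == "NON_DE"))
  attr(out, "totals") <- totals
  attr(out, "n_absent") <- length(union_genes) - nrow(union_present)
  out
}

#' @rdname classify_targets
#' @param records Output of [classify_targets()].
#' @export
linkage_totals <- function(records) {
  t <- attr(records, "totals", exact = TRUE)
  if (is.null(t)) stop_config("`records` carries no union totals; build it with classify_targets()")
  t
}

#' Fraction of each DE class covered by the target union
#'
#' For each class, the fraction of its genes that belong to the supplied
#' target gene set: `|class INTERSECT targets| / |class|`. An empty class
#' yields an undefined (`NA`) fraction rather than zero.
#'
#' @param de_class Classified DE table from [classify_de()].
#' @param union_targets Character vector of target gene IDs (e.g. the union
#'   over all specific miRNAs, or one miRNA's target set).
#' @return Tibble with columns `class`, `n_genes`, `n_targets`, `proportion`
#'   (and `percent` = 100 * proportion).
#' @export
target_proportions <- function(de_class, union_targets) {
  require_columns(de_class, c("gene_id", "class"), "classified DE table")
  union_targets <- unique(as.character(union_targets))
  de_class %>%
    group_by(class = .data$class) %>%
    summarise(n_genes = dplyr::n(),
              n_targets = sum(.data$gene_id %in% union_targets),
              .groups = "drop") %>%
    tidyr::complete(class, fill = list(n_genes = 0L, n_targets = 0L)) %>%
    mutate(proportion = ifelse(.data$n_genes > 0,
                               .data$n_targets / .data$n_genes, NA_real_),
           percent = 100 * .data$proportion)
}

#' Downregulated genes targeted by several miRNAs at once
#'
#' Lists the DOWN-classified genes that appear in the target sets of at
#' least `k` distinct miRNAs, with the contributing miRNA identifiers —
#' convergent silencing candidates.
#'
#' @param target_genes Gene-level target sets (`mirna_id`, `gene_id`).
#' @param de_class Classified DE table from [classify_de()].
#' @param k Minimum number of distinct targeting miRNAs (default 3).
#' @return Tibble with columns `gene_id`, `n_mirnas`, `mirna_ids`
#'   (list-column of contributing miRNA IDs), sorted by decreasing
#'   `n_mirnas`.
#' @export
multi_mirna_down_targets <- function(target_genes, de_class, k = 3) {
  if (k < 1) stop_config("`k` must be >= 1")
  down <- de_class$gene_id[de_class$class == "DOWN"]
  as_tibble(target_genes) %>%
    filter(.data$gene_id %in% down) %>%
    group_by(.data$gene_id) %>%
    summarise(n_mirnas = dplyr::n_distinct(.data$mirna_id),
              mirna_ids = list(sort(unique(.data$mirna_id))),
              .groups = "drop") %>%
    filter(.data$n_mirnas >= k) %>%
    arrange(desc(.data$n_mirnas), .data$gene_id)
}

#' Rank genes for set enrichment by signed significance
#'
#' Computes the ranking statistic `-log10(pvalue) * log2fc` and sorts genes
#' by it in decreasing order. Zero p-values are clamped to the smallest
#' representable positive double (with a warning) so all scores stay finite
#' and sortable. Enrichment testing itself is out of scope; the ranked list
#' feeds standard GSEA tools.
#'
#' @param de DE table (`gene_id`, `log2fc`, `pvalue`, `fdr`).
#' @return Tibble `gene_id`, `score`, sorted by decreasing score.
#' @export
gsea_ranking <- function(de) {
  de <- validate_de_table(de)
  p <- de$pvalue
  if (any(p == 0)) {
    warn(sprintf("gsea_ranking: %d zero p-value(s) clamped to %.3e",
                 sum(p == 0), .Machine$double.xmin))
    p[p == 0] <- .Machine$double.xmin
  }
  tibble(gene_id = de$gene_id, score = -log10(p) * de$log2fc) %>%
    arrange(desc(.data$score))
}
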