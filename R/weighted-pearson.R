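#' Weighted Pearson correlation with a t-based significance test
#'
#' Pearson's correlation computed with weighted means and covariances:
#' \deqn{r_w = \frac{\sum_i w_i (x_i-\bar x_w)(y_i-\bar y_w)}
#'   {\sqrt{\sum_i w_i (x_i-\bar x_w)^2 \; \sum_i w_i (y_i-\bar y_w)^2}}}
#' with \eqn{\bar x_w, \bar y_w} the weighted means. Points with zero weight
#' are removed before anything else and do not contribute to the sample
#' size. The two-sided p-value uses the usual t companion of Pearson's r,
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} with `n` = number of positive-weight
#' points, referred to a Student t distribution on `n - 2` degrees of
#' freedom. `r` is invariant to positive rescaling of the weights; with
#' equal weights the statistic reduces exactly to the unweighted Pearson
#' correlation, and with integer weights it equals the unweighted
#' correlation of the dataset in which point *i* is replicated \eqn{w_i}
#' times.
#'
#' @param x,y Numeric vectors of equal length.
#' @param w Non-negative numeric weights, same length; defaults to equal
#'   weights.
#' @param labels Optional character labels per point (carried into the
#'   result for plotting).
#' @return An object of class `weighted_pearson`: a list with `estimate`
#'   (r), `statistic` (t), `df`, `p.value`, `n_used`, `n_excluded`, and the
#'   retained `data` (tibble `x`, `y`, `w`, `label`). Methods: `print()`,
#'   [tidy()], [glance()], [autoplot()][ggplot2::autoplot].
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(8); y <- -x + rnorm(8, sd = 0.5)
#' weighted_pearson(x, y, w = c(1, 2, 1, 3, 1, 1, 2, 1))
weighted_pearson <- function(x, y, w = rep(1, length(x)), labels = NULL) {
  if (length(x) != length(y) || length(x) != length(w)) {
    stop_config("`x`, `y` and `w` must have the same length")
  }
  if (anyNA(w) || any(w < 0)) stop_config("weights must be non-negative and non-missing")
  keep <- w > 0 & !is.na(x) & !is.na(y)
  n_excluded <- length(x) - sum(keep)
  x <- x[keep]; y <- y[keep]; w <- w[keep]
  labels <- if (is.null(labels)) rep(NA_character_, sum(keep)) else as.character(labels)[keep]
  n <- length(x)
  if (n < 3) {
    stop_insufficient(sprintf(
      "need at least 3 positive-weight points with observed x and y; have %d", n))
  }
  xm <- sum(w * x) / sum(w)
  ym <- sum(w * y) / sum(w)
  sxx <- sum(w * (x - xm)^2)
  syy <- sum(w * (y - ym)^2)
  if (sxx == 0 || syy == 0) {
    stop_degenerate("zero weighted variance in x or y; correlation undefined")
  }
  r <- sum(w * (x - xm) * (y - ym)) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  df <- n - 2
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df)
  structure(
    list(estimate = r, statistic = tstat, df = df, p.value = p,
         n_used = n, n_excluded = n_excluded,
         data = tibble(x = x, y = y, w = w, label = labels)),
    class = "weighted_pearson")
}

#' @export
print.weighted_pearson <- function(x, digits = 3, ...) {
  cat("Weighted Pearson correlation\n")
  cat(sprintf("  r = %.*f, t = %.*f (df = %d), two-sided p = %.4g\n",
              digits, x$estimate, digits, x$statistic, x$df, x$p.value))
  cat(sprintf("  n used = %d (excluded: %d zero-weight or missing)\n",
              x$n_used, x$n_excluded))
  invisible(x)
}

#' @rdname weighted_pearson
#' @param x A `weighted_pearson` object (for methods).
#' @param ... Unused.
#' @method tidy weighted_pearson
#' @export
tidy.weighted_pearson <- function(x, ...) {
  tibble(estimate = x$estimate, statistic = x$statistic,
         parameter = x$df, p.value = x$p.value,
         method = "weighted Pearson correlation (t approximation)")
}

#' @rdname weighted_pearson
#' @method glance weighted_pearson
#' @export
glance.weighted_pearson <- function(x, ...) {
  tibble(r = x$estimate, statistic = x$statistic, df = x$df,
         p.value = x$p.value, n_used = x$n_used, n_excluded = x$n_excluded)
}

#' Two-sided p-value for a given weighted correlation and sample size
#'
#' The t companion used by [weighted_pearson()], exposed directly so a
#' reported r can be re-assessed under an explicit choice of contributing
#' sample size: `t = r * sqrt((n_used - 2) / (1 - r^2))`, two-sided against
#' Student t on `n_used - 2` degrees of freedom.
#'
#' @param r Correlation in (-1, 1).
#' @param n_used Number of contributing (positive-weight) points, >= 3.
#' @return Two-sided p-value.
#' @export
#' @examples
#' pearson_p_value(-0.65, n_used = 10)
pearson_p_value <- function(r, n_used) {
  if (abs(r) >= 1) stop_config("`r` must lie strictly inside (-1, 1)")
  if (n_used < 3) stop_insufficient("`n_used` must be >= 3")
  df <- n_used - 2
  2 * pt(-abs(r) * sqrt(df / (1 - r^2)), df)
}

#' Correlate EV miRNA abundance with repression of its downregulated targets
#'
#' The linkage statistic: across source-specific miRNAs, the weighted
#' Pearson correlation of `x` = mean log2 CPM in the EV libraries against
#' `y` = mean log2 fold change of the miRNA's downregulated high-confidence
#' targets in the recipient cells, each miRNA weighted by its number of
#' downregulated targets (`w = n_down`). miRNAs with no downregulated
#' target (undefined `y`, zero weight) are excluded and reported via
#' `n_excluded`; degrees of freedom follow the retained count.
#'
#' @param records Linkage records carrying `mirna_id`, `mean_log2_cpm`,
#'   `mean_log2fc_down`, `n_down` — e.g. [classify_targets()] output joined
#'   with [abundance_summary()], or [build_linkage_records()].
#' @return A [weighted_pearson()] object.
#' @export
abundance_repression_correlation <- function(records) {
  require_columns(records, c("mirna_id", "mean_log2_cpm", "mean_log2fc_down", "n_down"),
                  "linkage records")
  weighted_pearson(records$mean_log2_cpm, records$mean_log2fc_down,
                   w = records$n_down, labels = records$mirna_id)
}

#' Assemble per-miRNA linkage records
#'
#' Convenience chain joining target classification with abundance: filters
#' predictions to high confidence, maps them to gene level, classifies the
#' DE table, counts each specific miRNA's targets by class and attaches the
#' group's abundance summary.
#'
#' @param specific_mirnas Character vector of miRNA IDs to link (e.g. the
#'   `unique_to == group` calls from [call_specific_mirnas()]).
#' @param abundance Abundance summary for the EV source group
#'   ([abundance_summary()]).
#' @param pred Prediction table.
#' @param map Transcript-to-gene map.
#' @param de DE table.
#' @param score_cutoff,fdr_cutoff,abs_log2fc_cutoff Cutoffs passed to
#'   [filter_high_confidence()] and [classify_de()].
#' @return Linkage-record tibble (`mirna_id`, `mean_log2_cpm`, `mean_cpm`,
#'   `n_present`, `n_down`, `n_up`, `n_nonde`, `mean_log2fc_down`) with the
#'   union totals of [classify_targets()] preserved in attributes, plus
#'   attribute `"target_genes"` (the gene-level sets) and `"de_class"`.
#' @export
build_linkage_records <- function(specific_mirnas, abundance, pred, map, de,
                                  score_cutoff = 90, fdr_cutoff = 0.05,
                                  abs_log2fc_cutoff = NULL) {
  if (length(specific_mirnas) == 0) {
    stop_insufficient("no specific miRNAs supplied")
  }
  hc <- filter_high_confidence(pred, score_cutoff = score_cutoff) %>%
    filter(.data$mirna_id %in% specific_mirnas)
  target_genes <- targets_to_genes(hc, map)
  de_class <- classify_de(de, fdr_cutoff = fdr_cutoff,
                          abs_log2fc_cutoff = abs_log2fc_cutoff)
  records <- classify_targets(target_genes, de_class)
  totals <- attr(records, "totals")
  n_absent <- attr(records, "n_absent")
  n_unmapped <- attr(target_genes, "n_unmapped")
  # keep every requested miRNA, even with an empty surviving target set
  records <- tibble(mirna_id = specific_mirnas) %>%
    left_join(records, by = "mirna_id") %>%
    mutate(across(c("n_present", "n_down", "n_up", "n_nonde"),
                  ~ tidyr::replace_na(as.integer(.x), 0L))) %>%
    left_join(abundance, by = "mirna_id") %>%
    select("mirna_id", "mean_cpm", "mean_log2_cpm", "n_present",
           "n_down", "n_up", "n_nonde", "mean_log2fc_down")
  attr(records, "totals") <- totals
  attr(records, "n_absent") <- n_absent
  attr(records, "n_unmapped") <- n_unmapped
  attr(records, "target_genes") <- target_genes
  attr(records, "de_class") <- de_class
  records
}

#' Sensitivity of the linkage correlation to filtering cutoffs
#'
#' Re-runs the whole linkage chain (high-confidence filter, gene mapping,
#' DE classification, target classification, weighted correlation) for every
#' combination of target-score cutoff and FDR cutoff, so the dependence of
#' the headline correlation on the filtering criteria is explicit. Cells
#' with too few contributing miRNAs or degenerate variance are reported as
#' `NA` with a note rather than failing the grid.
#'
#' @inheritParams build_linkage_records
#' @param score_cutoffs,fdr_cutoffs Cutoff vectors; defaults
#'   `c(80, 85, 90)` and `c(0.05, 0.10, 0.20)`.
#' @return Tibble with one row per grid cell: `score_cutoff`, `fdr_cutoff`,
#'   `r`, `p`, `n_used`, `n_down_total`, `note`.
#' @export
sensitivity_grid <- function(specific_mirnas, abundance, pred, map, de,
                             score_cutoffs = c(80, 85, 90),
                             fdr_cutoffs = c(0.05, 0.10, 0.20),
                             abs_log2fc_cutoff = NULL) {
  if (length(score_cutoffs) == 0 || length(fdr_cutoffs) == 0) {
    stop_config("cutoff lists must be non-empty")
  }
  grid <- tidyr::expand_grid(score_cutoff = score_cutoffs, fdr_cutoff = fdr_cutoffs)
  purrr::pmap_dfr(grid, function(score_cutoff, fdr_cutoff) {
    cell <- tibble(score_cutoff = score_cutoff, fdr_cutoff = fdr_cutoff,
                   r = NA_real_, p = NA_real_, n_used = NA_integer_,
                   n_down_total = NA_integer_, note = NA_character_)
    tryCatch({
      records <- build_linkage_records(specific_mirnas, abundance, pred, map, de,
                                       score_cutoff = score_cutoff,
                                       fdr_cutoff = fdr_cutoff,
                                       abs_log2fc_cutoff = abs_log2fc_cutoff)
      cell$n_down_total <- linkage_totals(records)$n_down
      fit <- abundance_repression_correlation(records)
      cell$r <- fit$estimate
      cell$p <- fit$p.value
      cell$n_used <- fit$n_used
      cell
    }, evlink_data_error = function(e) {
      cell$note <- conditionMessage(e)
      cell
    })
  })
}
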