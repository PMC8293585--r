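#' Plot a detection-threshold sweep
#'
#' Detected and group-unique miRNA counts per raw-count threshold, one line
#' per group and panel per measure.
#'
#' @param sweep Output of [detection_sweep()].
#' @return A ggplot object.
#' @export
plot_detection_sweep <- function(sweep) {
  long <- sweep %>%
    tidyr::pivot_longer(c("n_detected", "n_unique"),
                        names_to = "measure", values_to = "n") %>%
    mutate(measure = dplyr::recode(.data$measure,
                                   n_detected = "detected",
                                   n_unique = "group-unique"))
  ggplot(long, aes(x = .data$threshold, y = .data$n, colour = .data$group)) +
    geom_line() +
    geom_point() +
    facet_wrap(~measure, scales = "free_y") +
    scale_x_continuous(breaks = unique(long$threshold)) +
    labs(x = "raw count threshold", y = "miRNAs", colour = "EV source") +
    theme_minimal()
}

#' Plot per-miRNA target counts by differential-expression class
#'
#' Stacked bars of each specific miRNA's high-confidence targets present in
#' the DE table, split into downregulated, upregulated and non-DE.
#'
#' @param records Linkage records ([classify_targets()] or
#'   [build_linkage_records()] output).
#' @return A ggplot object.
#' @export
plot_target_classes <- function(records) {
  long <- records %>%
    select("mirna_id", "n_down", "n_up", "n_nonde") %>%
    tidyr::pivot_longer(-"mirna_id", names_to = "class", values_to = "n") %>%
    mutate(class = factor(dplyr::recode(.data$class, n_down = "DOWN",
                                        n_up = "UP", n_nonde = "NON_DE"),
                          levels = c("NON_DE", "UP", "DOWN")))
  ggplot(long, aes(x = stats::reorder(.data$mirna_id, .data$n, sum),
                   y = .data$n, fill = .data$class)) +
    geom_col() +
    coord_flip() +
    scale_fill_manual(values = c(DOWN = "#2c7fb8", UP = "#e6550d",
                                 NON_DE = "grey70")) +
    labs(x = NULL, y = "high-confidence targets in DE table", fill = "DE class") +
    theme_minimal()
}

#' @rdname weighted_pearson
#' @param object A `weighted_pearson` object.
#' @method autoplot weighted_pearson
#' @export
autoplot.weighted_pearson <- function(object, ...) {
  d <- object$data
  ggplot(d, aes(x = .data$x, y = .data$y)) +
    geom_smooth(method = "lm", formula = y ~ x, aes(weight = .data$w),
                colour = "grey40", linewidth = 0.6) +
    geom_point(aes(size = .data$w), alpha = 0.8) +
    labs(x = "mean log2 CPM in EV libraries",
         y = "mean log2FC of downregulated targets",
         size = "downregulated\ntargets",
         subtitle = sprintf("weighted Pearson r = %.2f, p = %.3g (n = %d)",
                            object$estimate, object$p.value, object$n_used)) +
    theme_minimal()
}

#' Plot the abundance-repression relationship for linkage records
#'
#' Scatter of mean log2 CPM against mean log2FC of downregulated targets,
#' point size proportional to the number of downregulated targets, with the
#' weighted least-squares line.
#'
#' @param records Linkage records carrying `mean_log2_cpm`,
#'   `mean_log2fc_down`, `n_down`.
#' @return A ggplot object.
#' @export
plot_abundance_repression <- function(records) {
  fit <- abundance_repression_correlation(records)
  autoplot(fit) + geom_text(data = fit$data, aes(label = .data$label),
                            vjust = -1, size = 2.7, check_overlap = TRUE)
}

#' Plot a cutoff sensitivity grid
#'
#' Tile map of the weighted correlation across target-score and FDR
#' cutoffs; undefined cells are blank.
#'
#' @param grid Output of [sensitivity_grid()].
#' @return A ggplot object.
#' @export
plot_sensitivity_grid <- function(grid) {
  ggplot(grid, aes(x = factor(.data$score_cutoff), y = factor(.data$fdr_cutoff),
                   fill = .data$r)) +
    geom_tile() +
    geom_text(aes(label = ifelse(is.na(.data$r), "n/a",
                                 sprintf("r=%.2f\np=%.3f", .data$r, .data$p))),
              size = 3) +
    scale_fill_gradient2(low = "#2c7fb8", mid = "white", high = "#e6550d",
                         midpoint = 0, na.value = "grey90", limits = c(-1, 1)) +
    labs(x = "target score cutoff", y = "FDR cutoff", fill = "weighted r") +
    theme_minimal()
}
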