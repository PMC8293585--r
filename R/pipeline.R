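#' Build and validate a pipeline run configuration
#'
#' A run either consumes four input files (`counts`, `groups`, `de`,
#' `predictions`, `gene_map`) or simulates them (`simulation` = a list of
#' [sim_config()] arguments). All thresholds are explicit here and echoed
#' verbatim into the run summary; unknown keys are rejected.
#'
#' @param counts,groups,de,predictions,gene_map Paths of the input tables
#'   (all five required unless `simulation` is given).
#' @param simulation Optional list of [sim_config()] arguments; when set,
#'   inputs are generated into `<out_dir>/inputs/` and consumed from there.
#' @param out_dir Output directory (required).
#' @param ev_group EV source group whose specific miRNAs are linked to the
#'   DE table; default: first group in the assignment.
#' @param detection_threshold,min_libraries Specificity detection rule
#'   (defaults 5 and `ceiling(2/3 * group size)`).
#' @param score_cutoff,fdr_cutoff,abs_log2fc_cutoff Linkage cutoffs
#'   (defaults 90, 0.05, none).
#' @param sweep_thresholds Detection sweep (default `c(1, 3, 5, 10)`).
#' @param score_cutoffs,fdr_cutoffs Sensitivity grid axes (defaults
#'   `c(80, 85, 90)` and `c(0.05, 0.10, 0.20)`).
#' @param multi_mirna_k Minimum miRNA count for the convergent-target table
#'   (default 3).
#' @return A list of class `evlink_run_config`.
#' @export
run_config <- function(counts = NULL, groups = NULL, de = NULL,
                       predictions = NULL, gene_map = NULL,
                       simulation = NULL, out_dir = NULL, ev_group = NULL,
                       detection_threshold = 5, min_libraries = NULL,
                       score_cutoff = 90, fdr_cutoff = 0.05,
                       abs_log2fc_cutoff = NULL,
                       sweep_thresholds = c(1, 3, 5, 10),
                       score_cutoffs = c(80, 85, 90),
                       fdr_cutoffs = c(0.05, 0.10, 0.20),
                       multi_mirna_k = 3) {
  cfg <- as.list(environment())
  if (is.null(cfg$out_dir)) stop_config("`out_dir` is required")
  if (is.null(cfg$simulation)) {
    paths <- c(counts = cfg$counts, groups = cfg$groups, de = cfg$de,
               predictions = cfg$predictions, gene_map = cfg$gene_map)
    if (length(paths) < 5) {
      stop_config("all five input paths (counts, groups, de, predictions, gene_map) are required unless `simulation` is given")
    }
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0) {
      stop_config(sprintf("input file(s) not found: %s",
                          paste(sprintf("%s (%s)", names(missing), missing),
                                collapse = ", ")))
    }
  }
  structure(cfg, class = c("evlink_run_config", "list"))
}

load_run_config <- function(config) {
  if (inherits(config, "evlink_run_config")) return(config)
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_config("`config` must be a run_config(), a list, or a YAML path")
  unknown <- setdiff(names(config), names(formals(run_config)))
  if (length(unknown) > 0) {
    stop_config(sprintf("unknown run-config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, config)
}

write_run_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Run the full EV-miRNA linkage pipeline
#'
#' Executes, in order: input loading (or simulation), specificity calling
#' and the detection sweep, abundance summarization, target linkage with
#' the weighted abundance-repression correlation, the multi-miRNA
#' convergent-target table, and the cutoff sensitivity grid. Every stage
#' output is written as TSV/JSON under `out_dir`, together with
#' `run_summary.json` carrying the full configuration, input checksums,
#' package version, per-stage record counts and persisted warnings.
#' Identical inputs and configuration yield byte-identical outputs.
#'
#' @param config A [run_config()], a plain list of its arguments, or the
#'   path of a YAML file holding them.
#' @return The run summary (list), invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- load_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  notes <- character()
  if (!is.null(cfg$simulation)) {
    sim_cfg <- do.call(sim_config, cfg$simulation)
    paths <- make_fixture(file.path(cfg$out_dir, "inputs"), sim_cfg)
    cfg$counts <- unname(paths["counts"]); cfg$groups <- unname(paths["groups"])
    cfg$de <- unname(paths["de"]); cfg$predictions <- unname(paths["predictions"])
    cfg$gene_map <- unname(paths["gene_map"])
  }
  input_paths <- c(counts = cfg$counts, groups = cfg$groups, de = cfg$de,
                   predictions = cfg$predictions, gene_map = cfg$gene_map)
  checksums <- as.list(setNames(unname(tools::md5sum(input_paths)), names(input_paths)))
  groups <- read_library_groups(cfg$groups)
  counts <- read_count_matrix(cfg$counts, groups)
  de <- read_de_table(cfg$de)
  pred <- read_predictions(cfg$predictions)
  map <- read_gene_map(cfg$gene_map)
  ev_group <- cfg$ev_group %||% groups$group[1]

  calls <- call_specific_mirnas(counts, threshold = cfg$detection_threshold,
                                min_libraries = cfg$min_libraries)
  sweep <- detection_sweep(counts, thresholds = cfg$sweep_thresholds,
                           min_libraries = cfg$min_libraries)
  readr::write_tsv(calls, file.path(cfg$out_dir, "specificity.tsv"), quote = "none")
  readr::write_tsv(sweep, file.path(cfg$out_dir, "detection_sweep.tsv"), quote = "none")

  abundance <- abundance_summary(counts, ev_group)
  specific <- calls$mirna_id[!is.na(calls$unique_to) & calls$unique_to == ev_group]
  n_specific <- vapply(unique(groups$group),
                       function(g) sum(calls$unique_to == g, na.rm = TRUE), 0L)

  linkage <- tryCatch({
    records <- build_linkage_records(specific, abundance, pred, map, de,
                                     score_cutoff = cfg$score_cutoff,
                                     fdr_cutoff = cfg$fdr_cutoff,
                                     abs_log2fc_cutoff = cfg$abs_log2fc_cutoff)
    de_class <- attr(records, "de_class")
    target_genes <- attr(records, "target_genes")
    if (attr(records, "n_unmapped") > 0) {
      notes <- c(notes, sprintf("%d prediction row(s) dropped: unmapped transcripts",
                                attr(records, "n_unmapped")))
    }
    fit <- tryCatch(abundance_repression_correlation(records),
                    evlink_data_error = function(e) e)
    proportions <- target_proportions(de_class, unique(target_genes$gene_id))
    multi <- multi_mirna_down_targets(target_genes, de_class, k = cfg$multi_mirna_k)
    grid <- sensitivity_grid(specific, abundance, pred, map, de,
                             score_cutoffs = cfg$score_cutoffs,
                             fdr_cutoffs = cfg$fdr_cutoffs,
                             abs_log2fc_cutoff = cfg$abs_log2fc_cutoff)
    list(records = records, fit = fit, proportions = proportions,
         multi = multi, grid = grid)
  }, evlink_data_error = function(e) {
    notes <<- c(notes, sprintf("linkage stage skipped: %s", conditionMessage(e)))
    NULL
  })

  if (!is.null(linkage)) {
    readr::write_tsv(linkage$records, file.path(cfg$out_dir, "linkage_records.tsv"),
                     quote = "none")
    readr::write_tsv(linkage$proportions, file.path(cfg$out_dir, "target_proportions.tsv"),
                     quote = "none")
    readr::write_tsv(linkage$multi %>%
                       mutate(mirna_ids = map_chr(.data$mirna_ids, paste, collapse = ";")),
                     file.path(cfg$out_dir, "multi_mirna_down_targets.tsv"),
                     quote = "none")
    readr::write_tsv(linkage$grid, file.path(cfg$out_dir, "sensitivity_grid.tsv"),
                     quote = "none")
    if (inherits(linkage$fit, "weighted_pearson")) {
      fit <- linkage$fit
      if (fit$n_excluded > 0) {
        notes <- c(notes, sprintf("%d miRNA(s) with no downregulated targets excluded from the correlation",
                                  fit$n_excluded))
      }
      write_run_json(list(r = fit$estimate, p = fit$p.value, t = fit$statistic,
                          df = fit$df, n_used = fit$n_used,
                          n_excluded = fit$n_excluded,
                          weights = setNames(as.list(fit$data$w), fit$data$label)),
                     file.path(cfg$out_dir, "correlation.json"))
    } else {
      notes <- c(notes, sprintf("correlation undefined: %s",
                                conditionMessage(linkage$fit)))
    }
    totals <- linkage_totals(linkage$records)
    write_run_json(c(as.list(totals),
                     list(percent_of_down = linkage$proportions$percent[linkage$proportions$class == "DOWN"],
                          percent_of_up = linkage$proportions$percent[linkage$proportions$class == "UP"],
                          percent_of_nonde = linkage$proportions$percent[linkage$proportions$class == "NON_DE"])),
                   file.path(cfg$out_dir, "target_proportions.json"))
  }

  summary <- list(
    package_version = as.character(utils::packageVersion("evlink")),
    config = cfg[setdiff(names(cfg), "out_dir")],
    input_checksums = checksums,
    ev_group = ev_group,
    n_mirnas = nrow(counts),
    n_libraries = nrow(groups),
    n_genes_de = nrow(de),
    n_predictions = nrow(pred),
    n_specific = as.list(n_specific),
    linkage_complete = !is.null(linkage) && inherits(linkage$fit, "weighted_pearson"),
    notes = notes)
  write_run_json(summary, file.path(cfg$out_dir, "run_summary.json"))
  invisible(summary)
}

#' Render a human-readable report of a completed pipeline run
#'
#' Reads the outputs written by [run_pipeline()] from `run_dir` and formats
#' a Markdown summary: the detection sweep table, the per-miRNA target-class
#' table, the weighted correlation and its sensitivity grid, and the
#' target-proportion paragraph. Purely read-only: nothing in `run_dir` is
#' modified. Missing stage outputs yield a partial report with warnings.
#'
#' @param run_dir Directory of a completed (or partial) run.
#' @return Character vector of Markdown lines, invisibly; also printed.
#' @export
report_run <- function(run_dir) {
  p <- function(...) file.path(run_dir, ...)
  lines <- c("# EV miRNA cargo linkage report", "")
  fmt_tsv <- function(path) {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    header <- paste(names(df), collapse = " | ")
    rule <- paste(rep("---", ncol(df)), collapse = " | ")
    rows <- apply(df, 1, function(r) paste(format(r, trim = TRUE), collapse = " | "))
    c(paste("|", header, "|"), paste("|", rule, "|"), paste("|", rows, "|"))
  }
  if (file.exists(p("run_summary.json"))) {
    s <- jsonlite::read_json(p("run_summary.json"))
    lines <- c(lines,
               sprintf("Specific miRNAs per group: %s.",
                       paste(sprintf("%s = %s", names(s$n_specific), unlist(s$n_specific)),
                             collapse = ", ")), "")
    if (length(s$notes) > 0) {
      lines <- c(lines, "Warnings persisted from the run:",
                 paste0("- ", unlist(s$notes)), "")
    }
  } else {
    lines <- c(lines, "WARNING: run_summary.json missing; partial report.", "")
  }
  if (file.exists(p("detection_sweep.tsv"))) {
    lines <- c(lines, "## Detection sweep", "", fmt_tsv(p("detection_sweep.tsv")), "")
  } else lines <- c(lines, "WARNING: detection sweep output missing.", "")
  if (file.exists(p("linkage_records.tsv"))) {
    lines <- c(lines, "## Per-miRNA target classes", "",
               fmt_tsv(p("linkage_records.tsv")), "")
  } else lines <- c(lines, "WARNING: linkage records missing.", "")
  if (file.exists(p("correlation.json"))) {
    fit <- jsonlite::read_json(p("correlation.json"))
    lines <- c(lines, "## Abundance-repression correlation", "",
               sprintf("Weighted Pearson r = %.3f (two-sided p = %.4g, %d contributing miRNAs, %d excluded).",
                       fit$r, fit$p, fit$n_used, fit$n_excluded), "")
  } else lines <- c(lines, "WARNING: correlation output missing.", "")
  if (file.exists(p("sensitivity_grid.tsv"))) {
    lines <- c(lines, "## Cutoff sensitivity grid", "",
               fmt_tsv(p("sensitivity_grid.tsv")), "")
  }
  if (file.exists(p("target_proportions.tsv"))) {
    pr <- readr::read_tsv(p("target_proportions.tsv"), show_col_types = FALSE,
                          progress = FALSE)
    fmt_pct <- function(cl) {
      row <- pr[pr$class == cl, ]
      sprintf("%s of %s %s genes (%s%%)", row$n_targets, row$n_genes, cl,
              format(round(row$percent, 1), nsmall = 1))
    }
    lines <- c(lines, "## Target proportions", "",
               sprintf("Putative targets constituted %s, %s, and %s.",
                       fmt_pct("DOWN"), fmt_pct("UP"), fmt_pct("NON_DE")), "")
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
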