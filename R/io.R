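#' Strip trailing version suffixes from gene or transcript identifiers
#'
#' Ensembl gene IDs and RefSeq transcript IDs are frequently exported with a
#' trailing version (`ENSG00000115966.12`, `NM_001256.4`). Predicted-target
#' tables and expression tables rarely agree on versions, so all identifiers
#' are normalized at load time by removing a final `.<digits>` suffix. The
#' operation is idempotent.
#'
#' @param ids Character vector of identifiers.
#' @return Character vector with any trailing `.<digits>` removed.
#' @export
#' @examples
#' strip_id_version(c("ENSG00000115966.12", "NM_001256.4", "ENSG00000115966"))
strip_id_version <- function(ids) {
  sub("(\\.[0-9]+)+$", "", as.character(ids))
}

tsv_cols <- function(path, col_types) {
  readr::read_tsv(path, col_types = col_types, progress = FALSE,
                  na = character(), quote = "")
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_format(sprintf("%s is missing required column(s): %s",
                        what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# ---- grouped miRNA count matrix ---------------------------------------------

normalize_groups <- function(groups) {
  if (is.data.frame(groups)) {
    require_columns(groups, c("library", "group"), "group assignment")
    out <- tibble(library = as.character(groups$library),
                  group = as.character(groups$group))
  } else if (is.character(groups) && !is.null(names(groups))) {
    out <- tibble(library = names(groups), group = unname(groups))
  } else {
    stop_config("`groups` must be a data frame with columns library/group or a named character vector")
  }
  if (anyDuplicated(out$library)) {
    stop_config("each library must be assigned to exactly one group")
  }
  out
}

#' Construct a grouped miRNA count matrix
#'
#' Bundles a wide table of raw (deduplicated) read counts per mature miRNA
#' per sequencing library with a library-to-group assignment, after strict
#' validation: counts must be non-negative integers, miRNA IDs unique, every
#' library assigned to exactly one group, and every group non-empty.
#'
#' @param counts A data frame whose first column (named `mirna_id`) holds
#'   mature miRNA identifiers and whose remaining columns are per-library
#'   raw counts.
#' @param groups Library-to-group assignment: either a data frame with
#'   columns `library` and `group`, or a named character vector
#'   (`c(L1 = "A", ...)`). Every count column must appear.
#' @return A tibble of class `mirna_counts` (columns `mirna_id` then one
#'   column per library, ordered by group) carrying the assignment in
#'   attribute `"groups"`; retrieve it with [library_groups()].
#' @export
#' @examples
#' m <- mirna_counts(
#'   data.frame(mirna_id = c("miR-1", "miR-2"),
#'              L1 = c(5L, 0L), L2 = c(6L, 0L), L3 = c(0L, 9L)),
#'   c(L1 = "A", L2 = "A", L3 = "B"))
#' library_groups(m)
mirna_counts <- function(counts, groups) {
  counts <- as_tibble(counts)
  require_columns(counts, "mirna_id", "count matrix")
  if (names(counts)[1] != "mirna_id") {
    counts <- dplyr::relocate(counts, "mirna_id")
  }
  counts$mirna_id <- as.character(counts$mirna_id)
  if (anyDuplicated(counts$mirna_id)) {
    stop_format(sprintf("duplicate miRNA identifier(s): %s",
                        paste(unique(counts$mirna_id[duplicated(counts$mirna_id)]),
                              collapse = ", ")))
  }
  groups <- normalize_groups(groups)
  libs <- setdiff(names(counts), "mirna_id")
  if (length(libs) == 0) stop_format("count matrix has no library columns")
  unassigned <- setdiff(libs, groups$library)
  if (length(unassigned) > 0) {
    stop_config(sprintf("no group assigned for library(ies): %s",
                        paste(unassigned, collapse = ", ")))
  }
  unknown <- setdiff(groups$library, libs)
  if (length(unknown) > 0) {
    stop_config(sprintf("group assignment names library(ies) absent from the matrix: %s",
                        paste(unknown, collapse = ", ")))
  }
  for (lib in libs) {
    v <- counts[[lib]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v != floor(v))) {
      stop_format(sprintf("library '%s' contains negative, missing or non-integer counts", lib))
    }
    counts[[lib]] <- as.integer(round(v))
  }
  # canonical column order: groups in order of first appearance, then library
  groups <- dplyr::arrange(groups, match(.data$group, unique(groups$group)),
                           match(.data$library, libs))
  counts <- counts[c("mirna_id", groups$library)]
  structure(counts, groups = groups,
            class = c("mirna_counts", class(tibble())))
}

#' Library-to-group assignment of a count matrix
#'
#' @param x A `mirna_counts` object.
#' @return Tibble with columns `library` and `group`.
#' @export
library_groups <- function(x) {
  g <- attr(x, "groups", exact = TRUE)
  if (is.null(g)) stop_config("`x` does not carry a library-to-group assignment; build it with mirna_counts()")
  g
}

#' @export
print.mirna_counts <- function(x, ...) {
  g <- library_groups(x)
  cat(sprintf("miRNA count matrix: %d miRNAs x %d libraries (%s)\n",
              nrow(x), nrow(g),
              paste(sprintf("%s: %d", unique(g$group),
                            table(g$group)[unique(g$group)]), collapse = ", ")))
  NextMethod()
}

count_matrix <- function(x) {
  m <- as.matrix(as.data.frame(x[setdiff(names(x), "mirna_id")]))
  rownames(m) <- x$mirna_id
  storage.mode(m) <- "integer"
  m
}

group_library_names <- function(x, group) {
  g <- library_groups(x)
  if (!group %in% g$group) {
    stop_config(sprintf("unknown group '%s'; available: %s", group,
                        paste(unique(g$group), collapse = ", ")))
  }
  g$library[g$group == group]
}

#' Read and write a grouped miRNA count matrix
#'
#' The on-disk format is a UTF-8 tab-separated file with a header row of
#' library labels and the miRNA identifier in the first column (`mirna_id`);
#' no quoting. `write_count_matrix()` emits the canonical form (columns
#' ordered by group), so `write -> read` round-trips byte-identically.
#'
#' @param path Path to a TSV file.
#' @param groups Library-to-group assignment (see [mirna_counts()]).
#' @return `read_count_matrix()` returns a validated [mirna_counts()] object;
#'   `write_count_matrix()` returns `path` invisibly.
#' @export
read_count_matrix <- function(path, groups) {
  df <- tsv_cols(path, readr::cols("mirna_id" = readr::col_character(),
                                   .default = readr::col_double()))
  mirna_counts(df, groups)
}

#' @rdname read_count_matrix
#' @param x A `mirna_counts` object.
#' @export
write_count_matrix <- function(x, path) {
  readr::write_tsv(as_tibble(as.data.frame(x)), path, quote = "none")
  invisible(path)
}

#' Read a library-to-group assignment table
#'
#' @param path TSV with columns `library` and `group`.
#' @return Tibble with columns `library`, `group`.
#' @export
read_library_groups <- function(path) {
  df <- tsv_cols(path, readr::cols(.default = readr::col_character()))
  normalize_groups(df)
}

#' @rdname read_library_groups
#' @param groups Data frame with columns `library`, `group`.
#' @export
write_library_groups <- function(groups, path) {
  readr::write_tsv(normalize_groups(groups), path, quote = "none")
  invisible(path)
}

# ---- differential-expression table ------------------------------------------

#' Read and write a gene-level differential-expression table
#'
#' Expects tab-separated columns `gene_id`, `log2fc`, `pvalue`, `fdr` (extra
#' columns are preserved but ignored downstream). Gene identifier version
#' suffixes are stripped at load; p-values and FDR must lie in \[0, 1\] and
#' log2 fold changes must be finite.
#'
#' @param path Path to a TSV file.
#' @return A tibble with at least `gene_id`, `log2fc`, `pvalue`, `fdr`.
#' @export
read_de_table <- function(path) {
  df <- tsv_cols(path, readr::cols("gene_id" = readr::col_character(),
                                   .default = readr::col_double()))
  validate_de_table(df)
}

validate_de_table <- function(df) {
  df <- as_tibble(df)
  require_columns(df, c("gene_id", "log2fc", "pvalue", "fdr"), "DE table")
  df$gene_id <- strip_id_version(df$gene_id)
  if (anyDuplicated(df$gene_id)) {
    stop_format("duplicate gene identifier(s) in DE table after version stripping")
  }
  for (col in c("pvalue", "fdr")) {
    v <- df[[col]]
    if (anyNA(v) || any(v < 0 | v > 1)) {
      stop_format(sprintf("column '%s' must lie in [0, 1] with no missing values", col))
    }
  }
  if (anyNA(df$log2fc) || any(!is.finite(df$log2fc))) {
    stop_format("column 'log2fc' must be finite with no missing values")
  }
  df
}

#' @rdname read_de_table
#' @param de A DE table (tibble).
#' @export
write_de_table <- function(de, path) {
  readr::write_tsv(validate_de_table(de), path, quote = "none")
  invisible(path)
}

# ---- target predictions and transcript-to-gene map --------------------------

#' Read and write a scored miRNA target-prediction table
#'
#' miRDB-style flat file: tab-separated columns `mirna_id`, `transcript_id`
#' (RefSeq-style), `target_score` in \[0, 100\]. Transcript version suffixes
#' are stripped at load; duplicated (miRNA, transcript) pairs are rejected.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `mirna_id`, `transcript_id`, `target_score`.
#' @export
read_predictions <- function(path) {
  df <- tsv_cols(path, readr::cols("target_score" = readr::col_double(),
                                   .default = readr::col_character()))
  validate_predictions(df)
}

validate_predictions <- function(df) {
  df <- as_tibble(df)
  require_columns(df, c("mirna_id", "transcript_id", "target_score"), "prediction table")
  df$transcript_id <- strip_id_version(df$transcript_id)
  if (anyNA(df$target_score) || any(df$target_score < 0 | df$target_score > 100)) {
    stop_format("target_score must lie in [0, 100] with no missing values")
  }
  if (anyDuplicated(df[c("mirna_id", "transcript_id")])) {
    stop_format("duplicate (mirna_id, transcript_id) pair(s) in prediction table")
  }
  df
}

#' @rdname read_predictions
#' @param pred A prediction table (tibble).
#' @export
write_predictions <- function(pred, path) {
  readr::write_tsv(validate_predictions(pred), path, quote = "none")
  invisible(path)
}

#' Read and write a transcript-to-gene identifier map
#'
#' Tab-separated columns `transcript_id`, `gene_id`; many transcripts may map
#' to one gene, but a transcript mapping to two distinct genes is a format
#' error. Version suffixes are stripped on both columns; exact duplicate rows
#' are collapsed.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `transcript_id`, `gene_id`.
#' @export
read_gene_map <- function(path) {
  df <- tsv_cols(path, readr::cols(.default = readr::col_character()))
  validate_gene_map(df)
}

validate_gene_map <- function(df) {
  df <- as_tibble(df)
  require_columns(df, c("transcript_id", "gene_id"), "transcript-to-gene map")
  df <- df %>%
    mutate(transcript_id = strip_id_version(.data$transcript_id),
           gene_id = strip_id_version(.data$gene_id)) %>%
    distinct(.data$transcript_id, .data$gene_id)
  multi <- df %>% count(.data$transcript_id) %>% filter(.data$n > 1)
  if (nrow(multi) > 0) {
    stop_format(sprintf("transcript(s) mapped to more than one gene: %s",
                        paste(head(multi$transcript_id, 5), collapse = ", ")))
  }
  df
}

#' @rdname read_gene_map
#' @param map A transcript-to-gene map (tibble).
#' @export
write_gene_map <- function(map, path) {
  readr::write_tsv(validate_gene_map(map), path, quote = "none")
  invisible(path)
}
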