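# Small fixtures and independent oracles shared across test files.

# 2-group toy matrix: rows are miRNAs, 3 libraries per group.
toy_counts <- function(rows, mirna_ids = paste0("miR-", seq_along(rows))) {
  df <- tibble::tibble(mirna_id = mirna_ids)
  m <- do.call(rbind, rows)
  colnames(m) <- c("A1", "A2", "A3", "B1", "B2", "B3")
  mirna_counts(dplyr::bind_cols(df, tibble::as_tibble(m)),
               c(A1 = "A", A2 = "A", A3 = "A", B1 = "B", B2 = "B", B3 = "B"))
}

random_counts <- function(n_mirna = 20, nlib = 3, lambda = 8) {
  m <- matrix(stats::rpois(n_mirna * 2 * nlib, lambda), nrow = n_mirna)
  colnames(m) <- c(paste0("A", seq_len(nlib)), paste0("B", seq_len(nlib)))
  groups <- stats::setNames(rep(c("A", "B"), each = nlib), colnames(m))
  mirna_counts(dplyr::bind_cols(
    tibble::tibble(mirna_id = sprintf("miR-%03d", seq_len(n_mirna))),
    tibble::as_tibble(m)), groups)
}

# Brute-force oracle: with integer weights, the weighted Pearson correlation
# equals the unweighted correlation of the dataset where point i is
# replicated w_i times.
replication_oracle_r <- function(x, y, w) {
  stopifnot(w == floor(w))
  stats::cor(rep(x, w), rep(y, w))
}

# Deterministic construction of n points whose sample correlation is exactly
# r: mix a standardized x with a standardized residual orthogonal to it.
exact_cor_data <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  e <- stats::residuals(stats::lm(stats::rnorm(n) ~ x))
  sx <- as.numeric(scale(x))
  se <- as.numeric(scale(e))
  list(x = x, y = r * sx + sqrt(1 - r^2) * se)
}
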