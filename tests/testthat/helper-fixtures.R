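# Shared fixture builders; all randomness takes an explicit seed.

# Random non-overlapping genes on one chromosome.
random_genes <- function(n, seed, min_len = 2L, max_len = 5000L) {
  set.seed(seed)
  len <- sample(min_len:max_len, n, replace = TRUE)
  gap <- sample(100:2000, n, replace = TRUE)
  start <- cumsum(gap) + cumsum(c(0L, head(len, -1)))
  gene_models(sprintf("g%05d", seq_len(n)), "chr1", start, start + len,
              sample(c("+", "-"), n, replace = TRUE))
}

# A count_matrix around a bare integer matrix, with a two-level genotype.
toy_count_matrix <- function(counts, genotype, condition = "c") {
  stopifnot(ncol(counts) == length(genotype))
  if (is.null(rownames(counts))) rownames(counts) <- paste0("r", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  structure(
    list(counts = counts, region_ids = rownames(counts), regions = NULL,
         samples = tibble::tibble(sample_id = colnames(counts),
                                  genotype = genotype, condition = condition,
                                  replicate = seq_along(genotype)),
         library_sizes = colSums(counts)),
    class = "count_matrix")
}

# Brute-force BH step-up: adj_(k) = min_{i >= k} p_(i) * n / i, capped at 1.
brute_force_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj_sorted <- rev(cummin(rev(p[o] * n / seq_len(n))))
  out <- numeric(n)
  out[o] <- pmin(adj_sorted, 1)
  out
}

# Four-parameter logistic used to generate leakage test data.
logistic4 <- function(T, bottom, top, ec50, slope) {
  bottom + (top - bottom) / (1 + 10^((ec50 - T) * slope))
}

leakage_temps <- seq(-12, 0, length.out = 9)
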