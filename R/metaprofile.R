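# Scaled-region metagene profiles.

#' Scale a per-base coverage vector to a fixed number of bins
#'
#' The region is partitioned into `n_bins` contiguous intervals of equal
#' width `length / n_bins` (fractional bases are split proportionally
#' between adjacent bins, so the mean across bins equals the mean per-base
#' coverage). For `-` strand regions the result is reversed so bin 1 is
#' always the biological 5' end.
#'
#' @param coverage Numeric per-base coverage vector (5'-to-3' in genomic
#'   orientation, i.e. left-to-right).
#' @param strand `"+"` or `"-"`.
#' @param n_bins Number of bins (default 100).
#' @return Numeric vector of length `n_bins`, bin 1 = biological 5' end.
#' @export
scale_region <- function(coverage, strand = "+", n_bins = 100L) {
  L <- length(coverage)
  if (L < 1) stop("empty coverage vector")
  stopifnot(n_bins >= 1)
  strand <- normalize_strand(strand)
  edges <- seq(0, L, length.out = n_bins + 1)
  cum <- c(0, cumsum(as.numeric(coverage)))
  # piecewise-linear cumulative coverage: F(x) for fractional x
  lo <- pmin(floor(edges), L - 1)
  fx <- cum[lo + 1] + (edges - lo) * coverage[lo + 1]
  fx[edges >= L] <- cum[L + 1]
  vals <- diff(fx) / diff(edges)
  if (strand == "-") vals <- rev(vals)
  vals
}

#' Aggregate per-gene scaled profiles into a metagene profile
#'
#' Elementwise arithmetic mean across genes.
#'
#' @param profiles A list of equal-length numeric vectors, or a matrix with
#'   one row per gene.
#' @param label Optional group label (e.g. `"hen2 / cold"`).
#' @return A `meta_profile`: list with `values`, `n_bins`, `n_genes`,
#'   `label`.
#' @export
aggregate_profiles <- function(profiles, label = NULL) {
  if (is.list(profiles)) {
    if (length(profiles) == 0) stop("no profiles to aggregate")
    nb <- unique(lengths(profiles))
    if (length(nb) != 1) stop("profiles disagree on the number of bins")
    profiles <- do.call(rbind, profiles)
  }
  if (!is.matrix(profiles) || nrow(profiles) == 0) stop("no profiles to aggregate")
  structure(list(values = colMeans(profiles), n_bins = ncol(profiles),
                 n_genes = nrow(profiles), label = label),
            class = "meta_profile")
}

#' @export
print.meta_profile <- function(x, ...) {
  cat("meta_profile", if (!is.null(x$label)) paste0(" [", x$label, "]"), ": ",
      x$n_genes, " genes, ", x$n_bins, " bins\n", sep = "")
  invisible(x)
}

#' Metagene profile for a sample group
#'
#' Sums per-base coverage over the group's samples for each gene (optionally
#' weighting each sample by `1 / size_factor`), scales each gene to
#' `n_bins`, and averages across genes.
#'
#' @param frags Fragment tibble.
#' @param genes Gene model tibble (the gene set to profile).
#' @param sample_ids Samples belonging to the group.
#' @param n_bins Number of bins (default 100).
#' @param weights Optional named per-sample weights (e.g. reciprocal size
#'   factors); default 1 for every sample.
#' @param stranded Strand handling passed to [coverage_track()].
#' @return A `meta_profile`.
#' @export
group_metaprofile <- function(frags, genes, sample_ids, n_bins = 100L,
                              weights = NULL, stranded = "yes") {
  if (nrow(genes) == 0) stop("no genes to profile")
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(sample_ids)), sample_ids)
  prof <- matrix(0, nrow = nrow(genes), ncol = n_bins)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, , drop = FALSE]
    cov <- numeric(g$end - g$start)
    for (s in sample_ids) {
      cov <- cov + weights[[s]] *
        coverage_track(frags, g, sample_id = s, stranded = stranded)
    }
    prof[i, ] <- scale_region(cov, g$strand, n_bins)
  }
  aggregate_profiles(prof, label = paste(sample_ids, collapse = "+"))
}

#' Remove genes with close neighbours
#'
#' Drops genes whose span overlaps (`max_overlap_distance = 0`) or lies
#' within `max_overlap_distance` bases of another annotated gene on either
#' strand, so neighbouring transcription cannot contaminate a metagene
#' profile.
#'
#' @param genes Gene model tibble: the candidate set.
#' @param annotation Gene model tibble: the full annotation to screen
#'   against (should include `genes`).
#' @param max_overlap_distance Maximum tolerated gap in bases (default 0 =
#'   only literal overlap removes a gene).
#' @return The retained subset of `genes`, with the removed rows in
#'   `attr(, "removed")`.
#' @export
adjacency_filter <- function(genes, annotation, max_overlap_distance = 0L) {
  if (nrow(genes) == 0) return(genes)
  q <- as_granges(genes)
  s <- as_granges(annotation)
  maxgap <- if (max_overlap_distance > 0) max_overlap_distance else -1L
  hits <- GenomicRanges::findOverlaps(q, s, maxgap = maxgap,
                                      ignore.strand = TRUE)
  same <- genes$gene_id[S4Vectors::queryHits(hits)] ==
    annotation$gene_id[S4Vectors::subjectHits(hits)]
  flagged <- unique(S4Vectors::queryHits(hits)[!same])
  kept <- genes[setdiff(seq_len(nrow(genes)), flagged), , drop = FALSE]
  attr(kept, "removed") <- genes[flagged, , drop = FALSE]
  kept
}

#' Write metagene profiles as TSV
#'
#' @param profiles A named list of `meta_profile` objects (one column per
#'   group) or a single profile.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metaprofile <- function(profiles, path) {
  if (inherits(profiles, "meta_profile")) profiles <- list(profile = profiles)
  nb <- unique(vapply(profiles, function(p) p$n_bins, numeric(1)))
  if (length(nb) != 1) stop("profiles disagree on the number of bins")
  df <- data.frame(bin = seq_len(nb),
                   lapply(profiles, function(p) p$values),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
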