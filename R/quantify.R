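# Fragment counting, per-base coverage and median-of-ratios normalization.

#' Construct a sample sheet
#'
#' @param sample_id Unique sample identifiers.
#' @param genotype Genotype labels (e.g. `"WT"`, `"hen2"`, `"exosome_core"`,
#'   `"zcchc8ab"`).
#' @param condition Condition labels (e.g. `"control_22C"`, `"cold_12h_4C"`).
#' @param replicate Positive integer replicate index;
#'   (genotype, condition, replicate) must be unique.
#' @return A tibble with one row per sample.
#' @export
sample_sheet <- function(sample_id, genotype, condition, replicate) {
  ss <- tibble::tibble(sample_id = as.character(sample_id),
                       genotype = as.character(genotype),
                       condition = as.character(condition),
                       replicate = as.integer(replicate))
  if (anyDuplicated(ss$sample_id)) stop("duplicated sample_id")
  if (any(ss$replicate < 1L)) stop("replicate must be >= 1")
  key <- paste(ss$genotype, ss$condition, ss$replicate)
  if (anyDuplicated(key)) stop("duplicated (genotype, condition, replicate)")
  ss
}

#' Read a sample sheet TSV
#'
#' Expects a header with columns `sample_id`, `genotype`, `condition`,
#' `replicate`.
#' @param path Path to the TSV file.
#' @return A sample sheet tibble.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  sample_sheet(df$sample_id, df$genotype, df$condition, df$replicate)
}

#' Construct a fragment table
#'
#' A fragment is the outer genomic span of one aligned (paired-end merged)
#' sequencing fragment, with the strand of the originating RNA.
#'
#' @param chrom,start,end 0-based half-open genomic interval per fragment.
#' @param strand RNA strand, `"+"` or `"-"`.
#' @param sample_id Sample of origin.
#' @return A tibble with one row per fragment.
#' @export
fragments <- function(chrom, start, end, strand, sample_id) {
  fr <- tibble::tibble(chrom = as.character(chrom), start = as.integer(start),
                       end = as.integer(end),
                       strand = normalize_strand(strand),
                       sample_id = as.character(sample_id))
  if (any(fr$end <= fr$start)) stop("fragment with end <= start")
  if (any(!fr$strand %in% c("+", "-"))) stop("fragment with invalid strand")
  if (any(is.na(fr$sample_id) | fr$sample_id == "")) stop("fragment without sample_id")
  fr
}

#' Read fragments from BED or TSV
#'
#' Accepts either a headered TSV with columns `chrom`, `start`, `end`,
#' `strand`, `sample_id`, or a 6-column BED in which the name column (4)
#' carries the sample identifier.
#'
#' @param path Path to the file.
#' @return A fragment tibble.
#' @export
read_fragments <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) {
    return(fragments(character(), integer(), integer(), character(), character()))
  }
  if (grepl("^chrom\t", first)) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    return(fragments(df$chrom, df$start, df$end, df$strand, df$sample_id))
  }
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  fragments(df[[1]], df[[2]], df[[3]], df[[6]], df[[4]])
}

#' Write fragments as 6-column BED
#'
#' The name column carries the sample identifier so the file round-trips
#' through [read_fragments()].
#' @param frags A fragment tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(frags, path) {
  if (nrow(frags) == 0) {
    file.create(path)
    return(invisible(path))
  }
  df <- data.frame(frags$chrom, frags$start, frags$end, frags$sample_id, ".",
                   frags$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Count fragments in regions
#'
#' FeatureCounts-style counting with a deterministic half-assignment rule:
#' a fragment is assigned to the region containing its biological 5'-most
#' base, judged on the *region's* strand (fragment start for `+` regions,
#' `end - 1` for `-` regions). A fragment straddling the midpoint of a
#' bisected gene is therefore counted in exactly one half, and
#' `count(5' half) + count(3' half) = count(whole gene)` holds for fragments
#' inside the gene. Fragments overlapping no region, failing the strand
#' filter, or on chromosomes absent from the regions are left uncounted and
#' tallied in the report attached as `attr(, "report")`.
#'
#' @param frags A fragment tibble (see [fragments()]).
#' @param regions Half regions from [bisect_genes()] or whole genes from
#'   [gene_models()]/[read_annotation()].
#' @param stranded `"yes"` (fragment strand must match the region),
#'   `"reverse"` (dUTP-style: must be opposite), or `"no"` (ignored).
#' @param samples Optional sample sheet fixing the column set and order;
#'   defaults to the sorted sample ids present in `frags`.
#' @return A `count_matrix`: list with `counts` (integer matrix regions x
#'   samples), `region_ids`, `regions`, `samples`, `library_sizes`, and a
#'   `report` attribute tallying uncounted fragments.
#' @export
count_fragments <- function(frags, regions, stranded = c("yes", "reverse", "no"),
                            samples = NULL) {
  stranded <- match.arg(stranded)
  region_ids <- if ("region_id" %in% names(regions)) regions$region_id else regions$gene_id
  if (anyDuplicated(region_ids)) stop("duplicated region identifiers")
  if (is.null(samples)) {
    samples <- tibble::tibble(sample_id = sort(unique(frags$sample_id)))
  }
  sample_ids <- samples$sample_id
  counts <- matrix(0L, nrow = length(region_ids), ncol = length(sample_ids),
                   dimnames = list(region_ids, sample_ids))
  lib <- tabulate(factor(frags$sample_id, levels = sample_ids),
                  nbins = length(sample_ids))
  names(lib) <- sample_ids
  n_unknown_sample <- sum(!frags$sample_id %in% sample_ids)

  n_strand <- 0L
  n_chrom <- 0L
  n_nohit <- 0L
  if (nrow(frags) > 0 && nrow(regions) > 0) {
    fr <- frags[frags$sample_id %in% sample_ids, , drop = FALSE]
    known_chrom <- fr$chrom %in% unique(regions$chrom)
    n_chrom <- sum(!known_chrom)
    fr <- fr[known_chrom, , drop = FALSE]
    sidx <- match(fr$sample_id, sample_ids)
    hit <- logical(nrow(fr))
    for (rs in c("+", "-")) {
      reg <- regions[regions$strand == rs, , drop = FALSE]
      if (nrow(reg) == 0) next
      keep <- switch(stranded,
                     yes = fr$strand == rs,
                     reverse = fr$strand != rs,
                     no = rep(TRUE, nrow(fr)))
      if (!any(keep)) next
      # biological 5'-most base of the fragment on this region strand
      pos <- if (rs == "+") fr$start[keep] else fr$end[keep] - 1L
      pts <- GenomicRanges::GRanges(fr$chrom[keep],
                                    IRanges::IRanges(pos + 1L, width = 1L))
      hits <- GenomicRanges::findOverlaps(pts, as_granges(reg),
                                          ignore.strand = TRUE)
      if (length(hits) > 0) {
        hit[which(keep)[S4Vectors::queryHits(hits)]] <- TRUE
        reg_row <- match(
          (if ("region_id" %in% names(reg)) reg$region_id else reg$gene_id)[
            S4Vectors::subjectHits(hits)],
          region_ids)
        samp_row <- sidx[keep][S4Vectors::queryHits(hits)]
        tab <- table(factor(reg_row, levels = seq_along(region_ids)),
                     factor(samp_row, levels = seq_along(sample_ids)))
        counts <- counts + matrix(as.integer(tab), nrow = length(region_ids))
      }
    }
    n_nohit <- sum(!hit)
  }
  cm <- structure(
    list(counts = counts, region_ids = region_ids, regions = regions,
         samples = samples, library_sizes = lib),
    class = "count_matrix")
  attr(cm, "report") <- list(n_unknown_chrom = n_chrom,
                             n_unknown_sample = n_unknown_sample,
                             n_unassigned = n_nohit)
  cm
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$counts), " regions x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("library sizes: ", paste(x$library_sizes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write / read a count matrix as TSV
#'
#' First column `region_id`, one column per sample.
#' @param cm A `count_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path) {
  df <- data.frame(region_id = cm$region_ids, cm$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @param samples Sample sheet for the read counts.
#' @export
read_counts <- function(path, samples = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$region_id
  if (is.null(samples)) samples <- tibble::tibble(sample_id = colnames(counts))
  structure(
    list(counts = counts, region_ids = df$region_id, regions = NULL,
         samples = samples, library_sizes = colSums(counts)),
    class = "count_matrix")
}

#' Per-base coverage over a region
#'
#' Position `i` of the returned vector holds the number of selected fragments
#' overlapping base `region$start + i - 1`.
#'
#' @param frags A fragment tibble.
#' @param region A single region (one-row tibble with `chrom`, `start`,
#'   `end`, `strand`).
#' @param sample_id Optional sample filter (vector of ids to include).
#' @param stranded `"no"` (default), `"yes"` or `"reverse"`, as in
#'   [count_fragments()].
#' @return Integer vector of length `region$end - region$start`.
#' @export
coverage_track <- function(frags, region, sample_id = NULL,
                           stranded = c("no", "yes", "reverse")) {
  stranded <- match.arg(stranded)
  stopifnot(nrow(region) == 1)
  w <- region$end - region$start
  keep <- frags$chrom == region$chrom &
    frags$end > region$start & frags$start < region$end
  if (!is.null(sample_id)) keep <- keep & frags$sample_id %in% sample_id
  keep <- keep & switch(stranded,
                        no = TRUE,
                        yes = frags$strand == region$strand,
                        reverse = frags$strand != region$strand)
  fr <- frags[keep, , drop = FALSE]
  delta <- integer(w + 1L)
  if (nrow(fr) > 0) {
    s <- pmax(fr$start, region$start) - region$start + 1L
    e <- pmin(fr$end, region$end) - region$start + 1L  # one past the last base
    for (i in seq_along(s)) {
      delta[s[i]] <- delta[s[i]] + 1L
      delta[e[i]] <- delta[e[i]] - 1L
    }
  }
  cumsum(delta[seq_len(w)])
}

#' Median-of-ratios size factors
#'
#' DESeq-style normalization: for each sample, the factor is the median over
#' all-positive regions of that sample's count divided by the region's
#' geometric mean across samples, then rescaled so the factors have geometric
#' mean 1. If no region has all-positive counts the function falls back to
#' library-size ratios with a warning.
#'
#' @param cm A `count_matrix` (or a bare counts matrix).
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(cm) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else cm
  if (ncol(counts) == 1) return(stats::setNames(1, colnames(counts)))
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos)) {
    warning("no region with all-positive counts; using library-size ratios")
    lib <- colSums(counts)
    if (any(lib == 0)) stop("cannot normalize: empty sample library")
    sf <- lib / exp(mean(log(lib)))
    return(stats::setNames(sf, colnames(counts)))
  }
  lk <- log(counts[allpos, , drop = FALSE])
  loggeo <- rowMeans(lk)
  sf <- exp(apply(lk - loggeo, 2, stats::median))
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

# Counts divided by their size factors.
normalized_counts <- function(cm, sf = NULL) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else cm
  if (is.null(sf)) sf <- size_factors(cm)
  sweep(counts, 2, sf, "/")
}
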