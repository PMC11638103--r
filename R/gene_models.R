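# Gene annotation handling and strand-aware 5'/3' bisection.
#
# All coordinates are 0-based half-open internally (BED convention); GFF3/GTF
# input is converted on read.

#' Construct a validated gene model table
#'
#' Builds the package's canonical gene table: one row per gene with 0-based
#' half-open genomic coordinates and a mandatory strand.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param chrom Chromosome (sequence) names.
#' @param start 0-based inclusive start coordinates.
#' @param end Exclusive end coordinates (`end > start`).
#' @param strand `"+"` or `"-"` per gene; unstranded genes are not allowed.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `length`.
#' @export
gene_models <- function(gene_id, chrom, start, end, strand) {
  gene_id <- as.character(gene_id)
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  strand <- normalize_strand(strand)
  n <- length(gene_id)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(strand) == 1L) strand <- rep(strand, n)
  stopifnot(length(chrom) == n, length(start) == n, length(end) == n,
            length(strand) == n)
  if (n > 0 && anyNA(c(start, end))) stop("gene coordinates must be finite integers")
  bad <- which(end <= start)
  if (length(bad)) {
    stop("gene(s) with end <= start: ", paste(gene_id[bad], collapse = ", "))
  }
  bad_strand <- which(!strand %in% c("+", "-"))
  if (length(bad_strand)) {
    stop("gene(s) with invalid strand: ", paste(gene_id[bad_strand], collapse = ", "))
  }
  if (anyDuplicated(gene_id)) {
    stop("duplicated gene_id: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  }
  tibble::tibble(gene_id = gene_id, chrom = chrom, start = start, end = end,
                 strand = strand, length = end - start)
}

# Accept the unicode minus sign that shows up in hand-edited files.
normalize_strand <- function(strand) {
  strand <- as.character(strand)
  strand[strand == "−"] <- "-"
  strand
}

#' Read a gene annotation file
#'
#' Reads gene features from GFF3/GTF (feature type `"gene"`) or every record
#' of a 6-column BED file, converting coordinates to the package's internal
#' 0-based half-open convention. Records without a usable strand are dropped
#' with a warning stating how many were rejected.
#'
#' @param path Path to the annotation file.
#' @param fmt One of `"gff3"`, `"gtf"`, `"bed"`.
#' @param min_length Minimum gene length in bases; shorter genes are dropped.
#' @return A gene model tibble (see [gene_models()]).
#' @export
read_annotation <- function(path, fmt = c("gff3", "gtf", "bed"), min_length = 1L) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (fmt == "bed") {
    gm <- read_bed_regions(path)
  } else {
    lines <- readLines(path, warn = FALSE)
    body <- lines[!grepl("^\\s*(#|$)", lines)]
    if (length(body) == 0) {
      return(gene_models(character(), character(), integer(), integer(), character()))
    }
    gr <- tryCatch(
      rtracklayer::import(path, format = fmt),
      error = function(e) stop("failed to parse ", fmt, " file '", path, "': ",
                               conditionMessage(e), call. = FALSE)
    )
    md <- S4Vectors::mcols(gr)
    if ("type" %in% names(md)) gr <- gr[as.character(gr$type) == "gene"]
    md <- S4Vectors::mcols(gr)
    ids <- rep(NA_character_, length(gr))
    for (field in c("ID", "gene_id", "Name", "name")) {
      if (field %in% names(md)) {
        cand <- as.character(md[[field]])
        ids[is.na(ids) & !is.na(cand)] <- cand[is.na(ids) & !is.na(cand)]
      }
    }
    missing_id <- is.na(ids)
    ids[missing_id] <- paste0(GenomicRanges::seqnames(gr), ":",
                              GenomicRanges::start(gr) - 1L)[missing_id]
    str <- as.character(GenomicRanges::strand(gr))
    unstranded <- !str %in% c("+", "-")
    if (any(unstranded)) {
      warning(sum(unstranded), " record(s) without strand rejected")
    }
    keep <- !unstranded
    gm <- gene_models(ids[keep],
                      as.character(GenomicRanges::seqnames(gr))[keep],
                      GenomicRanges::start(gr)[keep] - 1L,  # 1-based -> 0-based
                      GenomicRanges::end(gr)[keep],
                      str[keep])
  }
  gm[gm$length >= min_length, , drop = FALSE]
}

# Light 6-column BED reader with per-line validation (records the offending
# line number on error, which rtracklayer does not).
read_bed_regions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|track|browser|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    return(gene_models(character(), character(), integer(), integer(), character()))
  }
  fields <- strsplit(lines[idx], "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 6)
  if (length(bad)) {
    stop("unparsable BED line ", idx[bad[1]], " in '", path,
         "': expected >= 6 fields, got ", nf[bad[1]])
  }
  m <- t(vapply(fields, function(f) f[1:6], character(6)))
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  nonnum <- which(is.na(start) | is.na(end))
  if (length(nonnum)) {
    stop("unparsable BED line ", idx[nonnum[1]], " in '", path,
         "': non-numeric coordinates")
  }
  strand <- normalize_strand(m[, 6])
  unstranded <- !strand %in% c("+", "-")
  if (any(unstranded)) {
    warning(sum(unstranded), " record(s) without strand rejected")
  }
  keep2 <- !unstranded
  gene_models(m[keep2, 4], m[keep2, 1], start[keep2], end[keep2], strand[keep2])
}

#' Bisect genes into 5' and 3' halves
#'
#' Splits each gene at its midpoint into a TSS-proximal (`five_prime`) and a
#' PAS-proximal (`three_prime`) half. The split is strand-aware: the
#' `five_prime` half always contains the biological transcription start. For
#' odd gene lengths the extra base goes to the `five_prime` half.
#'
#' @param genes A gene model tibble (see [gene_models()]); every gene must be
#'   at least 2 bases long.
#' @return A tibble of half regions with columns `region_id`
#'   (`"<gene_id>:<half>"`), `parent_gene_id`, `half`, `chrom`, `start`,
#'   `end`, `strand`, ordered gene by gene with the `five_prime` half first.
#' @export
bisect_genes <- function(genes) {
  stopifnot(is.data.frame(genes))
  if (nrow(genes) == 0) {
    return(tibble::tibble(region_id = character(), parent_gene_id = character(),
                          half = character(), chrom = character(),
                          start = integer(), end = integer(), strand = character()))
  }
  len <- genes$end - genes$start
  short <- which(len < 2L)
  if (length(short)) {
    stop("gene too short to bisect: ", paste(genes$gene_id[short], collapse = ", "))
  }
  plus <- genes$strand == "+"
  # 5' half gets ceiling(length / 2) bases counted from the biological TSS
  five_len <- as.integer(ceiling(len / 2))
  cut <- ifelse(plus, genes$start + five_len, genes$end - five_len)
  five_start <- as.integer(ifelse(plus, genes$start, cut))
  five_end <- as.integer(ifelse(plus, cut, genes$end))
  three_start <- as.integer(ifelse(plus, cut, genes$start))
  three_end <- as.integer(ifelse(plus, genes$end, cut))
  n <- nrow(genes)
  ord <- rep(seq_len(n), each = 2)
  half <- rep(c("five_prime", "three_prime"), n)
  start <- as.integer(rbind(five_start, three_start))
  end <- as.integer(rbind(five_end, three_end))
  tibble::tibble(
    region_id = paste0(genes$gene_id[ord], ":", half),
    parent_gene_id = genes$gene_id[ord],
    half = half,
    chrom = genes$chrom[ord],
    start = start,
    end = end,
    strand = genes$strand[ord]
  )
}

#' Write regions as 6-column BED
#'
#' Writes half regions (or whole genes) as standard BED6. Half regions get
#' `name = "<parent_gene_id>:<half>"` so the file round-trips through
#' [read_annotation()] with `fmt = "bed"`.
#'
#' @param regions A half-region tibble from [bisect_genes()] or a gene model
#'   tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  if (nrow(regions) == 0) {
    file.create(path)
    return(invisible(path))
  }
  name <- if ("region_id" %in% names(regions)) {
    regions$region_id
  } else {
    regions$gene_id
  }
  df <- data.frame(regions$chrom, regions$start, regions$end, name, ".",
                   regions$strand)
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write BED file '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  invisible(path)
}

# GRanges view of a gene/region table (1-based closed, as GRanges requires).
as_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    strand = regions$strand
  )
}
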