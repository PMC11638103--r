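# Generative simulator of RNAPII elongation with a per-base premature
# termination hazard and genotype-dependent exosome degradation.
#
# One transcription event walks 5'->3' through a gene of length L and
# terminates at base x with probability h*(1-h)^(x-1); with probability
# (1-h)^L it reaches the 3' end. Prematurely terminated RNAs survive
# degradation with probability (1 - degrade_pt), full-length mRNAs with
# (1 - degrade_fl). Surviving RNAs are optionally sheared into read-length
# fragments (uniform start) for RNA-seq realism. Per-sample event counts
# carry gamma-Poisson (NB) replicate noise.

#' Construct a termination model parameter bundle
#'
#' @param lambda Expected transcription initiation events per gene per
#'   library.
#' @param hazard Per-base premature-termination probability in `[0, 1)`.
#' @param degrade_pt Probability that a prematurely terminated RNA is
#'   degraded (removed) before sampling.
#' @param degrade_fl Same for full-length mRNA.
#' @param cold_induction Multiplicative initiation modifier applied to
#'   cold-responsive genes in the cold condition (>= 0).
#' @param dispersion Gamma-Poisson overdispersion of per-gene event counts
#'   across replicates (0 = Poisson).
#' @param termination_prone If `TRUE`, genes flagged as affected get an
#'   elevated hazard under this genotype (the *hen2* elongation defect).
#' @return A `termination_model` list.
#' @export
termination_model <- function(lambda = 100, hazard = 2e-4, degrade_pt = 0.95,
                              degrade_fl = 0, cold_induction = 4,
                              dispersion = 0.05, termination_prone = FALSE) {
  stopifnot(lambda >= 0, hazard >= 0, hazard < 1,
            degrade_pt >= 0, degrade_pt <= 1,
            degrade_fl >= 0, degrade_fl <= 1,
            cold_induction >= 0, dispersion >= 0)
  structure(list(lambda = lambda, hazard = hazard, degrade_pt = degrade_pt,
                 degrade_fl = degrade_fl, cold_induction = cold_induction,
                 dispersion = dispersion, termination_prone = termination_prone),
            class = "termination_model")
}

#' Genotype presets for the termination simulator
#'
#' Parameter bundles reproducing the qualitative genotype contrasts: wild
#' type degrades prematurely terminated RNAs efficiently; *hen2* both fails
#' to degrade them (5'-end accumulation) and, at affected genes, suffers
#' elevated premature termination (3'-end depletion); core-exosome mutants
#' only fail to degrade (5'-end accumulation without 3' depletion);
#' *zcchc8a/b* carries a mild full-length-level modifier only. Magnitudes
#' are package defaults, not measured rates.
#'
#' @param lambda Baseline initiation events per gene per library.
#' @return Named list of [termination_model()] objects
#'   (`WT`, `hen2`, `exosome_core`, `zcchc8ab`).
#' @export
genotype_presets <- function(lambda = 100) {
  list(
    WT = termination_model(lambda = lambda, degrade_pt = 0.95),
    hen2 = termination_model(lambda = lambda, degrade_pt = 0.2,
                             termination_prone = TRUE),
    exosome_core = termination_model(lambda = lambda, degrade_pt = 0.2),
    zcchc8ab = termination_model(lambda = lambda, degrade_pt = 0.95,
                                 degrade_fl = 0.3)
  )
}

# Hazard giving a `effect`-fold drop in full-length yield relative to h0:
# (1 - h')^L = (1 - h0)^L / effect.
elevated_hazard <- function(h0, gene_length, effect) {
  1 - (1 - h0) * effect^(-1 / gene_length)
}

#' Closed-form expectations of the termination model
#'
#' Analytic companion to the sampler (unsheared RNAs). A premature event
#' terminating at base `x` (probability `h (1-h)^(x-1)`) survives with
#' probability `1 - degrade_pt` and contributes a fragment `[0, x)`; a
#' full-length event (probability `(1-h)^L`) survives with `1 - degrade_fl`
#' and contributes `[0, L)`. Under 5'-most-base half assignment every
#' surviving unsheared fragment lands in the 5' half, so `e3 = 0`; the
#' per-base expected coverage and the coverage-proportional half
#' expectations are returned alongside.
#'
#' @param model A [termination_model()].
#' @param gene_length Gene length `L` in bases.
#' @param midpoint Half boundary `m` (default `ceiling(L / 2)`), with the 5'
#'   half spanning bases `1..m` in biological orientation.
#' @param hazard Optional hazard override (e.g. an elevated affected-gene
#'   hazard).
#' @return List with `e5`, `e3` (expected 5'-base-assigned half counts),
#'   `coverage` (expected per-base coverage, 5'-to-3'), and `e5_cov`,
#'   `e3_cov` (expected half coverage sums).
#' @export
expected_half_counts <- function(model, gene_length,
                                 midpoint = ceiling(gene_length / 2),
                                 hazard = NULL) {
  stopifnot(inherits(model, "termination_model"),
            gene_length >= 2, midpoint > 0, midpoint < gene_length)
  h <- if (is.null(hazard)) model$hazard else hazard
  stopifnot(h >= 0, h < 1)
  lam <- model$lambda
  spt <- 1 - model$degrade_pt
  sfl <- 1 - model$degrade_fl
  x <- 0:(gene_length - 1)
  surv <- (1 - h)^x            # P(event still elongating at base x)
  survL <- (1 - h)^gene_length # P(full length)
  coverage <- lam * (spt * (surv - survL) + sfl * survL)
  e5 <- lam * (spt * (1 - survL) + sfl * survL)
  list(e5 = e5, e3 = 0,
       coverage = coverage,
       e5_cov = sum(coverage[1:midpoint]),
       e3_cov = sum(coverage[(midpoint + 1):gene_length]))
}

#' Estimate the termination hazard from a coverage decay
#'
#' For unsheared coverage with no degradation the expected coverage decays
#' as `lambda * (1-h)^x`; the hazard is recovered from the slope of a
#' log-linear least-squares fit over positive-coverage positions.
#'
#' @param coverage Per-base coverage vector in biological 5'-to-3'
#'   orientation.
#' @return Estimated per-base hazard.
#' @export
estimate_hazard <- function(coverage) {
  x <- seq_along(coverage) - 1
  pos <- coverage > 0
  if (sum(pos) < 2) stop("not enough positive coverage to fit a decay")
  fit <- stats::lm(log(coverage[pos]) ~ x[pos])
  1 - exp(unname(stats::coef(fit)[2]))
}

#' Sample a fragment library from the termination model
#'
#' Draws per-gene, per-sample event counts from a gamma-Poisson, runs each
#' event through the termination hazard and degradation, and converts
#' surviving RNAs to genomic fragments. All randomness derives from `seed`
#' with deterministic per-sample substreams.
#'
#' @param models Named list of [termination_model()] objects keyed by
#'   genotype; every genotype in `samples` must be present.
#' @param genes Gene model tibble.
#' @param samples Sample sheet (see [sample_sheet()]); the condition
#'   `cold_condition` triggers cold induction and cold-specific hazard
#'   elevation.
#' @param cold_induced Gene ids whose initiation is multiplied by
#'   `cold_induction` in the cold condition (default: all genes).
#' @param termination_genes Gene ids subject to the baseline premature
#'   termination hazard (default: all genes). Genes outside the set have
#'   zero hazard and yield only full-length mRNA, mirroring that most genes
#'   show no isoform effect in any genotype.
#' @param affected_cold Gene ids with cold-specific elevated termination in
#'   `termination_prone` genotypes.
#' @param affected_always Gene ids with constitutively elevated termination
#'   in `termination_prone` genotypes.
#' @param effect Fold reduction in full-length yield for affected genes.
#' @param seed Integer seed.
#' @param shear If `TRUE` (default), each surviving RNA is sheared to one
#'   read-length fragment with uniform start within the RNA; if `FALSE`
#'   the fragment is the full RNA span.
#' @param read_length Sheared fragment length in bases (default 100).
#' @param cold_condition Condition label treated as cold.
#' @return List with `fragments` (fragment tibble) and `truth` (tibble
#'   `gene_id`, `cold_induced`, `termination_prone`, `affected_cold`,
#'   `affected_always`).
#' @export
sample_library <- function(models, genes, samples,
                           cold_induced = genes$gene_id,
                           termination_genes = genes$gene_id,
                           affected_cold = character(),
                           affected_always = character(),
                           effect = 4, seed = 1, shear = TRUE,
                           read_length = 100L,
                           cold_condition = "cold_12h_4C") {
  stopifnot(all(samples$genotype %in% names(models)))
  truth <- tibble::tibble(
    gene_id = genes$gene_id,
    cold_induced = genes$gene_id %in% cold_induced,
    termination_prone = genes$gene_id %in% termination_genes,
    affected_cold = genes$gene_id %in% affected_cold,
    affected_always = genes$gene_id %in% affected_always
  )
  out <- vector("list", nrow(samples))
  for (j in seq_len(nrow(samples))) {
    set.seed((as.integer(seed) + 7919L * j) %% 2147483647L)
    s <- samples[j, ]
    mod <- models[[s$genotype]]
    cold <- s$condition == cold_condition
    if (nrow(genes) == 0 || mod$lambda == 0) next
    lam <- rep(mod$lambda, nrow(genes))
    if (cold) lam[truth$cold_induced] <- lam[truth$cold_induced] * mod$cold_induction
    h <- ifelse(truth$termination_prone, mod$hazard, 0)
    if (mod$termination_prone) {
      hot <- truth$affected_always | (cold & truth$affected_cold)
      h[hot] <- elevated_hazard(h[hot], genes$length[hot], effect)
    }
    n_events <- if (mod$dispersion > 0) {
      stats::rnbinom(nrow(genes), mu = lam, size = 1 / mod$dispersion)
    } else {
      stats::rpois(nrow(genes), lam)
    }
    if (sum(n_events) == 0) next
    gi <- rep(seq_len(nrow(genes)), n_events)
    L <- genes$length[gi]
    hz <- h[gi]
    # termination base (1-indexed); > L means full length
    x <- ifelse(hz > 0, stats::rgeom(length(gi), pmax(hz, 1e-12)) + 1L, L + 1L)
    full <- x > L
    len <- ifelse(full, L, x)
    p_surv <- ifelse(full, 1 - models[[s$genotype]]$degrade_fl,
                     1 - models[[s$genotype]]$degrade_pt)
    keep <- stats::runif(length(gi)) < p_surv
    gi <- gi[keep]; len <- len[keep]
    if (length(gi) == 0) next
    if (shear) {
      flen <- pmin(read_length, len)
      off <- floor(stats::runif(length(gi)) * (len - flen + 1))
      rna_start <- off
      rna_end <- off + flen
    } else {
      rna_start <- rep(0, length(gi))
      rna_end <- len
    }
    plus <- genes$strand[gi] == "+"
    gstart <- ifelse(plus, genes$start[gi] + rna_start, genes$end[gi] - rna_end)
    gend <- ifelse(plus, genes$start[gi] + rna_end, genes$end[gi] - rna_start)
    out[[j]] <- tibble::tibble(chrom = genes$chrom[gi],
                               start = as.integer(gstart),
                               end = as.integer(gend),
                               strand = genes$strand[gi],
                               sample_id = s$sample_id)
  }
  frs <- out[!vapply(out, is.null, logical(1))]
  frag <- if (length(frs)) do.call(rbind, frs) else
    fragments(character(), integer(), integer(), character(), character())
  list(fragments = frag, truth = truth)
}

#' Build a full synthetic benchmark dataset
#'
#' Generates an annotation of long, variable-length genes, a WT-vs-*hen2*
#' sample sheet (two conditions, `n_replicates` each), a simulated fragment
#' library, and a truth table marking the genes that carry cold-specific
#' (and optionally constitutive) 3'-end depletion in *hen2*. All true
#' positives are cold-induced so the wild-type cross-reference step can be
#' exercised; 30% of the remaining genes are cold-induced background.
#'
#' @param n_genes Number of genes.
#' @param n_true_positive Genes with cold-specific elevated termination in
#'   *hen2*.
#' @param n_constitutive Genes with constitutively elevated termination.
#' @param background_termination_frac Fraction of the unaffected genes that
#'   carry the baseline termination hazard (and hence 5'-fragment
#'   accumulation in degradation-impaired genotypes) without any
#'   genotype-specific elevation (default 0.2).
#' @param effect Fold reduction in full-length yield at affected genes.
#' @param n_replicates Replicates per genotype x condition.
#' @param lambda Baseline initiation events per gene per library.
#' @param seed Integer seed.
#' @param outdir Optional directory; when given, writes `genes.gff3`,
#'   `fragments.bed`, `samples.tsv`, `truth.tsv`.
#' @return List with `genes`, `samples`, `fragments`, `truth`, and `paths`
#'   (when `outdir` is given).
#' @export
make_benchmark <- function(n_genes = 600, n_true_positive = 60,
                           n_constitutive = 0,
                           background_termination_frac = 0.2,
                           effect = 4, n_replicates = 3,
                           lambda = 100, seed = 1, outdir = NULL) {
  stopifnot(n_true_positive + n_constitutive <= n_genes)
  set.seed(as.integer(seed) %% 2147483647L)
  if (n_genes > 0) {
    len <- pmax(600L, as.integer(round(stats::rlnorm(n_genes, log(2200), 0.4))))
    gap <- 2000L
    start <- cumsum(c(0L, utils::head(len, -1) + gap))
    genes <- gene_models(sprintf("g%04d", seq_len(n_genes)), "chr1", start,
                         start + len,
                         sample(c("+", "-"), n_genes, replace = TRUE))
  } else {
    genes <- gene_models(character(), character(), integer(), integer(), character())
  }
  flagged <- sample(genes$gene_id, n_true_positive + n_constitutive)
  tp <- flagged[seq_len(n_true_positive)]
  constit <- setdiff(flagged, tp)
  rest <- setdiff(genes$gene_id, flagged)
  cold_ind <- c(tp, constit, sample(rest, round(0.3 * length(rest))))
  term_genes <- c(flagged,
                  sample(rest, round(background_termination_frac * length(rest))))
  samples <- sample_sheet(
    sample_id = paste0(rep(c("WT", "hen2"), each = 2 * n_replicates), "_",
                       rep(rep(c("ctrl", "cold"), each = n_replicates), 2), "_",
                       rep(seq_len(n_replicates), 4)),
    genotype = rep(c("WT", "hen2"), each = 2 * n_replicates),
    condition = rep(rep(c("control_22C", "cold_12h_4C"), each = n_replicates), 2),
    replicate = rep(seq_len(n_replicates), 4)
  )
  sim <- sample_library(genotype_presets(lambda = lambda), genes, samples,
                        cold_induced = cold_ind,
                        termination_genes = term_genes, affected_cold = tp,
                        affected_always = constit, effect = effect,
                        seed = as.integer(seed) + 1L)
  truth <- sim$truth
  truth$is_positive <- truth$affected_cold
  res <- list(genes = genes, samples = samples, fragments = sim$fragments,
              truth = truth)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(genes = file.path(outdir, "genes.gff3"),
                  fragments = file.path(outdir, "fragments.bed"),
                  samples = file.path(outdir, "samples.tsv"),
                  truth = file.path(outdir, "truth.tsv"))
    write_gff3(genes, paths$genes)
    write_fragments(sim$fragments, paths$fragments)
    utils::write.table(samples, paths$samples, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    res$paths <- paths
  }
  res
}

#' Write gene models as GFF3
#'
#' Minimal gene-feature GFF3 writer (1-based inclusive coordinates on
#' output); round-trips through [read_annotation()].
#' @param genes Gene model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes) > 0) {
    writeLines(sprintf("%s\tterminseq\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       genes$chrom, genes$start + 1L, genes$end, genes$strand,
                       genes$gene_id), con)
  }
  invisible(path)
}
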