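# Negative-binomial differential testing of gene halves and the
# cold-specific 3'-end depletion selection logic.

#' Specify a differential contrast
#'
#' @param genotype_test Genotype of interest (e.g. `"hen2"`).
#' @param genotype_ref Reference genotype (e.g. `"WT"`).
#' @param condition Condition within which the genotypes are compared.
#' @param alpha FDR threshold for calling a region UP/DOWN (default 0.05).
#' @param lfc_min Minimum absolute log2 fold change for a call (default 0).
#' @return A `contrast_spec` list.
#' @export
contrast_spec <- function(genotype_test, genotype_ref, condition,
                          alpha = 0.05, lfc_min = 0) {
  stopifnot(alpha > 0, alpha < 1, lfc_min >= 0)
  structure(list(genotype_test = genotype_test, genotype_ref = genotype_ref,
                 condition = condition, alpha = alpha, lfc_min = lfc_min),
            class = "contrast_spec")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment, order-preserving. Input values outside
#' `[0, 1]` are an error.
#'
#' @param pvalues Numeric vector of p-values.
#' @return Adjusted values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Estimate per-region NB dispersions
#'
#' Method-of-moments dispersion on size-factor-normalized counts, pooled
#' within groups, then shrunk toward a fitted mean-dispersion trend
#' `alpha_trend(mu) = a0 + a1 / mu` with weight `w = n / (n + 4)` on the raw
#' estimate, where `n` is the pooled residual degrees of freedom (so a
#' design with one replicate per group gets the pure trend value). Regions
#' with no data (all zero) receive the trend value.
#'
#' @param cm A `count_matrix` or bare counts matrix.
#' @param groups Factor (or vector) assigning each sample to a group;
#'   variances are computed within groups.
#' @param sf Optional size factors; computed with [size_factors()] when
#'   missing.
#' @return Named numeric vector of dispersions (one per region, >= 0).
#' @export
estimate_dispersions <- function(cm, groups, sf = NULL) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else cm
  groups <- as.factor(groups)
  stopifnot(length(groups) == ncol(counts))
  if (max(table(groups)) < 2) {
    warning("no group with >= 2 samples; dispersions are trend-only")
  }
  k <- normalized_counts(counts, sf = if (is.null(sf)) size_factors(counts) else sf)
  mu <- rowMeans(k)
  # pooled within-group variance
  ssq <- numeric(nrow(k))
  dfree <- 0
  for (g in levels(groups)) {
    cols <- which(groups == g)
    if (length(cols) < 2) next
    gm <- rowMeans(k[, cols, drop = FALSE])
    ssq <- ssq + rowSums((k[, cols, drop = FALSE] - gm)^2)
    dfree <- dfree + length(cols) - 1
  }
  s2 <- if (dfree > 0) ssq / dfree else rep(NA_real_, nrow(k))
  raw <- ifelse(mu > 0 & !is.na(s2), (s2 - mu) / mu^2, NA_real_)
  raw_pos <- pmax(raw, 0)

  trend <- fit_dispersion_trend(mu, raw)
  mu_floor <- pmax(mu, 0.5)
  alpha_trend <- trend$a0 + trend$a1 / mu_floor
  w <- dfree / (dfree + 4)
  alpha <- ifelse(is.na(raw_pos), alpha_trend,
                  w * raw_pos + (1 - w) * alpha_trend)
  alpha <- pmax(alpha, 0)
  names(alpha) <- rownames(counts)
  alpha
}

# Least-squares fit of log(alpha) ~ log(a0 + a1/mu) over regions with a
# positive raw estimate; falls back to the mean raw estimate when too few
# regions inform the trend.
fit_dispersion_trend <- function(mu, raw) {
  use <- which(!is.na(raw) & raw > 0 & mu > 0)
  if (length(use) < 3) {
    a0 <- if (length(use)) mean(raw[use]) else 0.01
    return(list(a0 = max(a0, 1e-8), a1 = 0))
  }
  x <- 1 / mu[use]
  y <- raw[use]
  start <- stats::coef(stats::lm(y ~ x))
  start <- pmax(c(start[1], start[2]), 1e-8)
  obj <- function(par) {
    a <- exp(par)
    sum((log(y) - log(a[1] + a[2] * x))^2)
  }
  opt <- stats::optim(log(start), obj, method = "Nelder-Mead",
                      control = list(maxit = 500))
  a <- exp(opt$par)
  list(a0 = a[1], a1 = a[2])
}

#' NB Wald test for a genotype contrast within one condition
#'
#' For each region the two genotype group means of normalized counts are
#' compared on the log2 scale with a pseudocount of 0.5. The standard error
#' follows from the NB variance `mu + alpha * mu^2` by the delta method, the
#' Wald statistic is referred to the standard normal, and p-values are
#' BH-adjusted across all tested regions. Calls are `UP`/`DOWN` when
#' `fdr <= alpha` and `|log2FC| >= lfc_min`, otherwise `NS`.
#'
#' @param cm A `count_matrix` whose sample sheet carries `genotype` and
#'   `condition` columns.
#' @param contrast A [contrast_spec()].
#' @param dispersions Optional per-region dispersions; estimated on the
#'   contrast's samples (grouped by genotype) when missing.
#' @param sf Optional size factors for the full matrix.
#' @return A tibble with columns `region_id`, `baseMean`, `log2FC`,
#'   `dispersion`, `pvalue`, `fdr`, `call`.
#' @export
nb_wald_test <- function(cm, contrast, dispersions = NULL, sf = NULL) {
  stopifnot(inherits(contrast, "contrast_spec"))
  ss <- cm$samples
  if (!all(c("genotype", "condition") %in% names(ss))) {
    stop("count matrix sample sheet lacks genotype/condition columns")
  }
  sel <- ss$condition == contrast$condition &
    ss$genotype %in% c(contrast$genotype_test, contrast$genotype_ref)
  if (sum(sel) < 2) stop("contrast needs at least 2 samples")
  counts <- cm$counts[, sel, drop = FALSE]
  ssel <- ss[sel, , drop = FALSE]
  test_cols <- ssel$genotype == contrast$genotype_test
  if (!any(test_cols) || all(test_cols)) {
    stop("both contrast genotypes must be present in condition ",
         contrast$condition)
  }
  if (is.null(sf)) sf <- size_factors(counts)
  k <- normalized_counts(counts, sf = sf[colnames(counts)])
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersions(counts, groups = ssel$genotype,
                                        sf = sf[colnames(counts)])
  }
  alpha_r <- dispersions[cm$region_ids]
  alpha_r[is.na(alpha_r)] <- 0

  nt <- sum(test_cols)
  nr <- sum(!test_cols)
  mu_t <- rowMeans(k[, test_cols, drop = FALSE])
  mu_r <- rowMeans(k[, !test_cols, drop = FALSE])
  lfc <- log2((mu_t + 0.5) / (mu_r + 0.5))
  var_t <- (mu_t + alpha_r * mu_t^2) / (nt * (mu_t + 0.5)^2)
  var_r <- (mu_r + alpha_r * mu_r^2) / (nr * (mu_r + 0.5)^2)
  se <- sqrt((var_t + var_r) / log(2)^2)
  z <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  empty <- mu_t == 0 & mu_r == 0
  p[empty] <- 1
  lfc[empty] <- 0
  fdr <- bh_fdr(p)
  call <- ifelse(fdr <= contrast$alpha & abs(lfc) >= contrast$lfc_min & lfc != 0,
                 ifelse(lfc > 0, "UP", "DOWN"), "NS")
  tibble::tibble(region_id = cm$region_ids,
                 baseMean = rowMeans(k),
                 log2FC = unname(lfc),
                 dispersion = unname(alpha_r),
                 pvalue = unname(p),
                 fdr = unname(fdr),
                 call = unname(call))
}

# Strip the half tag, keeping only 3'-half rows of a DE table.
three_prime_rows <- function(de) {
  is3p <- grepl(":three_prime$", de$region_id)
  d <- if (any(is3p)) de[is3p, , drop = FALSE] else de
  d$gene_id <- sub(":three_prime$", "", d$region_id)
  d
}

#' Select genes with condition-specific 3'-end depletion
#'
#' A gene is selected when its 3' half is called `DOWN` in the cold contrast
#' and `NS` (not differentially expressed) in the control contrast --- the
#' definition of a cold-specific 3'-end depleted gene.
#'
#' @param de_3p_cold,de_3p_control DE tables from [nb_wald_test()] over the
#'   same 3'-half regions (tables containing both halves are filtered to the
#'   3' halves automatically).
#' @return Sorted character vector of selected gene ids.
#' @export
select_3prime_specific <- function(de_3p_cold, de_3p_control) {
  cold <- three_prime_rows(de_3p_cold)
  ctrl <- three_prime_rows(de_3p_control)
  only_cold <- setdiff(cold$gene_id, ctrl$gene_id)
  only_ctrl <- setdiff(ctrl$gene_id, cold$gene_id)
  if (length(only_cold) || length(only_ctrl)) {
    stop("region sets differ between contrasts; cold-only: ",
         paste(utils::head(only_cold, 5), collapse = ", "),
         "; control-only: ", paste(utils::head(only_ctrl, 5), collapse = ", "))
  }
  ctrl_call <- ctrl$call[match(cold$gene_id, ctrl$gene_id)]
  sort(cold$gene_id[cold$call == "DOWN" & ctrl_call == "NS"])
}

#' Cross-reference selected genes against the wild-type cold response
#'
#' Labels each selected gene with its call in a whole-gene WT
#' cold-vs-control DE table and tallies the labels. Genes missing from the
#' WT table are labeled `NS` with a warning.
#'
#' @param selected Character vector of gene ids (from
#'   [select_3prime_specific()]).
#' @param de_wt_wholegene Whole-gene DE table for WT cold vs control
#'   (`region_id` = gene id).
#' @return List with `labels` (tibble `gene_id`, `wt_call`) and `counts`
#'   (named vector over `UP`, `DOWN`, `NS`).
#' @export
cross_reference_wt_response <- function(selected, de_wt_wholegene) {
  idx <- match(selected, de_wt_wholegene$region_id)
  wt_call <- de_wt_wholegene$call[idx]
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " selected gene(s) missing from the WT table; labeled NS")
    wt_call[is.na(idx)] <- "NS"
  }
  labels <- tibble::tibble(gene_id = selected, wt_call = wt_call)
  counts <- vapply(c("UP", "DOWN", "NS"), function(l) sum(wt_call == l), integer(1))
  list(labels = labels, counts = counts)
}

#' Write a DE table as TSV
#' @param de DE tibble from [nb_wald_test()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
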