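# Relative qPCR quantification (2^-ddCt) and electrolyte-leakage EC50
# comparison via a four-parameter logistic fit and an extra sum-of-squares
# F-test.

#' Construct a qPCR record
#'
#' @param ct_target Ct value (cycles) of the target amplicon.
#' @param ct_refs Numeric vector of reference-gene Ct values (>= 1);
#'   multiple references are combined by arithmetic mean of Ct, equivalent
#'   to a geometric mean of linear quantities.
#' @param sample_id,genotype,condition,target Optional metadata.
#' @return A `qpcr_record` list.
#' @export
qpcr_record <- function(ct_target, ct_refs, sample_id = NA, genotype = NA,
                        condition = NA, target = NA) {
  if (length(ct_refs) < 1 || anyNA(ct_refs)) stop("missing reference Ct")
  if (!is.finite(ct_target)) stop("missing target Ct")
  structure(list(ct_target = ct_target, ct_refs = as.numeric(ct_refs),
                 sample_id = sample_id, genotype = genotype,
                 condition = condition, target = target),
            class = "qpcr_record")
}

#' Relative expression by the 2^-ddCt method
#'
#' `dCt = Ct_target - mean(Ct_refs)` per record,
#' `ddCt = dCt(test) - dCt(reference)`, fold change `2^-ddCt`.
#'
#' @param rec_test,rec_ref [qpcr_record()]s (or lists with `ct_target` and
#'   `ct_refs`) for the sample of interest and the reference sample; both
#'   must measure the same target.
#' @return Positive fold change.
#' @export
ddct_fold_change <- function(rec_test, rec_ref) {
  for (r in list(rec_test, rec_ref)) {
    if (is.null(r$ct_refs) || length(r$ct_refs) < 1 || anyNA(r$ct_refs)) {
      stop("missing reference Ct")
    }
  }
  if (!is.null(rec_test$target) && !is.null(rec_ref$target) &&
      !is.na(rec_test$target) && !is.na(rec_ref$target) &&
      rec_test$target != rec_ref$target) {
    stop("records measure different targets")
  }
  dct_test <- rec_test$ct_target - mean(rec_test$ct_refs)
  dct_ref <- rec_ref$ct_target - mean(rec_ref$ct_refs)
  2^(-(dct_test - dct_ref))
}

#' Per-replicate fold changes from a qPCR table
#'
#' For each target x condition, the reference dCt is the mean dCt of the
#' reference genotype; every record is converted to `2^-(dCt - dCt_ref)` and
#' summarized per genotype with the SEM computed on the fold-change scale.
#'
#' @param tbl Data frame with columns `genotype`, `condition`, `target`,
#'   `ct_target`, and one or more `ct_ref*` columns.
#' @param ref_genotype Reference genotype (default `"WT"`).
#' @return Tibble with `genotype`, `condition`, `target`, `n`, `fold_change`
#'   (mean), `sem`.
#' @export
qpcr_fold_changes <- function(tbl, ref_genotype = "WT") {
  refcols <- grep("^ct_ref", names(tbl), value = TRUE)
  if (length(refcols) == 0) stop("no ct_ref columns found")
  dct <- tbl$ct_target - rowMeans(tbl[, refcols, drop = FALSE])
  key <- interaction(tbl$target, tbl$condition, drop = TRUE)
  out <- lapply(levels(key), function(k) {
    rows <- which(key == k)
    ref_rows <- rows[tbl$genotype[rows] == ref_genotype]
    if (length(ref_rows) == 0) stop("no ", ref_genotype, " records for ", k)
    ref_dct <- mean(dct[ref_rows])
    fc <- 2^(-(dct[rows] - ref_dct))
    g <- tbl$genotype[rows]
    agg <- lapply(unique(g), function(gt) {
      v <- fc[g == gt]
      tibble::tibble(genotype = gt, condition = tbl$condition[rows][1],
                     target = tbl$target[rows][1], n = length(v),
                     fold_change = mean(v),
                     sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
    })
    do.call(rbind, agg)
  })
  do.call(rbind, out)
}

#' Relative electrolyte leakage
#'
#' Conductivity after the freezing treatment divided by total conductivity
#' after killing the tissue by flash freezing.
#'
#' @param cond_initial Conductivity before the kill step.
#' @param cond_total_after_kill Total conductivity after the kill step
#'   (> 0).
#' @return Fraction in `[0, 1]` (values above 1 are clipped with a
#'   warning).
#' @export
relative_leakage <- function(cond_initial, cond_total_after_kill) {
  if (any(cond_total_after_kill <= 0)) stop("total conductivity must be positive")
  if (any(cond_initial > cond_total_after_kill)) {
    warning("initial conductivity above total; clipping to 1")
  }
  pmin(pmax(cond_initial / cond_total_after_kill, 0), 1)
}

# Four-parameter logistic on the temperature axis:
# leakage(T) = bottom + (top - bottom) / (1 + 10^((logec50 - T) * slope))
sigmoid_fun <- function(T, bottom, top, logec50, slope) {
  bottom + (top - bottom) / (1 + 10^((logec50 - T) * slope))
}

#' Fit a sigmoidal dose-response curve to leakage data
#'
#' Least-squares fit of the four-parameter logistic
#' `leakage(T) = bottom + (top - bottom) / (1 + 10^((LogEC50 - T) * slope))`
#' with a deterministic multi-start grid over LogEC50 and slope. The fit is
#' canonicalized so `bottom <= top` (the parameterization is symmetric
#' under swapping the asymptotes and negating the slope).
#'
#' @param temperature Treatment temperatures (degrees C).
#' @param leakage Relative leakage in `[0, 1]` at each temperature.
#' @return A `sigmoid_fit` list: `bottom`, `top`, `logec50`, `slope`,
#'   `rss`, `df` (`n - 4`), `fitted`, `degenerate` (flat-data flag).
#' @export
fit_sigmoid <- function(temperature, leakage) {
  stopifnot(length(temperature) == length(leakage), length(temperature) >= 5)
  o <- order(temperature)
  T <- temperature[o]; y <- leakage[o]
  if (diff(range(y)) < 1e-8) {
    return(structure(list(bottom = mean(y), top = mean(y), logec50 = NA_real_,
                          slope = NA_real_, rss = sum((y - mean(y))^2),
                          df = length(y) - 4L, fitted = rep(mean(y), length(y)),
                          degenerate = TRUE),
                     class = "sigmoid_fit"))
  }
  starts <- expand.grid(
    logec50 = stats::quantile(T, c(0.25, 0.5, 0.75), names = FALSE),
    slope = c(-2, -0.8, -0.3, 0.3, 0.8, 2)
  )
  best <- NULL
  diagnostics <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ sigmoid_fun(T, bottom, top, logec50, slope),
        start = list(bottom = min(y), top = max(y),
                     logec50 = starts$logec50[i], slope = starts$slope[i]),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(fit, "error")) { diagnostics <- conditionMessage(fit); next }
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- c(as.list(stats::coef(fit)), list(rss = rss, fitted = stats::fitted(fit)))
    }
  }
  if (is.null(best)) {
    stop("sigmoid fit failed from every start; last error: ", diagnostics)
  }
  if (best$bottom > best$top) {
    tmp <- best$bottom; best$bottom <- best$top; best$top <- tmp
    best$slope <- -best$slope
  }
  structure(list(bottom = best$bottom, top = best$top,
                 logec50 = best$logec50, slope = best$slope, rss = best$rss,
                 df = length(y) - 4L, fitted = best$fitted,
                 degenerate = abs(best$top - best$bottom) < 1e-3),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("sigmoid_fit: bottom=%.4g top=%.4g LogEC50=%.4g slope=%.4g rss=%.4g df=%d%s\n",
              x$bottom, x$top, x$logec50, x$slope, x$rss, x$df,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

# Least-squares fit of two curves with shared bottom/top/slope and either
# separate (full) or shared (null) LogEC50.
fit_two_curves <- function(T1, y1, T2, y2, shared_ec50, start) {
  T <- c(T1, T2); y <- c(y1, y2)
  g2 <- c(rep(0, length(T1)), rep(1, length(T2)))
  fit <- if (shared_ec50) {
    minpack.lm::nlsLM(
      y ~ sigmoid_fun(T, bottom, top, e, slope),
      start = list(bottom = start$bottom, top = start$top,
                   e = start$e1, slope = start$slope),
      control = minpack.lm::nls.lm.control(maxiter = 300))
  } else {
    minpack.lm::nlsLM(
      y ~ sigmoid_fun(T, bottom, top, e1 + (e2 - e1) * g2, slope),
      start = list(bottom = start$bottom, top = start$top,
                   e1 = start$e1, e2 = start$e2, slope = start$slope),
      control = minpack.lm::nls.lm.control(maxiter = 300))
  }
  list(rss = sum(stats::resid(fit)^2), coef = as.list(stats::coef(fit)))
}

#' Compare LogEC50 between two leakage curves
#'
#' Extra sum-of-squares F-test of the nested pair: the null model shares
#' every parameter between the curves (4 free parameters); the full model
#' frees LogEC50 per curve (5) while keeping `bottom`, `top` and `slope`
#' shared.
#' `F = ((RSS0 - RSS1) / (df0 - df1)) / (RSS1 / df1)` with p from
#' `F(df0 - df1, df1)`.
#'
#' @param temperature_a,leakage_a First curve.
#' @param temperature_b,leakage_b Second curve.
#' @return List with `F`, `pvalue`, `df` (numerator, denominator),
#'   `rss_full`, `rss_null`, `logec50` (per-curve estimates).
#' @export
compare_ec50_ftest <- function(temperature_a, leakage_a,
                               temperature_b, leakage_b) {
  fa <- fit_sigmoid(temperature_a, leakage_a)
  fb <- fit_sigmoid(temperature_b, leakage_b)
  start <- list(bottom = mean(c(fa$bottom, fb$bottom)),
                top = mean(c(fa$top, fb$top)),
                slope = mean(c(fa$slope, fb$slope)),
                e1 = fa$logec50, e2 = fb$logec50)
  null_fit <- fit_two_curves(temperature_a, leakage_a, temperature_b,
                             leakage_b, shared_ec50 = TRUE, start = start)
  # seed the full model from the null solution too, so RSS_full <= RSS_null
  full_fit <- fit_two_curves(temperature_a, leakage_a, temperature_b,
                             leakage_b, shared_ec50 = FALSE, start = start)
  start0 <- list(bottom = null_fit$coef$bottom, top = null_fit$coef$top,
                 slope = null_fit$coef$slope, e1 = null_fit$coef$e,
                 e2 = null_fit$coef$e)
  full_fit0 <- fit_two_curves(temperature_a, leakage_a, temperature_b,
                              leakage_b, shared_ec50 = FALSE, start = start0)
  if (full_fit0$rss < full_fit$rss) full_fit <- full_fit0
  if (full_fit$rss > null_fit$rss * (1 + 1e-8)) {
    stop("optimizer failure: full-model RSS above null-model RSS")
  }
  n <- length(leakage_a) + length(leakage_b)
  df_full <- n - 5L
  df_null <- n - 4L
  rss_full <- min(full_fit$rss, null_fit$rss)
  Fstat <- max(0, (null_fit$rss - rss_full) / (df_null - df_full) /
                 (rss_full / df_full))
  list(F = Fstat,
       pvalue = stats::pf(Fstat, df_null - df_full, df_full, lower.tail = FALSE),
       df = c(df_null - df_full, df_full),
       rss_full = rss_full, rss_null = null_fit$rss,
       logec50 = c(full_fit$coef$e1, full_fit$coef$e2))
}

#' Read a leakage table and compute relative leakage
#'
#' Expects columns `genotype`, `acclimation`, `temperature_C`,
#' `conductivity_initial`, `conductivity_total`.
#' @param path TSV file path.
#' @return Tibble with an added `leakage` column.
#' @export
read_leakage <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$leakage <- relative_leakage(df$conductivity_initial, df$conductivity_total)
  tibble::as_tibble(df[order(df$genotype, df$temperature_C), ])
}
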