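test_that("closed-form expectations honour the hazard-model limits", {
  # h = 0, no degradation: flat coverage at lambda, halves balanced
  m0 <- termination_model(lambda = 50, hazard = 0, degrade_pt = 0,
                          degrade_fl = 0, dispersion = 0)
  e0 <- expected_half_counts(m0, gene_length = 1000)
  expect_equal(e0$coverage, rep(50, 1000))
  expect_equal(e0$e5_cov, e0$e3_cov)
  expect_equal(e0$e5, 50)
  # h = 0, full-length degradation 1: nothing survives
  m1 <- termination_model(lambda = 50, hazard = 0, degrade_pt = 0,
                          degrade_fl = 1, dispersion = 0)
  expect_equal(expected_half_counts(m1, 1000)$coverage, rep(0, 1000))
  # coverage decays geometrically with the hazard
  m2 <- termination_model(lambda = 100, hazard = 1e-3, degrade_pt = 0,
                          degrade_fl = 0, dispersion = 0)
  cov <- expected_half_counts(m2, 2000)$coverage
  expect_equal(cov[1] / cov[2000], 1 / (1 - 1e-3)^1999, tolerance = 1e-9)
  expect_error(expected_half_counts(m2, 2000, midpoint = 0))
})

test_that("sampled coverage matches the closed form within Monte Carlo error", {
  mod <- termination_model(lambda = 100, hazard = 1e-3, degrade_pt = 0,
                           degrade_fl = 0, dispersion = 0, cold_induction = 1)
  genes <- gene_models(sprintf("g%02d", 1:20), "chr1", (0:19) * 3000L,
                       (0:19) * 3000L + 2000L, "+")
  ss <- sample_sheet("s1", "WT", "control_22C", 1)
  sim <- sample_library(list(WT = mod), genes, ss, seed = 7, shear = FALSE)
  exp_cov <- expected_half_counts(mod, 2000)$coverage
  probe <- round(seq(50, 1950, length.out = 10))
  emp <- vapply(seq_len(nrow(genes)), function(i)
    coverage_track(sim$fragments, genes[i, ], stranded = "yes")[probe],
    numeric(10))
  agg <- rowSums(emp)  # Poisson-distributed totals across 20 genes
  expv <- 20 * exp_cov[probe]
  expect_true(all(abs(agg - expv) <= 3 * sqrt(expv)))
})

test_that("event counts follow the gamma-Poisson and the zero limit", {
  genes <- gene_models(sprintf("g%04d", 1:1000), "chr1", (0:999) * 1500L,
                       (0:999) * 1500L + 1000L, "+")
  ss <- sample_sheet("s1", "WT", "control_22C", 1)
  m0 <- termination_model(lambda = 0)
  expect_equal(nrow(sample_library(list(WT = m0), genes, ss, seed = 1)$fragments), 0)
  # phi = 0, h = 0, no degradation: counts are Poisson(lambda)
  mp <- termination_model(lambda = 40, hazard = 0, degrade_pt = 0,
                          degrade_fl = 0, dispersion = 0, cold_induction = 1)
  sim <- sample_library(list(WT = mp), genes, ss, seed = 2, shear = FALSE)
  counts <- tabulate(factor(findInterval(sim$fragments$start, genes$start),
                            levels = seq_len(nrow(genes))), nbins = nrow(genes))
  expect_lt(abs(mean(counts) - 40), 3 * sqrt(40 / 1000))
  expect_gt(var(counts) / mean(counts), 0.8)  # Poisson: index of dispersion ~ 1
  expect_lt(var(counts) / mean(counts), 1.2)
})

test_that("genotype presets reproduce the qualitative phenotype contrasts", {
  genes <- gene_models(sprintf("g%03d", 1:200), "chr1", (0:199) * 4000L,
                       (0:199) * 4000L + 2000L, "+")
  ss <- sample_sheet(c("wt1", "h1", "x1"), c("WT", "hen2", "exosome_core"),
                     "cold_12h_4C", c(1, 1, 1))
  sim <- sample_library(genotype_presets(), genes, ss,
                        affected_cold = genes$gene_id, seed = 5)
  cm <- count_fragments(sim$fragments, bisect_genes(genes), "yes")
  k <- cm$counts
  f5 <- grepl(":five_prime$", rownames(k))
  # hen2: 5' up AND 3' down vs WT
  expect_lt(t.test(k[f5, "h1"], k[f5, "wt1"], paired = TRUE,
                   alternative = "greater")$p.value, 0.01)
  expect_lt(t.test(k[!f5, "h1"], k[!f5, "wt1"], paired = TRUE,
                   alternative = "less")$p.value, 0.01)
  # core exosome: 5' up only, 3' NOT depleted
  expect_lt(t.test(k[f5, "x1"], k[f5, "wt1"], paired = TRUE,
                   alternative = "greater")$p.value, 0.01)
  expect_gte(mean(k[!f5, "x1"]) / mean(k[!f5, "wt1"]), 0.95)
})

test_that("hazard is recoverable from the coverage decay", {
  mod <- termination_model(lambda = 150, hazard = 1e-3, degrade_pt = 0,
                           degrade_fl = 0, dispersion = 0, cold_induction = 1)
  genes <- gene_models(sprintf("g%02d", 1:20), "chr1", (0:19) * 3000L,
                       (0:19) * 3000L + 2000L, "+")
  ss <- sample_sheet("s1", "WT", "control_22C", 1)
  sim <- sample_library(list(WT = mod), genes, ss, seed = 29, shear = FALSE)
  cov <- Reduce(`+`, lapply(seq_len(20), function(i)
    coverage_track(sim$fragments, genes[i, ], stranded = "yes")))
  hhat <- estimate_hazard(cov)
  expect_lt(abs(hhat - 1e-3) / 1e-3, 0.2)
})

test_that("benchmark generation is deterministic and emits valid files", {
  d1 <- tempfile(); d2 <- tempfile()
  b1 <- make_benchmark(n_genes = 30, n_true_positive = 3, seed = 33, outdir = d1)
  b2 <- make_benchmark(n_genes = 30, n_true_positive = 3, seed = 33, outdir = d2)
  for (f in c("genes.gff3", "fragments.bed", "samples.tsv", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  back <- read_annotation(file.path(d1, "genes.gff3"), "gff3")
  expect_equal(back$gene_id, b1$genes$gene_id)
  expect_equal(back$start, b1$genes$start)
  expect_equal(back$end, b1$genes$end)
  expect_equal(nrow(read_fragments(file.path(d1, "fragments.bed"))),
               nrow(b1$fragments))
  # empty benchmark still writes valid files
  d0 <- tempfile()
  b0 <- make_benchmark(n_genes = 0, n_true_positive = 0, seed = 1, outdir = d0)
  expect_equal(nrow(read_annotation(file.path(d0, "genes.gff3"), "gff3")), 0)
  expect_equal(nrow(b0$fragments), 0)
})
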