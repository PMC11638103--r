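test_that("fragments are assigned to the half holding their biological 5' base", {
  g <- gene_models(c("gp", "gm"), "chr1", c(100L, 100L), c(200L, 200L),
                   c("+", "-"))
  h <- bisect_genes(g)
  # inside the 5' half of the + gene
  cm <- count_fragments(fragments("chr1", 110, 140, "+", "s1"),
                        h[h$parent_gene_id == "gp", ], "yes")
  expect_equal(cm$counts["gp:five_prime", "s1"], 1L)
  expect_equal(cm$counts["gp:three_prime", "s1"], 0L)
  # straddles the midpoint 150: 5'-most base 140 is in the 5' half
  cm <- count_fragments(fragments("chr1", 140, 160, "+", "s1"),
                        h[h$parent_gene_id == "gp", ], "yes")
  expect_equal(cm$counts["gp:five_prime", "s1"], 1L)
  expect_equal(cm$counts["gp:three_prime", "s1"], 0L)
  # same interval against the - gene: biological 5' base is 159, in [150,200)
  cm <- count_fragments(fragments("chr1", 140, 160, "-", "s1"),
                        h[h$parent_gene_id == "gm", ], "yes")
  expect_equal(cm$counts["gm:five_prime", "s1"], 1L)
  # antisense fragment under stranded = yes is uncounted
  cm <- count_fragments(fragments("chr1", 140, 160, "-", "s1"),
                        h[h$parent_gene_id == "gp", ], "yes")
  expect_equal(sum(cm$counts), 0L)
  expect_equal(attr(cm, "report")$n_unassigned, 1L)
  # ... and counted under stranded = reverse
  cm <- count_fragments(fragments("chr1", 140, 160, "-", "s1"),
                        h[h$parent_gene_id == "gp", ], "reverse")
  expect_equal(cm$counts["gp:five_prime", "s1"], 1L)
})

test_that("half counts conserve whole-gene counts and ignore input order", {
  b <- make_benchmark(n_genes = 40, n_true_positive = 4, seed = 61)
  h <- bisect_genes(b$genes)
  cm_h <- count_fragments(b$fragments, h, "yes", b$samples)
  cm_g <- count_fragments(b$fragments, b$genes, "yes", b$samples)
  five <- cm_h$counts[paste0(b$genes$gene_id, ":five_prime"), , drop = FALSE]
  three <- cm_h$counts[paste0(b$genes$gene_id, ":three_prime"), , drop = FALSE]
  expect_equal(unname(five + three), unname(cm_g$counts))

  set.seed(1)
  shuf <- b$fragments[sample(nrow(b$fragments)), ]
  cm_s <- count_fragments(shuf, h, "yes", b$samples)
  expect_equal(cm_s$counts, cm_h$counts)
})

test_that("fragments on unknown chromosomes are tallied, not counted", {
  g <- gene_models("g1", "chr1", 0L, 100L, "+")
  fr <- fragments(c("chr1", "chrX"), c(10, 10), c(20, 20), "+", "s1")
  cm <- count_fragments(fr, g, "yes")
  expect_equal(sum(cm$counts), 1L)
  expect_equal(attr(cm, "report")$n_unknown_chrom, 1L)
  expect_equal(unname(cm$library_sizes["s1"]), 2L)
})

test_that("coverage_track matches a brute-force per-base count", {
  reg <- gene_models("g1", "chr1", 100L, 220L, "+")
  expect_equal(coverage_track(fragments("chr1", 100, 110, "+", "s"), reg),
               c(rep(1L, 10), rep(0L, 110)))
  expect_equal(coverage_track(fragments("chr1", 1, 2, "+", "s")[0, ], reg),
               rep(0L, 120))
  # linearity: duplicated fragment doubles the track
  fr1 <- fragments("chr1", 150, 190, "+", "s")
  expect_equal(coverage_track(rbind(fr1, fr1), reg),
               2L * coverage_track(fr1, reg))

  set.seed(71)
  fr <- fragments("chr1", s <- sample(0:300, 200, TRUE), s + sample(1:80, 200, TRUE),
                  sample(c("+", "-"), 200, TRUE), "s")
  cov <- coverage_track(fr, reg)
  brute <- vapply(reg$start:(reg$end - 1L), function(b)
    sum(fr$start <= b & fr$end > b), integer(1))
  expect_equal(cov, brute)
  overlap <- pmax(0L, pmin(fr$end, reg$end) - pmax(fr$start, reg$start))
  expect_equal(sum(cov), sum(overlap))
})

test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(rpois(200, 50), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  # identical samples
  expect_equal(unname(size_factors(cbind(a = m[, 1], b = m[, 1]))), c(1, 1))
  # exact doubling
  m2 <- cbind(a = m[, 1] + 1L, b = 2L * (m[, 1] + 1L))
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)))
  # single sample
  expect_equal(unname(size_factors(m2[, 1, drop = FALSE])), 1)
  # no all-positive region falls back to library sizes
  m3 <- cbind(a = c(0L, 5L), b = c(5L, 0L))
  expect_warning(sf <- size_factors(m3), "library-size")
  expect_equal(unname(sf), c(1, 1))
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(81)
  depth <- c(1, 2, 0.5, 1.5, 1, 0.8)
  base <- matrix(rnbinom(500 * 6, mu = 100, size = 5), ncol = 6)
  m <- matrix(rpois(length(base), sweep(base, 2, depth, `*`)), ncol = 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  storage.mode(m) <- "integer"
  ours <- size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ref <- ref / exp(mean(log(ref)))  # same geometric-mean-1 convention
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("fragment and count TSV round-trips preserve data", {
  b <- make_benchmark(n_genes = 10, n_true_positive = 2, seed = 91)
  fp <- tempfile(fileext = ".bed")
  write_fragments(b$fragments, fp)
  back <- read_fragments(fp)
  expect_equal(nrow(back), nrow(b$fragments))
  expect_equal(back$start, b$fragments$start)
  expect_equal(back$sample_id, b$fragments$sample_id)

  cm <- count_fragments(b$fragments, b$genes, "yes", b$samples)
  cp <- tempfile(fileext = ".tsv")
  write_counts(cm, cp)
  cm2 <- read_counts(cp, b$samples)
  expect_equal(cm2$counts, cm$counts)
})
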