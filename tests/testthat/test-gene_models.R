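test_that("annotation readers convert every dialect to 0-based half-open", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1",
               "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=t1;Parent=g1",
               "chr2\tsrc\tgene\t51\t80\t.\t-\t.\tID=g2"), gff)
  g <- read_annotation(gff, "gff3")
  expect_equal(g$gene_id, c("g1", "g2"))
  expect_equal(g$start, c(100L, 50L))
  expect_equal(g$end, c(200L, 80L))
  expect_equal(g$strand, c("+", "-"))

  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tg1\t.\t-", bed)
  gb <- read_annotation(bed, "bed")
  expect_equal(gb$start, 100L)
  expect_equal(gb$end, 200L)
  expect_equal(gb$strand, "-")
})

test_that("empty and malformed annotation files are handled", {
  empty <- tempfile(fileext = ".bed")
  file.create(empty)
  expect_equal(nrow(read_annotation(empty, "bed")), 0)
  empty_gff <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty_gff)
  expect_equal(nrow(read_annotation(empty_gff, "gff3")), 0)

  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tg1\t.\t+", "chr1\tnotanumber"), bad)
  expect_error(read_annotation(bad, "bed"), "line 2")

  unstranded <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tg1\t.\t+", "chr1\t300\t400\tg2\t.\t."), unstranded)
  expect_warning(g <- read_annotation(unstranded, "bed"), "1 record")
  expect_equal(g$gene_id, "g1")
})

test_that("gene model invariants are enforced", {
  expect_error(gene_models("g1", "chr1", 100, 100, "+"), "end <= start")
  expect_error(gene_models("g1", "chr1", 100, 200, "*"), "invalid strand")
  expect_error(gene_models(c("g1", "g1"), "chr1", c(0, 300), c(100, 400),
                           c("+", "+")), "duplicated")
})

test_that("bisection matches the worked examples", {
  g <- gene_models(c("ga", "gb", "gc"), "chr1", c(100L, 100L, 0L),
                   c(200L, 201L, 2L), c("+", "-", "+"))
  h <- bisect_genes(g)
  ga <- h[h$parent_gene_id == "ga", ]
  expect_equal(ga$start[ga$half == "five_prime"], 100L)
  expect_equal(ga$end[ga$half == "five_prime"], 150L)
  expect_equal(ga$start[ga$half == "three_prime"], 150L)
  expect_equal(ga$end[ga$half == "three_prime"], 200L)
  # odd length on the minus strand: extra base goes to the 5' half
  gb <- h[h$parent_gene_id == "gb", ]
  expect_equal(gb$start[gb$half == "five_prime"], 150L)
  expect_equal(gb$end[gb$half == "five_prime"], 201L)
  expect_equal(gb$start[gb$half == "three_prime"], 100L)
  expect_equal(gb$end[gb$half == "three_prime"], 150L)
  gc <- h[h$parent_gene_id == "gc", ]
  expect_equal(gc$end[gc$half == "five_prime"], 1L)
  expect_error(bisect_genes(gene_models("x", "chr1", 5, 6, "+")),
               "too short")
})

test_that("halves partition the gene span on random annotations", {
  g <- random_genes(300, seed = 21)
  h <- bisect_genes(g)
  for (i in seq_len(nrow(g))) {
    hh <- h[h$parent_gene_id == g$gene_id[i], ]
    expect_equal(min(hh$start), g$start[i])
    expect_equal(max(hh$end), g$end[i])
    expect_equal(sum(hh$end - hh$start), g$length[i])
    # disjoint
    expect_true(max(hh$start) >= min(hh$end))
  }
})

test_that("bisection is strand-symmetric", {
  g <- random_genes(100, seed = 31)
  h <- bisect_genes(g)
  # reflect coordinates around an arbitrary pivot and flip strand
  pivot <- 10000000L
  gr <- gene_models(g$gene_id, g$chrom, pivot - g$end, pivot - g$start,
                    ifelse(g$strand == "+", "-", "+"))
  hr <- bisect_genes(gr)
  for (i in seq_len(nrow(g))) {
    a <- h[h$parent_gene_id == g$gene_id[i], ]
    b <- hr[hr$parent_gene_id == g$gene_id[i], ]
    for (side in c("five_prime", "three_prime")) {
      la <- a$end[a$half == side] - a$start[a$half == side]
      lb <- b$end[b$half == side] - b$start[b$half == side]
      expect_equal(la, lb)
    }
  }
})

test_that("bisection agrees with per-base brute-force TSS-distance assignment", {
  g <- random_genes(1000, seed = 41)
  h <- bisect_genes(g)
  for (i in seq_len(nrow(g))) {
    bases <- g$start[i]:(g$end[i] - 1L)
    dist <- if (g$strand[i] == "+") bases - g$start[i] else (g$end[i] - 1L) - bases
    five <- bases[dist < ceiling(g$length[i] / 2)]
    hh <- h[h$parent_gene_id == g$gene_id[i] & h$half == "five_prime", ]
    expect_equal(range(five), c(hh$start, hh$end - 1L))
  }
})

test_that("BED writing round-trips through the reader", {
  g <- random_genes(50, seed = 51)
  h <- bisect_genes(g)
  path <- tempfile(fileext = ".bed")
  write_bed(h, path)
  back <- read_annotation(path, "bed")
  expect_equal(back$gene_id, h$region_id)
  expect_equal(back$start, h$start)
  expect_equal(back$end, h$end)
  expect_equal(back$strand, h$strand)
  # empty collection writes an empty file
  p2 <- tempfile(fileext = ".bed")
  write_bed(h[0, ], p2)
  expect_equal(nrow(read_annotation(p2, "bed")), 0)
})
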