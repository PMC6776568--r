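# Interval data model, standard-format I/O, overlap and shuffle engine.

test_that("read_bed maps fields, skips non-data lines, and rejects bad coordinates", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=x", "# comment", "chr1\t100\t200\tpk1"), f)
  ps <- read_bed(f)
  expect_equal(nrow(ps), 1)
  expect_equal(ps$chrom, "chr1")
  expect_equal(ps$start, 100)
  expect_equal(ps$end, 200)
  expect_equal(ps$name, "pk1")

  writeLines(character(), f)
  expect_equal(nrow(read_bed(f)), 0)

  writeLines(c("chr1\t100\t200", "chr1\t300\t250"), f)
  expect_error(read_bed(f), "line 2")
  writeLines("chr1\tabc\t200", f)
  expect_error(read_bed(f), "line 1")
})

test_that("BED write/read round-trips a generated 1000-interval set", {
  set.seed(42)
  sizes <- test_sizes()
  ps <- peak_set(sample(names(sizes), 1000, replace = TRUE),
                 s <- floor(runif(1000, 0, 9e5)),
                 s + sample(50:5000, 1000, replace = TRUE),
                 name = sprintf("p%04d", 1:1000),
                 score = round(runif(1000), 3),
                 strand = sample(c("+", "-", "."), 1000, replace = TRUE),
                 label = "x")
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(ps, f)
  back <- read_bed(f, label = "x")
  expect_equal(as.data.frame(back), as.data.frame(ps))
})

test_that("gene table I/O enforces strand conventions and uniqueness", {
  f <- withr::local_tempfile(fileext = ".tsv")
  g <- data.frame(gene_id = c("g1", "g2"), symbol = c("Oct4", "Sox2"),
                  chrom = "chr1", strand = c("+", "-"),
                  tss = c(5000, 9000), tes = c(9000, 5000))
  write_gene_table(g, f)
  back <- read_gene_table(f)
  expect_equal(back$tss, c(5000, 9000))   # minus-strand tss > tes accepted
  expect_equal(back, g)

  g2 <- g; g2$gene_id <- c("g1", "g1")
  write_gene_table(g2, f)
  expect_error(read_gene_table(f), "duplicate")
  g3 <- g; g3$tss[1] <- 9000; g3$tes[1] <- 5000  # "+" with tss > tes
  write_gene_table(g3, f)
  expect_error(read_gene_table(f), "inconsistent")

  # round trip on 200 generated genes
  set.seed(7)
  n <- 200
  strand <- sample(c("+", "-"), n, replace = TRUE)
  a <- floor(runif(n, 0, 9e5)); b <- a + sample(1000:20000, n, replace = TRUE)
  gg <- data.frame(gene_id = sprintf("g%03d", 1:n), symbol = sprintf("S%d", 1:n),
                   chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                   strand = strand,
                   tss = ifelse(strand == "+", a, b),
                   tes = ifelse(strand == "+", b, a))
  write_gene_table(gg, f)
  expect_equal(read_gene_table(f), gg)
})

test_that("bedGraph reading computes total signal and rejects overlapping steps", {
  f <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chr1\t0\t10\t2.0", f)
  expect_equal(read_bedgraph(f)$total_signal, 20)
  writeLines(c("chr1\t0\t10\t1.0", "chr1\t20\t30\t3.0"), f)
  expect_equal(read_bedgraph(f)$total_signal, 40)
  writeLines(c("chr1\t0\t10\t1.0", "chr1\t5\t15\t1.0"), f)
  expect_error(read_bedgraph(f), "overlapping")

  # generated track: reader's total equals the construction bookkeeping
  set.seed(11)
  starts <- sort(sample(seq(0, 1e6, by = 50), 500))
  vals <- rpois(500, 5)
  df <- data.frame(chrom = "chr1", start = starts, end = starts + 40,
                   value = vals)
  tr <- coverage_track(df)
  expect_equal(tr$total_signal, sum(vals * 40))
  write_bedgraph(tr, f)
  expect_equal(read_bedgraph(f)$total_signal, sum(vals * 40))
})

test_that("overlap_pairs matches the brute-force oracle and is symmetric", {
  a <- peak_set("chr1", 100, 200)
  b <- peak_set("chr1", 150, 160)
  got <- overlap_pairs(a, b)
  expect_equal(got$overlap_bp, 10)
  expect_equal(nrow(overlap_pairs(a, peak_set("chr2", 100, 200))), 0)

  set.seed(99)
  sizes <- test_sizes(1e5)
  for (rep in 1:10) {
    a <- rand_peaks(sample(0:200, 1), sizes, 4000)
    b <- rand_peaks(sample(1:200, 1), sizes, 4000)
    mo <- sample(c(1, 1, 100), 1)
    got <- overlap_pairs(a, b, mo)
    expect_same_pairs(got, brute_pairs(a, b, mo))
    # symmetry: transpose of the swapped call
    sw <- overlap_pairs(b, a, mo)
    sw <- sw[order(sw$idx_b, sw$idx_a), ]
    expect_equal(got$idx_a, sw$idx_b)
    expect_equal(got$idx_b, sw$idx_a)
    expect_equal(got$overlap_bp, sw$overlap_bp)
  }
})

test_that("shuffle_intervals preserves lengths, is seeded, and places uniformly", {
  sizes <- chrom_sizes(c(chr1 = 500))
  a <- peak_set("chr1", 123, 623)          # length == chromosome length
  expect_equal(shuffle_intervals(a, sizes, 3)$start, 0)  # forced placement

  sizes <- test_sizes()
  a <- rand_peaks(50, sizes)
  expect_identical(shuffle_intervals(a, sizes, 5),
                   shuffle_intervals(a, sizes, 5))
  s1 <- shuffle_intervals(a, sizes, 5)
  expect_equal(sort(s1$end - s1$start), sort(a$end - a$start))
  expect_equal(s1$chrom, a$chrom)          # match_chrom default

  # an interval longer than every chromosome is rejected
  expect_error(shuffle_intervals(peak_set("chr1", 0, 2e6), sizes, 1),
               "longer")

  # uniformity: 10,000 re-placements of one 100 bp interval on a 10 kb chrom
  sizes <- chrom_sizes(c(chr1 = 10000))
  one <- peak_set("chr1", 0, 100)
  set.seed(17)
  seeds <- sample.int(1e8, 10000)
  starts <- vapply(seeds,
                   function(s) shuffle_intervals(one, sizes, s)$start,
                   numeric(1))
  expect_true(all(starts >= 0 & starts <= 9900))
  cs <- stats::chisq.test(table(cut(starts, seq(0, 9901, length.out = 21))))
  expect_gt(cs$p.value, 0.01)
})
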