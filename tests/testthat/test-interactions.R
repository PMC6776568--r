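# Promoter-capture interaction I/O, classification, anchor occupancy, reports.

mk_calls <- function(n = 4, oe_chrom = "chr1") {
  data.frame(bait_chrom = "chr1", bait_start = seq(1000, by = 10000, length.out = n),
             bait_end = seq(3000, by = 10000, length.out = n),
             bait_genes = sprintf("g%02d", seq_len(n)),
             oe_chrom = rep_len(oe_chrom, n),
             oe_start = seq(50000, by = 10000, length.out = n),
             oe_end = seq(52000, by = 10000, length.out = n),
             score = round(runif(n, 5, 15), 2), stringsAsFactors = FALSE)
}

test_that("interaction I/O round-trips and flags inter-chromosomal pairs", {
  f <- withr::local_tempfile(fileext = ".tsv")
  calls <- mk_calls(300, oe_chrom = sample(c("chr1", "chr2"), 300, TRUE))
  calls$bait_genes[1] <- "g01;g02"
  write_interactions(calls, f)
  back <- read_interactions(f)
  expect_equal(as.data.frame(back)[, names(calls)], calls)
  expect_equal(back$inter_chromosomal, calls$oe_chrom != "chr1")

  calls$bait_genes[2] <- ""
  write_interactions(calls, f)
  expect_error(read_interactions(f), "row 2")
})

test_that("interaction classes follow promoter > enhancer precedence and partition", {
  calls <- mk_calls(4)
  # promoters over other end 1; enhancers over other ends 2 (super) and 3 (active)
  prom <- peak_set("chr1", 50500, 51000, name = "gP")
  regions <- peak_set("chr1", c(60500, 70500), c(61000, 71000))
  ec <- classify_enhancers(regions, peak_set("chr1", 60400, 61100),
                           peak_set("chr1", 70600, 70700),
                           peak_set("chr1", 70600, 70700), peak_set())
  icc <- classify_interactions(calls, prom, ec)
  expect_equal(as.character(icc$calls$iclass),
               c("promoter_promoter", "promoter_enhancer",
                 "promoter_enhancer", "promoter_other"))
  expect_equal(icc$calls$enh_subclass, c(NA, "super", "active", NA))
  expect_equal(sum(icc$counts), nrow(calls))

  # an other end overlapping both a promoter and an enhancer stays P-P
  both <- mk_calls(1)
  prom2 <- peak_set("chr1", 50000, 52000)
  icc2 <- classify_interactions(both, prom2, ec0 <- classify_enhancers(
    peak_set("chr1", 50000, 52000), peak_set("chr1", 50000, 52000),
    peak_set(), peak_set(), peak_set()))
  expect_equal(as.character(icc2$calls$iclass), "promoter_promoter")
})

test_that("planted interaction classes and mediated fraction are recovered exactly", {
  b <- default_bundle()
  calls <- read_interactions(file.path(b$dir, "interactions.tsv"))
  genes <- read_gene_table(file.path(b$dir, "genes.tsv"))
  ec <- classify_enhancers(read_bed(file.path(b$dir, "enhancer_regions.bed")),
                           read_bed(file.path(b$dir, "se_regions.bed")),
                           read_bed(file.path(b$dir, "h3k27ac.bed")),
                           read_bed(file.path(b$dir, "h3k4me1.bed")),
                           read_bed(file.path(b$dir, "h3k27me3.bed")))
  icc <- classify_interactions(calls, promoter_regions(genes), ec)
  want <- b$manifest$interaction_class_counts
  expect_equal(icc$counts, unlist(want[icc$classes], use.names = FALSE))
  # per-row classes match the planted truth
  expect_equal(as.character(icc$calls$iclass),
               b$manifest$interaction_truth$iclass)

  med <- peaks_at_interactions(icc, read_bed(file.path(b$dir, "tfa_peaks.bed")))
  expect_equal(med$fraction, b$manifest$mediated_fraction)
  expect_equal(med$subset$bait_genes,
               calls$bait_genes[b$manifest$interaction_truth$mediated])
})

test_that("anchor-occupancy rules: saturation, absence, and either-anchor dominance", {
  calls <- mk_calls(5)
  genome <- peak_set("chr1", 0, 1e6)
  expect_equal(peaks_at_interactions(calls, genome)$fraction, 1.0)
  off <- peak_set("chr7", 0, 1000)
  expect_equal(peaks_at_interactions(calls, off)$fraction, 0.0)
  tf <- peak_set("chr1", c(1500, 50200), c(1600, 50300))
  for (w in c("bait", "other_end")) {
    sub_w <- peaks_at_interactions(calls, tf, w)$n_mediated
    sub_e <- peaks_at_interactions(calls, tf, "either")$n_mediated
    expect_gte(sub_e, sub_w)
  }
  expect_error(peaks_at_interactions(calls[0, ], tf), "empty")
})

test_that("second-factor enrichment recovers planted anchor fractions", {
  # identity universe gives ratio 1
  calls <- mk_calls(10)
  tf2 <- peak_set("chr1", 50100, 50300)
  enr <- factor_enrichment_in_mediated(calls, calls, tf2)
  expect_equal(enr$ratio, 1.0)
  # absent factor is degenerate, flagged
  enr0 <- factor_enrichment_in_mediated(calls, calls, peak_set("chr9", 0, 10))
  expect_true(enr0$degenerate)
  expect_true(is.na(enr0$ratio))

  # planted 80% vs 40% anchor occupancy, n = 500 interactions
  set.seed(61)
  ok <- vapply(1:100, function(r) {
    n <- 500
    base <- seq(1e5, by = 4000, length.out = n)
    calls <- data.frame(bait_chrom = "chr2", bait_start = seq(1000, by = 3000,
                                                              length.out = n),
                        bait_end = seq(2000, by = 3000, length.out = n),
                        bait_genes = sprintf("g%03d", 1:n), oe_chrom = "chr1",
                        oe_start = base, oe_end = base + 2000, score = 1,
                        stringsAsFactors = FALSE)
    mediated_rows <- sort(sample(n, 200))
    rest <- setdiff(seq_len(n), mediated_rows)
    has_tf2 <- logical(n)
    # 80% of mediated anchors carry tf2; the pooled universe sits at 40%
    has_tf2[sample(mediated_rows, round(0.8 * 200))] <- TRUE
    has_tf2[sample(rest, round(0.4 * n) - round(0.8 * 200))] <- TRUE
    tf2 <- peak_set("chr1", base[has_tf2] + 500, base[has_tf2] + 700)
    med <- calls[mediated_rows, ]
    enr <- factor_enrichment_in_mediated(calls, med, tf2)
    abs(enr$fraction_mediated - 0.8) <= 0.05 &&
      abs(enr$fraction_all - 0.4) <= 0.05 && enr$p_value < 0.01
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("gene-centric reports pass rows through with distances and TF flags", {
  calls <- mk_calls(3)
  calls$bait_genes[2] <- "g01;gX"
  icc <- classify_interactions(calls, peak_set(), classify_enhancers(
    peak_set(), peak_set(), peak_set(), peak_set(), peak_set()))
  expect_equal(nrow(gene_interactions("absent", icc)), 0)
  r <- gene_interactions("g01", icc)
  expect_equal(nrow(r), 2)                 # multi-gene bait rows included
  expect_equal(r$distance,
               abs((r$oe_start + r$oe_end) %/% 2 -
                   (r$bait_start + r$bait_end) %/% 2))

  # duplicate bait rows are not de-duplicated
  dup <- rbind(calls, calls[1, ])
  icc2 <- classify_interactions(dup, peak_set(), classify_enhancers(
    peak_set(), peak_set(), peak_set(), peak_set(), peak_set()))
  expect_equal(nrow(gene_interactions("g01", icc2)), 3)

  # inter-chromosomal distance is unbounded; TF flags mark anchors
  tc <- mk_calls(2, oe_chrom = c("chr1", "chr2"))
  icc3 <- classify_interactions(tc, peak_set(), classify_enhancers(
    peak_set(), peak_set(), peak_set(), peak_set(), peak_set()))
  r3 <- gene_interactions("g02", icc3, tf = list(A = peak_set("chr2", 60000, 63000)))
  expect_equal(r3$distance, Inf)
  expect_true(r3$tf_A)
})
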