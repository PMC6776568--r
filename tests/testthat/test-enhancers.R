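# Enhancer taxonomy, SE-to-gene mapping, stitch-and-rank SE calling.

test_that("enhancer classes are mutually exclusive with SE-list precedence", {
  regions <- peak_set("chr1", c(0, 1000, 2000, 3000, 4000) * 10,
                      c(500, 1500, 2500, 3500, 4500) * 10)
  se <- peak_set("chr1", 100, 300)
  k27ac <- peak_set("chr1", c(150, 10100), c(250, 10200))
  k4me1 <- peak_set("chr1", c(150, 10100, 20100, 30100), c(250, 10200, 20200, 30200))
  k27me3 <- peak_set("chr1", 30100, 30200)
  ec <- classify_enhancers(regions, se, k27ac, k4me1, k27me3)
  expect_equal(as.character(ec$calls$enh_class),
               c("super", "active", "intermediate", "poised", "unclassified"))
  expect_equal(sum(ec$counts), nrow(regions))   # classes partition the input
})

test_that("planted enhancer class counts are recovered exactly from the bundle", {
  b <- default_bundle()
  ec <- classify_enhancers(read_bed(file.path(b$dir, "enhancer_regions.bed")),
                           read_bed(file.path(b$dir, "se_regions.bed")),
                           read_bed(file.path(b$dir, "h3k27ac.bed")),
                           read_bed(file.path(b$dir, "h3k4me1.bed")),
                           read_bed(file.path(b$dir, "h3k27me3.bed")))
  want <- unlist(b$manifest$enhancer_class_counts[
    c("super", "active", "intermediate", "poised")], use.names = FALSE)
  expect_equal(ec$counts, c(want, 0))
})

test_that("SE-to-gene mapping picks the nearest TSS with a lexicographic tie rule", {
  # equidistant flanking TSSs: 500 bp left of the start, 500 bp right of the
  # last covered base (end - 1)
  g <- data.frame(gene_id = c("gB", "gA"), symbol = c("x", "y"),
                  chrom = "chr1", strand = "+",
                  tss = c(500, 2499), tes = c(1400, 3400))
  m <- assign_se_genes(peak_set("chr1", 1000, 2000), g)
  expect_equal(m$gene_id, "gA")            # equal distance 500 on both sides
  expect_equal(m$distance, 500)
  expect_true(m$tie)

  g2 <- data.frame(gene_id = "g1", symbol = "s", chrom = "chr1", strand = "+",
                   tss = 1500, tes = 3000)
  m2 <- assign_se_genes(peak_set("chr1", 1000, 2000), g2)
  expect_equal(m2$distance, 0)             # TSS inside the SE

  m3 <- assign_se_genes(peak_set("chr1", 1000, 2000), g2, max_distance = 10)
  expect_equal(m3$distance, 0)
  m4 <- assign_se_genes(peak_set("chr1", 5e6, 5.001e6), g2)
  expect_true(is.na(m4$gene_id))           # beyond max_distance

  # distance is invariant under coordinate mirroring of the genome
  G <- 1e6
  set.seed(14)
  ses <- rand_peaks(30, chrom_sizes(c(chr1 = G)), 5000)
  tss <- sort(sample(seq(1000, G - 1000, 997), 40))
  gg <- data.frame(gene_id = sprintf("g%02d", 1:40), symbol = "s",
                   chrom = "chr1", strand = "+", tss = tss, tes = tss + 500)
  fwd <- assign_se_genes(ses, gg, max_distance = G)
  ses_m <- peak_set("chr1", G - ses$end, G - ses$start, sort = FALSE)
  gg_m <- gg; gg_m$tss <- G - 1 - gg$tss; gg_m$tes <- gg_m$tss + 500
  rev <- assign_se_genes(ses_m, gg_m, max_distance = G)
  expect_equal(fwd$distance, rev$distance)
})

test_that("planted SE-gene assignments match the generator manifest", {
  b <- default_bundle()
  m <- assign_se_genes(read_bed(file.path(b$dir, "se_regions.bed")),
                       read_gene_table(file.path(b$dir, "genes.tsv")))
  want <- b$manifest$se_gene_map
  got <- structure(m$gene_id, names = m$name)
  expect_equal(unname(got[want$se_name]), want$gene_id)
  expect_false(any(m$tie))
})

test_that("stitching merges peaks within the gap and the tangent cutoff splits SEs", {
  # two peaks 10 kb apart stitch into one region at 12.5 kb
  tr <- coverage_track(data.frame(chrom = "chr1", start = 0, end = 1e5,
                                  value = 1))
  p <- peak_set("chr1", c(1000, 12000, 60000, 90000),
                c(2000, 13000, 61000, 91000))
  sr <- stitch_and_rank(p, tr, stitch_distance = 12500)
  expect_equal(nrow(sr$se_list) + nrow(sr$te_list), 3)

  # equal signal everywhere degenerates the ranking: zero SEs, flagged
  p_eq <- peak_set("chr1", c(1000, 30000, 60000, 90000),
                   c(2000, 31000, 61000, 91000))
  sr_eq <- stitch_and_rank(p_eq, tr, stitch_distance = 12500)
  expect_true(sr_eq$degenerate)
  expect_equal(nrow(sr_eq$se_list), 0)

  expect_error(stitch_and_rank(peak_set("chr1", 0, 100), tr), "fewer than 3")

  # 5 planted 20x clusters among 100 background peaks are recovered
  set.seed(33)
  hits <- vapply(1:20, function(r) {
    bg_start <- seq(0, 99 * 5e4, 5e4) + sample(0:1000, 100, TRUE)
    cl_base <- 5.2e6 + (0:4) * 1e5
    cl_start <- as.vector(outer(c(0, 3000, 6000), cl_base, `+`))
    peaks <- peak_set("chr1", c(bg_start, cl_start),
                      c(bg_start + 1000, cl_start + 1000))
    amp <- function(n, lam) rpois(n, lam * 10) / 10
    steps <- data.frame(chrom = "chr1",
                        start = c(bg_start, cl_start),
                        end = c(bg_start + 1000, cl_start + 1000),
                        value = c(amp(100, 1), amp(15, 20)))
    sr <- stitch_and_rank(peaks, coverage_track(steps))
    nrow(sr$se_list) == 5 &&
      all(sort(sr$se_list$start) == sort(cl_base))
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # SE/TE lists partition the stitched regions: total length conserved
  b <- default_bundle()
  tfa <- read_bed(file.path(b$dir, "tfa_peaks.bed"))
  tr2 <- read_bedgraph(file.path(b$dir, "tfa_coverage.bedGraph"))
  sr2 <- stitch_and_rank(tfa, tr2)
  st <- selink:::.stitch(tfa, 12500)
  expect_equal(sum(sr2$se_list$end - sr2$se_list$start) +
                 sum(sr2$te_list$end - sr2$te_list$start),
               sum(st$end - st$start))
})
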