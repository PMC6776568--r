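# Shared fixtures and independent oracles. The default synthetic bundle is
# generated once per test run and reused.

.fixtures <- new.env()

default_bundle <- function() {
  if (is.null(.fixtures$dir)) {
    d <- file.path(tempdir(), "selink-default-bundle")
    .fixtures$manifest <- simulate_study(sim_config(seed = 1), d)
    .fixtures$dir <- d
  }
  list(dir = .fixtures$dir, manifest = .fixtures$manifest)
}

# brute-force all-pairs overlap scan, the independent oracle for overlap_pairs
brute_pairs <- function(a, b, min_overlap = 1) {
  rows <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov >= min_overlap)
      rows[[length(rows) + 1]] <- data.frame(idx_a = i, idx_b = j,
                                             overlap_bp = ov)
  }
  if (length(rows) == 0)
    return(data.frame(idx_a = integer(), idx_b = integer(),
                      overlap_bp = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$idx_a, out$idx_b), , drop = FALSE]
}

rand_peaks <- function(n, sizes, max_width = 2000, label = "rand") {
  chrom <- sample(names(sizes), n, replace = TRUE)
  w <- sample(seq(50, max_width), n, replace = TRUE)
  start <- floor(runif(n, 0, as.numeric(sizes[chrom]) - w))
  peak_set(chrom, start, start + w, label = label, sort = FALSE)
}

test_sizes <- function(len = 1e6, n = 3)
  chrom_sizes(stats::setNames(rep(len, n), paste0("chr", seq_len(n))))

# per-base summation oracle for region signal (slow, exact)
per_base_region_sum <- function(track, region) {
  st <- track$steps[track$steps$chrom == region$chrom, , drop = FALSE]
  total <- 0
  for (pos in seq(region$start, region$end - 1)) {
    hit <- st$start <= pos & st$end > pos
    if (any(hit)) total <- total + st$value[hit][1]
  }
  total
}

# exact hypergeometric upper-tail by direct combinatorial summation
hyper_tail_oracle <- function(k, n_a, n_b, universe) {
  ks <- seq(k, min(n_a, n_b))
  sum(choose(n_b, ks) * choose(universe - n_b, n_a - ks)) / choose(universe, n_a)
}

expect_same_pairs <- function(got, want) {
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got$idx_a, want$idx_a)
  expect_equal(got$idx_b, want$idx_b)
  expect_equal(got$overlap_bp, want$overlap_bp)
}
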