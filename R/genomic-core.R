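# Interval data model and standard-format I/O. All coordinates are 0-based
# half-open (BED convention); length == end - start.

#' Construct a chromosome-size table
#'
#' @param sizes named numeric vector, chromosome name -> length in bp.
#' @return named integer vector of class `chrom_sizes`.
#' @export
chrom_sizes <- function(sizes) {
  if (is.null(names(sizes)) || any(names(sizes) == ""))
    stop("chrom_sizes: every chromosome needs a name")
  if (anyDuplicated(names(sizes)))
    stop("chrom_sizes: duplicate chromosome names")
  if (any(sizes < 1)) stop("chrom_sizes: lengths must be >= 1")
  structure(as.integer(sizes), names = names(sizes), class = "chrom_sizes")
}

#' Read a UCSC-style two-column chromosome-size file
#' @param path file with columns chrom, length.
#' @return `chrom_sizes` vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "length"),
                   colClasses = c("character", "integer"))
  chrom_sizes(structure(df$length, names = df$chrom))
}

#' @rdname read_chrom_sizes
#' @param sizes a `chrom_sizes` vector to write.
#' @export
write_chrom_sizes <- function(sizes, path) {
  write.table(data.frame(names(sizes), as.integer(sizes)), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a peak set
#'
#' A peak set is a data.frame of half-open genomic intervals with columns
#' `chrom`, `start`, `end`, `name`, `score`, `strand`, sorted by
#' (chrom, start, end) so downstream output is byte-reproducible.
#'
#' @param chrom character chromosome names.
#' @param start,end 0-based half-open coordinates, `start < end`.
#' @param name interval names (recycled "" if missing).
#' @param score optional numeric score.
#' @param strand "+", "-" or "." (default).
#' @param label free-text label for the whole set (factor or mark name).
#' @param sizes optional `chrom_sizes`; when given, intervals must fit.
#' @param sort sort by (chrom, start, end)? Default TRUE.
#' @return data.frame of class `peak_set` with attribute `label`.
#' @export
peak_set <- function(chrom = character(), start = integer(), end = integer(),
                     name = NULL, score = NULL, strand = NULL,
                     label = "", sizes = NULL, sort = TRUE) {
  n <- max(length(chrom), length(start), length(end))
  if (length(chrom) == 1) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(start) != n || length(end) != n)
    stop("peak_set: chrom/start/end lengths differ")
  start <- as.numeric(start); end <- as.numeric(end)
  if (n > 0) {
    if (any(is.na(start) | is.na(end))) stop("peak_set: NA coordinates")
    if (any(start < 0)) stop("peak_set: negative start")
    if (any(start >= end)) stop("peak_set: start >= end")
    if (!is.null(sizes)) {
      len <- sizes[chrom]
      if (any(is.na(len))) stop("peak_set: chromosome absent from sizes")
      if (any(end > len)) stop("peak_set: interval exceeds chromosome length")
    }
  }
  df <- data.frame(
    chrom = as.character(chrom),
    start = start,
    end = end,
    name = if (is.null(name)) rep("", n) else as.character(name),
    score = if (is.null(score)) rep(NA_real_, n) else as.numeric(score),
    strand = if (is.null(strand)) rep(".", n) else as.character(strand),
    stringsAsFactors = FALSE
  )
  if (sort && n > 0) df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, label = label, class = c("peak_set", "data.frame"))
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set '%s': %d intervals on %d chromosome(s)\n",
              attr(x, "label"), nrow(x), length(unique(x$chrom))))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

# internal: 1-based closed GRanges view of a 0-based half-open interval table
.as_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1, df$end))
}

#' Read a BED file into a peak set
#'
#' Track and comment (`#`) lines are skipped; coordinates are kept 0-based
#' half-open exactly as BED defines them.
#'
#' @param path BED file path.
#' @param dialect "bed3" (chrom/start/end) or "bed6" (+ name/score/strand).
#' @param label label attached to the returned set (defaults to file stem).
#' @return `peak_set`.
#' @export
read_bed <- function(path, dialect = c("bed6", "bed3"), label = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_bed: no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (is.null(label)) label <- sub("\\.bed$", "", basename(path))
  if (length(lines) == 0)
    return(peak_set(label = label))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("read_bed: fewer than 3 fields at line ", lineno[which(nf < 3)[1]])
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- is.na(start) | is.na(end) | start >= end | start != floor(start) |
    end != floor(end)
  if (any(bad))
    stop("read_bed: malformed coordinates at line ", lineno[which(bad)[1]])
  name <- score <- strand <- NULL
  if (dialect == "bed6") {
    name <- ifelse(nf >= 4, vapply(fields, function(f) if (length(f) >= 4) f[[4]] else "", ""), "")
    score <- suppressWarnings(as.numeric(
      ifelse(nf >= 5, vapply(fields, function(f) if (length(f) >= 5) f[[5]] else NA_character_, ""), NA)))
    strand <- ifelse(nf >= 6, vapply(fields, function(f) if (length(f) >= 6) f[[6]] else ".", ""), ".")
  }
  peak_set(chrom, start, end, name = name, score = score, strand = strand,
           label = label)
}

#' Write a peak set to BED
#'
#' @param peaks `peak_set`.
#' @param path output path.
#' @param dialect "bed3" or "bed6".
#' @export
write_bed <- function(peaks, path, dialect = c("bed6", "bed3")) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(peaks)
  out <- if (dialect == "bed3" || nrow(df) == 0 && dialect == "bed3") {
    df[, c("chrom", "start", "end"), drop = FALSE]
  } else {
    data.frame(df$chrom, df$start, df$end, df$name,
               ifelse(is.na(df$score), 0, df$score), df$strand)
  }
  # integer-format coordinates so round-trips are byte-identical
  out[[2]] <- sprintf("%d", as.integer(out[[2]]))
  out[[3]] <- sprintf("%d", as.integer(out[[3]]))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a tab-separated gene table
#'
#' Expected header: gene_id, symbol, chrom, strand, tss, tes. TSS/TES are
#' 0-based; for "+" genes tss < tes, for "-" genes tss > tes.
#'
#' @param path file path.
#' @return data.frame with one row per gene.
#' @export
read_gene_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = c(gene_id = "character", symbol = "character",
                                  chrom = "character", strand = "character",
                                  tss = "numeric", tes = "numeric"))
  need <- c("gene_id", "symbol", "chrom", "strand", "tss", "tes")
  if (!all(need %in% names(df)))
    stop("read_gene_table: header must contain ", paste(need, collapse = ", "))
  df <- df[, need]
  validate_genes(df)
  df
}

#' @rdname read_gene_table
#' @param genes gene table to write.
#' @export
write_gene_table <- function(genes, path) {
  out <- genes
  out$tss <- sprintf("%d", as.integer(out$tss))
  out$tes <- sprintf("%d", as.integer(out$tes))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_genes <- function(genes) {
  if (anyDuplicated(genes$gene_id))
    stop("gene table: duplicate gene_id: ",
         genes$gene_id[duplicated(genes$gene_id)][1])
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene table: strand must be '+' or '-'")
  if (any(genes$tss == genes$tes)) stop("gene table: tss == tes")
  bad <- (genes$strand == "+" & genes$tss >= genes$tes) |
    (genes$strand == "-" & genes$tss <= genes$tes)
  if (any(bad))
    stop("gene table: strand/tss/tes inconsistent for gene ",
         genes$gene_id[which(bad)[1]])
  invisible(genes)
}

#' Construct a coverage track
#'
#' A stepwise per-chromosome signal. `total_signal` (the per-million
#' normaliser) defaults to the integral of the track,
#' `sum(value * (end - start))`.
#'
#' @param steps data.frame with columns chrom, start, end, value.
#' @param total_signal library-size proxy; must be > 0.
#' @return list of class `coverage_track` with elements `steps`, `total_signal`.
#' @export
coverage_track <- function(steps, total_signal = NULL) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(steps)))
  steps <- steps[order(steps$chrom, steps$start, steps$end), , drop = FALSE]
  rownames(steps) <- NULL
  if (nrow(steps) > 0) {
    if (any(steps$start >= steps$end)) stop("coverage_track: start >= end")
    if (any(steps$value < 0)) stop("coverage_track: negative values")
    ov <- unlist(tapply(seq_len(nrow(steps)), steps$chrom, function(i) {
      if (length(i) < 2) return(FALSE)
      any(steps$start[i][-1] < steps$end[i][-length(i)])
    }))
    if (any(ov)) stop("coverage_track: overlapping steps on one chromosome")
  }
  if (is.null(total_signal))
    total_signal <- sum(steps$value * (steps$end - steps$start))
  if (!is.finite(total_signal) || total_signal <= 0)
    stop("coverage_track: total_signal must be > 0")
  structure(list(steps = steps, total_signal = total_signal),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d steps, total_signal = %.4g\n",
              nrow(x$steps), x$total_signal))
  invisible(x)
}

#' Read a 4-column bedGraph into a coverage track
#'
#' Steps may arrive unsorted; they are sorted and checked non-overlapping.
#'
#' @param path bedGraph path.
#' @return `coverage_track`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  if (!any(keep)) {
    return(coverage_track(data.frame(chrom = character(), start = numeric(),
                                     end = numeric(), value = numeric()),
                          total_signal = 1))
  }
  con <- textConnection(lines[keep])
  on.exit(close(con))
  df <- read.table(con, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "value"),
                   colClasses = c("character", "numeric", "numeric", "numeric"))
  coverage_track(df)
}

#' @rdname read_bedgraph
#' @param track `coverage_track` to write.
#' @export
write_bedgraph <- function(track, path) {
  df <- track$steps
  out <- data.frame(df$chrom, sprintf("%d", as.integer(df$start)),
                    sprintf("%d", as.integer(df$end)),
                    formatC(df$value, format = "g", digits = 15))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' All overlapping interval pairs between two peak sets
#'
#' @param a,b `peak_set`s (any data.frame with chrom/start/end works).
#' @param min_overlap_bp minimum intersection length, default 1.
#' @return data.frame with columns `idx_a`, `idx_b`, `overlap_bp`, one row per
#'   pair with intersection length >= `min_overlap_bp`. Indices are row numbers
#'   in `a` and `b`.
#' @export
overlap_pairs <- function(a, b, min_overlap_bp = 1L) {
  stopifnot(min_overlap_bp >= 1)
  if (nrow(a) == 0 || nrow(b) == 0)
    return(data.frame(idx_a = integer(), idx_b = integer(),
                      overlap_bp = numeric()))
  # disjoint chromosome sets are a legitimate query, not a user error
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(.as_gr(a), .as_gr(b),
                                minoverlap = as.integer(min_overlap_bp)))
  ia <- S4Vectors::queryHits(hits); ib <- S4Vectors::subjectHits(hits)
  ov <- pmin(a$end[ia], b$end[ib]) - pmax(a$start[ia], b$start[ib])
  out <- data.frame(idx_a = ia, idx_b = ib, overlap_bp = ov)
  out[order(out$idx_a, out$idx_b), , drop = FALSE]
}

# internal: sample uniform starts for intervals of widths w on chromosomes of
# length L (vector recycled); returns integer starts in [0, L - w]
.sample_starts <- function(widths, chrom_len) {
  if (any(widths > chrom_len))
    stop("shuffle: interval longer than its chromosome")
  floor(runif(length(widths), 0, chrom_len - widths + 1))
}

#' Randomly re-place intervals across the genome
#'
#' Each output interval keeps the length of its source; placement is uniform
#' over valid start positions. With `match_chrom = TRUE` (default) every
#' interval stays on its source chromosome; otherwise a destination chromosome
#' is drawn with probability proportional to its length among those long enough
#' to hold the interval.
#'
#' @param a `peak_set`.
#' @param sizes `chrom_sizes`.
#' @param seed integer seed; same seed gives identical output.
#' @param match_chrom keep intervals on their source chromosome?
#' @return `peak_set` (unsorted: row i is the re-placement of row i of `a`).
#' @export
shuffle_intervals <- function(a, sizes, seed, match_chrom = TRUE) {
  set.seed(as.integer(seed))
  .shuffle_once(a, sizes, match_chrom)
}

.shuffle_once <- function(a, sizes, match_chrom = TRUE) {
  n <- nrow(a)
  if (n == 0) return(a)
  w <- a$end - a$start
  if (match_chrom) {
    len <- as.numeric(sizes[a$chrom])
    if (any(is.na(len))) stop("shuffle: chromosome absent from sizes")
    chrom <- a$chrom
  } else {
    L <- as.numeric(sizes)
    ok <- outer(w, L, `<=`)           # n x n_chrom feasibility
    if (any(rowSums(ok) == 0))
      stop("shuffle: interval longer than every available chromosome")
    prob <- t(apply(ok, 1, function(r) ifelse(r, L, 0)))
    chrom <- names(sizes)[apply(prob, 1, function(p) sample.int(length(p), 1, prob = p))]
    len <- as.numeric(sizes[chrom])
  }
  start <- .sample_starts(w, len)
  peak_set(chrom, start, start + w, name = a$name, score = a$score,
           strand = a$strand, label = attr(a, "label"), sort = FALSE)
}
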