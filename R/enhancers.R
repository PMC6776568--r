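# Enhancer-class assignment, SE-to-gene mapping, and an optional
# stitch-and-rank super-enhancer caller for users without a published SE list.

ENH_LEVELS <- c("super", "active", "intermediate", "poised", "unclassified")

#' Classify regions into enhancer classes
#'
#' Mutually exclusive, exhaustive classes by precedence: overlap with a
#' supplied super-enhancer list wins outright (a published SE catalogue
#' overrides local mark logic); otherwise H3K27ac marks an active enhancer,
#' H3K27me3 together with H3K4me1 a poised enhancer, H3K4me1 alone an
#' intermediate enhancer; anything else is unclassified.
#'
#' @param regions `peak_set` of candidate enhancer regions.
#' @param se_list super-enhancer `peak_set` (may be empty).
#' @param k27ac,k4me1,k27me3 histone-mark `peak_set`s.
#' @return list of class `enhancer_calls`: `calls` (regions + `enh_class`),
#'   `counts` per class.
#' @export
classify_enhancers <- function(regions, se_list, k27ac, k4me1, k27me3) {
  n <- nrow(regions)
  ov <- function(b) {
    hit <- rep(FALSE, n)
    if (n > 0 && nrow(b) > 0)
      hit[unique(overlap_pairs(regions, b)$idx_a)] <- TRUE
    hit
  }
  is_se <- ov(se_list); has_ac <- ov(k27ac)
  has_me1 <- ov(k4me1); has_me3 <- ov(k27me3)
  cls <- ifelse(is_se, "super",
         ifelse(has_ac, "active",
         ifelse(has_me3 & has_me1, "poised",
         ifelse(has_me1, "intermediate", "unclassified"))))
  calls <- as.data.frame(regions)
  calls$enh_class <- factor(cls, levels = ENH_LEVELS)
  structure(list(calls = calls, counts = as.integer(table(calls$enh_class)),
                 classes = ENH_LEVELS),
            class = "enhancer_calls")
}

#' @export
print.enhancer_calls <- function(x, ...) {
  cat("enhancer classes:\n")
  print(data.frame(class = x$classes, n = x$counts))
  invisible(x)
}

#' Map super-enhancers to their nearest gene
#'
#' Each SE is assigned the gene whose TSS is nearest to the SE boundary
#' (distance 0 when the TSS lies inside the SE). SEs whose nearest TSS is
#' farther than `max_distance` are left unassigned. Equidistant candidates are
#' broken toward the lexicographically smaller gene_id and flagged.
#'
#' @param se_list `peak_set` of SEs.
#' @param genes nonempty gene table.
#' @param max_distance maximum boundary-to-TSS distance in bp, default 100000.
#' @return data.frame: SE coordinates plus `gene_id`, `distance`, `tie`.
#' @export
assign_se_genes <- function(se_list, genes, max_distance = 1e5) {
  if (nrow(genes) == 0) stop("assign_se_genes: empty gene table")
  n <- nrow(se_list)
  out <- data.frame(chrom = se_list$chrom, start = se_list$start,
                    end = se_list$end, name = se_list$name,
                    gene_id = NA_character_, distance = NA_real_, tie = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    g <- genes[genes$chrom == se_list$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) next
    d <- pmax(0, se_list$start[i] - g$tss, g$tss - se_list$end[i] + 1)
    dmin <- min(d)
    if (dmin > max_distance) next
    cand <- sort(g$gene_id[d == dmin])
    out$gene_id[i] <- cand[1]
    out$distance[i] <- dmin
    out$tie[i] <- length(cand) > 1
  }
  out
}

# internal: merge intervals whose gap is <= stitch_distance, per chromosome
.stitch <- function(peaks, stitch_distance) {
  df <- as.data.frame(peaks)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  pieces <- lapply(split(df, df$chrom), function(d) {
    s <- d$start; e <- d$end
    grp <- cumsum(c(1, as.integer(s[-1] > cummax(e[-length(e)]) + stitch_distance)))
    data.frame(chrom = d$chrom[1],
               start = tapply(s, grp, min),
               end = tapply(e, grp, max))
  })
  res <- do.call(rbind, pieces)
  peak_set(res$chrom, res$start, res$end, label = "stitched")
}

#' Stitch candidate peaks and rank them into SEs and TEs
#'
#' ROSE-style convenience: peaks within `stitch_distance` of each other are
#' merged; stitched regions are ranked by total track signal; the SE/TE cutoff
#' is the point of the ranked curve where a line of slope (max - min)/(n - 1)
#' is tangent (the geometric inflection on axis-scaled coordinates). Regions
#' above the cutoff are called super-enhancers.
#'
#' @param candidate_peaks `peak_set` of enhancer candidates.
#' @param track `coverage_track` supplying the ranking signal.
#' @param stitch_distance merge gap in bp, default 12500.
#' @param tss_exclude optional `peak_set`; candidate peaks overlapping it are
#'   removed before stitching (conventional TSS exclusion).
#' @return list of class `stitch_rank`: `se_list`, `te_list` (both `peak_set`,
#'   together partitioning the stitched regions), `signal` (sorted ascending),
#'   `cutoff_signal`, `degenerate` (TRUE when all signals are equal, in which
#'   case no SEs are called).
#' @export
stitch_and_rank <- function(candidate_peaks, track, stitch_distance = 12500,
                            tss_exclude = NULL) {
  peaks <- candidate_peaks
  if (!is.null(tss_exclude) && nrow(tss_exclude) > 0 && nrow(peaks) > 0) {
    drop <- unique(overlap_pairs(peaks, tss_exclude)$idx_a)
    if (length(drop) > 0) peaks <- peaks[-drop, , drop = FALSE]
  }
  stitched <- .stitch(peaks, stitch_distance)
  n <- nrow(stitched)
  if (n < 3) stop("stitch_and_rank: fewer than 3 stitched regions")
  sig <- .track_region_sum(track, stitched)
  o <- order(sig)
  y <- sig[o]
  degenerate <- max(y) == min(y)
  if (degenerate) {
    is_se <- rep(FALSE, n)
    cutoff <- max(y)
  } else {
    ys <- (y - min(y)) / (max(y) - min(y)) * (n - 1)
    xs <- seq_len(n) - 1
    t_idx <- which.min(ys - xs)          # tangent point of the slope-1 line
    cutoff <- y[t_idx]
    is_se_sorted <- seq_len(n) > t_idx
    is_se <- logical(n)
    is_se[o] <- is_se_sorted
  }
  sub <- function(keep) {
    d <- as.data.frame(stitched)[keep, , drop = FALSE]
    peak_set(d$chrom, d$start, d$end, score = sig[keep],
             label = if (identical(keep, is_se)) "SE" else "TE")
  }
  structure(list(se_list = sub(is_se), te_list = sub(!is_se),
                 signal = y, cutoff_signal = cutoff, degenerate = degenerate),
            class = "stitch_rank")
}

#' @export
print.stitch_rank <- function(x, ...) {
  cat(sprintf("stitch_and_rank: %d SE / %d TE (cutoff signal %.4g%s)\n",
              nrow(x$se_list), nrow(x$te_list), x$cutoff_signal,
              if (x$degenerate) ", degenerate ranking" else ""))
  invisible(x)
}
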