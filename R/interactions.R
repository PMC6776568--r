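# Promoter-capture interaction calls: I/O, classification against promoters
# and classified enhancers, TF occupancy at anchors, and gene-centric reports.

#' Read promoter-capture interaction calls
#'
#' ibed-style tab-separated file with header:
#' bait_chrom bait_start bait_end bait_genes oe_chrom oe_start oe_end score.
#' `bait_genes` holds one or more gene ids separated by ";".
#'
#' @param path file path.
#' @return data.frame of class `interaction_calls` with the eight columns above
#'   plus `inter_chromosomal`.
#' @export
read_interactions <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = c("character", "numeric", "numeric",
                                  "character", "character", "numeric",
                                  "numeric", "numeric"))
  need <- c("bait_chrom", "bait_start", "bait_end", "bait_genes",
            "oe_chrom", "oe_start", "oe_end", "score")
  if (!all(need %in% names(df)))
    stop("read_interactions: header must contain ", paste(need, collapse = ", "))
  df <- df[, need]
  empty <- !nzchar(df$bait_genes)
  if (any(empty))
    stop("read_interactions: empty bait_genes at row ", which(empty)[1])
  if (any(df$bait_start >= df$bait_end | df$oe_start >= df$oe_end))
    stop("read_interactions: malformed anchor coordinates")
  df$inter_chromosomal <- df$bait_chrom != df$oe_chrom
  class(df) <- c("interaction_calls", "data.frame")
  df
}

#' @rdname read_interactions
#' @param calls interaction table to write.
#' @export
write_interactions <- function(calls, path) {
  out <- as.data.frame(calls)[, c("bait_chrom", "bait_start", "bait_end",
                                  "bait_genes", "oe_chrom", "oe_start",
                                  "oe_end", "score")]
  for (col in c("bait_start", "bait_end", "oe_start", "oe_end"))
    out[[col]] <- sprintf("%d", as.integer(out[[col]]))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.anchor_set <- function(calls, which = c("oe", "bait")) {
  which <- match.arg(which)
  if (which == "oe")
    peak_set(calls$oe_chrom, calls$oe_start, calls$oe_end, sort = FALSE)
  else
    peak_set(calls$bait_chrom, calls$bait_start, calls$bait_end, sort = FALSE)
}

#' Classify interactions by what the other end touches
#'
#' Precedence promoter > enhancer: an other end overlapping a promoter window
#' is promoter_promoter regardless of enhancer overlap (the bait design is
#' promoter-centric); otherwise overlap with a classified enhancer gives
#' promoter_enhancer with that enhancer subclass; anything else is
#' promoter_other.
#'
#' @param calls `interaction_calls`.
#' @param promoters promoter `peak_set` (see [promoter_regions()]).
#' @param enh_calls `enhancer_calls` from [classify_enhancers()].
#' @return list of class `interaction_classes`: `calls` (input + `iclass` +
#'   `enh_subclass`), `counts` per class.
#' @export
classify_interactions <- function(calls, promoters, enh_calls) {
  n <- nrow(calls)
  oe <- .anchor_set(calls)
  in_prom <- rep(FALSE, n)
  if (n > 0 && nrow(promoters) > 0)
    in_prom[unique(overlap_pairs(oe, promoters)$idx_a)] <- TRUE
  subclass <- rep(NA_character_, n)
  enh_df <- enh_calls$calls
  if (n > 0 && nrow(enh_df) > 0) {
    hp <- overlap_pairs(oe, enh_df)
    if (nrow(hp) > 0) {
      # when an other end touches several enhancers, keep the highest class
      pri <- match(as.character(enh_df$enh_class[hp$idx_b]), ENH_LEVELS)
      best <- tapply(pri, hp$idx_a, min)
      subclass[as.integer(names(best))] <- ENH_LEVELS[as.integer(best)]
    }
  }
  iclass <- ifelse(in_prom, "promoter_promoter",
            ifelse(!is.na(subclass) & subclass != "unclassified",
                   "promoter_enhancer", "promoter_other"))
  out <- as.data.frame(calls)
  out$iclass <- factor(iclass, levels = c("promoter_promoter",
                                          "promoter_enhancer",
                                          "promoter_other"))
  out$enh_subclass <- ifelse(out$iclass == "promoter_enhancer", subclass,
                             NA_character_)
  structure(list(calls = out, counts = as.integer(table(out$iclass)),
                 classes = levels(out$iclass)),
            class = "interaction_classes")
}

#' @export
print.interaction_classes <- function(x, ...) {
  cat("interaction classes:\n")
  print(data.frame(class = x$classes, n = x$counts))
  invisible(x)
}

#' Interactions with a TF bound at an anchor
#'
#' @param calls classified interaction table (`interaction_classes$calls`) or
#'   a plain `interaction_calls` table.
#' @param tf TF `peak_set`.
#' @param where which anchor must carry a TF peak: "either" (default), "bait"
#'   or "other_end".
#' @param min_overlap_bp minimum overlap in bp, default 1.
#' @return list: `subset` (the mediated rows), `fraction`, `n`, `n_mediated`.
#' @export
peaks_at_interactions <- function(calls, tf,
                                  where = c("either", "bait", "other_end"),
                                  min_overlap_bp = 1L) {
  where <- match.arg(where)
  if (is.list(calls) && !is.data.frame(calls) && !is.null(calls$calls))
    calls <- calls$calls
  n <- nrow(calls)
  if (n == 0) stop("peaks_at_interactions: empty interaction set")
  hit_at <- function(anchor) {
    h <- rep(FALSE, n)
    hp <- overlap_pairs(.anchor_set(calls, anchor), tf, min_overlap_bp)
    h[unique(hp$idx_a)] <- TRUE
    h
  }
  hit <- switch(where,
                bait = hit_at("bait"),
                other_end = hit_at("oe"),
                either = hit_at("bait") | hit_at("oe"))
  list(subset = calls[hit, , drop = FALSE], fraction = mean(hit),
       n = n, n_mediated = sum(hit))
}

#' Second-factor enrichment in mediated vs all interactions
#'
#' Compares the fraction of interactions carrying a second factor at an anchor
#' between a mediated subset and the full universe, with a two-proportion test.
#'
#' @param calls_all full interaction table.
#' @param calls_mediated subset of `calls_all` (e.g. those with the primary TF
#'   at an anchor).
#' @param tf2 second-factor `peak_set`.
#' @param where anchor rule passed to [peaks_at_interactions()].
#' @return list: `fraction_mediated`, `fraction_all`, `ratio` (NA, flagged
#'   `degenerate`, when both fractions are 0), `p_value`, `n_mediated`, `n_all`.
#' @export
factor_enrichment_in_mediated <- function(calls_all, calls_mediated, tf2,
                                          where = "either") {
  if (is.list(calls_all) && !is.data.frame(calls_all) && !is.null(calls_all$calls))
    calls_all <- calls_all$calls
  if (is.list(calls_mediated) && !is.data.frame(calls_mediated) &&
      !is.null(calls_mediated$calls))
    calls_mediated <- calls_mediated$calls
  if (nrow(calls_all) == 0 || nrow(calls_mediated) == 0)
    stop("factor_enrichment_in_mediated: empty universe")
  fm <- peaks_at_interactions(calls_mediated, tf2, where)
  fa <- peaks_at_interactions(calls_all, tf2, where)
  degenerate <- fm$fraction == 0 && fa$fraction == 0
  p <- if (degenerate) NA_real_ else suppressWarnings(
    stats::prop.test(c(fm$n_mediated, fa$n_mediated),
                     c(fm$n, fa$n))$p.value)
  list(fraction_mediated = fm$fraction, fraction_all = fa$fraction,
       ratio = if (degenerate) NA_real_ else fm$fraction / fa$fraction,
       p_value = p, n_mediated = fm$n, n_all = fa$n, degenerate = degenerate)
}

#' Per-gene interaction report
#'
#' All interactions whose bait gene list contains `gene_id`, with class,
#' anchor distance (absolute midpoint separation; Inf for inter-chromosomal
#' pairs) and, optionally, TF occupancy flags at either anchor. Duplicate bait
#' rows are passed through, not de-duplicated.
#'
#' @param gene_id gene identifier.
#' @param calls classified interaction table (`interaction_classes` or its
#'   `$calls`).
#' @param tf optional named list of `peak_set`s; adds a logical `tf_<name>`
#'   column per set.
#' @return data.frame (possibly empty) of the gene's interactions.
#' @export
gene_interactions <- function(gene_id, calls, tf = NULL) {
  if (is.list(calls) && !is.data.frame(calls) && !is.null(calls$calls))
    calls <- calls$calls
  hit <- vapply(strsplit(calls$bait_genes, ";", fixed = TRUE),
                function(g) gene_id %in% g, logical(1))
  out <- calls[hit, , drop = FALSE]
  out$distance <- ifelse(out$bait_chrom != out$oe_chrom, Inf,
                         abs(floor((out$oe_start + out$oe_end) / 2) -
                             floor((out$bait_start + out$bait_end) / 2)))
  for (nm in names(tf)) {
    flag <- rep(FALSE, nrow(out))
    if (nrow(out) > 0) {
      b <- unique(overlap_pairs(.anchor_set(out, "bait"), tf[[nm]])$idx_a)
      o <- unique(overlap_pairs(.anchor_set(out, "oe"), tf[[nm]])$idx_a)
      flag[union(b, o)] <- TRUE
    }
    out[[paste0("tf_", nm)]] <- flag
  }
  rownames(out) <- NULL
  out
}
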