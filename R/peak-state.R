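# Chromatin-state classification of TF peaks and genomic-compartment
# annotation. States follow the overlap rule: H3K4me3 only -> active,
# both marks -> bivalent, H3K27me3 only -> repressive, neither -> unmarked.

STATE_LEVELS <- c("active_k4me3", "bivalent", "repressive_k27me3", "unmarked")

#' Promoter windows around transcription start sites
#'
#' One window per gene, `[tss - halfwidth, tss + halfwidth)`, clipped at
#' chromosome bounds when `sizes` is supplied. The default +/- 3 kb gives the
#' conventional 6 kb promoter definition.
#'
#' @param genes gene table (see [read_gene_table()]).
#' @param halfwidth window half-width in bp, default 3000.
#' @param sizes optional `chrom_sizes` used for clipping.
#' @return `peak_set` carrying gene_id as the interval name.
#' @export
promoter_regions <- function(genes, halfwidth = 3000, sizes = NULL) {
  stopifnot(halfwidth > 0)
  start <- pmax(0, genes$tss - halfwidth)
  end <- genes$tss + halfwidth
  if (!is.null(sizes)) end <- pmin(end, as.numeric(sizes[genes$chrom]))
  peak_set(genes$chrom, start, end, name = genes$gene_id,
           strand = genes$strand, label = "promoters")
}

#' Classify peaks by chromatin state from histone-mark overlap
#'
#' @param peaks TF `peak_set`.
#' @param k4me3 H3K4me3 `peak_set` (active mark).
#' @param k27me3 H3K27me3 `peak_set` (repressive mark).
#' @param min_overlap_bp minimum overlap for a mark call, default 1.
#' @param drop_unmarked report only the three marked groups (the unmarked
#'   residue is excluded from calls and composition)? Default FALSE.
#' @return list of class `state_calls`: `calls` (peaks + `state` column),
#'   `counts` and `fractions` per state.
#' @export
classify_states <- function(peaks, k4me3, k27me3, min_overlap_bp = 1L,
                            drop_unmarked = FALSE) {
  n <- nrow(peaks)
  has_k4 <- has_k27 <- rep(FALSE, n)
  if (n > 0) {
    has_k4[unique(overlap_pairs(peaks, k4me3, min_overlap_bp)$idx_a)] <- TRUE
    has_k27[unique(overlap_pairs(peaks, k27me3, min_overlap_bp)$idx_a)] <- TRUE
  }
  state <- ifelse(has_k4 & has_k27, "bivalent",
           ifelse(has_k4, "active_k4me3",
           ifelse(has_k27, "repressive_k27me3", "unmarked")))
  calls <- as.data.frame(peaks)
  calls$state <- factor(state, levels = STATE_LEVELS)
  if (drop_unmarked) calls <- droplevels(calls[calls$state != "unmarked", ])
  counts <- table(calls$state)
  fractions <- if (sum(counts) > 0) counts / sum(counts) else counts
  structure(list(calls = calls,
                 counts = as.integer(counts),
                 fractions = as.numeric(fractions),
                 states = names(counts)),
            class = "state_calls")
}

#' @export
print.state_calls <- function(x, ...) {
  cat("chromatin-state calls:\n")
  print(data.frame(state = x$states, n = x$counts,
                   fraction = round(x$fractions, 4)))
  invisible(x)
}

#' Annotate peaks to genomic compartments
#'
#' Assigns each peak exactly one category with precedence
#' promoter > gene body > intergenic. In the `cobind` scheme the gene-body
#' category is reported as "other" (promoter / intergenic / other), matching
#' the three-way split used for co-binding site distributions.
#'
#' @param peaks TF `peak_set`.
#' @param genes gene table.
#' @param scheme "three_way" (promoter/gene_body/intergenic) or "cobind"
#'   (promoter/intergenic/other).
#' @param halfwidth promoter half-width in bp, default 3000.
#' @param sizes optional `chrom_sizes` for promoter clipping.
#' @return list of class `feature_annotation`: `annotation` (peaks +
#'   `category` + `assigned_genes`), `counts`, `percent`.
#' @export
annotate_features <- function(peaks, genes, scheme = c("three_way", "cobind"),
                              halfwidth = 3000, sizes = NULL) {
  scheme <- match.arg(scheme)
  n <- nrow(peaks)
  prom <- promoter_regions(genes, halfwidth, sizes)
  # gene body: min(tss,tes)..max(tss,tes), promoter window handled by precedence
  body <- peak_set(genes$chrom, pmin(genes$tss, genes$tes),
                   pmax(genes$tss, genes$tes), name = genes$gene_id,
                   label = "gene_bodies")
  in_prom <- in_body <- rep(FALSE, n)
  assigned <- rep("", n)
  if (n > 0) {
    hp <- overlap_pairs(peaks, prom)
    in_prom[unique(hp$idx_a)] <- TRUE
    if (nrow(hp) > 0) {
      gl <- tapply(prom$name[hp$idx_b], hp$idx_a,
                   function(g) paste(sort(unique(g)), collapse = ";"))
      assigned[as.integer(names(gl))] <- as.character(gl)
    }
    in_body[unique(overlap_pairs(peaks, body)$idx_a)] <- TRUE
  }
  category <- ifelse(in_prom, "promoter",
              ifelse(in_body, "gene_body", "intergenic"))
  levels3 <- c("promoter", "gene_body", "intergenic")
  if (scheme == "cobind") {
    category[category == "gene_body"] <- "other"
    levels3 <- c("promoter", "intergenic", "other")
  }
  ann <- as.data.frame(peaks)
  ann$category <- factor(category, levels = levels3)
  ann$assigned_genes <- ifelse(ann$category == "promoter", assigned, "")
  counts <- table(ann$category)
  percent <- if (n > 0) 100 * counts / n else counts
  structure(list(annotation = ann, counts = as.integer(counts),
                 percent = as.numeric(percent), categories = names(counts),
                 scheme = scheme),
            class = "feature_annotation")
}

#' @export
print.feature_annotation <- function(x, ...) {
  cat(sprintf("feature annotation (%s scheme):\n", x$scheme))
  print(data.frame(category = x$categories, n = x$counts,
                   percent = round(x$percent, 2)))
  invisible(x)
}

#' Assign target genes to peaks by promoter-window overlap
#'
#' Gene g is a target of peak p iff the `[tss - halfwidth, tss + halfwidth)`
#' window of g overlaps p. A peak may target several genes and a gene may be
#' hit by several peaks.
#'
#' @inheritParams annotate_features
#' @return list with `peak_to_genes` (list indexed by peak row: character
#'   vectors of gene_id) and `gene_to_peaks` (named list gene_id -> integer
#'   peak rows).
#' @export
assign_target_genes <- function(peaks, genes, halfwidth = 3000, sizes = NULL) {
  prom <- promoter_regions(genes, halfwidth, sizes)
  hp <- overlap_pairs(peaks, prom)
  peak_to_genes <- rep(list(character()), nrow(peaks))
  gene_to_peaks <- list()
  if (nrow(hp) > 0) {
    sp <- split(prom$name[hp$idx_b], hp$idx_a)
    for (k in names(sp)) peak_to_genes[[as.integer(k)]] <- sort(unique(sp[[k]]))
    gp <- split(hp$idx_a, prom$name[hp$idx_b])
    gene_to_peaks <- lapply(gp, function(i) sort(unique(i)))
  }
  list(peak_to_genes = peak_to_genes, gene_to_peaks = gene_to_peaks)
}
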