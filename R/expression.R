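# Differential-expression significance rule and joins between DE status and
# peak-derived gene sets.

#' Call differential-expression status from fold change and p-value
#'
#' A gene is up when fold_change > `fc_threshold` and p < `p_threshold`, down
#' when fold_change < 1 / `fc_threshold` and p < `p_threshold`, otherwise ns.
#' Both inequalities are strict, so fold_change exactly at the threshold is ns.
#' Fold changes are knockdown / control on the linear scale.
#'
#' @param table data.frame with columns gene_id, fold_change (> 0, linear) and
#'   p_value (in \[0, 1\]); a `log2fc` column is accepted with
#'   `log2 = TRUE`.
#' @param fc_threshold linear fold-change cutoff, default 1.3.
#' @param p_threshold p-value cutoff, default 0.05.
#' @param log2 interpret the fold-change column as log2? Default FALSE.
#' @param adjust apply Benjamini-Hochberg correction to the p-values before
#'   thresholding? Off by default (the rule filters on raw p).
#' @return list of class `de_calls`: `records` (table + `status`), `n_up`,
#'   `n_down`, `n_ns`.
#' @export
call_de <- function(table, fc_threshold = 1.3, p_threshold = 0.05,
                    log2 = FALSE, adjust = FALSE) {
  stopifnot(fc_threshold > 0, p_threshold > 0)
  fc <- if (log2) 2^table$log2fc else table$fold_change
  if (any(!is.finite(fc) | fc <= 0))
    stop("call_de: non-positive fold change for gene ",
         table$gene_id[which(!is.finite(fc) | fc <= 0)[1]])
  p <- table$p_value
  if (adjust) p <- stats::p.adjust(p, method = "BH")
  status <- ifelse(fc > fc_threshold & p < p_threshold, "up",
            ifelse(fc < 1 / fc_threshold & p < p_threshold, "down", "ns"))
  records <- data.frame(gene_id = table$gene_id, fold_change = fc,
                        p_value = table$p_value,
                        status = factor(status, levels = c("up", "down", "ns")),
                        stringsAsFactors = FALSE)
  structure(list(records = records,
                 n_up = sum(status == "up"),
                 n_down = sum(status == "down"),
                 n_ns = sum(status == "ns")),
            class = "de_calls")
}

#' @export
print.de_calls <- function(x, ...) {
  cat(sprintf("DE calls: %d up, %d down, %d ns (n = %d)\n",
              x$n_up, x$n_down, x$n_ns, nrow(x$records)))
  invisible(x)
}

#' Read a DE table (gene_id, fold_change, p_value)
#' @param path tab-separated file with that header.
#' @return data.frame.
#' @export
read_de_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "fold_change", "p_value")
  if (!all(need %in% names(df)))
    stop("read_de_table: header must contain ", paste(need, collapse = ", "))
  df[, need]
}

#' @rdname read_de_table
#' @param table DE table to write.
#' @export
write_de_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' DE-status composition of labelled gene sets
#'
#' For each labelled gene set, the fractions of measured genes that are up,
#' down or ns. Genes absent from the DE table are counted as unmeasured and
#' reported separately; fractions are over measured genes and sum to 1 (NA
#' when no gene of the set was measured).
#'
#' @param gene_sets named list of character vectors of gene_id.
#' @param de `de_calls` (or its `records`).
#' @return data.frame: label, n, n_measured, n_unmeasured, frac_up, frac_down,
#'   frac_ns.
#' @export
class_de_summary <- function(gene_sets, de) {
  rec <- if (inherits(de, "de_calls")) de$records else de
  status <- structure(as.character(rec$status), names = rec$gene_id)
  rows <- lapply(names(gene_sets), function(lab) {
    g <- unique(gene_sets[[lab]])
    st <- status[g]
    measured <- !is.na(st)
    m <- sum(measured)
    data.frame(label = lab, n = length(g), n_measured = m,
               n_unmeasured = length(g) - m,
               frac_up = if (m) sum(st[measured] == "up") / m else NA_real_,
               frac_down = if (m) sum(st[measured] == "down") / m else NA_real_,
               frac_ns = if (m) sum(st[measured] == "ns") / m else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Gene-set overlap with a hypergeometric enrichment p-value
#'
#' One-sided upper-tail p for observing at least the given overlap when
#' `|set_a|` genes are drawn from a universe containing `|set_b|` marked genes.
#'
#' @param set_a,set_b character vectors of gene_id.
#' @param universe_size integer universe size, at least as large as either set.
#' @return list: `n_overlap`, `p_value`, `n_a`, `n_b`, `universe_size`,
#'   `expected`.
#' @export
geneset_overlap <- function(set_a, set_b, universe_size) {
  a <- unique(set_a); b <- unique(set_b)
  if (universe_size < length(a) || universe_size < length(b))
    stop("geneset_overlap: universe smaller than a set")
  k <- length(intersect(a, b))
  p <- stats::phyper(k - 1, length(b), universe_size - length(b), length(a),
                     lower.tail = FALSE)
  list(n_overlap = k, p_value = p, n_a = length(a), n_b = length(b),
       universe_size = universe_size,
       expected = length(a) * length(b) / universe_size)
}
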