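# Pipeline orchestration: a run config naming inputs and thresholds, staged
# execution in dependency order, and a machine-readable JSON run report.

.STAGES <- c("classify", "annotate", "profile", "enhancers", "cobind",
             "interactions", "de")
.STAGE_DEPS <- list(cobind = "classify", interactions = "enhancers")

#' Build a run configuration
#'
#' @param inputs named list of input paths: `chrom_sizes`, `genes`, `tfa`,
#'   `tfb`, `k4me3`, `k27me3`, `k4me1`, `k27ac`, `se`, `te`,
#'   `enhancer_regions`, `med1_coverage`, `tfa_coverage`, `interactions`,
#'   `de`. A bundle directory from [simulate_study()] supplies all of them via
#'   `bundle_run_config()`.
#' @param out_dir output directory.
#' @param promoter_halfwidth promoter half-width in bp (default 3000).
#' @param fc_threshold,p_threshold DE rule thresholds (defaults 1.3, 0.05).
#' @param n_draws resampling draws for the overlap CI (default 100).
#' @param min_overlap_bp minimum overlap in bp (default 1).
#' @param seed base seed; each stage derives its own namespaced stream.
#' @return list of class `run_config`.
#' @export
run_config <- function(inputs, out_dir, promoter_halfwidth = 3000,
                       fc_threshold = 1.3, p_threshold = 0.05,
                       n_draws = 100, min_overlap_bp = 1L, seed = 1) {
  missing <- !vapply(inputs, file.exists, logical(1))
  if (any(missing))
    stop("run_config: missing input file(s): ",
         paste(unlist(inputs[missing]), collapse = ", "))
  stopifnot(promoter_halfwidth > 0, fc_threshold > 0, p_threshold > 0,
            p_threshold <= 1, n_draws >= 2, min_overlap_bp >= 1)
  structure(list(inputs = inputs, out_dir = out_dir,
                 promoter_halfwidth = promoter_halfwidth,
                 fc_threshold = fc_threshold, p_threshold = p_threshold,
                 n_draws = as.integer(n_draws),
                 min_overlap_bp = as.integer(min_overlap_bp),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param bundle_dir directory written by [simulate_study()].
#' @param ... passed on to [run_config()].
#' @export
bundle_run_config <- function(bundle_dir, out_dir, ...) {
  man <- jsonlite::read_json(file.path(bundle_dir, "manifest.json"),
                             simplifyVector = TRUE)
  inputs <- lapply(man$files, function(f) file.path(bundle_dir, f))
  run_config(inputs, out_dir, ...)
}

#' Read a YAML run configuration
#'
#' Expects top-level keys `inputs` (path map), `out_dir`, and optionally any
#' threshold accepted by [run_config()].
#'
#' @param path YAML file.
#' @return `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$inputs) || is.null(y$out_dir))
    stop("read_run_config: 'inputs' and 'out_dir' are required")
  args <- y[setdiff(names(y), c("inputs", "out_dir"))]
  do.call(run_config, c(list(inputs = y$inputs, out_dir = y$out_dir), args))
}

.stage_seed <- function(config, stage) {
  config$seed * 131L + match(stage, .STAGES)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order (`cobind` requires
#' `classify`; `interactions` requires `enhancers`), writes per-stage TSV/BED
#' outputs and a consolidated JSON report into `config$out_dir`, and returns
#' the report. Reruns with the same config and inputs are byte-identical.
#' A failing stage is recorded in the report, later stages are skipped, and
#' outputs of completed stages are left intact.
#'
#' @param config `run_config`.
#' @param stages subset of classify, annotate, profile, enhancers, cobind,
#'   interactions, de. Default: all.
#' @return list of class `run_report`.
#' @export
run_pipeline <- function(config, stages = .STAGES) {
  stages <- match.arg(stages, .STAGES, several.ok = TRUE)
  for (s in stages) {
    dep <- .STAGE_DEPS[[s]]
    if (!is.null(dep) && !dep %in% stages)
      stop("run_pipeline: stage '", s, "' requires stage '", dep, "'")
  }
  stages <- .STAGES[.STAGES %in% stages]   # dependency order
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- config$inputs
  env <- new.env(parent = emptyenv())
  load1 <- function(key, reader) {
    if (!exists(key, envir = env, inherits = FALSE))
      assign(key, reader(inp[[key]]), envir = env)
    get(key, envir = env, inherits = FALSE)
  }
  sizes <- read_chrom_sizes(inp$chrom_sizes)
  out <- function(f) file.path(config$out_dir, f)
  report <- list(package_version = as.character(packageVersion("selink")),
                 config = list(inputs = inp, out_dir = config$out_dir,
                               promoter_halfwidth = config$promoter_halfwidth,
                               fc_threshold = config$fc_threshold,
                               p_threshold = config$p_threshold,
                               n_draws = config$n_draws,
                               min_overlap_bp = config$min_overlap_bp,
                               seed = config$seed),
                 stages = list())
  state_calls <- NULL; enh_calls <- NULL
  failed <- FALSE
  for (stage in stages) {
    if (failed) {
      report$stages[[stage]] <- list(status = "skipped")
      next
    }
    res <- tryCatch({
      summary <- switch(stage,
        classify = {
          sc <- classify_states(load1("tfa", read_bed),
                                load1("k4me3", read_bed),
                                load1("k27me3", read_bed),
                                config$min_overlap_bp)
          state_calls <- sc
          write.table(sc$calls, out("state_calls.tsv"), sep = "\t",
                      quote = FALSE, row.names = FALSE)
          list(n = nrow(sc$calls), states = sc$states, counts = sc$counts,
               fractions = sc$fractions)
        },
        annotate = {
          genes <- load1("genes", read_gene_table)
          fa <- annotate_features(load1("tfa", read_bed), genes,
                                  halfwidth = config$promoter_halfwidth,
                                  sizes = sizes)
          tg <- assign_target_genes(load1("tfa", read_bed), genes,
                                    config$promoter_halfwidth, sizes)
          write.table(fa$annotation, out("feature_annotation.tsv"),
                      sep = "\t", quote = FALSE, row.names = FALSE)
          list(n = nrow(fa$annotation), categories = fa$categories,
               counts = fa$counts, percent = fa$percent,
               fractions = fa$counts / nrow(fa$annotation),
               n_target_genes = length(tg$gene_to_peaks))
        },
        profile = {
          track <- load1("med1_coverage", read_bedgraph)
          dse <- region_density(track, load1("se", read_bed))
          dte <- region_density(track, load1("te", read_bed))
          cmp <- compare_density(dse, dte)
          prof <- metaprofile(load1("tfa_coverage", read_bedgraph),
                              load1("tfa", read_bed), sizes = sizes)
          write.table(dse, out("se_density.tsv"), sep = "\t", quote = FALSE,
                      row.names = FALSE)
          write.table(dte, out("te_density.tsv"), sep = "\t", quote = FALSE,
                      row.names = FALSE)
          write.table(data.frame(position = prof$positions,
                                 value = prof$values, n = prof$n_contrib),
                      out("tfa_metaprofile.tsv"), sep = "\t", quote = FALSE,
                      row.names = FALSE)
          list(n_se = nrow(dse), n_te = nrow(dte),
               median_se = cmp$median_a, median_te = cmp$median_b,
               median_fold = cmp$median_fold, rank_sum_p = cmp$p_value,
               profile_peak_value = max(prof$values))
        },
        enhancers = {
          ec <- classify_enhancers(load1("enhancer_regions", read_bed),
                                   load1("se", read_bed),
                                   load1("k27ac", read_bed),
                                   load1("k4me1", read_bed),
                                   load1("k27me3", read_bed))
          enh_calls <- ec
          sg <- assign_se_genes(load1("se", read_bed),
                                load1("genes", read_gene_table))
          write.table(ec$calls, out("enhancer_classes.tsv"), sep = "\t",
                      quote = FALSE, row.names = FALSE)
          write.table(sg, out("se_gene_map.tsv"), sep = "\t", quote = FALSE,
                      row.names = FALSE)
          list(n = nrow(ec$calls), classes = ec$classes, counts = ec$counts,
               se_gene_map = sg[, c("name", "gene_id", "distance")])
        },
        cobind = {
          tfa <- load1("tfa", read_bed); tfb <- load1("tfb", read_bed)
          ip <- intersect_peaksets(tfa, tfb, config$min_overlap_bp)
          strata <- split(seq_len(nrow(state_calls$calls)),
                          state_calls$calls$state)
          strata <- lapply(strata, function(i) tfa[i, , drop = FALSE])
          cf <- conditional_fraction(strata, tfb, config$min_overlap_bp)
          ci <- overlap_ci(tfa, tfb, sizes, n_draws = config$n_draws,
                           seed = .stage_seed(config, "cobind"),
                           min_overlap_bp = config$min_overlap_bp)
          write_bed(ip$co_set, out("cobinding_sites.bed"))
          write.table(cf, out("conditional_fractions.tsv"), sep = "\t",
                      quote = FALSE, row.names = FALSE)
          list(n_a = ip$n_a, n_b = ip$n_b, n_cobound = nrow(ip$co_set),
               fraction_a = ip$fraction_a, fraction_b = ip$fraction_b,
               conditional = cf,
               overlap_ci = list(observed = ci$observed,
                                 n_query = ci$n_query, ci_low = ci$ci_low,
                                 ci_high = ci$ci_high,
                                 empirical_p = ci$empirical_p,
                                 n_draws = ci$n_draws, seed = ci$seed))
        },
        interactions = {
          calls <- read_interactions(inp$interactions)
          genes <- load1("genes", read_gene_table)
          prom <- promoter_regions(genes, config$promoter_halfwidth, sizes)
          icc <- classify_interactions(calls, prom, enh_calls)
          med <- peaks_at_interactions(icc, load1("tfa", read_bed),
                                       "either", config$min_overlap_bp)
          enr <- factor_enrichment_in_mediated(icc$calls, med$subset,
                                               load1("tfb", read_bed))
          write.table(icc$calls, out("interaction_classes.tsv"), sep = "\t",
                      quote = FALSE, row.names = FALSE)
          list(n = nrow(icc$calls), classes = icc$classes,
               counts = icc$counts,
               fractions = icc$counts / nrow(icc$calls),
               mediated_fraction = med$fraction, n_mediated = med$n_mediated,
               tf2_fraction_mediated = enr$fraction_mediated,
               tf2_fraction_all = enr$fraction_all,
               tf2_ratio = enr$ratio, tf2_p = enr$p_value)
        },
        de = {
          dc <- call_de(read_de_table(inp$de), config$fc_threshold,
                        config$p_threshold)
          write.table(dc$records, out("de_status.tsv"), sep = "\t",
                      quote = FALSE, row.names = FALSE)
          list(n = nrow(dc$records), n_up = dc$n_up, n_down = dc$n_down,
               n_ns = dc$n_ns)
        })
      c(list(status = "ok", seed = .stage_seed(config, stage)), summary)
    }, error = function(e) {
      failed <<- TRUE
      list(status = "failed", error = conditionMessage(e))
    })
    report$stages[[stage]] <- res
  }
  class(report) <- "run_report"
  jsonlite::write_json(unclass(report), out("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline run report (selink", x$package_version, ")\n")
  for (s in names(x$stages))
    cat(sprintf("  %-13s %s\n", s, x$stages[[s]]$status))
  invisible(x)
}
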