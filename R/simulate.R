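# Synthetic miniature study with planted ground truth. Every entity is placed
# by construction so that the downstream classifiers recover the planted label
# exactly, and every planted parameter is recorded in a manifest.
#
# Genome layout: each chromosome is divided into fixed 95 kb "territories".
# Within a territory starting at base B:
#   gene span        [B+10000, B+30000)   strand alternates; promoter +/- 3 kb
#   SE zone          [B+42000, B+52000)   only in SE territories
#   TE zone          [B+56000, B+58000)   only in TE territories
#   enhancer zone    [B+62000, B+64000)   candidate enhancer regions
#   empty zone       [B+66000, B+68000)   "other"-class interaction anchors
#   free zone        [B+70000, B+93000)   intergenic TF peaks (1.5 kb pitch)
# The zones are mutually disjoint and keep >= 3 kb clearance from every
# promoter window, so feature categories are unambiguous.

.TERR_STRIDE <- 95000
.TERR_BASE0 <- 50000
.PEAK_W <- 400

#' Configuration for a synthetic study
#'
#' Defaults define the reference study conditions: a 3 x 10 Mb genome, 300
#' genes, 2000 TF-A peaks with state composition 0.50/0.20/0.20/0.10
#' (active/bivalent/repressive/unmarked) and feature composition 0.01/0.29/0.70
#' (promoter/gene body/intergenic), TF-B co-binding at 0.60 of TF-A peaks
#' (0.70 of active-state and 0.50 of repressive-state peaks), 20 SEs and 60 TEs
#' with a 3-fold SE/TE signal amplitude ratio, 100 candidate enhancer regions
#' in classes 0.10/0.40/0.30/0.20 (super/active/intermediate/poised), 500
#' promoter-capture interactions in classes 0.60/0.30/0.10 (P-P/P-E/other)
#' with 0.40 TF-mediated, and a 1000-gene DE table with 120 up / 80 down.
#'
#' @param seed integer seed driving all randomness.
#' @param chrom_length,n_chrom genome shape (default 3 chromosomes of 10 Mb).
#' @param n_genes number of positional genes (default 300).
#' @param n_tf_peaks number of TF-A peaks (default 2000).
#' @param state_composition named fractions over the four chromatin states.
#' @param feature_composition named fractions over promoter/gene_body/intergenic.
#' @param conditional_cobind named per-state TF-B co-binding fractions; their
#'   state-weighted mean is the pooled co-binding fraction.
#' @param n_tfb_extra TF-B-only peaks (default 800).
#' @param n_se,n_te super-/typical-enhancer region counts (default 20/60).
#' @param se_te_signal_fold SE/TE coverage amplitude ratio (default 3).
#' @param te_amplitude TE coverage amplitude in reads per bp (default 2).
#' @param coverage_noise Poisson rate scaling; 0 disables noise (deterministic
#'   rectangular bumps), larger values reduce relative noise. Default 1.
#' @param n_enhancer_regions candidate enhancer regions (default 100).
#' @param enhancer_class_fractions named fractions over
#'   super/active/intermediate/poised.
#' @param n_interactions promoter-capture interactions (default 500).
#' @param interaction_class_fractions named fractions over
#'   promoter_promoter/promoter_enhancer/promoter_other.
#' @param mediated_fraction fraction of interactions with TF-A at an anchor.
#' @param de_n_genes,de_n_up,de_n_down DE-table shape (default 1000/120/80).
#' @param promoter_halfwidth promoter half-width used in planting (default 3000).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       chrom_length = 1e7, n_chrom = 3,
                       n_genes = 300,
                       n_tf_peaks = 2000,
                       state_composition = c(active_k4me3 = 0.50,
                                             bivalent = 0.20,
                                             repressive_k27me3 = 0.20,
                                             unmarked = 0.10),
                       feature_composition = c(promoter = 0.01,
                                               gene_body = 0.29,
                                               intergenic = 0.70),
                       conditional_cobind = c(active_k4me3 = 0.70,
                                              bivalent = 0.50,
                                              repressive_k27me3 = 0.50,
                                              unmarked = 0.50),
                       n_tfb_extra = 800,
                       n_se = 20, n_te = 60,
                       se_te_signal_fold = 3,
                       te_amplitude = 2,
                       coverage_noise = 1,
                       n_enhancer_regions = 100,
                       enhancer_class_fractions = c(super = 0.10,
                                                    active = 0.40,
                                                    intermediate = 0.30,
                                                    poised = 0.20),
                       n_interactions = 500,
                       interaction_class_fractions = c(promoter_promoter = 0.60,
                                                       promoter_enhancer = 0.30,
                                                       promoter_other = 0.10),
                       mediated_fraction = 0.40,
                       de_n_genes = 1000, de_n_up = 120, de_n_down = 80,
                       promoter_halfwidth = 3000) {
  cfg <- list(seed = as.integer(seed), chrom_length = chrom_length,
              n_chrom = n_chrom, n_genes = n_genes, n_tf_peaks = n_tf_peaks,
              state_composition = state_composition,
              feature_composition = feature_composition,
              conditional_cobind = conditional_cobind,
              n_tfb_extra = n_tfb_extra, n_se = n_se, n_te = n_te,
              se_te_signal_fold = se_te_signal_fold,
              te_amplitude = te_amplitude, coverage_noise = coverage_noise,
              n_enhancer_regions = n_enhancer_regions,
              enhancer_class_fractions = enhancer_class_fractions,
              n_interactions = n_interactions,
              interaction_class_fractions = interaction_class_fractions,
              mediated_fraction = mediated_fraction,
              de_n_genes = de_n_genes, de_n_up = de_n_up,
              de_n_down = de_n_down,
              promoter_halfwidth = promoter_halfwidth)
  for (f in list(cfg$state_composition, cfg$feature_composition,
                 cfg$enhancer_class_fractions,
                 cfg$interaction_class_fractions))
    if (abs(sum(f) - 1) > 1e-9) stop("sim_config: fractions must sum to 1")
  pooled <- sum(cfg$state_composition * cfg$conditional_cobind[
    names(cfg$state_composition)])
  cfg$cobind_fraction <- pooled
  class(cfg) <- "sim_config"
  cfg
}

# rounded per-class counts that sum exactly to n (largest-remainder method)
.apportion <- function(fractions, n) {
  raw <- fractions * n
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    o <- order(raw - k, decreasing = TRUE)
    k[o[seq_len(rem)]] <- k[o[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(k), names(fractions))
}

#' Generate a complete synthetic study bundle with ground truth
#'
#' Writes a chromosome-size file, gene table, BED peak sets (TF-A, TF-B,
#' H3K4me3, H3K27me3, H3K4me1, H3K27ac), SE/TE region BEDs, candidate enhancer
#' regions, two bedGraph coverage tracks (TF-A bumps; an SE/TE coactivator-like
#' track with SE amplitude = `se_te_signal_fold` x TE amplitude before noise),
#' an interaction table, a DE table, and `manifest.json` recording every
#' planted label and parameter. Deterministic given `config$seed`.
#'
#' @param config `sim_config`.
#' @param out_dir output directory (created if absent).
#' @return the manifest, invisibly (also written as JSON into `out_dir`).
#' @export
simulate_study <- function(config = sim_config(), out_dir) {
  cfg <- config
  set.seed(cfg$seed)
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  sizes <- chrom_sizes(stats::setNames(rep(cfg$chrom_length, cfg$n_chrom),
                                       chroms))
  terr_per_chrom <- floor((cfg$chrom_length - .TERR_BASE0) / .TERR_STRIDE)
  n_terr <- terr_per_chrom * cfg$n_chrom
  if (cfg$n_genes > n_terr)
    stop("simulate_study: more genes than territories; enlarge the genome")
  # territory t (1..n_genes): chromosome, base coordinate
  t_idx <- seq_len(cfg$n_genes)
  t_chrom <- chroms[(t_idx - 1) %/% terr_per_chrom + 1]
  t_base <- .TERR_BASE0 + ((t_idx - 1) %% terr_per_chrom) * .TERR_STRIDE

  ## genes -------------------------------------------------------------------
  strand <- ifelse(t_idx %% 2 == 1, "+", "-")
  tss <- ifelse(strand == "+", t_base + 10000, t_base + 30000)
  tes <- ifelse(strand == "+", t_base + 30000, t_base + 10000)
  gid <- sprintf("g%04d", t_idx)
  genes <- data.frame(gene_id = gid, symbol = paste0("Sym", t_idx),
                      chrom = t_chrom, strand = strand, tss = tss, tes = tes,
                      stringsAsFactors = FALSE)

  ## designations (modular so each chromosome carries every feature kind) ----
  mod15 <- ((t_idx - 1) %% 15) + 1
  feat_counts <- .apportion(cfg$feature_composition, cfg$n_tf_peaks)
  prom_terr <- t_idx[mod15 == 1]
  if (feat_counts["promoter"] > length(prom_terr))
    stop("simulate_study: more promoter peaks than promoter-designated genes")
  prom_terr <- prom_terr[seq_len(feat_counts["promoter"])]
  se_terr <- t_idx[mod15 == 2]
  if (cfg$n_se > length(se_terr))
    stop("simulate_study: not enough territories for SEs")
  se_terr <- se_terr[seq_len(cfg$n_se)]
  te_terr <- t_idx[mod15 %in% 3:5]
  if (cfg$n_te > length(te_terr))
    stop("simulate_study: not enough territories for TEs")
  te_terr <- te_terr[seq_len(cfg$n_te)]
  enh_terr <- t_idx[mod15 %in% 6:10]
  other_med_terr <- t_idx[mod15 == 11]
  other_free_terr <- t_idx[mod15 %in% 12:13]

  ## TF-A peaks --------------------------------------------------------------
  # promoter peaks sit on the TSS of designated genes
  pk <- list()
  pk$promoter <- data.frame(chrom = t_chrom[prom_terr],
                            start = tss[prom_terr] - 200,
                            terr = prom_terr, zone = "promoter")
  nb <- feat_counts["gene_body"]
  if (nb > 2 * cfg$n_genes)
    stop("simulate_study: too many gene-body peaks for the gene count")
  bi <- seq_len(nb)
  b_terr <- ((bi - 1) %% cfg$n_genes) + 1
  b_slot <- (bi - 1) %/% cfg$n_genes
  pk$gene_body <- data.frame(chrom = t_chrom[b_terr],
                             start = t_base[b_terr] + 14000 + b_slot * 1500,
                             terr = b_terr, zone = "gene_body")
  # intergenic: some inside TF-bound enhancer regions, the rest in free zones
  n_enh_tf <- min(30L, length(enh_terr))
  n_inter <- feat_counts["intergenic"]
  if (n_inter < n_enh_tf)
    stop("simulate_study: intergenic peak budget below enhancer-bound quota")
  # the 10 super regions live in SE zones; TF-bound regions are non-super
  n_super <- .apportion(cfg$enhancer_class_fractions,
                        cfg$n_enhancer_regions)["super"]
  if (cfg$n_enhancer_regions - n_super > length(enh_terr))
    stop("simulate_study: not enough territories for enhancer regions")
  zone_terr <- enh_terr[seq_len(cfg$n_enhancer_regions - n_super)]
  tf_enh_terr <- zone_terr[seq_len(n_enh_tf)]
  pk$enh <- data.frame(chrom = t_chrom[tf_enh_terr],
                       start = t_base[tf_enh_terr] + 62200,
                       terr = tf_enh_terr, zone = "intergenic")
  nf <- n_inter - n_enh_tf
  if (nf > 5 * cfg$n_genes)
    stop("simulate_study: free zones too small for the intergenic peak count")
  fi <- seq_len(nf)
  f_terr <- ((fi - 1) %% cfg$n_genes) + 1
  f_slot <- (fi - 1) %/% cfg$n_genes
  pk$free <- data.frame(chrom = t_chrom[f_terr],
                        start = t_base[f_terr] + 70000 + f_slot * 1500,
                        terr = f_terr, zone = "intergenic")
  tfa <- do.call(rbind, pk)
  tfa$end <- tfa$start + .PEAK_W
  tfa$name <- sprintf("pkA%05d", seq_len(nrow(tfa)))
  tfa$category <- ifelse(tfa$zone == "intergenic", "intergenic", tfa$zone)

  ## chromatin states --------------------------------------------------------
  state_counts <- .apportion(cfg$state_composition, cfg$n_tf_peaks)
  # enhancer-hosted peaks must not deposit K27me3 inside an enhancer region,
  # so they draw from the active pool; everything else is permuted freely
  is_enh_peak <- tfa$zone == "intergenic" & tfa$start - t_base[tfa$terr] == 62200
  if (state_counts["active_k4me3"] < sum(is_enh_peak))
    stop("simulate_study: active-state budget below enhancer-hosted peak count")
  state <- character(nrow(tfa))
  state[is_enh_peak] <- "active_k4me3"
  remaining <- rep(names(state_counts),
                   state_counts - table(factor(state[is_enh_peak],
                                               levels = names(state_counts))))
  state[!is_enh_peak] <- sample(remaining)
  tfa$state <- state

  ## co-binding flags, per state ---------------------------------------------
  cobound <- rep(FALSE, nrow(tfa))
  for (s in names(state_counts)) {
    i <- which(tfa$state == s)
    k <- round(cfg$conditional_cobind[[s]] * length(i))
    cobound[sample(i, k)] <- TRUE
  }
  tfa$cobound <- cobound

  ## mark peak sets ----------------------------------------------------------
  k4 <- tfa$state %in% c("active_k4me3", "bivalent")
  k27 <- tfa$state %in% c("repressive_k27me3", "bivalent")
  k4me3 <- peak_set(tfa$chrom[k4], tfa$start[k4] + 50, tfa$start[k4] + 150,
                    label = "H3K4me3")
  k27me3_peaks <- data.frame(chrom = tfa$chrom[k27], start = tfa$start[k27] + 250,
                             end = tfa$start[k27] + 350)

  ## TF-B peaks --------------------------------------------------------------
  co <- which(tfa$cobound)
  tfb_co <- data.frame(chrom = tfa$chrom[co], start = tfa$start[co] + 100,
                       end = tfa$start[co] + 300)
  if (cfg$n_tfb_extra > 3 * cfg$n_genes)
    stop("simulate_study: too many TF-B-only peaks for the free zones")
  xi <- seq_len(cfg$n_tfb_extra)
  x_terr <- ((xi - 1) %% cfg$n_genes) + 1
  x_slot <- (xi - 1) %/% cfg$n_genes
  tfb_extra <- data.frame(chrom = t_chrom[x_terr],
                          start = t_base[x_terr] + 70000 + (8 + x_slot) * 1500,
                          end = t_base[x_terr] + 70000 + (8 + x_slot) * 1500 + .PEAK_W)
  tfb <- peak_set(c(tfb_co$chrom, tfb_extra$chrom),
                  c(tfb_co$start, tfb_extra$start),
                  c(tfb_co$end, tfb_extra$end),
                  name = sprintf("pkB%05d", seq_len(nrow(tfb_co) + nrow(tfb_extra))),
                  label = "TFB")

  ## SE / TE regions ---------------------------------------------------------
  se <- peak_set(t_chrom[se_terr], t_base[se_terr] + 42000,
                 t_base[se_terr] + 52000,
                 name = sprintf("SE%03d", seq_along(se_terr)), label = "SE")
  te <- peak_set(t_chrom[te_terr], t_base[te_terr] + 56000,
                 t_base[te_terr] + 58000,
                 name = sprintf("TE%03d", seq_along(te_terr)), label = "TE")
  se_gene <- data.frame(se_name = sprintf("SE%03d", seq_along(se_terr)),
                        gene_id = gid[se_terr],
                        stringsAsFactors = FALSE)

  ## candidate enhancer regions + their marks --------------------------------
  enh_counts <- .apportion(cfg$enhancer_class_fractions, cfg$n_enhancer_regions)
  if (enh_counts["super"] > cfg$n_se)
    stop("simulate_study: more super regions than SEs")
  super_terr <- se_terr[seq_len(enh_counts["super"])]
  enh_regions <- data.frame(
    chrom = c(t_chrom[super_terr], t_chrom[zone_terr]),
    start = c(t_base[super_terr] + 44000, t_base[zone_terr] + 62000),
    end = c(t_base[super_terr] + 46000, t_base[zone_terr] + 64000),
    terr = c(super_terr, zone_terr),
    stringsAsFactors = FALSE)
  zone_class <- rep(c("active", "intermediate", "poised"),
                    enh_counts[c("active", "intermediate", "poised")])
  enh_regions$class <- c(rep("super", enh_counts["super"]), zone_class)
  enh_regions$name <- sprintf("ENH%03d", seq_len(nrow(enh_regions)))
  enh_regions$tf_bound <- enh_regions$terr %in% tf_enh_terr
  # marks live in the right half of each zone region, clear of hosted TF peaks
  mk <- function(cls_need) {
    i <- which(enh_regions$class %in% cls_need & enh_regions$class != "super")
    data.frame(chrom = enh_regions$chrom[i],
               start = t_base[enh_regions$terr[i]] + 63200,
               end = t_base[enh_regions$terr[i]] + 63600)
  }
  k4me1 <- do.call(rbind, list(mk(c("active", "intermediate", "poised"))))
  k27ac <- mk("active")
  k27me3_all <- rbind(k27me3_peaks, mk("poised"))
  k27me3 <- peak_set(k27me3_all$chrom, k27me3_all$start, k27me3_all$end,
                     label = "H3K27me3")
  k4me1 <- peak_set(k4me1$chrom, k4me1$start, k4me1$end, label = "H3K4me1")
  k27ac <- peak_set(k27ac$chrom, k27ac$start, k27ac$end, label = "H3K27ac")

  ## coverage tracks ---------------------------------------------------------
  bumps <- function(regions, amp) {
    out <- list()
    for (i in seq_len(nrow(regions))) {
      bs <- seq(regions$start[i], regions$end[i] - 1, by = 100)
      be <- pmin(bs + 100, regions$end[i])
      v <- if (cfg$coverage_noise == 0) rep(amp[i], length(bs)) else
        rpois(length(bs), amp[i] * (be - bs) * cfg$coverage_noise) /
          ((be - bs) * cfg$coverage_noise)
      out[[i]] <- data.frame(chrom = regions$chrom[i], start = bs, end = be,
                             value = v)
    }
    do.call(rbind, out)
  }
  tfa_df <- data.frame(chrom = tfa$chrom, start = tfa$start, end = tfa$end)
  track_tfa <- coverage_track(bumps(tfa_df, rep(4, nrow(tfa_df))))
  sete <- rbind(data.frame(chrom = se$chrom, start = se$start, end = se$end),
                data.frame(chrom = te$chrom, start = te$start, end = te$end))
  amp <- c(rep(cfg$se_te_signal_fold * cfg$te_amplitude, nrow(se)),
           rep(cfg$te_amplitude, nrow(te)))
  track_med1 <- coverage_track(bumps(sete, amp))

  ## interactions ------------------------------------------------------------
  icounts <- .apportion(cfg$interaction_class_fractions, cfg$n_interactions)
  med_counts <- .apportion(stats::setNames(
    icounts / cfg$n_interactions, names(icounts)),
    round(cfg$mediated_fraction * cfg$n_interactions))
  bait_pool <- t_idx[mod15 != 1]        # genes without promoter TF peaks
  bait_cycle <- function(n, offset = 0)
    bait_pool[((seq_len(n) - 1 + offset) %% length(bait_pool)) + 1]
  mk_int <- function(n, oe_chrom, oe_start, oe_end, iclass, mediated, offset) {
    if (n == 0) return(NULL)
    bt <- bait_cycle(n, offset)
    data.frame(bait_chrom = t_chrom[bt], bait_start = tss[bt] - 1000,
               bait_end = tss[bt] + 1000, bait_genes = gid[bt],
               oe_chrom = oe_chrom, oe_start = oe_start, oe_end = oe_end,
               iclass = iclass, mediated = mediated, stringsAsFactors = FALSE)
  }
  rows <- list()
  # P-P mediated: other end covers a promoter TF peak
  n_ppm <- med_counts["promoter_promoter"]
  pt <- prom_terr[((seq_len(n_ppm) - 1) %% length(prom_terr)) + 1]
  rows$ppm <- mk_int(n_ppm, t_chrom[pt], tss[pt] - 500, tss[pt] + 500,
                     "promoter_promoter", TRUE, 0)
  # P-P unmediated: other end is a TF-free gene's promoter
  n_ppu <- icounts["promoter_promoter"] - n_ppm
  ot <- bait_cycle(n_ppu, offset = 137)  # offset so bait != other-end gene
  rows$ppu <- mk_int(n_ppu, t_chrom[ot], tss[ot] - 500, tss[ot] + 500,
                     "promoter_promoter", FALSE, 7)
  if (!is.null(rows$ppu) && any(rows$ppu$bait_genes == gid[ot]))
    stop("simulate_study: self-loop in planted P-P pairs")
  # P-E mediated: other end is a TF-bound enhancer region
  n_pem <- med_counts["promoter_enhancer"]
  eb <- which(enh_regions$tf_bound)
  ei <- eb[((seq_len(n_pem) - 1) %% length(eb)) + 1]
  rows$pem <- mk_int(n_pem, enh_regions$chrom[ei], enh_regions$start[ei],
                     enh_regions$end[ei], "promoter_enhancer", TRUE, 11)
  # P-E unmediated: TF-free enhancer region
  n_peu <- icounts["promoter_enhancer"] - n_pem
  ef <- which(!enh_regions$tf_bound)
  ej <- ef[((seq_len(n_peu) - 1) %% length(ef)) + 1]
  rows$peu <- mk_int(n_peu, enh_regions$chrom[ej], enh_regions$start[ej],
                     enh_regions$end[ej], "promoter_enhancer", FALSE, 23)
  # other mediated: other end covers a free-zone TF peak (slot 0)
  n_om <- med_counts["promoter_other"]
  mt <- other_med_terr[((seq_len(n_om) - 1) %% length(other_med_terr)) + 1]
  rows$om <- mk_int(n_om, t_chrom[mt], t_base[mt] + 69900, t_base[mt] + 70500,
                    "promoter_other", TRUE, 31)
  # other unmediated: empty zone
  n_ou <- icounts["promoter_other"] - n_om
  ut <- other_free_terr[((seq_len(n_ou) - 1) %% length(other_free_terr)) + 1]
  rows$ou <- mk_int(n_ou, t_chrom[ut], t_base[ut] + 66000, t_base[ut] + 67000,
                    "promoter_other", FALSE, 43)
  inter <- do.call(rbind, rows)
  inter$score <- round(runif(nrow(inter), 5, 15), 3)
  rownames(inter) <- NULL

  ## DE table ----------------------------------------------------------------
  de_ids <- sprintf("g%04d", seq_len(cfg$de_n_genes))
  status <- rep("ns", cfg$de_n_genes)
  pick <- sample(cfg$de_n_genes, cfg$de_n_up + cfg$de_n_down)
  status[pick[seq_len(cfg$de_n_up)]] <- "up"
  status[pick[cfg$de_n_up + seq_len(cfg$de_n_down)]] <- "down"
  fc <- p <- numeric(cfg$de_n_genes)
  i <- status == "up"
  fc[i] <- runif(sum(i), 1.4, 3.0); p[i] <- runif(sum(i), 1e-6, 0.049)
  i <- status == "down"
  fc[i] <- runif(sum(i), 0.33, 0.71); p[i] <- runif(sum(i), 1e-6, 0.049)
  i <- status == "ns"
  # most null genes have flat fold changes; a slice has large fold but p >= 0.05
  big <- i & (seq_len(cfg$de_n_genes) %% 10 == 0)
  fc[i] <- runif(sum(i), 0.86, 1.16); p[i] <- runif(sum(i), 0, 1)
  fc[big] <- runif(sum(big), 1.4, 2.5); p[big] <- runif(sum(big), 0.06, 1)
  de <- data.frame(gene_id = de_ids, fold_change = round(fc, 6),
                   p_value = signif(p, 6), stringsAsFactors = FALSE)

  ## write bundle ------------------------------------------------------------
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(out_dir, x)
  write_chrom_sizes(sizes, fp("genome.chrom.sizes"))
  write_gene_table(genes, fp("genes.tsv"))
  tfa_ps <- peak_set(tfa$chrom, tfa$start, tfa$end, name = tfa$name,
                     label = "TFA")
  write_bed(tfa_ps, fp("tfa_peaks.bed"))
  write_bed(tfb, fp("tfb_peaks.bed"))
  write_bed(k4me3, fp("h3k4me3.bed"))
  write_bed(k27me3, fp("h3k27me3.bed"))
  write_bed(k4me1, fp("h3k4me1.bed"))
  write_bed(k27ac, fp("h3k27ac.bed"))
  write_bed(se, fp("se_regions.bed"))
  write_bed(te, fp("te_regions.bed"))
  enh_ps <- peak_set(enh_regions$chrom, enh_regions$start, enh_regions$end,
                     name = enh_regions$name, label = "enhancer_candidates")
  write_bed(enh_ps, fp("enhancer_regions.bed"))
  write_bedgraph(track_tfa, fp("tfa_coverage.bedGraph"))
  write_bedgraph(track_med1, fp("med1_coverage.bedGraph"))
  write_interactions(inter[, c("bait_chrom", "bait_start", "bait_end",
                               "bait_genes", "oe_chrom", "oe_start", "oe_end",
                               "score")], fp("interactions.tsv"))
  write_de_table(de, fp("de_table.tsv"))

  manifest <- list(
    schema_version = "1.0",
    config = unclass(cfg),
    files = list(chrom_sizes = "genome.chrom.sizes", genes = "genes.tsv",
                 tfa = "tfa_peaks.bed", tfb = "tfb_peaks.bed",
                 k4me3 = "h3k4me3.bed", k27me3 = "h3k27me3.bed",
                 k4me1 = "h3k4me1.bed", k27ac = "h3k27ac.bed",
                 se = "se_regions.bed", te = "te_regions.bed",
                 enhancer_regions = "enhancer_regions.bed",
                 tfa_coverage = "tfa_coverage.bedGraph",
                 med1_coverage = "med1_coverage.bedGraph",
                 interactions = "interactions.tsv", de = "de_table.tsv"),
    state_counts = as.list(state_counts),
    state_fractions = as.list(state_counts / cfg$n_tf_peaks),
    feature_counts = as.list(feat_counts),
    feature_fractions = as.list(feat_counts / cfg$n_tf_peaks),
    cobind_fraction = sum(cobound) / nrow(tfa),
    n_cobound = sum(cobound),
    conditional_cobind = lapply(names(state_counts), function(s) {
      i <- tfa$state == s
      list(stratum = s, n = sum(i), fraction = sum(cobound[i]) / sum(i))
    }),
    enhancer_class_counts = as.list(enh_counts),
    se_gene_map = se_gene,
    interaction_class_counts = as.list(icounts),
    interaction_class_fractions = as.list(icounts / cfg$n_interactions),
    n_mediated = sum(inter$mediated),
    mediated_fraction = sum(inter$mediated) / nrow(inter),
    de_counts = list(n_up = sum(status == "up"),
                     n_down = sum(status == "down"),
                     n_ns = sum(status == "ns")),
    total_signal = list(tfa_coverage = track_tfa$total_signal,
                        med1_coverage = track_med1$total_signal),
    peak_truth = data.frame(name = tfa$name, state = tfa$state,
                            category = tfa$category, cobound = tfa$cobound,
                            stringsAsFactors = FALSE),
    interaction_truth = data.frame(bait_gene = inter$bait_genes,
                                   iclass = inter$iclass,
                                   mediated = inter$mediated,
                                   stringsAsFactors = FALSE),
    de_truth = data.frame(gene_id = de_ids, status = status,
                          stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Degrade a synthetic bundle
#'
#' Robustness fixture: translates every TF peak by a uniform integer in
#' `[-jitter_bp, jitter_bp]` and drops a fixed fraction of peaks (exactly
#' `round(n * dropout)` entries, seeded), writing degraded copies of the TF-A
#' and TF-B peak files and an updated manifest listing dropped entities.
#'
#' @param bundle_dir directory written by [simulate_study()].
#' @param jitter_bp maximum absolute shift in bp.
#' @param dropout fraction of peaks to drop, in \[0, 1).
#' @param seed integer seed.
#' @param out_dir output directory (default: degrade in place).
#' @return updated manifest, invisibly.
#' @export
degrade <- function(bundle_dir, jitter_bp = 0, dropout = 0, seed = 1,
                    out_dir = bundle_dir) {
  stopifnot(jitter_bp >= 0, dropout >= 0, dropout < 1)
  set.seed(as.integer(seed))
  manifest <- jsonlite::read_json(file.path(bundle_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (out_dir != bundle_dir) {
    for (f in list.files(bundle_dir))
      file.copy(file.path(bundle_dir, f), file.path(out_dir, f),
                overwrite = TRUE)
  }
  dropped <- list()
  for (key in c("tfa", "tfb")) {
    f <- manifest$files[[key]]
    ps <- read_bed(file.path(bundle_dir, f))
    n <- nrow(ps)
    keep <- sort(sample(n, n - round(n * dropout)))
    ps <- ps[keep, , drop = FALSE]
    shift <- if (jitter_bp > 0)
      sample(seq(-jitter_bp, jitter_bp), nrow(ps), replace = TRUE) else 0
    out <- peak_set(ps$chrom, pmax(0, ps$start + shift), ps$end + shift,
                    name = ps$name, label = key)
    write_bed(out, file.path(out_dir, f))
    dropped[[key]] <- setdiff(seq_len(n), keep)
  }
  manifest$degrade <- list(jitter_bp = jitter_bp, dropout = dropout,
                           seed = seed,
                           n_dropped = vapply(dropped, length, integer(1)),
                           dropped_rows = dropped)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
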