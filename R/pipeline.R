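#' Study configuration with literature defaults
#'
#' Collects every tunable of the pipeline in one list. Defaults follow
#' the published analysis conventions where stated: MAF filter 0.05,
#' missingness 0.5, candidate flank 300 kb, BSA window 1.5 Mb at 99%
#' confidence, 30/30 extreme pools, LD block threshold r^2 = 0.8.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @param n_lines,markers_per_chrom synthetic panel shape.
#' @param n_qtl,effect_frac,n_carriers planted-QTL design.
#' @param basis_traits,orientation MFVD basis.
#' @param grade_cutoffs MFVD grade cutoffs (NULL: mean +/- 1.5, 0.5 sd).
#' @param maf_min,missing_max marker filter.
#' @param gwas_traits phenotypes scanned (DRC columns and/or "mfvd").
#' @param merge_bp peak-merge distance for scan-derived QTL.
#' @param lod_min linkage LOD threshold.
#' @param p_enter,p_exit,exclusion_bp stepwise scan tunables.
#' @param pool_k,mean_depth,min_depth,window_bp,step_bp,min_sites,level,n_sims
#'   BSA tunables.
#' @param flank_bp candidate-interval flank.
#' @param r2_min LD block threshold.
#' @param min_overlap_bp colocalization overlap rule.
#' @param run_bsa run the BSA stage (FALSE skips it; integration then
#'   uses GWAS and linkage records only).
#' @param out_dir optional directory for all intermediate tables.
#' @return a named list (class `study_config`).
#' @export
study_config <- function(seed = 1L,
                         n_lines = 319, markers_per_chrom = 400,
                         n_qtl = 5, effect_frac = 0.08, n_carriers = 30,
                         basis_traits = c("BW", "LW", "LP", "EBN",
                                          "FUHML", "FS", "MV", "FU"),
                         orientation = NULL,
                         grade_cutoffs = NULL,
                         maf_min = 0.05, missing_max = 0.5,
                         gwas_traits = NULL,
                         merge_bp = 1e6,
                         lod_min = 2.5, p_enter = 0.01, p_exit = 0.02,
                         exclusion_bp = 5e6,
                         pool_k = 30, mean_depth = 50, min_depth = 10,
                         window_bp = 1.5e6, step_bp = 1e5, min_sites = 3,
                         level = 0.99, n_sims = 10000,
                         flank_bp = 3e5, r2_min = 0.8,
                         min_overlap_bp = 1,
                         run_bsa = TRUE,
                         out_dir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "study_config"
  cfg
}

#' Run the full drought-QTL pipeline on a synthetic CSSL study
#'
#' Executes every stage end to end: simulate the study; fit BLUPs and
#' the phenomics statistics (DRC, MFVD, grades, correlation network);
#' filter markers, estimate kinship and run the mixed-model association
#' scan for each DRC basis trait and MFVD; build the bin map and run the
#' stepwise likelihood-ratio linkage scan; select MFVD extreme pools,
#' simulate pooled depths and call delta-SNP-index intervals against the
#' CSSL-aware confidence bands; then name, co-localize and haplotype the
#' QTL and run the pyramiding analysis. With `out_dir` set, every
#' intermediate table is written as commented TSV (intervals also as
#' BED-like files), so identical configurations and seeds produce
#' byte-identical output trees.
#'
#' @param config a [study_config()].
#' @return list with every stage's tables plus the truth and recovery
#'   summary.
#' @export
run_pipeline <- function(config = study_config()) {
  cfg <- config
  t0 <- Sys.time()
  log_msg <- function(...) message(sprintf("[cssldrought] %s", sprintf(...)))

  ## --- simulate -------------------------------------------------------
  truth <- default_truth(n_qtl = cfg$n_qtl, effect_frac = cfg$effect_frac,
                         seed = cfg$seed)
  study <- simulate_cssl_study(seed = cfg$seed, n_lines = cfg$n_lines,
                               markers_per_chrom = cfg$markers_per_chrom,
                               truth = truth, n_carriers = cfg$n_carriers)
  log_msg("simulated %d lines x %d markers, %d planted QTL",
          nrow(study$genotypes), ncol(study$genotypes),
          nrow(unique(study$truth$qtl[, c("chrom", "pos_bp")])))

  ## --- phenomics ------------------------------------------------------
  blups <- blup_table(study$observations)
  summaries <- do.call(rbind, lapply(unique(blups$trait), function(tr)
    summarize_condition(blups, tr)))
  drc <- compute_drc(blups)
  mfvd <- compute_mfvd(drc, basis_traits = cfg$basis_traits,
                       orientation = cfg$orientation)
  grading <- grade_lines(mfvd, cutoffs = cfg$grade_cutoffs)
  network <- correlation_network(drc)
  log_msg("phenomics done: %d graded lines, %d network edges",
          nrow(grading$grades), nrow(network))

  ## --- GWAS -----------------------------------------------------------
  flt <- filter_markers(study$genotypes, study$info,
                        maf_min = cfg$maf_min, missing_max = cfg$missing_max)
  K <- compute_kinship(flt$genotypes)
  thr <- association_thresholds(nrow(flt$info))
  gwas_traits <- cfg$gwas_traits %||%
    c(paste0("DRC_", cfg$basis_traits), "mfvd")
  pheno_tbl <- merge(drc, mfvd[, c("line_id", "mfvd")], by = "line_id")
  scans <- list(); gwas_qtl <- list()
  for (tr in gwas_traits) {
    y <- stats::setNames(pheno_tbl[[tr]], pheno_tbl$line_id)
    sc <- mlm_scan(flt$genotypes, flt$info, y, K)
    scans[[tr]] <- sc
    lab <- if (tr == "mfvd") "MFVD" else tr
    gwas_qtl[[tr]] <- qtl_from_scan(sc, thr$suggestive, trait = lab,
                                    merge_bp = cfg$merge_bp)
  }
  gwas_qtl <- do.call(rbind, gwas_qtl)
  rownames(gwas_qtl) <- NULL
  log_msg("GWAS: %d markers scanned, %d QTL at p < %.3g",
          nrow(flt$info), nrow(gwas_qtl), thr$suggestive)

  ## --- linkage --------------------------------------------------------
  bin_map <- build_bin_map(study$genotypes, study$info, study$chrom_map)
  link_qtl <- list()
  link_scans <- list()
  for (tr in gwas_traits) {
    y <- stats::setNames(pheno_tbl[[tr]], pheno_tbl$line_id)
    sc <- rstep_lrt_add_scan(bin_map, y, p_enter = cfg$p_enter,
                             p_exit = cfg$p_exit,
                             exclusion_bp = cfg$exclusion_bp)
    link_scans[[tr]] <- sc
    lab <- if (tr == "mfvd") "MFVD" else tr
    link_qtl[[tr]] <- qtl_from_linkage(sc, lod_min = cfg$lod_min, trait = lab,
                                       merge_bp = cfg$merge_bp)
  }
  link_qtl <- do.call(rbind, link_qtl)
  rownames(link_qtl) <- NULL
  log_msg("linkage: %d bins, %d QTL at LOD >= %.1f",
          nrow(bin_map$bins), nrow(link_qtl), cfg$lod_min)

  ## --- BSA ------------------------------------------------------------
  if (isTRUE(cfg$run_bsa)) {
  pools <- select_extreme_pools(mfvd, k = cfg$pool_k)
  depths <- simulate_pool_depths(study$genotypes, study$info,
                                 pools$resistant$line_ids,
                                 pools$sensitive$line_ids,
                                 mean_depth = cfg$mean_depth,
                                 seed = child_seed(cfg$seed, 3))
  idx <- snp_index(depths, min_depth = cfg$min_depth)
  pf <- colMeans(study$genotypes, na.rm = TRUE) / 2
  idx <- confidence_bands(idx, pop_freq = pf[match(idx$marker_id,
                                                   study$info$marker_id)],
                          pool_size = cfg$pool_k, level = cfg$level,
                          n_sims = cfg$n_sims,
                          seed = child_seed(cfg$seed, 4))
  windows <- sliding_windows(idx, chrom_lengths = study$chrom_map,
                             window_bp = cfg$window_bp,
                             step_bp = cfg$step_bp,
                             min_sites = cfg$min_sites)
  bsa_qtl <- call_bsa_intervals(windows)
  log_msg("BSA: %d sites, %d windows, %d intervals",
          nrow(idx), nrow(windows), nrow(bsa_qtl))
  } else {
    pools <- NULL; idx <- NULL; windows <- NULL
    bsa_qtl <- call_bsa_intervals(
      data.frame(chrom = character(0), start_bp = numeric(0),
                 end_bp = numeric(0), n_sites = integer(0),
                 mean_delta = numeric(0), lower = numeric(0),
                 upper = numeric(0), flagged = logical(0)))
    log_msg("BSA stage skipped")
  }

  ## --- integration ----------------------------------------------------
  all_qtl <- name_qtl(rbind(gwas_qtl, link_qtl, bsa_qtl))
  coloc <- colocalize(all_qtl, min_overlap_bp = cfg$min_overlap_bp)
  gw <- name_qtl(gwas_qtl)
  calls <- classify_haplotypes(study$genotypes, study$info, gw)
  per_qtl_trait <- stats::setNames(
    ifelse(gw$trait == "MFVD", "mfvd", gw$trait), gw$name)
  resistant <- choose_resistant_haplotype(calls, pheno_tbl, per_qtl_trait)
  pyramiding <- if (sum(resistant$scorable) >= 2)
    pyramiding_analysis(calls, resistant, mfvd) else NULL
  recovery <- evaluate_recovery(all_qtl, study$truth)
  log_msg("integration: %d groups (%d multi-method); pyramiding r = %s",
          coloc$counts["n_groups"], coloc$counts["multi_method"],
          if (is.null(pyramiding)) "NA" else sprintf("%.2f", pyramiding$r))

  bundle <- list(config = cfg, truth = study$truth, study = study,
                 blups = blups, summaries = summaries, drc = drc,
                 mfvd = mfvd, grading = grading, network = network,
                 filter = flt$counts, thresholds = thr, scans = scans,
                 gwas_qtl = gwas_qtl, bin_map = bin_map,
                 link_scans = link_scans, link_qtl = link_qtl,
                 pools = pools, snp_index = idx, windows = windows,
                 bsa_qtl = bsa_qtl, qtl = all_qtl, coloc = coloc,
                 haplotypes = calls, resistant = resistant,
                 pyramiding = pyramiding, recovery = recovery,
                 elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(cfg$out_dir)) write_bundle(bundle, cfg$out_dir)
  bundle
}

#' Score planted-QTL recovery of each mapping method
#'
#' A planted QTL counts as recovered by a method when the method reports
#' an interval whose distance to the true position is at most `tol_bp`
#' (zero when the interval covers the position).
#'
#' @param qtl combined QTL records.
#' @param truth a [cssl_truth()].
#' @param tol_bp recovery tolerance (default 2 Mb).
#' @return data.frame per true locus x method: `chrom`, `pos_bp`,
#'   `method`, `recovered`, `distance_bp`.
#' @export
evaluate_recovery <- function(qtl, truth, tol_bp = 2e6) {
  loci <- unique(truth$qtl[, c("chrom", "pos_bp")])
  methods <- c("gwas", "linkage", "bsa")
  out <- list()
  for (i in seq_len(nrow(loci))) for (m in methods) {
    r <- qtl[qtl$method == m & qtl$chrom == loci$chrom[i], , drop = FALSE]
    d <- if (nrow(r) == 0) Inf else
      min(pmax(0, pmax(r$start_bp - loci$pos_bp[i],
                       loci$pos_bp[i] - r$end_bp)))
    out[[length(out) + 1L]] <- data.frame(
      chrom = loci$chrom[i], pos_bp = loci$pos_bp[i], method = m,
      recovered = d <= tol_bp, distance_bp = d, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f, comment) write_table_commented(x, file.path(dir, f), comment)
  w(bundle$blups, "blups.tsv",
    "per-line BLUP values (trait units) by trait and condition")
  w(bundle$summaries, "trait_summaries.tsv",
    "condition means (trait units), percent change, sd, cv = sd/mean")
  w(bundle$drc, "drc.tsv",
    "drought-resistance coefficient DRC = drought BLUP / control BLUP (dimensionless)")
  w(bundle$mfvd, "mfvd.tsv",
    "membership-function value of drought resistance, in [0,1]")
  w(bundle$grading$grades, "grades.tsv",
    "five-level drought-resistance grade (I sensitive .. V tolerant)")
  w(bundle$network, "correlation_network.tsv",
    "Pearson correlations of DRC traits; significant: p<0.05 and |r|>0.1")
  w(bundle$qtl, "qtl.tsv",
    "QTL records, 1-based inclusive coordinates; statistic: -log10 p (gwas), LOD (linkage), max |delta index| (bsa)")
  write_intervals_bed(bundle$qtl, file.path(dir, "qtl.bed"))
  w(bundle$coloc$groups, "coloc_groups.tsv",
    "single-linkage overlap groups across mapping methods")
  w(bundle$haplotypes, "haplotypes.tsv",
    "per-line haplotype call at each GWAS QTL peak SNP")
  w(bundle$resistant, "resistant_haplotypes.tsv",
    "drought-resistant haplotype per QTL with Welch contrast p")
  if (!is.null(bundle$pyramiding))
    w(bundle$pyramiding$counts, "pyramiding.tsv",
      "per-line count of resistant haplotypes vs MFVD")
  if (!is.null(bundle$windows))
    w(bundle$windows, "bsa_windows.tsv",
      "delta SNP-index in 1.5 Mb windows with 99% confidence band")
  w(bundle$recovery, "recovery.tsv",
    "planted-QTL recovery per method (distance in bp, tolerance 2 Mb)")
  write_truth(bundle$truth, file.path(dir, "truth"))
  invisible(dir)
}
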