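# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# A small two-chromosome CSSL study with two planted pleiotropic QTL:
# 120 lines, 80 markers per chromosome, phenotypes for all 14 traits.
small_study <- function() {
  if (!is.null(.fixtures$small)) return(.fixtures$small)
  cm <- cotton_chrom_map()
  cm <- cm[cm$name %in% c("A11", "D09"), ]
  truth <- default_truth(n_qtl = 2, seed = 3)
  anchors <- data.frame(chrom = unique(truth$qtl$chrom),
                        pos_bp = unique(truth$qtl$pos_bp),
                        n_carriers = 20)
  sim <- simulate_cssl_genotypes(cm, n_lines = 120, markers_per_chrom = 80,
                                 anchors = anchors, seed = 3)
  for (i in seq_len(nrow(truth$qtl))) {
    oc <- sim$info[sim$info$chrom == truth$qtl$chrom[i], ]
    truth$qtl$pos_bp[i] <- oc$pos_bp[which.min(abs(oc$pos_bp -
                                                     truth$qtl$pos_bp[i]))]
  }
  obs <- simulate_phenotypes(sim$segments, truth, rownames(sim$genotypes),
                             info = sim$info, seed = 4)
  blups <- blup_table(obs)
  drc <- compute_drc(blups)
  mfvd <- compute_mfvd(drc)
  .fixtures$small <- list(chrom_map = cm, sim = sim, truth = truth,
                          obs = obs, blups = blups, drc = drc, mfvd = mfvd)
  .fixtures$small
}

# The full default study bundle (319 lines, 26 chromosomes, 5 QTL),
# shared by the acceptance tests.
default_bundle <- function() {
  if (!is.null(.fixtures$bundle)) return(.fixtures$bundle)
  .fixtures$bundle <- suppressMessages(run_pipeline(study_config(seed = 1)))
  .fixtures$bundle
}

# Balanced two-year, two-replicate observation table from a per-line
# generative model; used by the BLUP oracle tests.
make_obs <- function(n_lines, sg = 1, se = 1, year_eff = c(0, 0),
                     seed = 1) {
  set.seed(seed)
  line_ids <- sprintf("L%02d", seq_len(n_lines))
  g <- rnorm(n_lines, 0, sg)
  out <- expand.grid(line_id = line_ids, year = 1:2, replicate = 1:2,
                     stringsAsFactors = FALSE)
  out$trait <- "T"
  out$condition <- "control"
  out$value <- 10 + g[match(out$line_id, line_ids)] +
    year_eff[out$year] + rnorm(nrow(out), 0, se)
  out
}
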