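cm2 <- cotton_chrom_map()[c(1, 14), ]   # A01, D01

test_that("recurrent-parent identity: a line with no segments is all zero", {
  seg <- data.frame(line_id = character(0), chrom = character(0),
                    start_bp = numeric(0), end_bp = numeric(0),
                    dosage = integer(0))
  sim <- simulate_cssl_genotypes(cm2, n_lines = 1, markers_per_chrom = 10,
                                 segments = seg, missing_rate = 0, seed = 1)
  expect_true(all(sim$genotypes == 0))
})

test_that("a homozygous segment spanning a chromosome codes all its markers 2", {
  seg <- data.frame(line_id = "L001", chrom = "A01", start_bp = 1,
                    end_bp = cm2$length_bp[1], dosage = 2L)
  sim <- simulate_cssl_genotypes(cm2, n_lines = 1, markers_per_chrom = 12,
                                 segments = seg, missing_rate = 0,
                                 donor_cap = 1, seed = 1)
  on_a01 <- sim$info$chrom == "A01"
  expect_true(all(sim$genotypes[1, on_a01] == 2))
  expect_true(all(sim$genotypes[1, !on_a01] == 0))
})

test_that("marker donor frequencies equal a brute-force segment recount", {
  sim <- simulate_cssl_genotypes(cm2, n_lines = 60, markers_per_chrom = 40,
                                 missing_rate = 0, seed = 11)
  freq <- colMeans(sim$genotypes) / 2
  recount <- vapply(seq_len(nrow(sim$info)), function(j) {
    ch <- sim$info$chrom[j]; pos <- sim$info$pos_bp[j]
    hit <- sim$segments$chrom == ch & sim$segments$start_bp <= pos &
      sim$segments$end_bp >= pos
    sum(sim$segments$dosage[hit]) / (2 * 60)
  }, numeric(1))
  expect_equal(unname(freq), recount)
})

test_that("generator enforces its preconditions", {
  bad_cm <- data.frame(name = "X", length_bp = 0)
  expect_error(simulate_cssl_genotypes(bad_cm, 2, 10), "positive")
  seg <- data.frame(line_id = "L001", chrom = "A01", start_bp = 1,
                    end_bp = cm2$length_bp[1], dosage = 2L)
  expect_error(
    simulate_cssl_genotypes(cm2, 1, 10, segments = seg, donor_cap = 0.01),
    "cap")
  expect_error(simulate_cssl_genotypes(cm2, 2, 1), "markers_per_chrom")
})

test_that("genotype entries stay in {0,1,2,NA} and respect the donor cap", {
  sim <- simulate_cssl_genotypes(cm2, n_lines = 50, markers_per_chrom = 40,
                                 het_prob = 0.3, seed = 5)
  expect_true(all(sim$genotypes %in% c(0L, 1L, 2L, NA)))
  donor_bp <- tapply(sim$segments$end_bp - sim$segments$start_bp + 1,
                     sim$segments$line_id, sum)
  expect_true(all(donor_bp <= 0.10 * sum(cm2$length_bp)))
})

test_that("identical seeds reproduce identical studies", {
  a <- simulate_cssl_genotypes(cm2, 30, 20, seed = 42)
  b <- simulate_cssl_genotypes(cm2, 30, 20, seed = 42)
  expect_identical(a, b)
  o1 <- simulate_phenotypes(a$segments, default_truth(n_qtl = 0, seed = 1),
                            rownames(a$genotypes), seed = 9)
  o2 <- simulate_phenotypes(a$segments, default_truth(n_qtl = 0, seed = 1),
                            rownames(a$genotypes), seed = 9)
  expect_identical(o1, o2)
})

test_that("noise-free phenotypes reduce to means plus QTL effects", {
  truth <- default_truth(n_qtl = 0, seed = 1)
  truth$variance_components[, c("genetic", "year", "rep", "residual")] <- 0
  seg <- data.frame(line_id = "L001", chrom = "A01", start_bp = 1,
                    end_bp = cm2$length_bp[1], dosage = 2L)
  sim <- simulate_cssl_genotypes(cm2, n_lines = 4, markers_per_chrom = 10,
                                 segments = seg, missing_rate = 0,
                                 donor_cap = 1, seed = 1)
  obs <- simulate_phenotypes(sim$segments, truth, rownames(sim$genotypes),
                             seed = 2)
  mm <- truth$trait_means
  expected <- mm$mean[match(paste(obs$trait, obs$condition),
                            paste(mm$trait, mm$condition))]
  expect_equal(obs$value, expected)

  ## one QTL, drought-only effect -5: carriers shift by exactly -5 there
  truth2 <- truth
  truth2$qtl <- data.frame(chrom = "A01", pos_bp = sim$info$pos_bp[3],
                           trait = "FS", effect_control = 0,
                           effect_drought = -5, stringsAsFactors = FALSE)
  obs2 <- simulate_phenotypes(sim$segments, truth2, rownames(sim$genotypes),
                              info = sim$info, seed = 2)
  fs <- obs2[obs2$trait == "FS", ]
  carrier <- fs$line_id == "L001"
  drought <- fs$condition == "drought"
  expect_equal(unique(fs$value[carrier & drought] -
                        fs$value[!carrier & drought]), -5)
  expect_equal(unique(fs$value[carrier & !drought] -
                        fs$value[!carrier & !drought]), 0)
})

test_that("QTL positions must coincide with markers; variances must be >= 0", {
  truth <- default_truth(n_qtl = 1, seed = 1)
  sim <- simulate_cssl_genotypes(cotton_chrom_map(), 5, 10, seed = 1)
  truth$qtl$pos_bp <- truth$qtl$pos_bp + 7   # off-grid
  expect_error(simulate_phenotypes(sim$segments, truth,
                                   rownames(sim$genotypes), info = sim$info),
               "coincide")
  vc <- default_truth(n_qtl = 0)$variance_components
  vc$genetic[1] <- -1
  expect_error(cssl_truth(data.frame(chrom = character(0), pos_bp = numeric(0),
                                     trait = character(0),
                                     effect_control = numeric(0),
                                     effect_drought = numeric(0)),
                          default_trait_means(), vc), ">= 0")
})

test_that("realized line-mean heritability matches the variance components", {
  ## H2 of line means = genetic / (genetic + residual/(years*reps))
  truth <- default_truth(n_qtl = 0, seed = 1)
  sim <- simulate_cssl_genotypes(cm2, n_lines = 300, markers_per_chrom = 5,
                                 seed = 8)
  obs <- simulate_phenotypes(sim$segments, truth, rownames(sim$genotypes),
                             n_years = 2, n_reps = 2, seed = 21)
  d <- obs[obs$trait == "PH" & obs$condition == "control", ]
  lm_ <- tapply(d$value, d$line_id, mean)
  vc <- truth$variance_components
  v <- vc[vc$trait == "PH" & vc$condition == "control", ]
  expected_h2 <- v$genetic / (v$genetic + v$residual / 4)
  ## realized genetic variance via decomposition: var(line means) net of
  ## the residual share
  realized_h2 <- (stats::var(lm_) - v$residual / 4) / stats::var(lm_)
  expect_lt(abs(realized_h2 - expected_h2), 0.05)
})

test_that("phenotype decomposition leaves residuals at the residual variance", {
  truth <- default_truth(n_qtl = 0, seed = 1)
  sim <- simulate_cssl_genotypes(cm2, n_lines = 200, markers_per_chrom = 5,
                                 seed = 12)
  obs <- simulate_phenotypes(sim$segments, truth, rownames(sim$genotypes),
                             seed = 22)
  d <- obs[obs$trait == "BW" & obs$condition == "drought", ]
  ## removing line and year-replicate cell means leaves pure residual
  cell <- paste(d$year, d$replicate)
  fit <- stats::lm(value ~ line_id + cell, data = d)
  res_var <- sum(stats::resid(fit)^2) / fit$df.residual
  v <- truth$variance_components
  sigma2 <- v$residual[v$trait == "BW" & v$condition == "drought"]
  expect_lt(abs(res_var / sigma2 - 1), 0.2)
})

test_that("pool depths follow the pool allele frequencies", {
  g <- matrix(0L, 8, 6, dimnames = list(sprintf("L%d", 1:8),
                                        sprintf("M%d", 1:6)))
  g[1:4, ] <- 2L                      # pool a: all donor-homozygous
  info <- data.frame(marker_id = colnames(g), chrom = "A01",
                     pos_bp = 1:6 * 1e6)
  dp <- simulate_pool_depths(g, info, sprintf("L%d", 1:4), sprintf("L%d", 5:8),
                             mean_depth = 30, seed = 2)
  expect_true(all(dp$recurrent_a == 0))          # donor freq 1: all donor reads
  expect_true(all(dp$donor_b == 0))              # recurrent pool: none
  expect_error(simulate_pool_depths(g, info, "L1", "L1"), "disjoint")
  expect_error(simulate_pool_depths(g, info, "L1", "L2", mean_depth = 0),
               "positive")
})

test_that("pooled donor fraction is binomial around the pool frequency", {
  set.seed(31)
  n_sites <- 10000
  g <- matrix(0L, 60, n_sites)
  rownames(g) <- sprintf("L%03d", 1:60)
  carriers <- sample(1:30, 9)                    # pool freq 9/30 = 0.3
  g[carriers, ] <- 2L
  info <- data.frame(marker_id = sprintf("M%d", 1:n_sites), chrom = "A01",
                     pos_bp = seq_len(n_sites) * 1000)
  dp <- simulate_pool_depths(g, info, rownames(g)[1:30], rownames(g)[31:60],
                             mean_depth = 50, seed = 5)
  frac <- dp$donor_a / (dp$donor_a + dp$recurrent_a)
  se <- stats::sd(frac) / sqrt(n_sites)
  expect_lt(abs(mean(frac) - 0.3), 3 * se)
})

test_that("anchored loci segregate at the requested carrier count", {
  anchors <- data.frame(chrom = "A01", pos_bp = 50e6, n_carriers = 15)
  sim <- simulate_cssl_genotypes(cm2, n_lines = 100, markers_per_chrom = 40,
                                 anchors = anchors, missing_rate = 0,
                                 donor_cap = 0.3, seed = 6)
  j <- which.min(abs(sim$info$pos_bp - 50e6) +
                   (sim$info$chrom != "A01") * 1e12)
  expect_gte(sum(sim$genotypes[, j] == 2), 12)   # near 15, minus cap skips
})
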