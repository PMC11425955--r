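test_that("marker filter removes monomorphic and high-missing markers", {
  set.seed(1)
  n <- 40
  g <- cbind(mono = rep(0L, n),
             miss = c(rep(NA, 24), rbinom(16, 2, 0.5)),
             ok = rbinom(n, 2, 0.4))
  info <- data.frame(marker_id = colnames(g), chrom = "A01",
                     pos_bp = c(1e6, 2e6, 3e6))
  flt <- filter_markers(g, info)
  expect_equal(flt$info$marker_id, "ok")
  expect_equal(unname(flt$counts["removed"]), 2L)
})

test_that("surviving marker count equals a brute-force recount", {
  set.seed(2)
  n <- 80; m <- 1000
  f <- runif(m, 0, 0.3)
  g <- vapply(f, function(p) rbinom(n, 2, p), integer(n))
  g[sample(length(g), 4000)] <- NA
  info <- data.frame(marker_id = sprintf("M%d", 1:m), chrom = "A01",
                     pos_bp = seq_len(m) * 1e4)
  flt <- filter_markers(g, info, maf_min = 0.05, missing_max = 0.5)
  keep <- vapply(seq_len(m), function(j) {
    x <- g[, j]
    fr <- mean(x, na.rm = TRUE) / 2
    maf <- min(fr, 1 - fr)
    !is.nan(maf) && maf > 0.05 && mean(is.na(x)) < 0.5
  }, logical(1))
  expect_equal(unname(flt$counts["retained"]), sum(keep))
})

test_that("association thresholds are 1/M and 0.05/M", {
  thr <- association_thresholds(1309780)
  expect_equal(signif(thr$suggestive, 6), 7.63487e-07)
  expect_equal(signif(thr$significant, 6), 3.81743e-08)
  thr2 <- association_thresholds(20)
  expect_equal(thr2$suggestive, 0.05)
  expect_equal(thr2$significant, 0.0025)
})

test_that("kinship matches a brute-force double loop and basic structure", {
  set.seed(3)
  g <- matrix(rbinom(100, 2, 0.4), 5, 20)
  rownames(g) <- sprintf("L%d", 1:5)
  K <- compute_kinship(g)
  p <- colMeans(g) / 2
  cc <- sum(2 * p * (1 - p))
  Kbf <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5)
    Kbf[i, j] <- sum((g[i, ] - 2 * p) * (g[j, ] - 2 * p)) / cc
  expect_equal(unname(K), Kbf, tolerance = 1e-12)
  ## identical lines have off-diagonal equal to their diagonals
  g2 <- rbind(g, g[1, , drop = FALSE])
  rownames(g2) <- sprintf("L%d", 1:6)
  K2 <- compute_kinship(g2)
  expect_equal(K2[1, 6], K2[1, 1])
  ## unrelated lines: off-diagonals shrink to zero at many markers
  set.seed(4)
  g3 <- matrix(rbinom(20 * 10000, 2, 0.3), 20, 10000)
  rownames(g3) <- sprintf("L%02d", 1:20)
  K3 <- compute_kinship(g3)
  expect_lt(mean(abs(K3[upper.tri(K3)])), 0.1)
  expect_error(compute_kinship(matrix(NA_integer_, 2, 3)), "missing")
})

test_that("with identity kinship the mixed-model scan reduces to OLS", {
  set.seed(5)
  n <- 60; m <- 30
  g <- matrix(rbinom(n * m, 2, 0.4), n, m,
              dimnames = list(sprintf("L%02d", 1:n), sprintf("M%d", 1:m)))
  info <- data.frame(marker_id = colnames(g), chrom = "A01",
                     pos_bp = seq_len(m) * 1e5)
  y <- setNames(rnorm(n), rownames(g))
  sc <- mlm_scan(g, info, y, diag(n))
  p_ols <- vapply(seq_len(m), function(j)
    summary(lm(y ~ g[, j]))$coefficients[2, 4], numeric(1))
  expect_equal(-log10(sc$p), -log10(p_ols), tolerance = 1e-6)
})

test_that("a marker perfectly collinear with the phenotype underflows", {
  set.seed(6)
  n <- 50
  x <- rbinom(n, 2, 0.5)
  g <- cbind(M1 = x, M2 = rbinom(n, 2, 0.5))
  rownames(g) <- sprintf("L%02d", 1:n)
  info <- data.frame(marker_id = colnames(g), chrom = "A01",
                     pos_bp = c(1e6, 2e6))
  y <- setNames(as.numeric(x), rownames(g))
  sc <- mlm_scan(g, info, y, diag(n))
  expect_gt(sc$neg_log10_p[1], 15)
})

test_that("the scan is invariant to allele-coding flips", {
  st <- small_study()
  flt <- filter_markers(st$sim$genotypes, st$sim$info)
  K <- compute_kinship(flt$genotypes)
  y <- setNames(st$drc$DRC_FS, st$drc$line_id)
  sub <- 1:40
  g1 <- flt$genotypes[, sub]
  g2 <- 2L - g1
  sc1 <- mlm_scan(g1, flt$info[sub, ], y, K)
  sc2 <- mlm_scan(g2, flt$info[sub, ], y, K)
  expect_equal(sc1$beta, -sc2$beta, tolerance = 1e-10)
  expect_equal(sc1$p, sc2$p, tolerance = 1e-10)
})

test_that("pairwise missing handling equals exact GLS on the observed subset", {
  set.seed(8)
  n <- 45; m <- 25
  g <- matrix(rbinom(n * m, 2, 0.3), n, m,
              dimnames = list(sprintf("L%02d", 1:n), sprintf("M%d", 1:m)))
  g[sample(length(g), 60)] <- NA
  info <- data.frame(marker_id = colnames(g), chrom = "A01",
                     pos_bp = seq_len(m) * 1e5)
  Kg <- matrix(rbinom(n * 500, 2, 0.4), n, 500,
               dimnames = list(rownames(g), NULL))
  K <- compute_kinship(Kg)
  y <- setNames(rnorm(n) + 0.2 * rowSums(Kg[, 1:5]), rownames(g))
  sc <- mlm_scan(g, info, y, K)
  gamma <- attr(sc, "gamma")
  V <- gamma * K + diag(n)
  for (j in seq_len(m)) {
    ok <- !is.na(g[, j])
    if (var(g[ok, j]) == 0) next
    Vi <- solve(V[ok, ok])
    X <- cbind(1, g[ok, j])
    yk <- y[ok]
    b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% yk)
    rss <- as.numeric(t(yk - X %*% b) %*% Vi %*% (yk - X %*% b))
    s2 <- rss / (sum(ok) - 2)
    se <- sqrt(s2 * solve(t(X) %*% Vi %*% X)[2, 2])
    expect_equal(sc$beta[j], b[2], tolerance = 1e-8)
    expect_equal(sc$se[j], se, tolerance = 1e-8)
  }
})

test_that("profiled variance ratio agrees with a dense grid search", {
  set.seed(9)
  pg <- simulate_polygenic_study(n_lines = 120, n_markers = 600, h2 = 0.6,
                                 seed = 10)
  K <- compute_kinship(pg$genotypes)
  y <- pg$phenotype
  prof <- cssldrought:::profile_variance_ratio(y, matrix(1, 120, 1), K)
  eg <- prof$eigen
  yr <- crossprod(eg$vectors, y)
  Xr <- crossprod(eg$vectors, matrix(1, 120, 1))
  dense <- seq(-10, 10, by = 0.01)
  ll <- vapply(dense, cssldrought:::reml_loglik_gamma, numeric(1),
               yr = yr, Xr = Xr, lambda = pmax(eg$values, 0))
  expect_gte(prof$loglik, max(ll) - 1e-4)
  expect_lt(abs(log(prof$gamma) - dense[which.max(ll)]), 0.02)
})

test_that("exact per-marker REML agrees with the one-profile approximation", {
  set.seed(19)
  n <- 60; m <- 12
  g <- matrix(rbinom(n * m, 2, 0.4), n, m,
              dimnames = list(sprintf("L%02d", 1:n), sprintf("M%d", 1:m)))
  info <- data.frame(marker_id = colnames(g), chrom = "A01",
                     pos_bp = seq_len(m) * 1e5)
  Kg <- matrix(rbinom(n * 400, 2, 0.4), n, 400,
               dimnames = list(rownames(g), NULL))
  K <- compute_kinship(Kg)
  y <- setNames(rnorm(n), rownames(g))
  sc1 <- mlm_scan(g, info, y, K)
  sc2 <- mlm_scan(g, info, y, K, per_marker_reml = TRUE)
  expect_equal(-log10(sc1$p), -log10(sc2$p), tolerance = 0.15)
})

test_that("significant markers merge into intervals with min-p peaks", {
  assoc <- data.frame(
    marker_id = sprintf("M%d", 1:6), chrom = c(rep("A01", 5), "D02"),
    pos_bp = c(1e6, 1.4e6, 1.9e6, 5e6, 5.2e6, 3e6), n = 100,
    beta = 1, se = 0.1,
    p = c(1e-8, 1e-10, 1e-7, 1e-9, 0.5, 1e-8))
  assoc$neg_log10_p <- -log10(assoc$p)
  q <- qtl_from_scan(assoc, 1e-6, trait = "DRC_FS", merge_bp = 1e6)
  expect_equal(nrow(q), 3)
  a <- q[q$chrom == "A01" & q$start_bp == 1e6, ]
  expect_equal(a$end_bp, 1.9e6)
  expect_equal(a$peak_marker, "M2")
  expect_equal(q$start_bp[q$chrom == "A01" & q$peak_marker == "M4"], 5e6)
})

test_that("LD r2 handles identity, complement and independence", {
  set.seed(11)
  n <- 500
  x <- rbinom(n, 2, 0.4)
  g <- cbind(a = x, b = x, c = 2L - x)
  expect_equal(ld_r2(g, "a", "b"), 1)
  expect_equal(ld_r2(g, "a", "c"), 1)
  r2s <- replicate(200, {
    gg <- cbind(u = rbinom(n, 2, 0.4), v = rbinom(n, 2, 0.4))
    ld_r2(gg, "u", "v")
  })
  expect_lt(abs(mean(r2s) - 1 / n), 3 * stats::sd(r2s) / sqrt(200))
  expect_true(is.na(ld_r2(cbind(a = rep(1L, 5), b = rbinom(5, 2, .5)),
                          "a", "b")))
})

test_that("greedy LD blocks recover planted structure", {
  set.seed(12)
  n <- 100
  blockvec <- rbinom(n, 2, 0.5)
  g <- cbind(vapply(1:3, function(i) rbinom(n, 2, 0.5), integer(n)),
             vapply(1:5, function(i) blockvec, integer(n)),
             vapply(1:3, function(i) rbinom(n, 2, 0.5), integer(n)))
  colnames(g) <- sprintf("M%02d", 1:11)
  info <- data.frame(marker_id = colnames(g), chrom = "A01",
                     pos_bp = seq_len(11) * 1e5)
  bl <- ld_blocks(g, info, r2_min = 0.8)
  mem <- attr(bl, "membership")
  expect_equal(length(unique(mem[4:8])), 1)       # planted block intact
  expect_equal(length(unique(mem[c(1:3, 9:11)])), 6)  # noise is singletons
  ## all-identical markers form a single chromosome-wide block
  g2 <- vapply(1:6, function(i) blockvec, integer(n))
  colnames(g2) <- sprintf("M%d", 1:6)
  bl2 <- ld_blocks(g2, data.frame(marker_id = colnames(g2), chrom = "A01",
                                  pos_bp = 1:6 * 1e6))
  expect_equal(nrow(bl2), 1)
})

test_that("candidate intervals flank, clip and unite with blocks", {
  ci <- candidate_interval("D09", 40715689)
  expect_equal(ci$start_bp, 40415689)
  expect_equal(ci$end_bp, 41015689)
  expect_equal(ci$width_bp, 600000)
  ci2 <- candidate_interval("A01", 100000, chrom_length_bp = 1e6)
  expect_equal(ci2$start_bp, 1)
  blocks <- data.frame(block_id = 1, chrom = "D09", start_bp = 40e6,
                       end_bp = 41.5e6, n_markers = 10)
  ci3 <- candidate_interval("D09", 40715689, blocks = blocks)
  expect_equal(ci3$start_bp, 40e6)
  expect_equal(ci3$end_bp, 41.5e6)
  expect_equal(ci3$provenance, "flank+block")
})
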