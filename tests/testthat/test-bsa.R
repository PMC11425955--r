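test_that("extreme pools are the MFVD top and bottom k", {
  set.seed(1)
  mf <- data.frame(line_id = sprintf("L%03d", 1:319), mfvd = runif(319))
  p <- select_extreme_pools(mf, k = 30)
  o <- mf[order(-mf$mfvd, mf$line_id), ]
  expect_setequal(p$resistant$line_ids, o$line_id[1:30])
  expect_setequal(p$sensitive$line_ids, rev(o$line_id)[1:30])
  ## 60 lines, k = 30: exact bipartition at the median
  mf60 <- mf[1:60, ]
  p60 <- select_extreme_pools(mf60, k = 30)
  med <- stats::median(mf60$mfvd)
  expect_true(all(mf60$mfvd[mf60$line_id %in% p60$resistant$line_ids] >= med))
  expect_true(all(mf60$mfvd[mf60$line_id %in% p60$sensitive$line_ids] <= med))
  ## k = 1: argmax and argmin
  p1 <- select_extreme_pools(mf, k = 1)
  expect_equal(p1$resistant$line_ids, mf$line_id[which.max(mf$mfvd)])
  expect_equal(p1$sensitive$line_ids, mf$line_id[which.min(mf$mfvd)])
  expect_error(select_extreme_pools(mf[1:10, ], k = 30), "2k")
})

test_that("tie-breaking at the pool boundary is deterministic by line id", {
  mf <- data.frame(line_id = c("B", "A", "C", "D"), mfvd = c(1, 1, 0, 0))
  p <- select_extreme_pools(mf, k = 1)
  expect_equal(p$resistant$line_ids, "A")
  expect_equal(p$sensitive$line_ids, "C")
})

test_that("SNP-index is the donor-read fraction with depth filtering", {
  d <- data.frame(marker_id = sprintf("M%d", 1:4), chrom = "A01",
                  pos_bp = 1:4 * 1e6,
                  donor_a = c(30, 10, 3, 0), recurrent_a = c(0, 10, 3, 20),
                  donor_b = c(0, 10, 4, 0), recurrent_b = c(25, 10, 8, 30),
                  parent_donor = 2L, parent_recurrent = 0L)
  ix <- snp_index(d, min_depth = 10)
  expect_equal(nrow(ix), 3)                 # site 3 dropped (depth 6 < 10)
  expect_equal(ix$index_a, c(1, 0.5, 0))
  expect_equal(ix$delta[1], 1)
  expect_equal(ix$delta[2], 0)
  expect_equal(unname(attr(ix, "dropped")["low_depth"]), 1L)
  ## parent-concordant sites never enter
  d$parent_recurrent[1] <- 2L
  ix2 <- snp_index(d, min_depth = 10)
  expect_equal(unname(attr(ix2, "dropped")["parent_concordant"]), 1L)
})

test_that("indices match a direct recomputation on simulated sites", {
  set.seed(2)
  m <- 1000
  d <- data.frame(marker_id = sprintf("M%d", 1:m), chrom = "A01",
                  pos_bp = seq_len(m) * 1e4,
                  donor_a = rbinom(m, 50, 0.2), recurrent_a = rbinom(m, 50, 0.8),
                  donor_b = rbinom(m, 50, 0.05), recurrent_b = rbinom(m, 50, 0.9),
                  parent_donor = 2L, parent_recurrent = 0L)
  ix <- snp_index(d, min_depth = 10)
  keep <- (d$donor_a + d$recurrent_a) >= 10 & (d$donor_b + d$recurrent_b) >= 10
  expect_equal(nrow(ix), sum(keep))
  expect_equal(ix$index_a,
               (d$donor_a / (d$donor_a + d$recurrent_a))[keep])
  expect_true(all(ix$index_a >= 0 & ix$index_a <= 1))
  expect_true(all(ix$delta >= -1 & ix$delta <= 1))
})

test_that("window means equal a brute-force per-window average", {
  set.seed(3)
  rec <- data.frame(marker_id = sprintf("M%d", 1:300), chrom = "A01",
                    pos_bp = sort(sample(1:30e6, 300)),
                    depth_a = 50, depth_b = 50,
                    index_a = runif(300), index_b = runif(300))
  rec$delta <- rec$index_a - rec$index_b
  w <- sliding_windows(rec, chrom_lengths = c(A01 = 30e6), min_sites = 1)
  for (k in sample(nrow(w), 25)) {
    inw <- rec$pos_bp >= w$start_bp[k] &
      rec$pos_bp < w$start_bp[k] + 1.5e6
    expect_equal(w$n_sites[k], sum(inw))
    if (sum(inw) > 0)
      expect_equal(w$mean_delta[k], mean(rec$delta[inw]))
    else expect_true(is.na(w$mean_delta[k]) && w$flagged[k])
  }
  ## constant deltas average to the constant
  rec$delta <- 0.25
  w2 <- sliding_windows(rec, chrom_lengths = c(A01 = 30e6), min_sites = 1)
  expect_true(all(w2$mean_delta[w2$n_sites > 0] == 0.25))
})

test_that("confidence bands shrink with depth and are seed-stable", {
  rec <- data.frame(marker_id = sprintf("M%d", 1:3), chrom = "A01",
                    pos_bp = 1:3 * 1e6,
                    depth_a = c(20, 100, 500), depth_b = c(20, 100, 500),
                    index_a = 0.1, index_b = 0.1, delta = 0)
  b1 <- confidence_bands(rec, pop_freq = rep(0.08, 3), pool_size = 30,
                         n_sims = 10000, depth_bin = 1, seed = 1)
  width <- b1$upper - b1$lower
  expect_true(all(diff(width) < 0))        # monotone shrink with depth
  b2 <- confidence_bands(rec, pop_freq = rep(0.08, 3), pool_size = 30,
                         n_sims = 10000, depth_bin = 1, seed = 2)
  rel <- abs((b2$upper - b2$lower) - width) / width
  expect_true(all(rel < 0.05))             # two seeds agree within 5%
  expect_warning(confidence_bands(rec, rep(0.08, 3), n_sims = 500, seed = 1),
                 "noisy")
})

test_that("interval calling merges exceeding windows and tolerates one gap", {
  mkw <- function(delta) data.frame(chrom = "A01",
                                    start_bp = seq(1, 9.1e6, by = 1e6),
                                    end_bp = seq(1, 9.1e6, by = 1e6) + 1.5e6 - 1,
                                    n_sites = 20, mean_delta = delta,
                                    lower = -0.2, upper = 0.2, flagged = FALSE)
  ## nothing exceeds
  expect_equal(nrow(call_bsa_intervals(mkw(rep(0.1, 10)))), 0)
  ## one isolated exceeding window
  d <- rep(0, 10); d[4] <- 0.5
  q <- call_bsa_intervals(mkw(d))
  expect_equal(nrow(q), 1)
  expect_equal(q$start_bp, 3e6 + 1)
  expect_equal(q$end_bp, 3e6 + 1.5e6)
  ## a run with one sub-threshold gap merges into one interval
  d2 <- rep(0, 10); d2[c(3, 4, 6, 7)] <- 0.5
  q2 <- call_bsa_intervals(mkw(d2), gap_windows = 1)
  expect_equal(nrow(q2), 1)
  q3 <- call_bsa_intervals(mkw(d2), gap_windows = 0)
  expect_equal(nrow(q3), 2)
})

test_that("a planted enriched region is recovered as one covering interval", {
  set.seed(5)
  m <- 400
  pos <- sort(sample(1:40e6, m))
  delta <- rnorm(m, 0, 0.03)
  plant <- pos >= 20e6 & pos <= 23e6
  delta[plant] <- delta[plant] + 0.4
  rec <- data.frame(marker_id = sprintf("M%d", 1:m), chrom = "A01",
                    pos_bp = pos, depth_a = 50, depth_b = 50,
                    index_a = 0.5, index_b = 0.5, delta = delta,
                    lower = -0.2, upper = 0.2)
  w <- sliding_windows(rec, chrom_lengths = c(A01 = 40e6), min_sites = 1)
  q <- call_bsa_intervals(w)
  expect_equal(nrow(q), 1)
  expect_lte(q$start_bp, 20e6)
  expect_gte(q$end_bp, 23e6)
  expect_lte(20e6 - q$start_bp, 1.6e6)     # covers the plant within one window
  expect_lte(q$end_bp - 23e6, 1.6e6)
})

test_that("swapping pool labels negates delta and mirrors intervals", {
  set.seed(6)
  m <- 300
  d <- data.frame(marker_id = sprintf("M%d", 1:m), chrom = "A01",
                  pos_bp = sort(sample(1:30e6, m)),
                  donor_a = rbinom(m, 50, 0.4), recurrent_a = rbinom(m, 50, 0.6),
                  donor_b = rbinom(m, 50, 0.1), recurrent_b = rbinom(m, 50, 0.9),
                  parent_donor = 2L, parent_recurrent = 0L)
  ix1 <- snp_index(d)
  d2 <- d
  d2[, c("donor_a", "recurrent_a", "donor_b", "recurrent_b")] <-
    d[, c("donor_b", "recurrent_b", "donor_a", "recurrent_a")]
  ix2 <- snp_index(d2)
  expect_equal(ix1$delta, -ix2$delta)
  ix1$lower <- -0.25; ix1$upper <- 0.25
  ix2$lower <- -0.25; ix2$upper <- 0.25
  w1 <- sliding_windows(ix1, chrom_lengths = c(A01 = 30e6), min_sites = 1)
  w2 <- sliding_windows(ix2, chrom_lengths = c(A01 = 30e6), min_sites = 1)
  q1 <- call_bsa_intervals(w1)
  q2 <- call_bsa_intervals(w2)
  expect_equal(q1[, c("chrom", "start_bp", "end_bp")],
               q2[, c("chrom", "start_bp", "end_bp")])
})
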