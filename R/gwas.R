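#' Filter markers on minor-allele frequency and missingness
#'
#' Recomputes MAF and missing rate from the dosage matrix and keeps
#' markers with `maf > maf_min` and `missing_rate < missing_max`
#' (defaults: discard MAF <= 5% and missingness >= 50%).
#'
#' @param genotypes lines x markers dosage matrix (0/1/2/NA).
#' @param info marker table aligned with the matrix columns.
#' @param maf_min,missing_max filter thresholds.
#' @return list `genotypes`, `info` (filtered, with refreshed `maf` and
#'   `missing_rate`), and `counts` (input, retained, removed).
#' @export
filter_markers <- function(genotypes, info, maf_min = 0.05, missing_max = 0.5) {
  if (ncol(genotypes) != nrow(info)) stop("genotypes and info are not aligned")
  f <- colMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  maf[is.nan(maf)] <- 0
  miss <- colMeans(is.na(genotypes))
  keep <- maf > maf_min & miss < missing_max
  if (!any(keep)) warning("no markers survive the filter")
  info <- info[keep, , drop = FALSE]
  info$maf <- maf[keep]
  info$missing_rate <- miss[keep]
  rownames(info) <- NULL
  list(genotypes = genotypes[, keep, drop = FALSE], info = info,
       counts = c(input = length(keep), retained = sum(keep),
                  removed = sum(!keep)))
}

#' Genome-wide association thresholds
#'
#' Suggestive threshold `1/n_markers` and significant threshold
#' `0.05/n_markers` (Bonferroni at 0.05), as used for panels of ~1.3
#' million SNPs where they evaluate to 7.63e-7 and 3.82e-8.
#'
#' @param n_markers number of tested markers (>= 1).
#' @return list `suggestive`, `significant`.
#' @export
association_thresholds <- function(n_markers) {
  stopifnot_scalar_pos(n_markers, "n_markers")
  list(suggestive = 1 / n_markers, significant = 0.05 / n_markers)
}

#' VanRaden-type kinship matrix
#'
#' Centered cross-product estimator `K = W W' / c` with `W` the
#' column-centered dosage matrix (centering at twice the donor-allele
#' frequency) and `c = sum(2 p (1-p))`. Missing dosages are mean-imputed
#' for the kinship computation only.
#'
#' @param genotypes lines x markers dosage matrix.
#' @return symmetric positive-semidefinite lines x lines matrix.
#' @export
compute_kinship <- function(genotypes) {
  if (ncol(genotypes) < 2) stop("need >= 2 markers")
  if (any(rowMeans(is.na(genotypes)) == 1))
    stop("line with all genotypes missing")
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  W <- sweep(genotypes, 2, 2 * p)
  W[is.na(W)] <- 0                       # mean imputation after centering
  cc <- sum(2 * p * (1 - p))
  if (cc == 0) stop("all markers monomorphic")
  K <- tcrossprod(W) / cc
  (K + t(K)) / 2
}

## REML log-likelihood of the null model for variance ratio gamma =
## sigma_g^2 / sigma_e^2, in the eigenbasis of K (lambda = eigenvalues).
reml_loglik_gamma <- function(log_gamma, yr, Xr, lambda) {
  g <- exp(log_gamma)
  w <- 1 / (g * lambda + 1)
  n <- length(yr); p <- ncol(Xr)
  XtWX <- crossprod(Xr, w * Xr)
  XtWy <- crossprod(Xr, w * yr)
  beta <- solve(XtWX, XtWy)
  rss <- sum(w * yr^2) - sum(beta * XtWy)
  -0.5 * ((n - p) * log(rss) - sum(log(w)) + determinant(XtWX)$modulus[1])
}

## Profile the variance ratio on the null model: 64-point grid on
## log gamma in [-10, 10] (natural log scale of the ratio), refined by
## golden-section search to 1e-6.
profile_variance_ratio <- function(y, X, K) {
  eg <- eigen(K, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  U <- eg$vectors
  yr <- crossprod(U, y)
  Xr <- crossprod(U, X)
  grid <- seq(-10, 10, length.out = 64)
  ll <- vapply(grid, reml_loglik_gamma, numeric(1), yr = yr, Xr = Xr,
               lambda = lambda)
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(reml_loglik_gamma, c(lo, hi), maximum = TRUE,
                         tol = 1e-6, yr = yr, Xr = Xr, lambda = lambda)
  ## treat a boundary optimum at the low end as gamma = 0
  gamma <- exp(opt$maximum)
  if (opt$maximum <= -10 + 1e-4) gamma <- 0
  list(gamma = gamma, loglik = opt$objective, grid = grid, grid_ll = ll,
       eigen = eg)
}

#' Mixed-linear-model association scan
#'
#' Tests each marker for an additive effect on the phenotype under the
#' model `y = mu + x b + u + e` with polygenic effect
#' `u ~ N(0, sigma_g^2 K)`. The variance ratio
#' `gamma = sigma_g^2/sigma_e^2` is profiled once on the null
#' (marker-free) model by REML on the spectral decomposition of K; each
#' marker is then tested by generalized least squares at that ratio, with
#' a two-sided Wald t-test on `b/se(b)` at residual degrees of freedom
#' (the population-parameters-previously-determined approximation).
#' Missing dosages are dropped pairwise per marker: the GLS normal
#' equations on the observed subset are obtained exactly from the
#' precomputed full-panel inverse covariance by a block downdate over the
#' (few) missing lines. Markers constant after missing-drop are skipped
#' with a reason. `per_marker_reml = TRUE` re-profiles the variance ratio
#' for every marker (exact, slower; complete markers only).
#'
#' @param genotypes lines x markers dosage matrix.
#' @param info marker table aligned with columns.
#' @param phenotype named per-line vector (a DRC trait or MFVD).
#' @param K kinship from [compute_kinship()].
#' @param min_lines minimum phenotyped lines (default 30).
#' @param per_marker_reml exact per-marker variance-ratio profiling.
#' @return data.frame `marker_id`, `chrom`, `pos_bp`, `n`, `beta`, `se`,
#'   `p`, `neg_log10_p`, `skipped`; attributes `gamma` and `reml`.
#' @export
mlm_scan <- function(genotypes, info, phenotype, K,
                     min_lines = 30, per_marker_reml = FALSE) {
  lines <- rownames(genotypes)
  ph <- phenotype[lines]
  keep <- !is.na(ph)
  if (sum(keep) < min_lines)
    stop("phenotype defined for fewer than ", min_lines, " lines")
  G <- genotypes[keep, , drop = FALSE]
  y <- as.numeric(ph[keep])
  Kk <- K[keep, keep]
  n <- length(y)
  X0 <- matrix(1, n, 1)

  prof <- profile_variance_ratio(y, X0, Kk)
  gamma <- prof$gamma

  if (per_marker_reml) {
    res <- mlm_scan_exact(G, info, y, prof)
  } else {
    res <- mlm_scan_pppd(G, info, y, Kk, gamma)
  }
  attr(res, "gamma") <- gamma
  attr(res, "reml") <- prof$loglik
  res
}

mlm_scan_pppd <- function(G, info, y, K, gamma) {
  n <- length(y)
  V <- gamma * K + diag(n)
  P <- solve(V)
  ones <- rep(1, n)
  u <- P %*% ones                        # P 1
  v <- P %*% y                           # P y
  Gz <- G; Gz[is.na(Gz)] <- 0
  W <- P %*% Gz                          # P x (x zeroed at missing)
  m <- ncol(G)
  beta <- se <- pval <- rep(NA_real_, m)
  nn <- integer(m)
  skipped <- character(m)

  s11_full <- sum(ones * u); s1y_full <- sum(ones * v); syy_full <- sum(y * v)
  miss_list <- apply(is.na(G), 2, which, simplify = FALSE)

  for (j in seq_len(m)) {
    M <- miss_list[[j]]
    x <- Gz[, j]
    nS <- n - length(M)
    nn[j] <- nS
    xs <- x
    if (length(M) == 0) {
      if (stats::var(x) == 0) { skipped[j] <- "constant"; next }
      w <- W[, j]
      s11 <- s11_full; s1y <- s1y_full; syy <- syy_full
      s1x <- sum(w); sxy <- sum(y * w); sxx <- sum(x * w)
    } else {
      if (stats::var(x[-M]) == 0) { skipped[j] <- "constant"; next }
      PM <- P[, M, drop = FALSE]
      ## zero-padded base vectors restricted to the observed set S
      P1t <- u - rowSums(PM)                       # P (1 zeroed at M)
      Pyt <- v - PM %*% y[M]                       # P (y zeroed at M)
      Pxt <- W[, j]                                # x already zero at M
      ones_t <- ones; ones_t[M] <- 0
      y_t <- y; y_t[M] <- 0
      ## downdate: a' V_SS^-1 b = a~' P b~ - (P a~)_M' P_MM^-1 (P b~)_M
      RMi <- solve(P[M, M, drop = FALSE])
      c1 <- P1t[M]; cy <- Pyt[M]; cx <- Pxt[M]
      s11 <- sum(ones_t * P1t) - as.numeric(crossprod(c1, RMi %*% c1))
      s1y <- sum(ones_t * Pyt) - as.numeric(crossprod(c1, RMi %*% cy))
      syy <- sum(y_t * Pyt) - as.numeric(crossprod(cy, RMi %*% cy))
      s1x <- sum(ones_t * Pxt) - as.numeric(crossprod(c1, RMi %*% cx))
      sxy <- sum(y_t * Pxt) - as.numeric(crossprod(cy, RMi %*% cx))
      sxx <- sum(xs * Pxt) - as.numeric(crossprod(cx, RMi %*% cx))
    }
    det2 <- s11 * sxx - s1x^2
    if (det2 <= 0 || nS <= 2) { skipped[j] <- "singular"; next }
    b1 <- (s11 * sxy - s1x * s1y) / det2
    b0 <- (s1y - s1x * b1) / s11
    rss <- syy - b0 * s1y - b1 * sxy
    rss <- max(rss, 0)
    sigma2 <- rss / (nS - 2)
    vb <- sigma2 * s11 / det2
    beta[j] <- b1
    se[j] <- sqrt(vb)
    tt <- if (se[j] > 0) b1 / se[j] else sign(b1) * Inf
    ## a perfect fit underflows; keep p in (0, 1]
    pval[j] <- max(2 * stats::pt(-abs(tt), df = nS - 2), 1e-300)
  }
  data.frame(marker_id = info$marker_id, chrom = info$chrom,
             pos_bp = info$pos_bp, n = nn, beta = beta, se = se, p = pval,
             neg_log10_p = -log10(pval), skipped = skipped,
             stringsAsFactors = FALSE)
}

mlm_scan_exact <- function(G, info, y, prof) {
  if (any(is.na(G)))
    stop("per-marker REML requires complete genotypes")
  eg <- prof$eigen
  lambda <- pmax(eg$values, 0); U <- eg$vectors
  n <- length(y)
  yr <- crossprod(U, y)
  onesr <- crossprod(U, rep(1, n))
  m <- ncol(G)
  beta <- se <- pval <- rep(NA_real_, m)
  skipped <- character(m)
  for (j in seq_len(m)) {
    x <- G[, j]
    if (stats::var(x) == 0) { skipped[j] <- "constant"; next }
    Xr <- cbind(onesr, crossprod(U, x))
    opt <- stats::optimize(reml_loglik_gamma, c(-10, 10), maximum = TRUE,
                           tol = 1e-6, yr = yr, Xr = Xr, lambda = lambda)
    g <- exp(opt$maximum)
    w <- 1 / (g * lambda + 1)
    XtWX <- crossprod(Xr, w * Xr)
    XtWy <- crossprod(Xr, w * yr)
    bb <- solve(XtWX, XtWy)
    rss <- sum(w * yr^2) - sum(bb * XtWy)
    sigma2 <- rss / (n - 2)
    vb <- sigma2 * solve(XtWX)[2, 2]
    beta[j] <- bb[2]; se[j] <- sqrt(vb)
    pval[j] <- 2 * stats::pt(-abs(bb[2] / se[j]), df = n - 2)
  }
  data.frame(marker_id = info$marker_id, chrom = info$chrom,
             pos_bp = info$pos_bp, n = n, beta = beta, se = se, p = pval,
             neg_log10_p = -log10(pval), skipped = skipped,
             stringsAsFactors = FALSE)
}

#' Merge significant markers of a scan into QTL records
#'
#' Markers with `p < threshold` on one chromosome are merged into one
#' interval when less than `merge_bp` apart; the minimum-p marker of each
#' interval is the highlighted SNP (peak).
#'
#' @param assoc scan result from [mlm_scan()].
#' @param threshold p-value threshold (e.g. the suggestive 1/n).
#' @param trait trait label carried into the records.
#' @param merge_bp merge distance (default 1 Mb).
#' @return data.frame of QTL records (`method = "gwas"`): `trait`,
#'   `chrom`, `start_bp`, `end_bp`, `peak_bp`, `peak_marker`,
#'   `statistic` (max -log10 p).
#' @export
qtl_from_scan <- function(assoc, threshold, trait = "trait", merge_bp = 1e6) {
  sig <- assoc[!is.na(assoc$p) & assoc$p < threshold, , drop = FALSE]
  if (nrow(sig) == 0)
    return(data.frame(method = character(0), trait = character(0),
                      chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), peak_bp = numeric(0),
                      peak_marker = character(0), statistic = numeric(0)))
  out <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, ]
    s <- s[order(s$pos_bp), ]
    grp <- cumsum(c(1, diff(s$pos_bp) >= merge_bp))
    for (g in unique(grp)) {
      si <- s[grp == g, ]
      pk <- si[which.min(si$p), ]
      out[[length(out) + 1L]] <- data.frame(
        method = "gwas", trait = trait, chrom = ch,
        start_bp = min(si$pos_bp), end_bp = max(si$pos_bp),
        peak_bp = pk$pos_bp, peak_marker = pk$marker_id,
        statistic = pk$neg_log10_p, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start_bp), ]
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of the dosage vectors of two markers over
#' jointly non-missing lines; NA (flagged) when fewer than 3 joint lines
#' or a constant vector.
#'
#' @param genotypes dosage matrix.
#' @param marker_i,marker_j column ids or indices.
#' @return r-squared scalar.
#' @export
ld_r2 <- function(genotypes, marker_i, marker_j) {
  x <- genotypes[, marker_i]; y <- genotypes[, marker_j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])^2
}

#' Greedy r-squared LD blocks
#'
#' Per chromosome, a block starts at the first unassigned marker (the
#' seed) and grows while the next marker's r-squared with the seed is at
#' least `r2_min`; blocks are maximal and non-overlapping.
#'
#' @param genotypes dosage matrix.
#' @param info marker table sorted by position within chromosome.
#' @param r2_min block threshold (default 0.8).
#' @return data.frame `block_id`, `chrom`, `start_bp`, `end_bp`,
#'   `n_markers`, plus attribute `membership` (block id per marker).
#' @export
ld_blocks <- function(genotypes, info, r2_min = 0.8) {
  member <- integer(nrow(info))
  bid <- 0L
  for (ch in unique(info$chrom)) {
    idx <- which(info$chrom == ch)
    idx <- idx[order(info$pos_bp[idx])]
    i <- 1L
    while (i <= length(idx)) {
      bid <- bid + 1L
      seed <- idx[i]
      member[seed] <- bid
      j <- i + 1L
      while (j <= length(idx)) {
        r2 <- ld_r2(genotypes, seed, idx[j])
        if (!is.na(r2) && r2 >= r2_min) {
          member[idx[j]] <- bid
          j <- j + 1L
        } else break
      }
      i <- j
    }
  }
  blocks <- do.call(rbind, lapply(unique(member), function(b) {
    w <- which(member == b)
    data.frame(block_id = b, chrom = info$chrom[w[1]],
               start_bp = min(info$pos_bp[w]), end_bp = max(info$pos_bp[w]),
               n_markers = length(w), stringsAsFactors = FALSE)
  }))
  blocks <- blocks[order(blocks$block_id), ]
  rownames(blocks) <- NULL
  attr(blocks, "membership") <- member
  blocks
}

#' Candidate interval around a highlighted SNP
#'
#' Flanks the SNP by `flank_bp` on each side (default 300 kb, giving a
#' 600 kb screening range), clips to the chromosome, and unites the
#' result with the containing LD block when one exists.
#'
#' @param chrom,pos_bp highlighted SNP coordinates.
#' @param chrom_length_bp chromosome length for clipping (Inf to skip).
#' @param blocks optional LD block table from [ld_blocks()].
#' @param flank_bp flank size (default 3e5).
#' @return one-row data.frame `chrom`, `pos_bp`, `start_bp`, `end_bp`,
#'   `width_bp`, `provenance`.
#' @export
candidate_interval <- function(chrom, pos_bp, chrom_length_bp = Inf,
                               blocks = NULL, flank_bp = 3e5) {
  start <- max(1, pos_bp - flank_bp)
  end <- min(chrom_length_bp, pos_bp + flank_bp)
  prov <- "flank"
  if (!is.null(blocks)) {
    hit <- blocks$chrom == chrom & blocks$start_bp <= pos_bp &
      blocks$end_bp >= pos_bp
    if (any(hit)) {
      start <- min(start, blocks$start_bp[hit])
      end <- max(end, blocks$end_bp[hit])
      prov <- "flank+block"
    }
  }
  data.frame(chrom = chrom, pos_bp = pos_bp, start_bp = start, end_bp = end,
             width_bp = end - start, provenance = prov,
             stringsAsFactors = FALSE)
}
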