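#' Build an introgression bin map from marker dosages
#'
#' Consecutive markers whose dosage columns are identical across all
#' lines are merged into one bin; with missing entries, two columns are
#' merged when they agree at every jointly observed line, and the bin's
#' per-line genotype is the majority non-missing code over its member
#' markers. Bin boundaries fall at the midpoint between the flanking
#' markers of adjacent distinct bins; the first and last bin of a
#' chromosome extend to the chromosome ends when lengths are supplied,
#' otherwise to the outermost marker positions.
#'
#' @param genotypes lines x markers dosage matrix (markers sorted by
#'   position within chromosome).
#' @param info marker table.
#' @param chrom_map optional chromosome map for outer bin boundaries.
#' @return list `bins` (bin_id, chrom, start_bp, end_bp, n_markers) and
#'   `genotypes` (lines x bins dosage matrix).
#' @export
build_bin_map <- function(genotypes, info, chrom_map = NULL) {
  lines <- rownames(genotypes)
  bins <- list(); bingeno <- list()
  bid <- 0L
  for (ch in unique(info$chrom)) {
    idx <- which(info$chrom == ch)
    idx <- idx[order(info$pos_bp[idx])]
    L <- if (!is.null(chrom_map)) chrom_map$length_bp[chrom_map$name == ch] else NA
    ## consensus-based run grouping
    run_first <- idx[1]; run_last <- idx[1]
    consensus <- genotypes[, idx[1]]
    members <- list(genotypes[, idx[1]])
    starts <- integer(0); ends <- integer(0)
    flush <- function(next_first) {
      bid <<- bid + 1L
      mm <- do.call(cbind, members)
      maj <- apply(mm, 1, function(r) {
        r <- r[!is.na(r)]
        if (length(r) == 0) return(NA_integer_)
        tb <- table(r)
        as.integer(names(tb)[which.max(tb)])
      })
      bins[[bid]] <<- data.frame(
        bin_id = bid, chrom = ch,
        first_pos = info$pos_bp[run_first], last_pos = info$pos_bp[run_last],
        n_markers = length(members), stringsAsFactors = FALSE)
      bingeno[[bid]] <<- maj
    }
    for (k in idx[-1]) {
      col <- genotypes[, k]
      both <- !is.na(consensus) & !is.na(col)
      if (all(consensus[both] == col[both])) {
        consensus[is.na(consensus)] <- col[is.na(consensus)]
        members[[length(members) + 1L]] <- col
        run_last <- k
      } else {
        flush(k)
        run_first <- k; run_last <- k
        consensus <- col
        members <- list(col)
      }
    }
    flush(NA)
  }
  bins <- do.call(rbind, bins)
  ## midpoint boundaries per chromosome
  bins$start_bp <- bins$first_pos
  bins$end_bp <- bins$last_pos
  for (ch in unique(bins$chrom)) {
    w <- which(bins$chrom == ch)
    L <- if (!is.null(chrom_map)) chrom_map$length_bp[chrom_map$name == ch] else NA
    if (length(w) > 1) {
      mids <- floor((bins$last_pos[w[-length(w)]] + bins$first_pos[w[-1]]) / 2)
      bins$end_bp[w[-length(w)]] <- mids
      bins$start_bp[w[-1]] <- mids + 1
    }
    bins$start_bp[w[1]] <- 1
    bins$end_bp[w[length(w)]] <- if (!is.na(L)) L else bins$last_pos[w[length(w)]]
  }
  G <- do.call(cbind, bingeno)
  dimnames(G) <- list(lines, paste0("bin", bins$bin_id))
  list(bins = bins[, c("bin_id", "chrom", "start_bp", "end_bp", "n_markers")],
       genotypes = G)
}

## Partial-F p-values for adding each candidate column to the model
## spanned by the orthonormal basis Q (which includes the intercept).
partial_f_p <- function(Q, yres, B, n) {
  Bres <- B - Q %*% crossprod(Q, B)
  bss <- colSums(Bres^2)
  num <- colSums(Bres * yres)^2 / bss
  num[bss < 1e-10] <- NA               # collinear with current model
  k <- ncol(Q)
  rss1 <- sum(yres^2) - num
  f <- num / (rss1 / (n - k - 1))
  p <- stats::pf(f, 1, n - k - 1, lower.tail = FALSE)
  p
}

#' Stepwise-cofactor likelihood-ratio additive scan on a bin map
#'
#' A reimplementation of the stepwise likelihood-ratio additive QTL scan
#' used for substitution-line bin maps: (1) forward-backward stepwise
#' selection over bins by partial F-test (`p_enter`/`p_exit`) picks
#' background cofactor bins; (2) every bin is tested by a Gaussian
#' likelihood-ratio test of the additive model containing all selected
#' cofactors except those within `exclusion_bp` of the tested bin.
#' `LOD = LRT / (2 ln 10)`; the additive effect is half the fitted
#' donor-homozygote vs recurrent-homozygote contrast (the coefficient on
#' 0/1/2 dosage); PVE is the R-squared increment in percent. Bins
#' collinear with their cofactor model are skipped with a reason.
#'
#' @param bin_map list from [build_bin_map()].
#' @param phenotype named per-line vector.
#' @param p_enter,p_exit stepwise thresholds (defaults 0.01 / 0.02).
#' @param exclusion_bp cofactor exclusion window around the tested bin
#'   (default 5 Mb).
#' @param max_cofactors cap on selected cofactors (default 15).
#' @param min_lines minimum phenotyped lines (default 30).
#' @return data.frame `bin_id`, `chrom`, `start_bp`, `end_bp`, `lod`,
#'   `effect`, `pve`, `skipped`; attribute `cofactors` (selected bin ids).
#' @export
rstep_lrt_add_scan <- function(bin_map, phenotype, p_enter = 0.01,
                               p_exit = 0.02, exclusion_bp = 5e6,
                               max_cofactors = 15, min_lines = 30) {
  bins <- bin_map$bins
  B <- bin_map$genotypes
  ph <- phenotype[rownames(B)]
  keep <- !is.na(ph)
  if (sum(keep) < min_lines)
    stop("phenotype defined for fewer than ", min_lines, " lines")
  B <- B[keep, , drop = FALSE]
  y <- as.numeric(ph[keep])
  n <- length(y)
  ## mean-impute rare missing bin genotypes for the scan design
  for (j in which(colSums(is.na(B)) > 0)) {
    mj <- mean(B[, j], na.rm = TRUE)
    B[is.na(B[, j]), j] <- mj
  }
  storage.mode(B) <- "double"
  poly <- which(apply(B, 2, stats::var) > 0)

  ## forward-backward stepwise cofactor selection
  sel <- integer(0)
  repeat {
    X <- cbind(1, B[, sel, drop = FALSE])
    qr_ <- qr(X)
    Q <- qr.Q(qr_)
    yres <- as.numeric(y - Q %*% crossprod(Q, y))
    cand <- setdiff(poly, sel)
    if (length(cand) == 0 || length(sel) >= max_cofactors) break
    pv <- partial_f_p(Q, yres, B[, cand, drop = FALSE], n)
    best <- which.min(pv)
    changed <- FALSE
    if (length(best) && !is.na(pv[best]) && pv[best] < p_enter) {
      sel <- c(sel, cand[best]); changed <- TRUE
    }
    ## backward pass: drop the worst cofactor above p_exit
    if (length(sel) > 1) {
      X <- cbind(1, B[, sel, drop = FALSE])
      fit <- stats::lm.fit(X, y)
      rss1 <- sum(fit$residuals^2)
      pv_out <- vapply(seq_along(sel), function(i) {
        Xi <- X[, -(i + 1), drop = FALSE]
        rss0 <- sum(stats::lm.fit(Xi, y)$residuals^2)
        f <- (rss0 - rss1) / (rss1 / (n - ncol(X)))
        stats::pf(f, 1, n - ncol(X), lower.tail = FALSE)
      }, numeric(1))
      worst <- which.max(pv_out)
      if (pv_out[worst] > p_exit) { sel <- sel[-worst]; changed <- TRUE }
    }
    if (!changed) break
  }

  tss <- sum((y - mean(y))^2)
  lod <- eff <- pve <- rep(NA_real_, nrow(bins))
  skipped <- character(nrow(bins))
  for (j in seq_len(nrow(bins))) {
    if (!(j %in% poly)) { skipped[j] <- "monomorphic"; next }
    near <- bins$chrom[sel] == bins$chrom[j] &
      pmax(bins$start_bp[sel], bins$start_bp[j]) <=
        pmin(bins$end_bp[sel], bins$end_bp[j]) + exclusion_bp
    cof <- sel[!near & sel != j]
    X0 <- cbind(1, B[, cof, drop = FALSE])
    X1 <- cbind(X0, B[, j])
    f1 <- stats::lm.fit(X1, y)
    if (any(is.na(f1$coefficients))) { skipped[j] <- "collinear"; next }
    rss0 <- sum(stats::lm.fit(X0, y)$residuals^2)
    rss1 <- sum(f1$residuals^2)
    lrt <- n * (log(rss0) - log(rss1))
    lod[j] <- lrt / (2 * log(10))
    eff[j] <- f1$coefficients[ncol(X1)]
    pve[j] <- 100 * (rss0 - rss1) / tss
  }
  out <- data.frame(bin_id = bins$bin_id, chrom = bins$chrom,
                    start_bp = bins$start_bp, end_bp = bins$end_bp,
                    lod = lod, effect = eff, pve = pve, skipped = skipped,
                    stringsAsFactors = FALSE)
  attr(out, "cofactors") <- bins$bin_id[sel]
  out
}

#' QTL records from a linkage scan
#'
#' Bins with `lod >= lod_min` are merged into intervals when their bins
#' are less than `merge_bp` apart on a chromosome; the maximum-LOD bin is
#' the peak.
#'
#' @param scan result of [rstep_lrt_add_scan()].
#' @param lod_min LOD threshold (default 2.5).
#' @param trait trait label.
#' @param merge_bp merge distance (default 1 Mb).
#' @return QTL record data.frame (`method = "linkage"`).
#' @export
qtl_from_linkage <- function(scan, lod_min = 2.5, trait = "trait",
                             merge_bp = 1e6) {
  sig <- scan[!is.na(scan$lod) & scan$lod >= lod_min, , drop = FALSE]
  if (nrow(sig) == 0)
    return(data.frame(method = character(0), trait = character(0),
                      chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), peak_bp = numeric(0),
                      peak_marker = character(0), statistic = numeric(0)))
  out <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, ]
    s <- s[order(s$start_bp), ]
    gap <- c(0, pmax(s$start_bp[-1] - s$end_bp[-nrow(s)], 0))
    grp <- cumsum(gap >= merge_bp)
    for (g in unique(grp)) {
      si <- s[grp == g, ]
      pk <- si[which.max(si$lod), ]
      out[[length(out) + 1L]] <- data.frame(
        method = "linkage", trait = trait, chrom = ch,
        start_bp = min(si$start_bp), end_bp = max(si$end_bp),
        peak_bp = floor((pk$start_bp + pk$end_bp) / 2),
        peak_marker = paste0("bin", pk$bin_id),
        statistic = pk$lod, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start_bp), ]
}
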