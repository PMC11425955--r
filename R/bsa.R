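#' Select extreme phenotype pools by MFVD
#'
#' Top-k MFVD lines form the drought-resistant pool and bottom-k the
#' drought-sensitive pool; ties at the rank-k boundary are broken by
#' line-id order, deterministically. Overlapping pools (possible only
#' when fewer than 2k lines have a defined MFVD) are rejected.
#'
#' @param mfvd data.frame with `line_id` and `mfvd`.
#' @param k pool size (default 30).
#' @return list of two pool specs (`label`, `line_ids`, `size`).
#' @export
select_extreme_pools <- function(mfvd, k = 30) {
  d <- mfvd[!is.na(mfvd$mfvd), c("line_id", "mfvd")]
  if (nrow(d) < 2 * k) stop("need >= 2k lines with defined MFVD")
  d <- d[order(-d$mfvd, d$line_id), ]
  resistant <- d$line_id[seq_len(k)]
  d2 <- d[order(d$mfvd, d$line_id), ]
  sensitive <- d2$line_id[seq_len(k)]
  if (length(intersect(resistant, sensitive)) > 0)
    stop("extreme pools overlap; population too small or ties too wide")
  list(resistant = list(label = "resistant", line_ids = resistant, size = k),
       sensitive = list(label = "sensitive", line_ids = sensitive, size = k))
}

#' Per-site SNP-index and delta SNP-index of two pools
#'
#' For parent-discordant homozygous sites, the SNP-index of a pool is its
#' donor-read fraction `donor/(donor + recurrent)`; delta is oriented so
#' that positive values mean donor-allele enrichment in the resistant
#' pool (`index_a - index_b`, pool a resistant). Sites with total depth
#' below `min_depth` in either pool, or zero depth, are dropped with the
#' reason tallied in the `dropped` attribute.
#'
#' @param depths site table from [simulate_pool_depths()] or
#'   [read_pool_depths()].
#' @param min_depth per-pool minimum total depth (default 10).
#' @return data.frame `marker_id`, `chrom`, `pos_bp`, `depth_a`,
#'   `depth_b`, `index_a` (resistant), `index_b` (sensitive), `delta`.
#' @export
snp_index <- function(depths, min_depth = 10) {
  keep_parent <- depths$parent_donor != depths$parent_recurrent
  d <- depths[keep_parent, , drop = FALSE]
  ta <- d$donor_a + d$recurrent_a
  tb <- d$donor_b + d$recurrent_b
  low <- ta < min_depth | tb < min_depth
  dropped <- c(parent_concordant = sum(!keep_parent), low_depth = sum(low))
  d <- d[!low, , drop = FALSE]
  ta <- ta[!low]; tb <- tb[!low]
  out <- data.frame(marker_id = d$marker_id, chrom = d$chrom,
                    pos_bp = d$pos_bp,
                    depth_a = ta, depth_b = tb,
                    index_a = d$donor_a / ta, index_b = d$donor_b / tb,
                    stringsAsFactors = FALSE)
  out$delta <- out$index_a - out$index_b
  attr(out, "dropped") <- dropped
  out
}

#' Sliding-window smoothing of the delta SNP-index
#'
#' Tiles each chromosome with windows of `window_bp` (default 1.5 Mb)
#' advanced by `step_bp` (default 100 kb), averaging the per-site deltas
#' of the sites inside `[start, start + window)`. Windows with fewer than
#' `min_sites` sites are flagged and excluded from interval calling.
#' When per-site confidence bands are present (from
#' [confidence_bands()]), the window band is the mean of its member
#' sites' bands.
#'
#' @param records site table from [snp_index()], optionally with `lower`
#'   and `upper` band columns.
#' @param chrom_lengths named vector or chromosome map data.frame; when
#'   NULL, windows span the observed site range.
#' @param window_bp,step_bp window geometry.
#' @param min_sites minimum sites per window (default 10).
#' @return data.frame `chrom`, `start_bp`, `end_bp`, `n_sites`,
#'   `mean_delta`, `lower`, `upper`, `flagged`.
#' @export
sliding_windows <- function(records, chrom_lengths = NULL,
                            window_bp = 1.5e6, step_bp = 1e5,
                            min_sites = 10) {
  if (is.data.frame(chrom_lengths))
    chrom_lengths <- stats::setNames(chrom_lengths$length_bp, chrom_lengths$name)
  has_band <- all(c("lower", "upper") %in% names(records))
  out <- list()
  for (ch in unique(records$chrom)) {
    r <- records[records$chrom == ch, ]
    r <- r[order(r$pos_bp), ]
    L <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      chrom_lengths[[ch]] else max(r$pos_bp)
    starts <- seq(1, max(1, L - 1), by = step_bp)
    nw <- length(starts)
    ## window index range covering each site: start in (pos - window, pos]
    k_hi <- pmin(floor((r$pos_bp - 1) / step_bp) + 1L, nw)
    k_lo <- pmax(ceiling((r$pos_bp - window_bp) / step_bp) + 1L, 1L)
    reps <- k_hi - k_lo + 1L
    site_rep <- rep(seq_len(nrow(r)), reps)
    win_idx <- unlist(lapply(seq_len(nrow(r)), function(i) k_lo[i]:k_hi[i]))
    n_sites <- tabulate(win_idx, nbins = nw)
    sum_delta <- rowsum(r$delta[site_rep], win_idx)
    mean_delta <- rep(NA_real_, nw)
    mean_delta[as.integer(rownames(sum_delta))] <-
      sum_delta / n_sites[as.integer(rownames(sum_delta))]
    lower <- upper <- rep(NA_real_, nw)
    if (has_band) {
      sl <- rowsum(r$lower[site_rep], win_idx)
      su <- rowsum(r$upper[site_rep], win_idx)
      ii <- as.integer(rownames(sl))
      lower[ii] <- sl / n_sites[ii]
      upper[ii] <- su / n_sites[ii]
    }
    out[[ch]] <- data.frame(chrom = ch, start_bp = starts,
                            end_bp = pmin(starts + window_bp - 1, L),
                            n_sites = n_sites, mean_delta = mean_delta,
                            lower = lower, upper = upper,
                            flagged = n_sites < min_sites,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Monte-Carlo confidence bands for the delta SNP-index, CSSL-aware null
#'
#' Simulates the null distribution of the per-site delta: for each site,
#' the pooled donor-allele frequency of each pool is drawn by resampling
#' the pool's composition at the site's population donor frequency, then
#' reads are drawn binomially at the realized pool frequency and the
#' site's depth. The `(1-level)/2` and `(1+level)/2` quantiles of the
#' simulated delta give the band. The null is CSSL-aware in two ways:
#' it conditions on the observed population frequency, which is low and
#' locus-specific in a substitution-line panel (not 0.5 as in an F2
#' cross), and with `inbred = TRUE` (the default) it resamples
#' `pool_size` homozygous lines rather than `2 * pool_size` independent
#' chromosomes -- substitution lines are near-fixed, so a pool of k lines
#' carries only k independent chromosome draws and the outbred null
#' would under-disperse (and the band under-cover) by about a factor
#' sqrt(2) in the composition term. Simulation is tabulated over
#' (frequency bin, depth bin) cells and looked up per site; population
#' frequencies are floored at `freq_floor` so monomorphic sites get a
#' degenerate band.
#'
#' @param records site table from [snp_index()].
#' @param pop_freq population donor-allele frequency per site (aligned
#'   with `records`), e.g. column means of the dosage matrix / 2.
#' @param pool_size lines per pool (default 30).
#' @param level confidence level in (0,1) (default 0.99).
#' @param n_sims Monte-Carlo draws per cell (default 10000; < 1000 warns).
#' @param freq_bin,depth_bin tabulation granularity.
#' @param freq_floor lower bound on the simulated frequency.
#' @param inbred resample `pool_size` homozygous lines (TRUE, CSSL
#'   default) or `2 * pool_size` chromosomes (outbred pools).
#' @param seed RNG seed.
#' @return `records` with `lower` and `upper` columns appended; the cell
#'   table is attached as attribute `band_table`.
#' @export
confidence_bands <- function(records, pop_freq, pool_size = 30,
                             level = 0.99, n_sims = 10000,
                             freq_bin = 0.005, depth_bin = 10,
                             freq_floor = 0, inbred = TRUE, seed = 1L) {
  if (level <= 0 || level >= 1) stop("`level` must be in (0,1)")
  if (n_sims < 1000) warning("n_sims < 1000: bands will be noisy")
  if (length(pop_freq) != nrow(records))
    stop("`pop_freq` must align with `records`")
  p <- pmax(pop_freq, freq_floor)
  fb <- round(p / freq_bin) * freq_bin
  da <- pmax(round(records$depth_a / depth_bin) * depth_bin, 1)
  db <- pmax(round(records$depth_b / depth_bin) * depth_bin, 1)
  key <- paste(fb, da, db)
  cells <- !duplicated(key)
  qlo <- (1 - level) / 2; qhi <- 1 - qlo
  tab <- with_seed(seed, {
    do.call(rbind, lapply(which(cells), function(i) {
      pp <- fb[i]
      ndraw <- if (inbred) pool_size else 2 * pool_size
      fa <- stats::rbinom(n_sims, ndraw, pp) / ndraw
      fs <- stats::rbinom(n_sims, ndraw, pp) / ndraw
      ia <- stats::rbinom(n_sims, da[i], fa) / da[i]
      ib <- stats::rbinom(n_sims, db[i], fs) / db[i]
      dd <- ia - ib
      ## inverse-CDF (type 1) quantiles: interpolation is anti-conservative
      ## on the discrete delta support
      data.frame(key = key[i],
                 lower = stats::quantile(dd, qlo, names = FALSE, type = 1),
                 upper = stats::quantile(dd, qhi, names = FALSE, type = 1),
                 stringsAsFactors = FALSE)
    }))
  })
  m <- match(key, tab$key)
  records$lower <- tab$lower[m]
  records$upper <- tab$upper[m]
  attr(records, "band_table") <- tab
  records
}

#' Call significant BSA intervals from windowed deltas
#'
#' Maximal runs of consecutive unflagged windows whose `mean_delta`
#' exceeds the confidence band (above `upper` or below `lower`) are
#' merged into intervals, tolerating up to `gap_windows` sub-threshold
#' windows inside a run. Interval bounds are the outermost window bounds
#' and the peak is the window with the largest `|mean_delta|`.
#'
#' @param windows window table from [sliding_windows()] with band columns.
#' @param trait trait label (default "MFVD").
#' @param gap_windows sub-threshold windows tolerated inside a run.
#' @return QTL record data.frame (`method = "bsa"`).
#' @export
call_bsa_intervals <- function(windows, trait = "MFVD", gap_windows = 1) {
  w <- windows[!windows$flagged & !is.na(windows$mean_delta) &
                 !is.na(windows$upper), , drop = FALSE]
  exceed <- w$mean_delta > w$upper | w$mean_delta < w$lower
  out <- list()
  for (ch in unique(w$chrom)) {
    wi <- which(w$chrom == ch & exceed)
    if (length(wi) == 0) next
    s <- w[wi, ]
    o <- order(s$start_bp)
    s <- s[o, ]
    ## group exceeding windows; allow gap_windows missing steps between
    step <- if (nrow(w[w$chrom == ch, ]) > 1)
      min(diff(sort(unique(w$start_bp[w$chrom == ch])))) else 1
    grp <- cumsum(c(1, diff(s$start_bp) > (gap_windows + 1) * step))
    for (g in unique(grp)) {
      si <- s[grp == g, ]
      pk <- si[which.max(abs(si$mean_delta)), ]
      out[[length(out) + 1L]] <- data.frame(
        method = "bsa", trait = trait, chrom = ch,
        start_bp = min(si$start_bp), end_bp = max(si$end_bp),
        peak_bp = floor((pk$start_bp + pk$end_bp) / 2),
        peak_marker = NA_character_,
        statistic = max(abs(si$mean_delta)), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(method = character(0), trait = character(0),
                      chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), peak_bp = numeric(0),
                      peak_marker = character(0), statistic = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start_bp), ]
}
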