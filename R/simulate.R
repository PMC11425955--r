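#' Approximate chromosome map of the tetraploid cotton genome
#'
#' Returns the coordinate frame used by the synthetic study generator: the
#' 26 chromosomes of allotetraploid cotton (A01--A13, D01--D13) with
#' approximate physical lengths in base pairs, loosely following the TM-1
#' reference assembly (A subgenome chromosomes ~80--125 Mb, D subgenome
#' ~45--70 Mb, ~2.1 Gb total).
#'
#' @return A data.frame with columns `name` and `length_bp`.
#' @export
cotton_chrom_map <- function() {
  a_len <- c(117, 108, 113, 85, 109, 124, 97, 122, 82, 114, 120, 107, 108) * 1e6
  d_len <- c(63, 69, 52, 55, 61, 64, 55, 67, 51, 65, 71, 60, 62) * 1e6
  data.frame(
    name = c(sprintf("A%02d", 1:13), sprintf("D%02d", 1:13)),
    length_bp = as.numeric(c(a_len, d_len)),
    stringsAsFactors = FALSE
  )
}

validate_chrom_map <- function(chrom_map) {
  if (!is.data.frame(chrom_map) || !all(c("name", "length_bp") %in% names(chrom_map)))
    stop("`chrom_map` must be a data.frame with columns `name` and `length_bp`")
  if (any(duplicated(chrom_map$name))) stop("chromosome names must be unique")
  if (any(chrom_map$length_bp <= 0)) stop("chromosome lengths must be positive")
  invisible(chrom_map)
}

#' Simulate genotypes of a chromosome-segment substitution line panel
#'
#' Generates a bi-parentally coded SNP matrix for a CSSL panel: each line is
#' the recurrent-parent genome (dosage 0) carrying a small number of
#' introgressed donor segments, coded 2 (homozygous donor) or 1
#' (heterozygous) at every marker the segment covers. Segment endpoints are
#' free; marker dosage is determined by segment membership, so the realized
#' segment boundaries snap to the marker grid.
#'
#' Segments are either drawn at random per line (`segments` given as a
#' spec list) or supplied explicitly as a data.frame with columns
#' `line_id`, `chrom`, `start_bp`, `end_bp`, `dosage` (1 or 2). The random
#' draw takes a Poisson number of segments per line (mean
#' `mean_segments`), exponential lengths (mean `len_mean_bp`, truncated to
#' `[len_min_bp, len_max_bp]`), uniform placement on chromosomes chosen
#' proportionally to length, and rejects draws that would overlap an
#' existing segment of the same line or push the line's donor fraction
#' over `donor_cap`.
#'
#' `anchors` optionally lists loci that must segregate at an appreciable
#' donor frequency (e.g. planted QTL): for each row
#' (`chrom`, `pos_bp`, `n_carriers`) the given number of randomly chosen
#' lines receives one extra donor segment covering the locus, with
#' independently jittered endpoints. This mimics the enrichment of shared
#' introgressions in real CSSL panels, where loci not covered by recurring
#' segments are effectively monomorphic and fail the MAF filter.
#'
#' @param chrom_map data.frame of chromosome `name` and `length_bp`.
#' @param n_lines number of lines (>= 1).
#' @param markers_per_chrom markers simulated per chromosome (>= 2),
#'   near-evenly spaced with jitter.
#' @param segments random-draw spec list (`mean_segments`, `len_mean_bp`,
#'   `len_min_bp`, `len_max_bp`) or an explicit segment data.frame.
#' @param donor_cap maximum donor fraction of a line's genome (default 0.10).
#' @param het_prob probability a random segment is heterozygous rather than
#'   homozygous donor (default 0: CSSLs are near-fixed).
#' @param missing_rate fraction of genotype entries set missing (default 0.01).
#' @param anchors optional data.frame (`chrom`, `pos_bp`, `n_carriers`, and
#'   optionally `len_mean_bp`).
#' @param seed RNG seed.
#' @return list with `genotypes` (lines x markers integer matrix, entries
#'   0/1/2/NA), `info` (marker_id, chrom, pos_bp, maf, missing_rate) and
#'   `segments` (realized segment assignments).
#' @export
simulate_cssl_genotypes <- function(chrom_map = cotton_chrom_map(),
                                    n_lines = 319,
                                    markers_per_chrom = 400,
                                    segments = list(mean_segments = 5,
                                                    len_mean_bp = 18e6,
                                                    len_min_bp = 2e6,
                                                    len_max_bp = 40e6),
                                    donor_cap = 0.10,
                                    het_prob = 0,
                                    missing_rate = 0.01,
                                    anchors = NULL,
                                    seed = 1L) {
  validate_chrom_map(chrom_map)
  if (n_lines < 1) stop("`n_lines` must be >= 1")
  if (markers_per_chrom < 2) stop("`markers_per_chrom` must be >= 2")
  genome_bp <- sum(chrom_map$length_bp)
  line_ids <- sprintf("L%03d", seq_len(n_lines))

  with_seed(seed, {
    ## marker grid: near-even spacing with jitter, strictly increasing
    info <- do.call(rbind, lapply(seq_len(nrow(chrom_map)), function(ci) {
      L <- chrom_map$length_bp[ci]
      m <- markers_per_chrom
      base <- seq_len(m) * L / (m + 1)
      jit <- stats::runif(m, -0.3, 0.3) * L / (m + 1)
      pos <- sort(round(pmin(pmax(base + jit, 1), L)))
      while (anyDuplicated(pos)) pos <- sort(pos + cumsum(duplicated(pos)))
      data.frame(chrom = chrom_map$name[ci], pos_bp = pos,
                 stringsAsFactors = FALSE)
    }))
    info$marker_id <- paste0(info$chrom, "_", info$pos_bp)
    info <- info[, c("marker_id", "chrom", "pos_bp")]

    ## segment assignments
    if (is.data.frame(segments)) {
      seg <- segments
      need <- c("line_id", "chrom", "start_bp", "end_bp", "dosage")
      if (!all(need %in% names(seg)))
        stop("explicit `segments` needs columns ", paste(need, collapse = ", "))
      bad <- !(seg$chrom %in% chrom_map$name)
      if (any(bad)) stop("segment on unknown chromosome")
      len <- chrom_map$length_bp[match(seg$chrom, chrom_map$name)]
      if (any(seg$start_bp < 1 | seg$end_bp > len | seg$start_bp > seg$end_bp))
        stop("segment outside chromosome bounds")
      frac <- tapply(seg$end_bp - seg$start_bp + 1, seg$line_id, sum) / genome_bp
      if (any(frac > donor_cap))
        stop("explicit segments exceed the donor-fraction cap")
    } else {
      seg <- draw_random_segments(chrom_map, line_ids, segments,
                                  donor_cap, het_prob, genome_bp)
    }

    ## anchors: guarantee carriers at designated loci
    if (!is.null(anchors) && nrow(anchors) > 0) {
      seg <- add_anchor_segments(seg, anchors, chrom_map, line_ids,
                                 donor_cap, genome_bp)
    }

    ## code markers
    G <- matrix(0L, nrow = n_lines, ncol = nrow(info),
                dimnames = list(line_ids, info$marker_id))
    if (nrow(seg) > 0) {
      for (k in seq_len(nrow(seg))) {
        li <- match(seg$line_id[k], line_ids)
        if (is.na(li)) stop("segment for unknown line ", seg$line_id[k])
        hit <- which(info$chrom == seg$chrom[k] &
                       info$pos_bp >= seg$start_bp[k] &
                       info$pos_bp <= seg$end_bp[k])
        if (length(hit)) G[li, hit] <- as.integer(seg$dosage[k])
      }
    }

    if (missing_rate > 0) {
      nmiss <- round(missing_rate * length(G))
      if (nmiss > 0) G[sample(length(G), nmiss)] <- NA_integer_
    }

    f <- colMeans(G, na.rm = TRUE) / 2
    info$maf <- pmin(f, 1 - f)
    info$missing_rate <- colMeans(is.na(G))
    list(genotypes = G, info = info, segments = seg)
  })
}

draw_random_segments <- function(chrom_map, line_ids, spec, donor_cap,
                                 het_prob, genome_bp) {
  mean_segments <- spec$mean_segments %||% 5
  len_mean <- spec$len_mean_bp %||% 18e6
  len_min <- spec$len_min_bp %||% 2e6
  len_max <- spec$len_max_bp %||% 40e6
  rows <- list()
  for (id in line_ids) {
    ns <- stats::rpois(1, mean_segments)
    if (ns == 0) next
    placed <- data.frame(chrom = character(0), start_bp = numeric(0),
                         end_bp = numeric(0))
    donor_bp <- 0
    for (s in seq_len(ns)) {
      for (try in 1:8) {
        ci <- sample.int(nrow(chrom_map), 1, prob = chrom_map$length_bp)
        L <- chrom_map$length_bp[ci]
        len <- min(max(stats::rexp(1, 1 / len_mean), len_min), min(len_max, L - 1))
        start <- floor(stats::runif(1, 1, L - len))
        end <- floor(start + len)
        if (donor_bp + len > donor_cap * genome_bp) break
        same <- placed[placed$chrom == chrom_map$name[ci], , drop = FALSE]
        if (nrow(same) == 0 || all(end < same$start_bp | start > same$end_bp)) {
          placed <- rbind(placed, data.frame(chrom = chrom_map$name[ci],
                                             start_bp = start, end_bp = end))
          donor_bp <- donor_bp + len
          rows[[length(rows) + 1L]] <- data.frame(
            line_id = id, chrom = chrom_map$name[ci],
            start_bp = start, end_bp = end,
            dosage = if (stats::runif(1) < het_prob) 1L else 2L,
            stringsAsFactors = FALSE)
          break
        }
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(line_id = character(0), chrom = character(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      dosage = integer(0)))
  do.call(rbind, rows)
}

add_anchor_segments <- function(seg, anchors, chrom_map, line_ids,
                                donor_cap, genome_bp) {
  for (a in seq_len(nrow(anchors))) {
    chrom <- anchors$chrom[a]
    pos <- anchors$pos_bp[a]
    nc <- anchors$n_carriers[a]
    lm <- if ("len_mean_bp" %in% names(anchors)) anchors$len_mean_bp[a] else 12e6
    L <- chrom_map$length_bp[match(chrom, chrom_map$name)]
    if (is.na(L)) stop("anchor on unknown chromosome ", chrom)
    if (pos < 1 || pos > L) stop("anchor position outside chromosome")
    carriers <- sample(line_ids, min(nc, length(line_ids)))
    for (id in carriers) {
      len <- min(max(stats::rexp(1, 1 / lm), 4e6), 30e6)
      off <- stats::runif(1, 0.1, 0.9) # QTL sits at a random interior point
      start <- max(1, floor(pos - off * len))
      end <- min(L, floor(start + len))
      mine <- seg$line_id == id & seg$chrom == chrom
      hit <- mine & seg$start_bp <= end + 1 & seg$end_bp >= start - 1
      if (any(hit)) { # absorb overlapping segments into one
        start <- min(start, seg$start_bp[hit])
        end <- max(end, seg$end_bp[hit])
        seg <- seg[!hit, , drop = FALSE]
      }
      frac <- (sum(seg$end_bp[seg$line_id == id] - seg$start_bp[seg$line_id == id] + 1) +
                 end - start + 1) / genome_bp
      if (frac > donor_cap) next
      seg <- rbind(seg, data.frame(line_id = id, chrom = chrom,
                                   start_bp = start, end_bp = end,
                                   dosage = 2L, stringsAsFactors = FALSE))
    }
  }
  rownames(seg) <- NULL
  seg
}

# Donor dosage (0/1/2) of every line at one genomic position, from the
# ground-truth segment table (never affected by injected missingness).
segment_dosage_at <- function(segments, line_ids, chrom, pos_bp) {
  d <- stats::setNames(rep(0L, length(line_ids)), line_ids)
  hit <- segments$chrom == chrom & segments$start_bp <= pos_bp &
    segments$end_bp >= pos_bp
  if (any(hit)) {
    for (k in which(hit)) d[segments$line_id[k]] <- as.integer(segments$dosage[k])
  }
  d
}

#' Ground-truth specification for a synthetic CSSL study
#'
#' Bundles the planted QTL, the per-trait/condition means and variance
#' components, and the seed, so that downstream recovery can be scored
#' against known truth.
#'
#' @param qtl data.frame with columns `chrom`, `pos_bp`, `trait`,
#'   `effect_control`, `effect_drought` (trait units; the full effect is
#'   carried by homozygous-donor lines, half by heterozygotes).
#' @param trait_means data.frame `trait`, `condition`, `mean`.
#' @param variance_components data.frame `trait`, `condition`, `genetic`,
#'   `year`, `rep`, `residual` (variances, >= 0).
#' @param seed integer seed recorded with the truth.
#' @return object of class `cssl_truth`.
#' @export
cssl_truth <- function(qtl, trait_means, variance_components, seed = 1L) {
  vc <- variance_components
  if (any(vc$genetic < 0 | vc$year < 0 | vc$rep < 0 | vc$residual < 0))
    stop("variance components must be >= 0")
  if (!all(qtl$trait %in% trait_means$trait))
    stop("every QTL trait must appear in `trait_means`")
  structure(list(qtl = qtl, trait_means = trait_means,
                 variance_components = vc, seed = as.integer(seed)),
            class = "cssl_truth")
}

#' The 14 traits of the drought trial and their condition means
#'
#' Trait-by-condition population means used as generator defaults: seven
#' agronomic traits (PH, FT, WGP, FFSH, FFSBN, FSBN, EBN), three yield
#' traits (BW, LW, LP) and four fiber-quality traits (FUHML, FU, FS, MV).
#' Means under normal irrigation and drought mirror a two-year field trial
#' of the E22 x 3-79 introgression panel (e.g. WGP 131.665 vs 128.522 days,
#' PH 65.507 vs 37.541 cm, BW 5.293 vs 5.215 g).
#'
#' @return data.frame `trait`, `condition`, `mean`.
#' @export
default_trait_means <- function() {
  tm <- rbind(
    c("PH",    65.507, 37.541),
    c("FT",    62.000, 59.500),
    c("WGP",  131.665, 128.522),
    c("FFSH",  21.400, 16.800),
    c("FFSBN",  6.300,  5.400),
    c("FSBN",   7.804,  4.999),
    c("EBN",    5.539,  2.997),
    c("BW",     5.293,  5.215),
    c("LW",     2.420,  2.375),
    c("LP",    39.500, 39.800),
    c("FUHML", 26.973, 26.427),
    c("FU",    83.829, 83.507),
    c("FS",    25.985, 26.301),
    c("MV",     4.633,  5.405))
  data.frame(
    trait = rep(tm[, 1], each = 2),
    condition = rep(c("control", "drought"), nrow(tm)),
    mean = as.numeric(t(tm[, 2:3])),
    stringsAsFactors = FALSE
  )
}

#' Default ground truth: five condition-specific pleiotropic QTL
#'
#' Five planted QTL on five chromosomes, each affecting two of the eight
#' MFVD basis traits only under drought (effect_control = 0). Effects are
#' +8% of the trait's control mean for homozygous donor carriers, i.e. a
#' drought-resistance-coefficient shift of about +0.08, which at ~30
#' carriers out of 319 lines corresponds to roughly 15--25% of the DRC
#' variance per trait. Variance components default to coefficients of
#' variation of 3% (line genetic), 1.5% (year), 0.8% (replicate within
#' year) and 3% (residual) of each condition mean.
#'
#' @param n_qtl number of planted QTL (1--5), taken from the default list.
#' @param effect_frac drought effect as a fraction of the control mean.
#' @param seed recorded seed.
#' @return a [cssl_truth()] object.
#' @export
default_truth <- function(n_qtl = 5, effect_frac = 0.08, seed = 1L) {
  tm <- default_trait_means()
  loci <- data.frame(
    chrom = c("A11", "D09", "D06", "A04", "D07"),
    pos_bp = c(118.3e6, 40.7e6, 8.95e6, 60e6, 30e6),
    traits = I(list(c("FS", "FUHML"), c("FUHML", "FU"), c("EBN", "BW"),
                    c("LP", "FS"), c("BW", "LW"))),
    stringsAsFactors = FALSE
  )[seq_len(n_qtl), , drop = FALSE]
  qtl <- if (n_qtl == 0) {
    data.frame(chrom = character(0), pos_bp = numeric(0), trait = character(0),
               effect_control = numeric(0), effect_drought = numeric(0))
  } else do.call(rbind, lapply(seq_len(nrow(loci)), function(i) {
    trs <- loci$traits[[i]]
    mc <- tm$mean[tm$condition == "control"][match(trs, tm$trait[tm$condition == "control"])]
    data.frame(chrom = loci$chrom[i], pos_bp = loci$pos_bp[i], trait = trs,
               effect_control = 0, effect_drought = effect_frac * mc,
               stringsAsFactors = FALSE)
  }))
  cv <- c(genetic = 0.03, year = 0.015, rep = 0.008, residual = 0.03)
  vc <- data.frame(
    trait = tm$trait, condition = tm$condition,
    genetic = (cv["genetic"] * tm$mean)^2,
    year = (cv["year"] * tm$mean)^2,
    rep = (cv["rep"] * tm$mean)^2,
    residual = (cv["residual"] * tm$mean)^2,
    row.names = NULL, stringsAsFactors = FALSE
  )
  cssl_truth(qtl, tm, vc, seed = seed)
}

#' Simulate multi-year, two-condition phenotypes for a CSSL panel
#'
#' Draws trait observations under the additive decomposition
#' `value = mean(trait, condition) + polygenic line effect +
#' sum(QTL dosage/2 * condition effect) + year effect +
#' replicate-within-year effect + residual`, with all random terms
#' Gaussian at the variances recorded in `truth`. The polygenic line
#' effect is drawn independently per trait and condition; QTL dosage
#' comes from the ground-truth segment table so injected genotype
#' missingness never distorts the phenotypes. QTL positions must fall on
#' a simulated marker when `info` is supplied.
#'
#' @param assignments segment data.frame as returned by
#'   [simulate_cssl_genotypes()].
#' @param truth a [cssl_truth()] object.
#' @param line_ids character vector of line ids.
#' @param n_years,n_reps design: years and replicates within year.
#' @param info optional marker table used to check the QTL-on-marker
#'   invariant.
#' @param seed RNG seed.
#' @return long data.frame `line_id`, `trait`, `condition`, `year`,
#'   `replicate`, `value`.
#' @export
simulate_phenotypes <- function(assignments, truth, line_ids,
                                n_years = 2, n_reps = 2,
                                info = NULL, seed = 1L) {
  if (!inherits(truth, "cssl_truth")) stop("`truth` must be a cssl_truth object")
  vc <- truth$variance_components
  if (!is.null(info) && nrow(truth$qtl) > 0) {
    on_marker <- mapply(function(ch, p)
      any(info$chrom == ch & info$pos_bp == p),
      truth$qtl$chrom, truth$qtl$pos_bp)
    if (!all(on_marker))
      stop("every QTL position must coincide with a simulated marker")
  }
  tm <- truth$trait_means
  traits <- unique(tm$trait)
  conditions <- unique(tm$condition)
  n <- length(line_ids)

  ## QTL dosage per line (ground truth)
  qd <- lapply(seq_len(nrow(truth$qtl)), function(i)
    segment_dosage_at(assignments, line_ids,
                      truth$qtl$chrom[i], truth$qtl$pos_bp[i]))

  with_seed(seed, {
    out <- vector("list", length(traits) * length(conditions))
    k <- 0L
    for (tr in traits) for (cond in conditions) {
      k <- k + 1L
      mu <- tm$mean[tm$trait == tr & tm$condition == cond]
      v <- vc[vc$trait == tr & vc$condition == cond, ]
      if (nrow(v) != 1) stop("variance components missing for ", tr, "/", cond)
      g <- stats::rnorm(n, 0, sqrt(v$genetic))
      qsum <- rep(0, n)
      for (i in seq_len(nrow(truth$qtl))) {
        if (truth$qtl$trait[i] != tr) next
        eff <- if (cond == "drought") truth$qtl$effect_drought[i]
               else truth$qtl$effect_control[i]
        qsum <- qsum + (qd[[i]] / 2) * eff
      }
      yr_eff <- stats::rnorm(n_years, 0, sqrt(v$year))
      rep_eff <- matrix(stats::rnorm(n_years * n_reps, 0, sqrt(v$rep)),
                        n_years, n_reps)
      for (y in seq_len(n_years)) for (r in seq_len(n_reps)) {
        e <- stats::rnorm(n, 0, sqrt(v$residual))
        out[[length(out) + 1L]] <- data.frame(
          line_id = line_ids, trait = tr, condition = cond,
          year = y, replicate = r,
          value = mu + g + qsum + yr_eff[y] + rep_eff[y, r] + e,
          stringsAsFactors = FALSE)
      }
    }
    obs <- do.call(rbind, out)
    rownames(obs) <- NULL
    obs
  })
}

#' Simulate pooled sequencing depths for bulked segregant analysis
#'
#' For two disjoint line pools, computes each pool's true donor-allele
#' frequency at every marker (mean dosage over pool members / 2), draws a
#' Poisson read depth per pool and site around `mean_depth`, and samples
#' donor reads binomially at the pool frequency. Parents are homozygous
#' discordant at every simulated marker by construction.
#'
#' @param genotypes lines x markers dosage matrix.
#' @param info marker table (marker_id, chrom, pos_bp).
#' @param pool_a,pool_b character vectors of line ids (disjoint,
#'   non-empty); pool `a` is conventionally the drought-resistant pool.
#' @param mean_depth mean sequencing depth per pool and site (> 0).
#' @param seed RNG seed.
#' @return data.frame with per-pool donor/recurrent read counts per site.
#' @export
simulate_pool_depths <- function(genotypes, info, pool_a, pool_b,
                                 mean_depth = 50, seed = 1L) {
  if (mean_depth <= 0) stop("`mean_depth` must be positive")
  if (length(pool_a) == 0 || length(pool_b) == 0) stop("pools must be non-empty")
  if (length(intersect(pool_a, pool_b)) > 0) stop("pools must be disjoint")
  miss <- setdiff(c(pool_a, pool_b), rownames(genotypes))
  if (length(miss)) stop("pool lines absent from genotypes: ",
                         paste(miss, collapse = ", "))
  m <- ncol(genotypes)
  fa <- colMeans(genotypes[pool_a, , drop = FALSE], na.rm = TRUE) / 2
  fb <- colMeans(genotypes[pool_b, , drop = FALSE], na.rm = TRUE) / 2
  fa[is.nan(fa)] <- 0; fb[is.nan(fb)] <- 0
  with_seed(seed, {
    da <- stats::rpois(m, mean_depth)
    db <- stats::rpois(m, mean_depth)
    xa <- stats::rbinom(m, da, fa)
    xb <- stats::rbinom(m, db, fb)
    data.frame(marker_id = info$marker_id, chrom = info$chrom,
               pos_bp = info$pos_bp,
               donor_a = xa, recurrent_a = da - xa,
               donor_b = xb, recurrent_b = db - xb,
               parent_donor = 2L, parent_recurrent = 0L,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a null panel with a polygenic trait
#'
#' Generic marker panel (independent biallelic dosages at uniformly drawn
#' allele frequencies) plus a phenotype whose genetic part is the sum of
#' tiny effects of all markers, scaled to a target narrow-sense
#' heritability. No individual marker carries an appreciable effect, so
#' the panel serves as a null for association-test calibration under
#' polygenic background structure.
#'
#' @param n_lines,n_markers panel size.
#' @param h2 heritability of the polygenic trait in (0, 1).
#' @param maf_range range of simulated allele frequencies.
#' @param seed RNG seed.
#' @return list `genotypes`, `info`, `phenotype` (named vector).
#' @export
simulate_polygenic_study <- function(n_lines = 300, n_markers = 5000,
                                     h2 = 0.5, maf_range = c(0.1, 0.5),
                                     seed = 1L) {
  if (h2 <= 0 || h2 >= 1) stop("`h2` must be in (0, 1)")
  with_seed(seed, {
    f <- stats::runif(n_markers, maf_range[1], maf_range[2])
    G <- vapply(f, function(p) stats::rbinom(n_lines, 2, p), integer(n_lines))
    line_ids <- sprintf("L%03d", seq_len(n_lines))
    rownames(G) <- line_ids
    n_chr <- 10L
    chrom <- sprintf("C%02d", rep(seq_len(n_chr), length.out = n_markers))
    pos <- as.numeric(stats::ave(seq_len(n_markers), chrom, FUN = seq_along)) * 1e5
    info <- data.frame(marker_id = sprintf("M%05d", seq_len(n_markers)),
                       chrom = chrom, pos_bp = pos, stringsAsFactors = FALSE)
    colnames(G) <- info$marker_id
    a <- stats::rnorm(n_markers, 0, 1)
    gv <- as.numeric(scale(G %*% a))
    y <- sqrt(h2) * gv + sqrt(1 - h2) * stats::rnorm(n_lines)
    list(genotypes = G, info = info,
         phenotype = stats::setNames(as.numeric(y), line_ids))
  })
}

#' Simulate a complete default CSSL drought study
#'
#' Convenience wrapper assembling the default study: 319 lines, 26
#' chromosomes, `markers_per_chrom` markers each, random donor segments
#' plus ~30 anchored carriers at each of five planted condition-specific
#' QTL, and phenotypes for 14 traits under 2 conditions x 2 years x 2
#' replicates.
#'
#' @param seed master seed; per-stage child seeds are derived from it.
#' @param n_lines,markers_per_chrom panel shape.
#' @param truth a [cssl_truth()] (default [default_truth()]).
#' @param n_carriers anchored carrier lines per planted QTL.
#' @return list `chrom_map`, `genotypes`, `info`, `segments`, `truth`,
#'   `observations`.
#' @export
simulate_cssl_study <- function(seed = 1L, n_lines = 319,
                                markers_per_chrom = 400,
                                truth = default_truth(seed = seed),
                                n_carriers = 30) {
  cm <- cotton_chrom_map()
  loci <- unique(truth$qtl[, c("chrom", "pos_bp")])
  anchors <- data.frame(chrom = loci$chrom, pos_bp = loci$pos_bp,
                        n_carriers = n_carriers, stringsAsFactors = FALSE)
  sim <- simulate_cssl_genotypes(cm, n_lines = n_lines,
                                 markers_per_chrom = markers_per_chrom,
                                 anchors = anchors,
                                 seed = child_seed(seed, 1))
  ## snap QTL positions to the nearest simulated marker
  for (i in seq_len(nrow(truth$qtl))) {
    on_chr <- sim$info[sim$info$chrom == truth$qtl$chrom[i], ]
    j <- which.min(abs(on_chr$pos_bp - truth$qtl$pos_bp[i]))
    truth$qtl$pos_bp[i] <- on_chr$pos_bp[j]
  }
  obs <- simulate_phenotypes(sim$segments, truth, rownames(sim$genotypes),
                             n_years = 2, n_reps = 2, info = sim$info,
                             seed = child_seed(seed, 2))
  list(chrom_map = cm, genotypes = sim$genotypes, info = sim$info,
       segments = sim$segments, truth = truth, observations = obs)
}
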