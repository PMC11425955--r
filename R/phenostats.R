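#' Percent change of a trait mean under drought
#'
#' `100 * (mean_control - mean_drought) / mean_control`: positive values
#' are reductions under drought. Undefined (NA) when the control mean is
#' zero.
#'
#' @param mean_control,mean_drought condition means (trait units).
#' @return percent change (vectorized).
#' @export
percent_change <- function(mean_control, mean_drought) {
  out <- 100 * (mean_control - mean_drought) / mean_control
  out[mean_control == 0] <- NA_real_
  out
}

#' Condition-wise summary of one trait
#'
#' Means, standard deviations and coefficients of variation (CV = sd/mean)
#' of the per-line BLUP values under each condition, plus the percent
#' change of the mean from control to drought.
#'
#' @param blups long BLUP table from [blup_table()].
#' @param trait trait name.
#' @return one-row data.frame with `mean_control`, `mean_drought`,
#'   `percent_change`, `sd_control`, `sd_drought`, `cv_control`,
#'   `cv_drought`.
#' @export
summarize_condition <- function(blups, trait) {
  d <- blups[blups$trait == trait, ]
  if (!all(c("control", "drought") %in% d$condition))
    stop("both conditions required for ", trait)
  mc <- mean(d$blup[d$condition == "control"], na.rm = TRUE)
  md <- mean(d$blup[d$condition == "drought"], na.rm = TRUE)
  sc <- stats::sd(d$blup[d$condition == "control"], na.rm = TRUE)
  sd_ <- stats::sd(d$blup[d$condition == "drought"], na.rm = TRUE)
  data.frame(trait = trait, mean_control = mc, mean_drought = md,
             percent_change = percent_change(mc, md),
             sd_control = sc, sd_drought = sd_,
             cv_control = sc / mc, cv_drought = sd_ / md,
             stringsAsFactors = FALSE)
}

#' Drought-resistance coefficients
#'
#' DRC = drought value / control value per line and trait, computed from
#' the condition-wise BLUPs. Cells with a non-positive or missing control
#' value are NA and listed in the `undefined` attribute rather than being
#' silently zeroed.
#'
#' @param blups long BLUP table.
#' @return wide data.frame: `line_id` plus one `DRC_<trait>` column per
#'   trait; attribute `undefined` records flagged cells.
#' @export
compute_drc <- function(blups) {
  traits <- unique(blups$trait)
  lines <- unique(blups$line_id)
  out <- data.frame(line_id = lines, stringsAsFactors = FALSE)
  flagged <- list()
  for (tr in traits) {
    ctrl <- blups[blups$trait == tr & blups$condition == "control", ]
    drt <- blups[blups$trait == tr & blups$condition == "drought", ]
    cv <- ctrl$blup[match(lines, ctrl$line_id)]
    dv <- drt$blup[match(lines, drt$line_id)]
    drc <- dv / cv
    bad <- is.na(cv) | is.na(dv) | cv <= 0
    drc[bad] <- NA_real_
    if (any(bad))
      flagged[[tr]] <- data.frame(line_id = lines[bad], trait = tr,
                                  stringsAsFactors = FALSE)
    out[[paste0("DRC_", tr)]] <- drc
  }
  attr(out, "undefined") <- if (length(flagged)) do.call(rbind, flagged) else
    data.frame(line_id = character(0), trait = character(0))
  out
}

#' Membership-function value of drought resistance (MFVD)
#'
#' Min-max rescales the DRC of each basis trait over the population
#' (higher-better trait: `(x - min)/(max - min)`; lower-better:
#' `(max - x)/(max - min)`) and averages the memberships. By default the
#' eight basis traits are the four yield traits (BW, LW, LP, EBN) and the
#' four fiber-quality traits (FUHML, FS, MV, FU), all oriented
#' higher-better on the DRC scale; micronaire (MV) has an optimal quality
#' band rather than a monotone one, so its orientation is exposed for
#' override. A trait constant over the population gets membership 0.5
#' for every line, with a warning. Lines missing some basis DRCs are
#' averaged over the available traits, with the missing count recorded.
#'
#' @param drc wide DRC table from [compute_drc()].
#' @param basis_traits character vector of trait names (without the
#'   `DRC_` prefix).
#' @param orientation named character vector, `"higher"` or `"lower"` per
#'   basis trait; unnamed defaults to `"higher"` for all.
#' @return data.frame `line_id`, `mfvd`, `n_missing`, plus one
#'   `mem_<trait>` column per basis trait.
#' @export
compute_mfvd <- function(drc,
                         basis_traits = c("BW", "LW", "LP", "EBN",
                                          "FUHML", "FS", "MV", "FU"),
                         orientation = NULL) {
  ori <- stats::setNames(rep("higher", length(basis_traits)), basis_traits)
  if (!is.null(orientation)) ori[names(orientation)] <- orientation
  cols <- paste0("DRC_", basis_traits)
  miss <- setdiff(cols, names(drc))
  if (length(miss)) stop("DRC columns missing: ", paste(miss, collapse = ", "))
  mem <- matrix(NA_real_, nrow(drc), length(basis_traits),
                dimnames = list(NULL, paste0("mem_", basis_traits)))
  for (i in seq_along(basis_traits)) {
    x <- drc[[cols[i]]]
    if (sum(!is.na(x)) < 2) stop("need >= 2 lines with defined DRC for ",
                                 basis_traits[i])
    rng <- range(x, na.rm = TRUE)
    if (diff(rng) == 0) {
      warning("DRC constant for trait ", basis_traits[i],
              "; membership set to 0.5")
      m <- ifelse(is.na(x), NA_real_, 0.5)
    } else if (ori[basis_traits[i]] == "higher") {
      m <- (x - rng[1]) / diff(rng)
    } else {
      m <- (rng[2] - x) / diff(rng)
    }
    mem[, i] <- m
  }
  out <- data.frame(line_id = drc$line_id,
                    mfvd = rowMeans(mem, na.rm = TRUE),
                    n_missing = rowSums(is.na(mem)),
                    stringsAsFactors = FALSE)
  out$mfvd[out$n_missing == length(basis_traits)] <- NA_real_
  cbind(out, as.data.frame(mem))
}

#' Five-level drought-resistance grading
#'
#' Assigns grades I (most drought sensitive) to V (most drought tolerant)
#' by banding the MFVD distribution at four ascending cutoffs. Intervals
#' are half-open and lower-inclusive on the upper side: grade V iff
#' `mfvd >= c4`, grade I iff `mfvd < c1`. Default cutoffs are
#' `mean(mfvd) + c(-1.5, -0.5, 0.5, 1.5) * sd(mfvd)`.
#'
#' @param mfvd data.frame from [compute_mfvd()] (needs `line_id`, `mfvd`).
#' @param cutoffs four strictly ascending thresholds, or NULL for the
#'   default.
#' @return list with `grades` (line_id, mfvd, grade), `counts` (named
#'   I..V), `cutoffs`.
#' @export
grade_lines <- function(mfvd, cutoffs = NULL) {
  x <- mfvd$mfvd
  if (is.null(cutoffs)) {
    mu <- mean(x, na.rm = TRUE); s <- stats::sd(x, na.rm = TRUE)
    cutoffs <- mu + c(-1.5, -0.5, 0.5, 1.5) * s
  }
  if (length(cutoffs) != 4 || any(diff(cutoffs) <= 0))
    stop("`cutoffs` must be four strictly ascending thresholds")
  lev <- c("I", "II", "III", "IV", "V")
  gi <- findInterval(x, cutoffs) + 1L   # c_i <= x < c_{i+1}
  grade <- factor(lev[gi], levels = lev)
  counts <- table(grade)
  list(grades = data.frame(line_id = mfvd$line_id, mfvd = x, grade = grade,
                           stringsAsFactors = FALSE),
       counts = stats::setNames(as.integer(counts), lev),
       cutoffs = cutoffs)
}

#' Pearson correlation network of DRC traits
#'
#' One edge per unordered trait pair (n traits give `choose(n, 2)`
#' edges), with the Pearson coefficient over pairwise-complete lines, a
#' two-sided p-value, and a significance flag at `p < p_max` and
#' `|r| > r_min` on the signed coefficient. Pairs involving a constant
#' trait are flagged undefined (`r = NA`).
#'
#' @param drc wide DRC table from [compute_drc()] (every `DRC_` column is
#'   used).
#' @param p_max,r_min significance rule (defaults 0.05 and 0.1).
#' @return data.frame `trait_a`, `trait_b`, `n`, `r`, `p`, `significant`.
#' @export
correlation_network <- function(drc, p_max = 0.05, r_min = 0.1) {
  cols <- grep("^DRC_", names(drc), value = TRUE)
  traits <- sub("^DRC_", "", cols)
  if (length(cols) < 2) stop("need >= 2 DRC traits")
  out <- list()
  for (i in seq_len(length(cols) - 1)) for (j in (i + 1):length(cols)) {
    x <- drc[[cols[i]]]; y <- drc[[cols[j]]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      r <- NA_real_; p <- NA_real_
    } else {
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      r <- unname(ct$estimate); p <- ct$p.value
    }
    out[[length(out) + 1L]] <- data.frame(
      trait_a = traits[i], trait_b = traits[j], n = n, r = r, p = p,
      significant = !is.na(r) & p < p_max & abs(r) > r_min,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Physiology formulas: relative conductivity, MDA, expression fold change
#'
#' Computes, for vectors of raw readings: relative electrical
#' conductivity `REC = C1/C2 * 100` (percent; undefined when C2 <= 0);
#' malondialdehyde content `MDA = 25.8 * (A532 - A600)/fresh_weight`
#' (nmol per g fresh weight); and the qPCR relative expression fold
#' `2^-ddCt` with
#' `ddCt = (ct_target_treated - ct_ref_treated) - (ct_target_control - ct_ref_control)`.
#' Readings with `C1 > C2` (conductivity after boiling should bound the
#' initial reading) are computed but flagged.
#'
#' @param c1,c2 initial and post-boil conductivity readings.
#' @param a532,a600 absorbances; `fresh_weight` in grams (> 0).
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   cycle thresholds.
#' @return list with `rec`, `mda`, `fold_expression` and a `flags`
#'   data.frame.
#' @export
physiology <- function(c1 = NULL, c2 = NULL,
                       a532 = NULL, a600 = NULL, fresh_weight = NULL,
                       ct_target_treated = NULL, ct_ref_treated = NULL,
                       ct_target_control = NULL, ct_ref_control = NULL) {
  rec <- mda <- fold <- NULL
  flags <- list()
  if (!is.null(c1)) {
    rec <- ifelse(c2 > 0, c1 / c2 * 100, NA_real_)
    if (any(c2 <= 0, na.rm = TRUE))
      flags$rec_undefined <- which(c2 <= 0)
    if (any(c1 > c2, na.rm = TRUE))
      flags$conductivity_order <- which(c1 > c2)
  }
  if (!is.null(a532)) {
    if (any(fresh_weight <= 0)) stop("`fresh_weight` must be positive")
    mda <- 25.8 * (a532 - a600) / fresh_weight
  }
  if (!is.null(ct_target_treated)) {
    ddct <- (ct_target_treated - ct_ref_treated) -
      (ct_target_control - ct_ref_control)
    fold <- 2^(-ddct)
  }
  list(rec = rec, mda = mda, fold_expression = fold, flags = flags)
}
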