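#' Name QTL records by trait, chromosome and positional ordinal
#'
#' Names follow the convention `q.<TRAIT>.<Chr>.<k>`: "q", the trait
#' abbreviation, the chromosome, and the 1-based ordinal of the QTL among
#' records of the same trait on the same chromosome, in positional order
#' (e.g. `q.DRC_FS.A11.1`). Renaming is idempotent: names are recomputed
#' from scratch.
#'
#' @param records QTL record data.frame with `trait`, `chrom`, `start_bp`.
#' @return the records with a `name` column (first).
#' @export
name_qtl <- function(records) {
  records$name <- NA_character_
  if (nrow(records) > 0) {
    o <- order(records$trait, records$chrom, records$start_bp)
    r <- records[o, ]
    key <- paste(r$trait, r$chrom)
    ord <- stats::ave(seq_len(nrow(r)), key, FUN = seq_along)
    records$name[o] <- sprintf("q.%s.%s.%d", r$trait, r$chrom, ord)
  }
  records[, c("name", setdiff(names(records), "name"))]
}

#' Co-localize QTL intervals across mapping methods
#'
#' Single-linkage grouping of intervals on the same chromosome that
#' overlap by at least `min_overlap_bp`: any two records whose intervals
#' overlap are in the same group, and groups are the transitive closure.
#' Every record belongs to exactly one group. Each group reports its
#' span, the supporting methods and traits, and the summary counts the
#' groups supported by at least two and by all three methods.
#'
#' @param records QTL record data.frame (`method`, `trait`, `chrom`,
#'   `start_bp`, `end_bp`).
#' @param min_overlap_bp minimum overlap (default 1 bp).
#' @return list `records` (with `group` column), `groups` (per-group
#'   span, methods, traits, n_methods), `counts` (n_groups,
#'   multi_method, all_three).
#' @export
colocalize <- function(records, min_overlap_bp = 1) {
  n <- nrow(records)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (ch in unique(records$chrom)) {
    idx <- which(records$chrom == ch)
    if (length(idx) < 2) next
    ir <- IRanges::IRanges(start = records$start_bp[idx],
                           end = records$end_bp[idx])
    ov <- IRanges::findOverlaps(ir, minoverlap = min_overlap_bp,
                                drop.self = TRUE, drop.redundant = TRUE)
    for (k in seq_along(ov)) {
      a <- find(idx[S4Vectors::queryHits(ov)[k]])
      b <- find(idx[S4Vectors::subjectHits(ov)[k]])
      if (a != b) parent[a] <- b
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  group <- match(root, unique(root))
  records$group <- group
  groups <- do.call(rbind, lapply(sort(unique(group)), function(g) {
    r <- records[group == g, ]
    data.frame(group = g, chrom = r$chrom[1],
               start_bp = min(r$start_bp), end_bp = max(r$end_bp),
               n_records = nrow(r),
               n_methods = length(unique(r$method)),
               methods = paste(sort(unique(r$method)), collapse = ","),
               traits = paste(sort(unique(r$trait)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  counts <- c(n_groups = nrow(groups),
              multi_method = sum(groups$n_methods >= 2),
              all_three = sum(groups$n_methods == 3))
  list(records = records, groups = groups, counts = counts)
}

#' Classify line haplotypes at QTL peak SNPs
#'
#' Each line's haplotype at a QTL is read off its genotype at the QTL's
#' highlighted SNP: dosage 2 is `hap_donor` (matching the donor parent),
#' 0 is `hap_recurrent`, 1 is `het`, missing is `unknown`. Records
#' without a `peak_marker` present in the matrix use the marker nearest
#' their peak position on the same chromosome; QTL on chromosomes with no
#' markers get all-unknown calls with a warning.
#'
#' @param genotypes dosage matrix.
#' @param info marker table.
#' @param qtl named QTL record data.frame (needs `name`, `chrom`,
#'   `peak_bp`, optionally `peak_marker`).
#' @return data.frame `line_id`, `qtl_name`, `marker_id`, `call`.
#' @export
classify_haplotypes <- function(genotypes, info, qtl) {
  lines <- rownames(genotypes)
  out <- list()
  for (i in seq_len(nrow(qtl))) {
    mk <- if (!is.null(qtl$peak_marker) && !is.na(qtl$peak_marker[i]) &&
                qtl$peak_marker[i] %in% colnames(genotypes))
      qtl$peak_marker[i] else NA
    if (is.na(mk)) {
      on_chr <- which(info$chrom == qtl$chrom[i])
      if (length(on_chr) == 0) {
        warning("no marker for QTL ", qtl$name[i], "; calls unknown")
        out[[i]] <- data.frame(line_id = lines, qtl_name = qtl$name[i],
                               marker_id = NA_character_, call = "unknown",
                               stringsAsFactors = FALSE)
        next
      }
      mk <- info$marker_id[on_chr[which.min(abs(info$pos_bp[on_chr] -
                                                  qtl$peak_bp[i]))]]
    }
    d <- genotypes[, mk]
    call <- ifelse(is.na(d), "unknown",
                   ifelse(d == 2, "hap_donor",
                          ifelse(d == 0, "hap_recurrent", "het")))
    out[[i]] <- data.frame(line_id = lines, qtl_name = qtl$name[i],
                           marker_id = mk, call = call,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Choose the drought-resistant haplotype at each QTL
#'
#' For each QTL, lines are split by haplotype call (hets and unknowns
#' excluded) and the group with the larger mean of the QTL's associated
#' DRC trait (or MFVD) is labelled the drought-resistant haplotype; the
#' contrast is reported with a two-sided Welch t-test. QTL with an empty
#' group are flagged unscorable; exact ties get no label.
#'
#' @param calls haplotype calls from [classify_haplotypes()].
#' @param pheno data.frame with `line_id` and the phenotype columns named
#'   in `per_qtl_trait` (e.g. a DRC table or an MFVD table).
#' @param per_qtl_trait named character vector: QTL name -> phenotype
#'   column.
#' @return data.frame per QTL: `qtl_name`, `trait`, `resistant`,
#'   `mean_donor`, `mean_recurrent`, `n_donor`, `n_recurrent`, `p`,
#'   `scorable`.
#' @export
choose_resistant_haplotype <- function(calls, pheno, per_qtl_trait) {
  out <- list()
  for (qn in unique(calls$qtl_name)) {
    tr <- per_qtl_trait[[qn]]
    if (is.null(tr) || !(tr %in% names(pheno)))
      stop("no phenotype column for QTL ", qn)
    cc <- calls[calls$qtl_name == qn, ]
    v <- pheno[[tr]][match(cc$line_id, pheno$line_id)]
    vd <- v[cc$call == "hap_donor" & !is.na(v)]
    vr <- v[cc$call == "hap_recurrent" & !is.na(v)]
    if (length(vd) == 0 || length(vr) == 0) {
      out[[length(out) + 1L]] <- data.frame(
        qtl_name = qn, trait = tr, resistant = NA_character_,
        mean_donor = if (length(vd)) mean(vd) else NA_real_,
        mean_recurrent = if (length(vr)) mean(vr) else NA_real_,
        n_donor = length(vd), n_recurrent = length(vr),
        p = NA_real_, scorable = FALSE, stringsAsFactors = FALSE)
      next
    }
    md <- mean(vd); mr <- mean(vr)
    lab <- if (md > mr) "hap_donor" else if (mr > md) "hap_recurrent"
           else NA_character_
    p <- if (length(vd) > 1 && length(vr) > 1)
      tryCatch(stats::t.test(vd, vr)$p.value, error = function(e) NA_real_)
    else NA_real_
    out[[length(out) + 1L]] <- data.frame(
      qtl_name = qn, trait = tr, resistant = lab,
      mean_donor = md, mean_recurrent = mr,
      n_donor = length(vd), n_recurrent = length(vr),
      p = p, scorable = !is.na(lab), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Pyramiding analysis: resistant-locus counts versus MFVD
#'
#' Counts, per line, the scored QTL at which the line's haplotype call
#' equals the drought-resistant label, then correlates the count with
#' MFVD (Pearson, two-sided). Lines carrying the resistant haplotype at
#' every scored QTL are listed. An all-identical count vector leaves the
#' correlation undefined (flagged NA).
#'
#' @param calls haplotype calls from [classify_haplotypes()].
#' @param resistant result of [choose_resistant_haplotype()].
#' @param mfvd data.frame with `line_id` and `mfvd`.
#' @return list `counts` (line_id, resistant_count, mfvd), `r`, `p`,
#'   `n_scored_qtl`, `full_stack_lines`.
#' @export
pyramiding_analysis <- function(calls, resistant, mfvd) {
  sc <- resistant[resistant$scorable, ]
  if (nrow(sc) < 2) stop("need >= 2 scorable QTL")
  cc <- calls[calls$qtl_name %in% sc$qtl_name, ]
  lab <- stats::setNames(sc$resistant, sc$qtl_name)
  cc$hit <- cc$call == lab[cc$qtl_name]
  counts <- stats::aggregate(hit ~ line_id, data = cc, FUN = sum)
  names(counts)[2] <- "resistant_count"
  counts$mfvd <- mfvd$mfvd[match(counts$line_id, mfvd$line_id)]
  ok <- stats::complete.cases(counts$resistant_count, counts$mfvd)
  if (stats::sd(counts$resistant_count[ok]) == 0 ||
      stats::sd(counts$mfvd[ok]) == 0) {
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- stats::cor.test(counts$resistant_count[ok], counts$mfvd[ok])
    r <- unname(ct$estimate); p <- ct$p.value
  }
  full <- counts$line_id[counts$resistant_count == nrow(sc)]
  list(counts = counts, r = r, p = p, n_scored_qtl = nrow(sc),
       full_stack_lines = full)
}
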