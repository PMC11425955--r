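# Standard-format input/output. Coordinates are 1-based inclusive
# everywhere inside the package; BED-like interval output is 0-based
# half-open, converted on the way out and back.

#' Write a dosage matrix as a VCF
#'
#' Emits one biallelic record per marker with REF the recurrent-parent
#' allele and ALT the donor allele; sample GT fields are 0/0, 0/1, 1/1 or
#' ./. for dosages 0, 1, 2, NA. Positions are 1-based. The file is
#' bgzip-compressed when the path ends in `.gz` (via [vcfR::write.vcf]),
#' plain text otherwise.
#'
#' @param genotypes lines x markers dosage matrix.
#' @param info marker table (marker_id, chrom, pos_bp).
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, info, file) {
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow(info), nrow(genotypes))
  g <- t(genotypes)
  ok <- !is.na(g)
  gt[ok] <- gt_code[as.character(g[ok])]
  colnames(gt) <- rownames(genotypes)
  write_vcf_table(file,
                  chrom = info$chrom, pos = info$pos_bp, id = info$marker_id,
                  format = "GT", sample_fields = gt)
  invisible(file)
}

#' Write pooled allele depths as a two-sample VCF
#'
#' Two samples (`pool_a`, `pool_b`) carry AD fields
#' `recurrent_reads,donor_reads` (REF = recurrent allele); GT is `./.`.
#'
#' @param depths site table from [simulate_pool_depths()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_pool_vcf <- function(depths, file) {
  ad <- cbind(pool_a = paste0("./.:", depths$recurrent_a, ",", depths$donor_a),
              pool_b = paste0("./.:", depths$recurrent_b, ",", depths$donor_b))
  write_vcf_table(file,
                  chrom = depths$chrom, pos = depths$pos_bp,
                  id = depths$marker_id, format = "GT:AD",
                  sample_fields = ad)
  invisible(file)
}

write_vcf_table <- function(file, chrom, pos, id, format, sample_fields) {
  fix <- cbind(CHROM = as.character(chrom), POS = as.character(pos),
               ID = id, REF = "A", ALT = "T", QUAL = ".", FILTER = "PASS",
               INFO = ".")
  gt <- cbind(FORMAT = format, sample_fields)
  cls <- methods::getClass("vcfR", where = asNamespace("vcfR"))
  v <- methods::new(cls,
                    meta = c("##fileformat=VCFv4.2",
                             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                             "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths (recurrent,donor)\">"),
                    fix = fix, gt = gt)
  if (grepl("\\.gz$", file)) {
    vcfR::write.vcf(v, file = file)
  } else {
    tmp <- paste0(file, ".gz")
    vcfR::write.vcf(v, file = tmp)
    con <- gzfile(tmp, "rt")
    writeLines(readLines(con), file)
    close(con)
    unlink(tmp)
  }
  file
}

#' Read genotypes from VCF or a dosage TSV
#'
#' VCF GT fields are mapped to donor dosage. With `donor`/`recurrent`
#' sample names given, alleles are re-coded bi-parentally per site: the
#' allele carried homozygously by the donor parent counts as the donor
#' allele (sites where the named parents are not homozygous-discordant
#' are dropped). Without parent names, ALT is taken as the donor allele.
#' `./.` becomes missing. Dosage TSVs (markers in columns, `line_id`
#' first column) are read back as written by [write_dosage_tsv()].
#'
#' @param path input file.
#' @param format `"vcf"` or `"tsv"`; guessed from the extension.
#' @param donor,recurrent optional parent sample names (VCF only).
#' @return list `genotypes`, `info`.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv"),
                           donor = NULL, recurrent = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "tsv") return(read_dosage_tsv(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt_dosage <- function(x) {
    a <- substr(x, 1, 1); b <- substr(x, 3, 3)
    out <- suppressWarnings(as.integer(a) + as.integer(b))
    out
  }
  D <- apply(gt, 2, alt_dosage)
  if (!is.matrix(D)) D <- matrix(D, nrow = nrow(gt))
  dimnames(D) <- dimnames(gt)
  info <- data.frame(marker_id = rownames(gt),
                     chrom = vcfR::getCHROM(v),
                     pos_bp = vcfR::getPOS(v), stringsAsFactors = FALSE)
  if (!is.null(donor)) {
    if (is.null(recurrent))
      stop("bi-parental coding needs both `donor` and `recurrent`")
    miss <- setdiff(c(donor, recurrent), colnames(D))
    if (length(miss))
      stop("parent sample(s) absent from VCF: ", paste(miss, collapse = ", "))
    dd <- D[, donor]; dr <- D[, recurrent]
    keep <- !is.na(dd) & !is.na(dr) &
      ((dd == 2 & dr == 0) | (dd == 0 & dr == 2))
    flip <- dd == 0 & dr == 2
    D <- D[keep, setdiff(colnames(D), c(donor, recurrent)), drop = FALSE]
    info <- info[keep, , drop = FALSE]
    fl <- flip[keep]
    D[fl, ] <- 2L - D[fl, , drop = FALSE]
  }
  G <- t(D)
  storage.mode(G) <- "integer"
  list(genotypes = G, info = info)
}

#' Read pooled allele depths from a two-sample VCF
#'
#' Extracts per-pool AD fields written by [write_pool_vcf()] (or any VCF
#' whose first two samples are the resistant and sensitive pool).
#'
#' @param path VCF path.
#' @param pool_a,pool_b sample names (defaults `pool_a`, `pool_b`).
#' @return site depth table as produced by [simulate_pool_depths()].
#' @export
read_pool_depths <- function(path, pool_a = "pool_a", pool_b = "pool_b") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  split_ad <- function(x) {
    parts <- strsplit(x, ",", fixed = TRUE)
    cbind(as.integer(vapply(parts, `[`, "", 1)),
          as.integer(vapply(parts, `[`, "", 2)))
  }
  a <- split_ad(ad[, pool_a]); b <- split_ad(ad[, pool_b])
  data.frame(marker_id = rownames(ad), chrom = vcfR::getCHROM(v),
             pos_bp = vcfR::getPOS(v),
             donor_a = a[, 2], recurrent_a = a[, 1],
             donor_b = b[, 2], recurrent_b = b[, 1],
             parent_donor = 2L, parent_recurrent = 0L,
             stringsAsFactors = FALSE)
}

#' @rdname read_genotypes
#' @param genotypes,info matrix and marker table to write.
#' @param file output path.
#' @export
write_dosage_tsv <- function(genotypes, info, file) {
  con <- file(file, "w")
  writeLines(paste0("# donor-allele dosage (0 recurrent-hom, 1 het, 2 ",
                    "donor-hom, NA missing); positions 1-based; markers ",
                    "in columns"), con)
  d <- data.frame(line_id = rownames(genotypes), genotypes,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  meta <- sub("\\.tsv$", ".markers.tsv", file)
  write_table_commented(info, meta,
                        "marker map: chrom, pos_bp (1-based inclusive)")
  invisible(file)
}

read_dosage_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         check.names = FALSE, stringsAsFactors = FALSE)
  G <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(G) <- "integer"
  rownames(G) <- d$line_id
  meta <- sub("\\.tsv$", ".markers.tsv", path)
  info <- if (file.exists(meta))
    utils::read.table(meta, header = TRUE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE)
  else {
    parts <- strsplit(colnames(G), "_", fixed = TRUE)
    data.frame(marker_id = colnames(G),
               chrom = vapply(parts, `[`, "", 1),
               pos_bp = as.numeric(vapply(parts, `[`, "", 2)),
               stringsAsFactors = FALSE)
  }
  list(genotypes = G, info = info)
}

#' Write observations / tables as commented TSV
#'
#' All pipeline tables go out as tab-separated text with a leading `#`
#' comment line naming units and conventions.
#'
#' @param x data.frame.
#' @param file path.
#' @param comment header comment (without the `#`).
#' @export
write_table_commented <- function(x, file, comment = "") {
  con <- file(file, "w")
  if (nzchar(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(file)
}

read_table_commented <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' BED-like interval output (0-based half-open)
#'
#' Internal coordinates are 1-based inclusive; on output `start` is
#' decremented by 1 and `end` kept, the standard BED convention, and
#' [read_intervals_bed()] inverts it.
#'
#' @param records QTL records (`chrom`, `start_bp`, `end_bp`, plus extra
#'   columns carried through).
#' @param file path.
#' @export
write_intervals_bed <- function(records, file) {
  extra <- setdiff(names(records), c("chrom", "start_bp", "end_bp"))
  bed <- data.frame(chrom = records$chrom,
                    start = records$start_bp - 1,
                    end = records$end_bp,
                    records[, extra, drop = FALSE],
                    stringsAsFactors = FALSE)
  write_table_commented(bed, file,
                        "BED-like: 0-based half-open [start, end)")
  invisible(file)
}

#' @rdname write_intervals_bed
#' @param path BED-like file to read.
#' @export
read_intervals_bed <- function(path) {
  d <- read_table_commented(path)
  d$start_bp <- d$start + 1
  d$end_bp <- d$end
  d$start <- d$end <- NULL
  d
}

#' Write ground truth as structured key-value text
#'
#' Serializes a [cssl_truth()] as a pair of commented TSV tables plus a
#' DCF header (seed), readable by [read_truth()].
#'
#' @param truth a `cssl_truth`.
#' @param dir output directory.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c(paste0("seed: ", truth$seed)), file.path(dir, "truth.dcf"))
  write_table_commented(truth$qtl, file.path(dir, "truth_qtl.tsv"),
                        "planted QTL: effects in trait units for donor homozygotes")
  write_table_commented(truth$trait_means, file.path(dir, "truth_means.tsv"),
                        "trait-by-condition population means (trait units)")
  write_table_commented(truth$variance_components,
                        file.path(dir, "truth_varcomp.tsv"),
                        "variance components (squared trait units)")
  invisible(dir)
}

#' @rdname write_truth
#' @export
read_truth <- function(dir) {
  seed <- as.integer(sub("seed: *", "", readLines(file.path(dir, "truth.dcf"))[1]))
  cssl_truth(read_table_commented(file.path(dir, "truth_qtl.tsv")),
             read_table_commented(file.path(dir, "truth_means.tsv")),
             read_table_commented(file.path(dir, "truth_varcomp.tsv")),
             seed = seed)
}
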