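#' Read a methylation matrix
#'
#' Supported formats: `matrix-tsv` (columns `cpg_id`, `chrom`, `pos`, then
#' one column per sample, tab-separated, `NA` or `.` for missing) and
#' `bed-like` (columns `chrom`, `start`, `end`, `cpg_id`, then samples;
#' 0-based half-open start/end converted to a 1-based position on read).
#'
#' @param path path to the file.
#' @param format one of `"matrix-tsv"`, `"bed-like"`.
#' @return A [methylation_matrix()].
#' @export
read_methylation <- function(path, format = c("matrix-tsv", "bed-like")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", "."), data.table = FALSE,
                          colClasses = list(character = 1L))
  if (format == "matrix-tsv") {
    need <- c("cpg_id", "chrom", "pos")
    if (ncol(dt) < 4L || !identical(tolower(names(dt)[1:3]), need))
      stopf("malformed header in %s: expected columns %s, got %s",
            path, paste(need, collapse = ", "),
            paste(utils::head(names(dt), 3), collapse = ", "))
    ids <- as.character(dt[[1L]])
    chrom <- as.character(dt[[2L]])
    pos <- dt[[3L]]
    beta_cols <- dt[-(1:3)]
  } else {
    need <- c("chrom", "start", "end", "cpg_id")
    if (ncol(dt) < 5L || !identical(tolower(sub("^#", "", names(dt)[1:4])), need))
      stopf("malformed header in %s: expected columns %s", path,
            paste(need, collapse = ", "))
    ids <- as.character(dt[[4L]])
    chrom <- as.character(dt[[1L]])
    pos <- dt[[2L]] + 1L   # BED is 0-based half-open
    beta_cols <- dt[-(1:4)]
  }
  for (j in seq_along(beta_cols)) {
    if (!is.numeric(beta_cols[[j]])) {
      bad <- which(!is.na(beta_cols[[j]]) &
                     is.na(suppressWarnings(as.numeric(beta_cols[[j]]))))[1L]
      stopf("non-numeric beta in column '%s', line %d of %s",
            names(beta_cols)[j], bad + 1L, path)
    }
  }
  beta <- as.matrix(beta_cols)
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad))
    stopf("beta outside [0,1] at line %d (CpG '%s') of %s",
          bad[1L, 1L] + 1L, ids[bad[1L, 1L]], path)
  if (anyDuplicated(ids))
    stopf("duplicate CpG id '%s' in %s", ids[duplicated(ids)][1L], path)
  methylation_matrix(beta, chrom, pos, cpg_ids = ids,
                     sample_ids = names(beta_cols))
}

#' Write a methylation matrix as matrix-tsv
#'
#' @param mm a [methylation_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_methylation <- function(mm, path) {
  out <- data.frame(cpg_id = rownames(mm$beta), chrom = mm$chrom,
                    pos = mm$pos, mm$beta, check.names = FALSE,
                    stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read genotypes
#'
#' Supported formats: `vcf` (v4.x; only the GT field is used; phased and
#' unphased separators are equivalent; multi-allelic records are skipped
#' with a warning) and `dosage-tsv` (columns `snp_id`, `chrom`, `pos`,
#' `ref`, `alt`, then one 0/1/2 dosage column per sample; `NA` or `.` for
#' missing).
#'
#' @param path path to the file.
#' @param format one of `"vcf"`, `"dosage-tsv"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage-tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "vcf") return(read_genotypes_vcf(path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", "."), data.table = FALSE,
                          colClasses = list(character = 1L))
  need <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (ncol(dt) < 6L || !identical(tolower(names(dt)[1:5]), need))
    stopf("malformed header in %s: expected columns %s", path,
          paste(need, collapse = ", "))
  dos <- as.matrix(dt[-(1:5)])
  genotype_matrix(dos, chrom = dt$chrom, pos = dt$pos,
                  ref = dt$ref, alt = dt$alt,
                  snp_ids = as.character(dt$snp_id),
                  sample_ids = names(dt)[-(1:5)])
}

read_genotypes_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  if (!("GT" %in% rownames(VariantAnnotation::geno(
    VariantAnnotation::header(vcf)))))
    stopf("VCF %s has no GT field", path)
  alt_list <- VariantAnnotation::alt(vcf)
  multi <- S4Vectors::elementNROWS(alt_list) > 1L
  if (any(multi)) {
    warnf("skipping %d multi-allelic record(s) in %s", sum(multi), path)
    vcf <- vcf[!multi]
    alt_list <- alt_list[!multi]
  }
  if (nrow(vcf) == 0L) stopf("no biallelic records in %s", path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(unlist(alt_list))
  gt <- VariantAnnotation::geno(vcf)$GT
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  # GT "a/b" or "a|b": dosage = number of alt alleles; "." => missing
  clean <- gsub("\\|", "/", gt)
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
             "./." = NA_integer_, "." = NA_integer_,
             "./0" = NA_integer_, "0/." = NA_integer_,
             "./1" = NA_integer_, "1/." = NA_integer_)
  unknown <- setdiff(unique(as.vector(clean)), names(known))
  if (length(unknown))
    stopf("unknown allele code '%s' in GT field of %s", unknown[1L], path)
  dos[] <- known[clean]
  ids <- rownames(gt)
  if (is.null(ids) || anyDuplicated(ids))
    ids <- sprintf("%s:%d", as.character(GenomicRanges::seqnames(rr)),
                   GenomicRanges::start(rr))
  genotype_matrix(dos, chrom = as.character(GenomicRanges::seqnames(rr)),
                  pos = GenomicRanges::start(rr), ref = ref, alt = alt,
                  snp_ids = ids, sample_ids = colnames(gt))
}

#' Write genotypes as dosage-tsv
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path) {
  out <- data.frame(snp_id = rownames(gm$dosage), chrom = gm$chrom,
                    pos = gm$pos, ref = gm$ref, alt = gm$alt, gm$dosage,
                    check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a covariate table (TSV with a sample_id column)
#'
#' @param path TSV file whose first column is `sample_id`.
#' @return A [covariate_table()].
#' @export
read_covariates <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE,
                          colClasses = list(character = 1L))
  if (tolower(names(dt)[1L]) != "sample_id")
    stopf("malformed header in %s: first column must be sample_id", path)
  covariate_table(dt[-1L], sample_ids = dt[[1L]])
}

methqtl_columns <- c("cpg_id", "snp_id", "chrom", "cpg_pos", "snp_pos",
                     "distance", "slope", "se", "p_value", "n_samples")

#' Write a methQTL summary-statistics table
#'
#' Columns, in deterministic order: cpg_id, snp_id, chrom, cpg_pos,
#' snp_pos, distance, slope, se, p_value, n_samples.
#'
#' @param records data.frame of methQTL records (possibly empty).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_methqtl_table <- function(records, path) {
  if (is.null(records) || nrow(as.data.frame(records)) == 0L) {
    records <- as.data.frame(stats::setNames(
      rep(list(logical(0)), length(methqtl_columns)), methqtl_columns))
  }
  records <- as.data.frame(records)
  missing_cols <- setdiff(methqtl_columns, names(records))
  if (length(missing_cols))
    stopf("methQTL table lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  data.table::fwrite(records[, methqtl_columns], path, sep = "\t",
                     na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a methQTL summary-statistics table written by [write_methqtl_table()]
#'
#' @param path TSV path.
#' @return data.frame of methQTL records.
#' @export
read_methqtl_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = "NA", data.table = FALSE,
                          colClasses = list(character = c(1L, 2L, 3L)))
  missing_cols <- setdiff(methqtl_columns, names(dt))
  if (length(missing_cols))
    stopf("malformed methQTL table %s: lacks %s", path,
          paste(missing_cols, collapse = ", "))
  dt
}
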