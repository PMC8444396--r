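#' Quality-control parameters
#'
#' Defaults follow standard genotype QC practice for array/imputed data:
#' SNPs failing a Hardy-Weinberg exact test at P < 0.001, with more than
#' 10\% missing calls, or with minor-allele frequency below 5\% are
#' removed; samples with more than 5\% missing genotypes are removed
#' first.
#'
#' @param hwe_p_cutoff Hardy-Weinberg exact-test P-value cutoff.
#' @param snp_max_missing maximum fraction of missing calls per SNP.
#' @param min_maf minimum minor-allele frequency.
#' @param sample_max_missing maximum fraction of missing calls per sample.
#' @param drop_sex_chromosomes drop SNPs/CpGs on X/Y.
#' @return An object of class `QCParams`.
#' @export
qc_params <- function(hwe_p_cutoff = 0.001, snp_max_missing = 0.10,
                      min_maf = 0.05, sample_max_missing = 0.05,
                      drop_sex_chromosomes = TRUE) {
  fr <- c(hwe_p_cutoff, snp_max_missing, min_maf, sample_max_missing)
  if (any(fr < 0 | fr > 1)) stopf("QC fractions must lie in [0,1]")
  structure(list(hwe_p_cutoff = hwe_p_cutoff,
                 snp_max_missing = snp_max_missing,
                 min_maf = min_maf,
                 sample_max_missing = sample_max_missing,
                 drop_sex_chromosomes = isTRUE(drop_sex_chromosomes)),
            class = "QCParams")
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Two-sided exact test (Wigginton, Cutler & Abecasis 2005): conditioning
#' on the observed allele counts, the P-value is the sum of probabilities
#' of all heterozygote-count configurations whose probability does not
#' exceed that of the observed configuration. This is the standard (not
#' mid-p) version, matching the PLINK default.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (non-negative).
#' @return exact two-sided P-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(is.na(counts)) || any(counts < 0))
    stopf("genotype counts must be non-negative")
  n <- sum(counts)
  if (n == 0L) stopf("all genotype counts are zero")
  # rare = minor allele count; het counts share its parity
  n_rare <- 2L * min(n_hom_ref, n_hom_alt) + n_het
  hets <- seq.int(n_rare %% 2L, min(n_rare, 2L * n - n_rare), by = 2L)
  # unnormalized log-probabilities of each possible het count
  logp <- vapply(hets, function(h) {
    rare_hom <- (n_rare - h) %/% 2L
    com_hom <- n - h - rare_hom
    lgamma(n + 1) - lgamma(h + 1) - lgamma(rare_hom + 1) -
      lgamma(com_hom + 1) + h * log(2)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_het, hets)]
  # tolerance guards against ties lost to floating point
  min(1, sum(prob[prob <= p_obs * (1 + 1e-12)]))
}

#' Minor-allele frequency of a dosage vector
#'
#' @param dosage_row integer vector of 0/1/2 dosages (`NA` allowed).
#' @return `min(p, 1 - p)` where `p` is the alt-allele frequency over
#'   non-missing samples.
#' @export
minor_allele_frequency <- function(dosage_row) {
  ok <- !is.na(dosage_row)
  if (!any(ok)) stopf("all dosages missing")
  p <- sum(dosage_row[ok]) / (2 * sum(ok))
  min(p, 1 - p)
}

hwe_p_from_dosage <- function(dosage_row) {
  ok <- !is.na(dosage_row)
  if (!any(ok)) return(NA_real_)
  d <- dosage_row[ok]
  hwe_exact_test(sum(d == 0L), sum(d == 1L), sum(d == 2L))
}

#' Filter a genotype matrix
#'
#' Application order: (1) samples with more than `sample_max_missing`
#' missing calls are dropped; (2) on the remaining samples, SNPs are
#' dropped if their Hardy-Weinberg exact P-value falls below
#' `hwe_p_cutoff`, their missing fraction exceeds `snp_max_missing`, or
#' their minor-allele frequency falls below `min_maf`; sex-chromosome
#' SNPs are dropped if configured. The filter is idempotent.
#'
#' @param gm a [genotype_matrix()].
#' @param params a [qc_params()] object.
#' @return list with elements `genotypes` (filtered matrix) and `report`
#'   (counts removed per rule).
#' @export
filter_genotypes <- function(gm, params = qc_params()) {
  stopifnot(inherits(gm, "GenotypeMatrix"))
  miss_sample <- colMeans(is.na(gm$dosage))
  drop_samples <- miss_sample > params$sample_max_missing
  if (any(drop_samples))
    gm$dosage <- gm$dosage[, !drop_samples, drop = FALSE]

  d <- gm$dosage
  miss_snp <- rowMeans(is.na(d))
  maf <- apply(d, 1L, function(r)
    if (all(is.na(r))) NA_real_ else minor_allele_frequency(r))
  hwe_p <- apply(d, 1L, hwe_p_from_dosage)
  fail_miss <- miss_snp > params$snp_max_missing
  fail_hwe <- !is.na(hwe_p) & hwe_p < params$hwe_p_cutoff
  fail_maf <- is.na(maf) | maf < params$min_maf
  fail_sex <- params$drop_sex_chromosomes & is_sex_chrom(gm$chrom)
  drop_snp <- fail_miss | fail_hwe | fail_maf | fail_sex

  report <- list(
    n_samples_in = length(miss_sample),
    n_samples_removed = sum(drop_samples),
    n_snps_in = nrow(d),
    n_removed_missing = sum(fail_miss),
    n_removed_hwe = sum(fail_hwe),
    n_removed_maf = sum(fail_maf),
    n_removed_sex_chrom = sum(fail_sex),
    n_snps_removed = sum(drop_snp),
    n_snps_out = sum(!drop_snp),
    params = unclass(params))
  if (all(drop_snp)) {
    e <- simpleError("no SNPs survive genotype QC")
    e$report <- report
    stop(e)
  }
  cmq_log(sprintf(
    "genotype QC: %d/%d samples kept; %d/%d SNPs kept (miss %d, HWE %d, MAF %d, sex %d)",
    sum(!drop_samples), length(drop_samples), report$n_snps_out,
    report$n_snps_in, report$n_removed_missing, report$n_removed_hwe,
    report$n_removed_maf, report$n_removed_sex_chrom))
  list(genotypes = subset_geno(gm, !drop_snp), report = report)
}

#' Filter CpGs by an id mask and (optionally) sex chromosomes
#'
#' The mask is a user-supplied list of CpG ids to remove (for example
#' SNP-overlapping or cross-reactive probes, curated externally).
#'
#' @param mm a [methylation_matrix()].
#' @param mask_cpg_ids character vector of CpG ids to drop (may be empty).
#' @param params a [qc_params()] object (`drop_sex_chromosomes` honoured).
#' @return the filtered [methylation_matrix()]; an empty result is allowed
#'   with a warning.
#' @export
filter_cpgs <- function(mm, mask_cpg_ids = character(0),
                        params = qc_params()) {
  stopifnot(inherits(mm, "MethylationMatrix"))
  mask_cpg_ids <- unique(as.character(mask_cpg_ids))
  absent <- setdiff(mask_cpg_ids, rownames(mm$beta))
  if (length(absent))
    warnf("%d masked CpG id(s) not present in the matrix", length(absent))
  drop <- rownames(mm$beta) %in% mask_cpg_ids
  if (params$drop_sex_chromosomes) drop <- drop | is_sex_chrom(mm$chrom)
  out <- subset_meth(mm, !drop)
  if (nrow(out$beta) == 0L) warnf("all CpGs removed by filtering")
  out
}
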