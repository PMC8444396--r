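#' Methylation matrix container
#'
#' Holds per-CpG methylation levels (beta values in \[0,1\]) for a set of
#' samples, together with genomic coordinates. Rows are sorted by
#' chromosome and then position on construction; all coordinates are
#' 1-based, inclusive.
#'
#' @param beta numeric matrix, CpGs in rows, samples in columns; values in
#'   \[0,1\] or `NA`.
#' @param chrom character vector of chromosome names per CpG (a leading
#'   "chr" prefix is stripped).
#' @param pos integer vector, 1-based position of the CpG cytosine on the
#'   forward strand.
#' @param cpg_ids,sample_ids unique identifiers; default to the dimnames
#'   of `beta`.
#' @return An object of class `MethylationMatrix`: a list with elements
#'   `beta` (matrix with CpG/sample dimnames), `chrom`, `pos`.
#' @export
methylation_matrix <- function(beta, chrom, pos,
                               cpg_ids = rownames(beta),
                               sample_ids = colnames(beta)) {
  beta <- as.matrix(beta)
  storage.mode(beta) <- "double"
  if (is.null(cpg_ids)) stopf("methylation matrix requires CpG ids")
  if (is.null(sample_ids)) stopf("methylation matrix requires sample ids")
  if (anyDuplicated(cpg_ids)) stopf("duplicate CpG id: %s",
                                    cpg_ids[duplicated(cpg_ids)][1L])
  if (anyDuplicated(sample_ids)) stopf("duplicate sample id")
  if (length(chrom) != nrow(beta) || length(pos) != nrow(beta))
    stopf("chrom/pos length must match number of CpGs")
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1))
  if (length(bad))
    stopf("beta value outside [0,1] for CpG '%s'",
          cpg_ids[(bad[1L] - 1L) %% nrow(beta) + 1L])
  chrom <- normalize_chrom(chrom)
  pos <- as.integer(pos)
  dimnames(beta) <- list(cpg_ids, sample_ids)
  ord <- order(chrom, pos)
  obj <- structure(list(beta = beta[ord, , drop = FALSE],
                        chrom = chrom[ord], pos = pos[ord]),
                   class = "MethylationMatrix")
  obj
}

#' Genotype matrix container
#'
#' SNP-by-sample dosages of the alternative allele (0, 1, 2 or `NA`),
#' with 1-based coordinates and single-nucleotide REF/ALT alleles.
#'
#' @param dosage integer matrix with entries in \{0,1,2\} or `NA`; SNPs in
#'   rows, samples in columns.
#' @param chrom,pos coordinates per SNP (1-based; "chr" prefix stripped).
#' @param ref,alt single characters from \{A,C,G,T\} per SNP.
#' @param snp_ids,sample_ids unique identifiers; default to dimnames.
#' @return An object of class `GenotypeMatrix`.
#' @export
genotype_matrix <- function(dosage, chrom, pos, ref, alt,
                            snp_ids = rownames(dosage),
                            sample_ids = colnames(dosage)) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(snp_ids)) stopf("genotype matrix requires SNP ids")
  if (is.null(sample_ids)) stopf("genotype matrix requires sample ids")
  if (anyDuplicated(snp_ids)) stopf("duplicate SNP id: %s",
                                    snp_ids[duplicated(snp_ids)][1L])
  if (anyDuplicated(sample_ids)) stopf("duplicate sample id")
  if (!all(is.na(dosage) | dosage %in% 0:2))
    stopf("dosage entries must be 0, 1, 2 or missing")
  ok_allele <- function(a) all(a %in% c("A", "C", "G", "T"))
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  if (!ok_allele(ref) || !ok_allele(alt))
    stopf("unknown allele code (alleles must be single A/C/G/T)")
  chrom <- normalize_chrom(chrom)
  pos <- as.integer(pos)
  dimnames(dosage) <- list(snp_ids, sample_ids)
  ord <- order(chrom, pos)
  structure(list(dosage = dosage[ord, , drop = FALSE],
                 chrom = chrom[ord], pos = pos[ord],
                 ref = ref[ord], alt = alt[ord]),
            class = "GenotypeMatrix")
}

#' Covariate table container
#'
#' @param df data.frame of covariates; numeric columns are treated as
#'   continuous, character/factor columns as categorical.
#' @param sample_ids unique sample identifiers (default: rownames of `df`).
#' @return An object of class `CovariateTable` (a data.frame with sample
#'   ids as rownames; categorical columns coerced to factor).
#' @export
covariate_table <- function(df, sample_ids = rownames(df)) {
  df <- as.data.frame(df)
  if (is.null(sample_ids)) stopf("covariate table requires sample ids")
  if (anyDuplicated(sample_ids)) stopf("duplicate sample id in covariates")
  for (j in seq_along(df)) {
    if (is.character(df[[j]]) || is.logical(df[[j]]))
      df[[j]] <- factor(df[[j]])
    if (is.factor(df[[j]]) && nlevels(droplevels(df[[j]])) < 1L)
      stopf("categorical covariate '%s' has no levels", names(df)[j])
  }
  rownames(df) <- as.character(sample_ids)
  class(df) <- c("CovariateTable", "data.frame")
  df
}

#' @export
print.MethylationMatrix <- function(x, ...) {
  cat(sprintf("MethylationMatrix: %d CpGs x %d samples on %d chromosome(s)\n",
              nrow(x$beta), ncol(x$beta), length(unique(x$chrom))))
  invisible(x)
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d SNPs x %d samples on %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$chrom))))
  invisible(x)
}

#' @export
dim.MethylationMatrix <- function(x) dim(x$beta)

#' @export
dim.GenotypeMatrix <- function(x) dim(x$dosage)

# Row subsetting that keeps coordinates aligned with the matrix.
subset_meth <- function(mm, keep) {
  mm$beta <- mm$beta[keep, , drop = FALSE]
  mm$chrom <- mm$chrom[keep]
  mm$pos <- mm$pos[keep]
  mm
}

subset_geno <- function(gm, keep, samples = NULL) {
  gm$dosage <- gm$dosage[keep, , drop = FALSE]
  gm$chrom <- gm$chrom[keep]
  gm$pos <- gm$pos[keep]
  gm$ref <- gm$ref[keep]
  gm$alt <- gm$alt[keep]
  if (!is.null(samples)) gm$dosage <- gm$dosage[, samples, drop = FALSE]
  gm
}
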