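#' Association-testing parameters
#'
#' @param cis_window cis window in bp; SNPs strictly closer than this to
#'   the tag-CpG are tested (default 500 kb).
#' @param alpha family-wise error target for the Bonferroni-style cutoff.
#' @param covariate_names covariate columns to use (default: all).
#' @return An object of class `AssocParams`.
#' @export
assoc_params <- function(cis_window = 500000, alpha = 0.05,
                         covariate_names = NULL) {
  if (cis_window <= 0) stopf("cis_window must be positive")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0,1)")
  structure(list(cis_window = as.integer(cis_window), alpha = alpha,
                 covariate_names = covariate_names),
            class = "AssocParams")
}

#' Select the tag-CpG (medoid) of a correlation block
#'
#' Default method `medoid-of-medians`: compute the median beta of each
#' member CpG across samples; the tag is the CpG attaining the median of
#' that vector of medians. For blocks with an even number of candidates
#' the lower of the two central values is used; remaining ties are broken
#' by smallest genomic position. All-missing CpGs are excluded from
#' candidacy with a warning.
#'
#' @param member_cpg_ids character vector of the block's CpG ids.
#' @param mm a [methylation_matrix()].
#' @param method one of `"medoid-of-medians"`, `"mean-center"` (CpG whose
#'   mean is closest to the block's grand mean), `"first"` (left-most).
#' @return the tag CpG id.
#' @export
select_tag_cpg <- function(member_cpg_ids, mm,
                           method = c("medoid-of-medians", "mean-center",
                                      "first")) {
  method <- match.arg(method)
  stopifnot(length(member_cpg_ids) > 0L)
  rows <- match(member_cpg_ids, rownames(mm$beta))
  if (anyNA(rows)) stopf("block member '%s' not in methylation matrix",
                         member_cpg_ids[is.na(rows)][1L])
  b <- mm$beta[rows, , drop = FALSE]
  pos <- mm$pos[rows]
  all_missing <- rowSums(!is.na(b)) == 0L
  if (any(all_missing)) {
    warnf("%d all-missing CpG(s) excluded from tag candidacy",
          sum(all_missing))
    b <- b[!all_missing, , drop = FALSE]
    pos <- pos[!all_missing]
    member_cpg_ids <- member_cpg_ids[!all_missing]
  }
  if (nrow(b) == 0L) stopf("no non-missing CpG in block")
  if (method == "first") return(member_cpg_ids[which.min(pos)])
  if (method == "mean-center") {
    m <- rowMeans(b, na.rm = TRUE)
    cand <- which(abs(m - mean(m)) == min(abs(m - mean(m))))
  } else {
    meds <- apply(b, 1L, stats::median, na.rm = TRUE)
    k <- length(meds)
    target <- sort(meds)[ceiling(k / 2)]   # lower-median rule for even k
    cand <- which(meds == target)
  }
  cand <- cand[order(pos[cand])][1L]
  member_cpg_ids[cand]
}

#' Candidate cis SNPs for a tag-CpG
#'
#' SNPs on the same chromosome strictly closer than `cis_window` bp
#' (`|snp_pos - cpg_pos| < cis_window`) to the tag-CpG.
#'
#' @param tag_chrom,tag_pos tag-CpG coordinates.
#' @param gm a [genotype_matrix()].
#' @param cis_window window size in bp.
#' @return character vector of SNP ids (possibly empty).
#' @export
cis_candidates <- function(tag_chrom, tag_pos, gm, cis_window = 500000) {
  keep <- gm$chrom == normalize_chrom(tag_chrom) &
    abs(gm$pos - tag_pos) < cis_window
  rownames(gm$dosage)[keep]
}

#' Covariate-adjusted least-squares association of methylation on dosage
#'
#' Ordinary least squares of the beta value on an intercept, the alt-
#' allele dosage and the covariates; categorical covariates are expanded
#' to indicator columns dropping one reference level. Complete-case
#' analysis: samples missing the beta value, the dosage or any covariate
#' are removed for this pair. The reported slope and standard error are
#' those of the dosage coefficient; the P-value is the two-sided t
#' probability with `n - k` degrees of freedom.
#'
#' @param meth_vector numeric beta values, named by sample or aligned.
#' @param dosage_vector 0/1/2 dosages aligned with `meth_vector`.
#' @param covariates optional [covariate_table()] rows aligned with the
#'   samples (a data.frame; may be `NULL`).
#' @return list with `slope`, `se`, `p_value`, `n`; or, when the fit is
#'   impossible, a list with `skipped = TRUE` and a `reason`
#'   (`"monomorphic-in-subset"`, `"rank-deficient"`, `"too-few-samples"`).
#' @export
fit_association <- function(meth_vector, dosage_vector, covariates = NULL) {
  y <- as.numeric(meth_vector)
  g <- as.numeric(dosage_vector)
  if (length(y) != length(g)) stopf("meth/dosage length mismatch")
  cc <- !is.na(y) & !is.na(g)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    cc <- cc & stats::complete.cases(covariates)
  }
  y <- y[cc]; g <- g[cc]
  n <- length(y)
  if (!is.null(covariates) && ncol(covariates) > 0L) {
    cv <- droplevels(covariates[cc, , drop = FALSE])
    X <- stats::model.matrix(~ dosage + .,
                             data = cbind(dosage = g, cv))
  } else {
    X <- cbind(`(Intercept)` = 1, dosage = g)
  }
  k <- ncol(X)
  if (n < k + 1L)
    return(list(skipped = TRUE, reason = "too-few-samples", n = n))
  if (stats::var(g) == 0)
    return(list(skipped = TRUE, reason = "monomorphic-in-subset", n = n))
  qr_x <- qr(X)
  if (qr_x$rank < k)
    return(list(skipped = TRUE, reason = "rank-deficient", n = n))
  coefs <- qr.coef(qr_x, y)
  resid <- y - X %*% coefs
  df <- n - k
  sigma2 <- sum(resid^2) / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  j <- match("dosage", colnames(X))
  slope <- unname(coefs[j])
  se <- sqrt(sigma2 * xtx_inv[j, j])
  tval <- slope / se
  p <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  list(slope = slope, se = se, p_value = max(p, .Machine$double.xmin),
       n = n)
}

#' Call cis methQTLs for all correlation blocks
#'
#' For each block, the tag-CpG (medoid) is regressed on each candidate
#' cis SNP (strictly within the window) with covariate adjustment. The
#' full, unfiltered summary table is returned; significance filtering is
#' left to [genome_wide_cutoff()] downstream.
#'
#' @param mm a [methylation_matrix()].
#' @param gm a [genotype_matrix()].
#' @param covariates optional [covariate_table()]; rows are matched to
#'   samples by id.
#' @param blocks a `cpg_blocks` table from [call_blocks()].
#' @param params an [assoc_params()] object.
#' @param tag_method passed to [select_tag_cpg()].
#' @return data.frame of methQTL records (columns `cpg_id`, `snp_id`,
#'   `chrom`, `cpg_pos`, `snp_pos`, `distance`, `slope`, `se`,
#'   `p_value`, `n_samples`), with attributes `n_blocks`,
#'   `mean_snps_per_cpg` (rounded mean candidate count over tag-CpGs) and
#'   `tags` (named vector block_id -> tag CpG).
#' @export
call_methqtls <- function(mm, gm, covariates = NULL, blocks,
                          params = assoc_params(),
                          tag_method = "medoid-of-medians") {
  samples <- intersect(colnames(mm$beta), colnames(gm$dosage))
  if (!is.null(covariates))
    samples <- intersect(samples, rownames(covariates))
  if (length(samples) == 0L) stopf("no overlapping samples between inputs")
  beta <- mm$beta[, samples, drop = FALSE]
  dos <- gm$dosage[, samples, drop = FALSE]
  cv <- if (is.null(covariates)) NULL else {
    cv0 <- covariates[samples, , drop = FALSE]
    if (!is.null(params$covariate_names))
      cv0 <- cv0[, params$covariate_names, drop = FALSE]
    cv0
  }
  block_ids <- unique(blocks$block_id)
  recs <- vector("list", length(block_ids))
  tags <- character(length(block_ids)); names(tags) <- block_ids
  n_cand <- integer(length(block_ids))
  for (i in seq_along(block_ids)) {
    members <- blocks$cpg_id[blocks$block_id == block_ids[i]]
    tag <- select_tag_cpg(members, mm, method = tag_method)
    tags[i] <- tag
    ti <- match(tag, rownames(mm$beta))
    snps <- cis_candidates(mm$chrom[ti], mm$pos[ti], gm, params$cis_window)
    n_cand[i] <- length(snps)
    if (length(snps) == 0L) next
    y <- beta[tag, ]
    m <- length(snps)
    slope <- se <- pval <- rep(NA_real_, m)
    nn <- integer(m)
    for (si in seq_len(m)) {
      fit <- fit_association(y, dos[snps[si], ], cv)
      if (isTRUE(fit$skipped)) next
      slope[si] <- fit$slope; se[si] <- fit$se
      pval[si] <- fit$p_value; nn[si] <- fit$n
    }
    ok <- !is.na(slope)
    if (!any(ok)) next
    gi <- match(snps[ok], rownames(gm$dosage))
    recs[[i]] <- data.frame(
      cpg_id = tag, snp_id = snps[ok], chrom = mm$chrom[ti],
      cpg_pos = mm$pos[ti], snp_pos = gm$pos[gi],
      distance = gm$pos[gi] - mm$pos[ti],
      slope = slope[ok], se = se[ok], p_value = pval[ok],
      n_samples = nn[ok], stringsAsFactors = FALSE)
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0L) {
    warnf("no cis SNP within the window for any block: empty methQTL table")
    out <- as.data.frame(stats::setNames(
      rep(list(logical(0)), length(methqtl_columns)), methqtl_columns))
  } else {
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
  }
  attr(out, "n_blocks") <- length(block_ids)
  attr(out, "mean_snps_per_cpg") <- round(mean(n_cand))
  attr(out, "tags") <- tags
  out
}

#' Genome-wide Bonferroni-style P-value cutoff
#'
#' `alpha / (sum(block_counts) * mean_snps_per_cpg)`: the total number of
#' correlation blocks across runs (e.g., tissues) times the average
#' number of SNPs tested per tag-CpG.
#'
#' @param block_counts vector of per-run correlation-block counts.
#' @param mean_snps_per_cpg average number of candidate SNPs per tag-CpG.
#' @param alpha family-wise error target.
#' @return the P-value cutoff.
#' @export
genome_wide_cutoff <- function(block_counts, mean_snps_per_cpg,
                               alpha = 0.05) {
  if (any(block_counts <= 0) || mean_snps_per_cpg <= 0)
    stopf("block counts and mean SNPs per CpG must be positive")
  denom <- sum(as.numeric(block_counts)) * mean_snps_per_cpg
  if (denom == 0) stopf("zero denominator in cutoff")
  alpha / denom
}

#' Replication P-value cutoff
#'
#' `alpha / sum(methqtl_counts)`: Bonferroni over the total number of
#' discovery methQTLs carried into replication.
#'
#' @param methqtl_counts vector of per-run discovery methQTL counts.
#' @param alpha family-wise error target.
#' @return the P-value cutoff.
#' @export
replication_cutoff <- function(methqtl_counts, alpha = 0.05) {
  s <- sum(as.numeric(methqtl_counts))
  if (any(methqtl_counts <= 0) || s == 0)
    stopf("methQTL counts must be positive")
  alpha / s
}

#' Select the lead SNP per CpG
#'
#' For each CpG, keep the record with the smallest P-value; exact ties
#' are broken by smaller `|distance|`, then lexicographic SNP id.
#'
#' @param records methQTL record table.
#' @return one record per distinct `cpg_id`.
#' @export
select_lead_snps <- function(records) {
  if (nrow(records) == 0L) stopf("empty methQTL table")
  ord <- order(records$cpg_id, records$p_value, abs(records$distance),
               records$snp_id)
  records <- records[ord, ]
  out <- records[!duplicated(records$cpg_id), ]
  rownames(out) <- NULL
  out
}
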