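#' Colocalization parameters
#'
#' @param smr_fdr_cutoff BH-adjusted SMR P-value below which two tissues
#'   are taken to share the association signal (default 0.05).
#' @param heidi_p_cutoff HEIDI P-value at or below which heterogeneity is
#'   declared, i.e. linkage rather than pleiotropy (default 0.05; the
#'   stricter alternative 0.001 is also in routine use).
#' @param heidi_min_snps minimum instrument SNPs (besides the lead) for
#'   HEIDI to run; below this HEIDI is skipped and the verdict falls back
#'   to SMR alone, flagged.
#' @param heidi_max_snps maximum instruments, kept by descending anchor
#'   z-squared.
#' @param instrument_z2_min minimum squared anchor z-statistic for a SNP
#'   to serve as an instrument (default 10, approximately P < 1.6e-3).
#' @param ld_r2_exclude instruments in tighter LD than this r-squared with
#'   the lead SNP are excluded (default 0.9).
#' @return An object of class `ColocParams`.
#' @export
coloc_params <- function(smr_fdr_cutoff = 0.05, heidi_p_cutoff = 0.05,
                         heidi_min_snps = 3L, heidi_max_snps = 20L,
                         instrument_z2_min = 10, ld_r2_exclude = 0.9) {
  if (smr_fdr_cutoff <= 0 || smr_fdr_cutoff >= 1 ||
      heidi_p_cutoff <= 0 || heidi_p_cutoff >= 1)
    stopf("cutoffs must lie in (0,1)")
  structure(list(smr_fdr_cutoff = smr_fdr_cutoff,
                 heidi_p_cutoff = heidi_p_cutoff,
                 heidi_min_snps = as.integer(heidi_min_snps),
                 heidi_max_snps = as.integer(heidi_max_snps),
                 instrument_z2_min = instrument_z2_min,
                 ld_r2_exclude = ld_r2_exclude),
            class = "ColocParams")
}

#' Per-tissue methQTL summary for colocalization
#'
#' @param tissue tissue/cell-type label.
#' @param records full methQTL record table for that tissue (all cis
#'   SNP-by-tag-CpG statistics, unfiltered).
#' @return An object of class `TissueSummary` with elements `tissue`,
#'   `lead` (one lead-SNP record per tag-CpG) and `cis` (full table).
#' @export
tissue_summary <- function(tissue, records) {
  if (any(records$se <= 0, na.rm = TRUE)) stopf("non-positive SE in records")
  structure(list(tissue = tissue, lead = select_lead_snps(records),
                 cis = records),
            class = "TissueSummary")
}

#' Summary-data-based Mendelian randomization (SMR) test
#'
#' With `z_a = slope_a / se_a` and `z_b = slope_b / se_b`, the statistic
#' is `T = z_a^2 z_b^2 / (z_a^2 + z_b^2)`, referred to the upper tail of
#' a chi-square distribution with one degree of freedom. Symmetric in the
#' two traits; `T` is approximately the chi-square statistic of the Wald
#' ratio `slope_b / slope_a` treating the instrument association as
#' estimated.
#'
#' @param slope_a,se_a effect and standard error in the first tissue.
#' @param slope_b,se_b effect and standard error in the second tissue.
#' @return list with `stat` and `p`.
#' @export
smr_test <- function(slope_a, se_a, slope_b, se_b) {
  if (any(c(se_a, se_b) <= 0)) stopf("standard errors must be positive")
  z_a2 <- (slope_a / se_a)^2
  z_b2 <- (slope_b / se_b)^2
  if (z_a2 + z_b2 == 0) {
    warnf("degenerate SMR input: both z statistics are zero")
    return(list(stat = 0, p = 1))
  }
  stat <- z_a2 * z_b2 / (z_a2 + z_b2)
  list(stat = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values vector of raw P-values in (0, 1\].
#' @return adjusted values (monotone in rank, capped at 1), same order as
#'   the input; empty input gives empty output.
#' @export
bh_adjust <- function(p_values) {
  m <- length(p_values)
  if (m == 0L) return(numeric(0))
  ord <- order(p_values, decreasing = TRUE)
  adj <- pmin(1, cummin(m / seq.int(m, 1L) * p_values[ord]))
  adj[order(ord)]
}

# Upper-tail probability of a weighted sum of independent 1-df chi-squares
# (Q = sum lambda_k * chisq_1). Primary route: Imhof's numerical inversion
# of the characteristic function; fallback: Satterthwaite two-moment
# scaled chi-square match.
p_quadform <- function(q, lambda) {
  lambda <- lambda[lambda > 1e-10]
  if (length(lambda) == 0L) return(NA_real_)
  if (length(lambda) == 1L)
    return(stats::pchisq(q / lambda, df = 1, lower.tail = FALSE))
  imhof <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    sin(theta) / (u * rho)
  }
  p <- tryCatch({
    int <- stats::integrate(imhof, lower = 0, upper = Inf,
                            subdivisions = 500L, rel.tol = 1e-8)
    0.5 + int$value / pi
  }, error = function(e) {
    s1 <- sum(lambda); s2 <- sum(lambda^2)
    stats::pchisq(q * s1 / s2, df = s1^2 / s2, lower.tail = FALSE)
  })
  min(max(p, .Machine$double.xmin), 1)
}

#' Heterogeneity in dependent instruments (HEIDI) test
#'
#' Tests whether the Wald ratios `b_i = slope_b_i / slope_a_i` of the
#' instrument SNPs are homogeneous with that of the lead SNP. Under
#' pleiotropy (one causal variant, the others LD proxies) all `b_i`
#' estimate the same quantity and the differences `d_i = b_i - b_lead`
#' are zero in expectation; linkage of distinct causal variants induces
#' heterogeneity. Delta-method variances and covariances of the `d_i`
#' incorporate the LD correlation of the SNPs (within-tissue covariance
#' of slope estimates at SNPs i, j is approximated by
#' `r_ij * se_i * se_j`; the two tissues are independent samples). The
#' statistic is the sum of squared standardized differences over the
#' instruments; its null distribution is the corresponding weighted sum
#' of correlated 1-df chi-squares, evaluated from the eigenvalues of the
#' correlation matrix of the `d_i` (Imhof inversion, Satterthwaite
#' fallback).
#'
#' @param stats data.frame with columns `snp_id`, `slope_a`, `se_a`,
#'   `slope_b`, `se_b` (anchor tissue = a), one row per cis SNP;
#'   optional columns `n_a`, `n_b` (per-tissue sample sizes) enable the
#'   model-based covariance (see Details).
#' @param lead_snp id of the lead SNP (must be present in `stats`).
#' @param ld signed Pearson LD correlation matrix with dimnames covering
#'   the SNP ids in `stats`.
#' @param params a [coloc_params()] object.
#' @param sd_g optional named vector of dosage standard deviations from
#'   the LD reference; together with `n_a`/`n_b` it enables the
#'   model-based covariance.
#' @details Two covariance models for the slope estimates within a
#'   tissue are available. The generic summary-statistic heuristic
#'   `Cov(slope_i, slope_j) = r_ij se_i se_j` (the fallback) is accurate
#'   when each SNP explains a small fraction of trait variance; with the
#'   strong instruments typical of cis methQTLs it misattributes the
#'   genotype-sampling part of the variance and inflates the test. When
#'   `sd_g` and `n_a`/`n_b` are supplied, the covariance is instead
#'   derived under the HEIDI null itself (a single causal variant,
#'   proxied by the lead SNP): writing the marginal slope at SNP j as
#'   `gamma_j * beta + e_j` with `gamma_j` the in-sample regression
#'   coefficient of the lead dosage on dosage j, the covariance is
#'   `beta^2 Cov(gamma_i, gamma_j) + sigma^2 r_ij / (n sd_i sd_j)`, with
#'   `Cov(gamma_i, gamma_j)` from Gaussian fourth moments of the LD
#'   structure and `sigma^2` from the lead SNP's standard error.
#' @return list with `stat`, `p`, `m` (instruments used), `snps`, and
#'   `skipped`/`reason` when fewer than `heidi_min_snps` instruments
#'   remain.
#' @export
heidi_test <- function(stats, lead_snp, ld, params = coloc_params(),
                       sd_g = NULL) {
  li <- match(lead_snp, stats$snp_id)
  if (is.na(li)) stopf("lead SNP '%s' not in stats", lead_snp)
  z_a2 <- (stats$slope_a / stats$se_a)^2
  r_lead <- ld[stats$snp_id, lead_snp]
  cand <- which(stats$snp_id != lead_snp &
                  z_a2 >= params$instrument_z2_min &
                  r_lead^2 <= params$ld_r2_exclude &
                  stats$slope_a != 0)
  cand <- cand[order(z_a2[cand], decreasing = TRUE)]
  if (length(cand) > params$heidi_max_snps)
    cand <- cand[seq_len(params$heidi_max_snps)]
  if (length(cand) < params$heidi_min_snps)
    return(list(stat = NA_real_, p = NA_real_, m = 0L,
                snps = character(0), skipped = TRUE,
                reason = "too-few-instruments"))
  sel <- c(li, cand)                       # lead first
  s <- stats[sel, ]
  R <- ld[s$snp_id, s$snp_id]
  b <- s$slope_b / s$slope_a
  model_based <- !is.null(sd_g) && all(s$snp_id %in% names(sd_g)) &&
    all(c("n_a", "n_b") %in% names(stats))
  slope_cov <- function(slope, se, n) {
    if (!model_based) return(R * tcrossprod(se))
    sdg <- sd_g[s$snp_id]
    r <- R[, 1L]                           # LD with the lead (causal proxy)
    beta <- slope[1L]
    # Cov(gamma_i, gamma_j), gamma_j = in-sample coefficient of the lead
    # dosage on dosage j, via Gaussian fourth moments of the LD structure
    k2 <- length(r)
    G <- matrix(0, k2, k2)
    for (i in seq_len(k2)) for (j in seq_len(k2)) {
      G[i, j] <- R[i, j] * (1 - r[i]^2 - r[j]^2 + r[i] * r[j] * R[i, j]) +
        (r[i] - r[j] * R[i, j]) * (r[j] - r[i] * R[i, j])
    }
    sigma2_scaled <- sd_g[lead_snp]^2 * se[1L]^2    # sigma^2 / n
    G_cov <- sd_g[lead_snp]^2 * G / (n[1L] * tcrossprod(sdg))
    beta^2 * G_cov + sigma2_scaled * R / tcrossprod(sdg)
  }
  C_a <- slope_cov(s$slope_a, s$se_a, s$n_a)
  C_b <- slope_cov(s$slope_b, s$se_b, s$n_b)
  # delta-method covariance of the Wald ratios b = slope_b / slope_a
  inv_a <- 1 / s$slope_a
  w <- s$slope_b / s$slope_a^2
  C <- tcrossprod(inv_a) * C_b + tcrossprod(w) * C_a
  k <- length(cand)
  idx <- seq_len(k) + 1L
  V <- C[idx, idx, drop = FALSE] -
    matrix(C[idx, 1L], k, k) - matrix(C[1L, idx], k, k, byrow = TRUE) +
    C[1L, 1L]
  d <- b[idx] - b[1L]
  ok <- diag(V) > 0
  if (sum(ok) < params$heidi_min_snps)
    return(list(stat = NA_real_, p = NA_real_, m = 0L,
                snps = character(0), skipped = TRUE,
                reason = "degenerate-variance"))
  V <- V[ok, ok, drop = FALSE]
  d <- d[ok]
  sd_d <- sqrt(diag(V))
  z_d <- d / sd_d
  stat <- sum(z_d^2)
  corr <- V / tcrossprod(sd_d)
  lambda <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  lambda[lambda < 0] <- 0
  list(stat = stat, p = p_quadform(stat, lambda), m = sum(ok),
       snps = s$snp_id[-1L][ok], skipped = FALSE)
}

#' LD correlation matrix from a genotype matrix
#'
#' Signed Pearson correlation of alt-allele dosages (pairwise-complete),
#' the download-free stand-in for an external reference panel.
#'
#' @param gm a [genotype_matrix()].
#' @param snp_ids SNPs to include.
#' @return correlation matrix with SNP-id dimnames.
#' @export
ld_matrix <- function(gm, snp_ids = rownames(gm$dosage)) {
  d <- t(gm$dosage[snp_ids, , drop = FALSE])
  r <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0
  diag(r) <- 1
  r
}

#' Pool genotype matrices into one LD reference
#'
#' Intersects SNPs and concatenates samples (dropping duplicate sample
#' ids), yielding the largest available in-study panel for LD
#' estimation — in a multi-tissue cohort the genotypes of all donors.
#'
#' @param gms list of [genotype_matrix()] objects.
#' @return a [genotype_matrix()].
#' @export
pool_genotypes <- function(gms) {
  stopifnot(length(gms) >= 1L)
  snps <- Reduce(intersect, lapply(gms, function(g) rownames(g$dosage)))
  if (length(snps) == 0L) stopf("no common SNPs across genotype matrices")
  base <- gms[[1L]]
  keep <- match(snps, rownames(base$dosage))
  base <- subset_geno(base, keep)
  dos <- do.call(cbind, lapply(gms, function(g)
    g$dosage[snps, , drop = FALSE]))
  dos <- dos[, !duplicated(colnames(dos)), drop = FALSE]
  base$dosage <- dos
  base
}

#' Select cross-tissue colocalization tests
#'
#' Candidate CpGs are those selected as tag-CpGs in at least two tissues
#' whose lead-SNP P-value falls below the genome-wide cutoff in at least
#' one tissue. Each candidate is anchored at the tissue with the lowest
#' lead P-value and paired against every other tissue in which it is a
#' tag-CpG.
#'
#' @param summaries named list of [tissue_summary()] objects (>= 2).
#' @param cutoff genome-wide methQTL P-value cutoff.
#' @return data.frame with one row per (cpg, anchor, other) pair:
#'   `cpg_id`, `anchor_tissue`, `other_tissue`, `lead_snp`, `anchor_p`.
#' @export
select_coloc_tests <- function(summaries, cutoff) {
  if (length(summaries) < 2L) stopf("need summaries for >= 2 tissues")
  tissues <- vapply(summaries, `[[`, character(1), "tissue")
  names(summaries) <- tissues
  lead_of <- lapply(summaries, `[[`, "lead")
  cpgs <- table(unlist(lapply(lead_of, `[[`, "cpg_id")))
  cpgs <- names(cpgs)[cpgs >= 2L]
  rows <- list()
  for (cpg in cpgs) {
    have <- tissues[vapply(lead_of, function(l) cpg %in% l$cpg_id,
                           logical(1))]
    pv <- vapply(have, function(t)
      lead_of[[t]]$p_value[match(cpg, lead_of[[t]]$cpg_id)], numeric(1))
    if (!any(pv < cutoff)) next
    anchor <- have[which.min(pv)]
    lead_snp <- lead_of[[anchor]]$snp_id[match(cpg, lead_of[[anchor]]$cpg_id)]
    others <- setdiff(have, anchor)
    rows[[length(rows) + 1L]] <- data.frame(
      cpg_id = cpg, anchor_tissue = anchor, other_tissue = others,
      lead_snp = lead_snp, anchor_p = min(pv), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(cpg_id = character(0), anchor_tissue = character(0),
                      other_tissue = character(0), lead_snp = character(0),
                      anchor_p = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run SMR + HEIDI colocalization over the selected tests
#'
#' For each (CpG, anchor, other) pair, the SMR test compares the lead
#' SNP's effect in the two tissues; BH adjustment of SMR P-values is
#' performed jointly over all tests. For pairs passing the instrument
#' requirements, the HEIDI test discriminates pleiotropy from linkage
#' using LD from `ld_genotypes`. A pair's verdict is `shared` iff
#' `smr_fdr < smr_fdr_cutoff` and (HEIDI skipped or
#' `heidi_p > heidi_p_cutoff`).
#'
#' @param summaries named list of [tissue_summary()] objects.
#' @param tests output of [select_coloc_tests()].
#' @param ld_genotypes a [genotype_matrix()] used as the LD reference.
#' @param params a [coloc_params()] object.
#' @return data.frame of class `ColocResult` with per-test SMR/HEIDI
#'   statistics, `heidi_skipped` flag and `verdict`.
#' @export
run_coloc <- function(summaries, tests, ld_genotypes,
                      params = coloc_params()) {
  tissues <- vapply(summaries, `[[`, character(1), "tissue")
  names(summaries) <- tissues
  n <- nrow(tests)
  smr_stat <- smr_p <- heidi_stat <- heidi_p <- rep(NA_real_, n)
  heidi_m <- integer(n)
  heidi_skipped <- rep(TRUE, n)
  for (i in seq_len(n)) {
    cpg <- tests$cpg_id[i]
    a <- summaries[[tests$anchor_tissue[i]]]$cis
    b <- summaries[[tests$other_tissue[i]]]$cis
    a <- a[a$cpg_id == cpg, ]
    b <- b[b$cpg_id == cpg, ]
    lead <- tests$lead_snp[i]
    ia <- match(lead, a$snp_id); ib <- match(lead, b$snp_id)
    if (is.na(ia) || is.na(ib)) next     # lead not testable in both
    sm <- smr_test(a$slope[ia], a$se[ia], b$slope[ib], b$se[ib])
    smr_stat[i] <- sm$stat; smr_p[i] <- sm$p
    common <- intersect(a$snp_id, b$snp_id)
    st <- data.frame(snp_id = common,
                     slope_a = a$slope[match(common, a$snp_id)],
                     se_a = a$se[match(common, a$snp_id)],
                     slope_b = b$slope[match(common, b$snp_id)],
                     se_b = b$se[match(common, b$snp_id)],
                     n_a = a$n_samples[match(common, a$snp_id)],
                     n_b = b$n_samples[match(common, b$snp_id)],
                     stringsAsFactors = FALSE)
    ld_snps <- intersect(common, rownames(ld_genotypes$dosage))
    ld <- ld_matrix(ld_genotypes, ld_snps)
    sd_g <- apply(ld_genotypes$dosage[ld_snps, , drop = FALSE], 1L,
                  stats::sd, na.rm = TRUE)
    st <- st[st$snp_id %in% rownames(ld), ]
    if (lead %in% st$snp_id) {
      h <- heidi_test(st, lead, ld, params, sd_g = sd_g)
      if (!isTRUE(h$skipped)) {
        heidi_stat[i] <- h$stat; heidi_p[i] <- h$p
        heidi_m[i] <- h$m; heidi_skipped[i] <- FALSE
      }
    }
  }
  smr_fdr <- rep(NA_real_, n)
  ok <- !is.na(smr_p)
  smr_fdr[ok] <- bh_adjust(smr_p[ok])
  verdict <- ifelse(!ok, "not-shared",
                    ifelse(smr_fdr < params$smr_fdr_cutoff &
                             (heidi_skipped | heidi_p > params$heidi_p_cutoff),
                           "shared", "not-shared"))
  out <- cbind(tests,
               data.frame(smr_stat = smr_stat, smr_p = smr_p,
                          smr_fdr = smr_fdr, heidi_stat = heidi_stat,
                          heidi_p = heidi_p, heidi_m = heidi_m,
                          heidi_skipped = heidi_skipped,
                          verdict = verdict, stringsAsFactors = FALSE))
  class(out) <- c("ColocResult", "data.frame")
  out
}

#' Classify methQTLs as common / shared / tissue-specific
#'
#' Per CpG (with its anchor lead SNP): the label is `shared` when every
#' pairwise comparison has verdict shared; `common` when additionally the
#' methQTL P-value lies below the genome-wide cutoff in all tissues where
#' the CpG is a tag; `tissue-specific` when no pairwise comparison is
#' shared (the effect is attributed to the anchor tissue);
#' `partially-shared` otherwise (shared in some but not all
#' comparisons, a case the three canonical classes do not cover).
#'
#' @param coloc a `ColocResult` table from [run_coloc()].
#' @param tissue_pvalues data.frame with columns `cpg_id`, `tissue`,
#'   `p_value`: the lead-SNP methQTL P-value per tissue where the CpG is
#'   a tag (e.g. assembled from the [tissue_summary()] lead tables).
#' @param params a [coloc_params()] object.
#' @param gw_cutoff genome-wide methQTL P-value cutoff.
#' @return data.frame with one row per CpG: `cpg_id`, `anchor_tissue`,
#'   `lead_snp`, `n_tests`, `n_shared`, `label`.
#' @export
classify_methqtls <- function(coloc, tissue_pvalues,
                              params = coloc_params(), gw_cutoff) {
  if (nrow(coloc) == 0L)
    return(data.frame(cpg_id = character(0), anchor_tissue = character(0),
                      lead_snp = character(0), n_tests = integer(0),
                      n_shared = integer(0), label = character(0)))
  sp <- split(seq_len(nrow(coloc)), coloc$cpg_id)
  rows <- lapply(names(sp), function(cpg) {
    ii <- sp[[cpg]]
    n_tests <- length(ii)
    n_shared <- sum(coloc$verdict[ii] == "shared")
    pv <- tissue_pvalues$p_value[tissue_pvalues$cpg_id == cpg]
    label <- if (n_shared == n_tests) {
      if (length(pv) > 0L && all(pv < gw_cutoff)) "common" else "shared"
    } else if (n_shared == 0L) "tissue-specific" else "partially-shared"
    data.frame(cpg_id = cpg, anchor_tissue = coloc$anchor_tissue[ii[1L]],
               lead_snp = coloc$lead_snp[ii[1L]], n_tests = n_tests,
               n_shared = n_shared, label = label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
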