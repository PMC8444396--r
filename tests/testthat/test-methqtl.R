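make_block_mm <- function(meds, pos = seq_along(meds) * 100L) {
  # n odd so that each CpG's sample median equals its target exactly
  n <- 11L
  beta <- t(sapply(meds, function(m) {
    v <- m + seq(-0.05, 0.05, length.out = n)
    pmin(pmax(v, 0), 1)
  }))
  dimnames(beta) <- list(sprintf("cg%02d", seq_along(meds)),
                         sprintf("s%02d", seq_len(n)))
  methylation_matrix(beta, rep("1", length(meds)), pos)
}

test_that("medoid tag selection follows the lower-median rule", {
  mm3 <- make_block_mm(c(0.2, 0.5, 0.9))
  expect_equal(select_tag_cpg(rownames(mm3$beta), mm3), "cg02")

  mm4 <- make_block_mm(c(0.1, 0.4, 0.6, 0.9))
  expect_equal(select_tag_cpg(rownames(mm4$beta), mm4), "cg02")  # 0.4

  mm1 <- make_block_mm(0.3)
  expect_equal(select_tag_cpg("cg01", mm1), "cg01")

  # exact median tie broken by smaller genomic position
  mmt <- make_block_mm(c(0.5, 0.5, 0.9), pos = c(300L, 100L, 200L))
  expect_equal(select_tag_cpg(rownames(mmt$beta), mmt), "cg02")

  # all-missing member excluded with a warning
  mm5 <- make_block_mm(c(0.2, 0.5, 0.9))
  mm5$beta["cg03", ] <- NA
  expect_warning(tag <- select_tag_cpg(rownames(mm5$beta), mm5),
                 "all-missing")
  expect_equal(tag, "cg01")  # medians (0.2, 0.5): lower-median -> 0.2
})

test_that("cis candidate window is strict and chromosome-aware", {
  dos <- matrix(rep(0:2, 4), nrow = 4, byrow = TRUE,
                dimnames = list(sprintf("rs%d", 1:4),
                                sprintf("s%d", 1:3)))
  gm <- genotype_matrix(dos, chrom = c("1", "1", "1", "2"),
                        pos = c(1000499999L, 1000500000L, 999500001L,
                                1000000000L),
                        ref = rep("A", 4), alt = rep("G", 4))
  snps <- cis_candidates("1", 1000000000L, gm, 500000)
  expect_true("rs1" %in% snps)    # distance 499,999: included
  expect_false("rs2" %in% snps)   # distance 500,000: strict exclusion
  expect_true("rs3" %in% snps)    # 499,999 upstream
  expect_false("rs4" %in% snps)   # other chromosome
})

test_that("association fit recovers a noiseless construction exactly", {
  g <- rep(0:2, each = 10)
  y <- 0.2 + 0.15 * g
  fit <- fit_association(y, g)
  expect_equal(fit$slope, 0.15, tolerance = 1e-10)
  expect_lt(fit$p_value, 1e-200)
  expect_equal(fit$n, 30L)
})

test_that("association fit matches the normal-equations oracle", {
  set.seed(13)
  for (i in 1:25) {
    n <- 50
    g <- rbinom(n, 2, 0.4)
    cv <- data.frame(age = rnorm(n, 50, 8),
                     sex = factor(sample(c("F", "M"), n, TRUE)))
    y <- pmin(pmax(0.4 + 0.1 * g + 0.002 * cv$age +
                     0.05 * (cv$sex == "M") + rnorm(n, 0, 0.05), 0), 1)
    fit <- fit_association(y, g, cv)
    X <- cbind(1, g, cv$age, cv$sex == "M")
    oracle <- ols_oracle(y, X)
    expect_equal(fit$slope, unname(oracle$beta[2]), tolerance = 1e-10)
    expect_equal(fit$se, unname(oracle$se[2]), tolerance = 1e-10)
    expect_equal(fit$p_value, unname(oracle$p[2]), tolerance = 1e-10)
    # and agrees with stats::lm
    lm_fit <- summary(lm(y ~ g + age + sex, data = cv))
    expect_equal(fit$slope, lm_fit$coefficients["g", 1],
                 tolerance = 1e-10)
    expect_equal(fit$se, lm_fit$coefficients["g", 2], tolerance = 1e-10)
  }
})

test_that("association fit is exchangeable and equivariant to allele flips", {
  set.seed(14)
  n <- 80
  g <- rbinom(n, 2, 0.3)
  y <- pmin(pmax(0.5 + 0.08 * g + rnorm(n, 0, 0.06), 0), 1)
  fit <- fit_association(y, g)
  perm <- sample(n)
  fit_p <- fit_association(y[perm], g[perm])
  expect_equal(fit_p[c("slope", "se", "p_value")],
               fit[c("slope", "se", "p_value")], tolerance = 1e-12)
  fit_f <- fit_association(y, 2 - g)
  expect_equal(fit_f$slope, -fit$slope, tolerance = 1e-12)
  expect_equal(fit_f$se, fit$se, tolerance = 1e-12)
  expect_equal(fit_f$p_value, fit$p_value, tolerance = 1e-12)
})

test_that("degenerate association inputs are skipped with a reason", {
  expect_equal(fit_association(runif(20), rep(1, 20))$reason,
               "monomorphic-in-subset")
  expect_equal(fit_association(runif(2), c(0, 1))$reason,
               "too-few-samples")
  cv <- data.frame(x = rep(1, 20))  # constant covariate: rank deficient
  g <- rbinom(20, 2, 0.5)
  expect_equal(fit_association(runif(20), g, cv)$reason,
               "rank-deficient")
})

test_that("methQTL calling produces one record per tag-SNP pair", {
  set.seed(15)
  n <- 40
  beta <- matrix(pmin(pmax(rnorm(n, 0.5, 0.1), 0), 1), nrow = 1,
                 dimnames = list("cg1", sprintf("s%02d", 1:n)))
  mm <- methylation_matrix(beta, "1", 5000L)
  dos <- t(sapply(1:3, function(i) rbinom(n, 2, 0.4)))
  dimnames(dos) <- list(sprintf("rs%d", 1:3), colnames(beta))
  gm <- genotype_matrix(dos, rep("1", 3), c(1000L, 6000L, 9000L),
                        rep("A", 3), rep("G", 3))
  blocks <- data.frame(block_id = "b1", chrom = "1", cpg_id = "cg1",
                       pos = 5000L)
  recs <- call_methqtls(mm, gm, NULL, blocks)
  expect_equal(nrow(recs), 3L)
  expect_equal(recs$distance, c(-4000L, 1000L, 4000L))
  expect_equal(attr(recs, "mean_snps_per_cpg"), 3)

  # no SNP in window -> empty table with a warning
  gm_far <- genotype_matrix(dos, rep("1", 3),
                            c(1000000L, 2000000L, 3000000L),
                            rep("A", 3), rep("G", 3))
  expect_warning(empty <- call_methqtls(mm, gm_far, NULL, blocks),
                 "no cis SNP")
  expect_equal(nrow(empty), 0L)

  # disjoint samples -> error
  gm_bad <- gm
  colnames(gm_bad$dosage) <- sprintf("x%02d", 1:n)
  expect_error(call_methqtls(mm, gm_bad, NULL, blocks), "overlapping")
})

test_that("genome-wide and replication cutoffs reproduce the printed values", {
  expect_equal(signif(genome_wide_cutoff(c(82271, 69219, 75779, 76109),
                                         1905, 0.05), 3), 8.65e-11)
  expect_equal(genome_wide_cutoff(1, 1, 0.05), 0.05)
  base <- genome_wide_cutoff(c(100, 200), 10, 0.05)
  expect_equal(genome_wide_cutoff(c(200, 400), 10, 0.05), base / 2)
  expect_error(genome_wide_cutoff(c(0, 10), 5), "positive")

  expect_equal(signif(replication_cutoff(c(2508, 696, 1010, 868), 0.05),
                      3), 9.84e-06)
  expect_equal(replication_cutoff(1, 0.05), 0.05)
  cts <- c(17, 23, 40)
  expect_equal(replication_cutoff(cts, 0.05) * sum(cts), 0.05)
})

test_that("lead-SNP selection keeps the smallest p with stated tie-breaks", {
  recs <- data.frame(
    cpg_id = c("cgA", "cgA", "cgB", "cgB", "cgB"),
    snp_id = c("rs1", "rs2", "rs9", "rs3", "rs5"),
    distance = c(100L, 5000L, -200L, 5000L, 100L),
    p_value = c(1e-12, 1e-8, 1e-4, 1e-6, 1e-6))
  lead <- select_lead_snps(recs)
  expect_equal(nrow(lead), 2L)
  expect_equal(lead$snp_id[lead$cpg_id == "cgA"], "rs1")
  expect_equal(lead$snp_id[lead$cpg_id == "cgB"], "rs5")  # tie -> 100 bp
  expect_error(select_lead_snps(recs[0, ]), "empty")
})
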