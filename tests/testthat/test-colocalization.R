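test_that("SMR statistic matches its closed form and is symmetric", {
  # one trait without effect -> no evidence of a shared signal
  r0 <- smr_test(0, 0.1, 0.5, 0.1)
  expect_equal(r0$stat, 0)
  expect_equal(r0$p, 1)

  r <- smr_test(0.5, 0.1, 0.5, 0.1)     # z_a = z_b = 5
  expect_equal(r$stat, 12.5)
  expect_equal(r$p, pchisq(12.5, df = 1, lower.tail = FALSE),
               tolerance = 1e-14)

  set.seed(17)
  for (i in 1:20) {
    a <- rnorm(1); b <- rnorm(1); sa <- runif(1, .01, .2); sb <- runif(1, .01, .2)
    expect_equal(smr_test(a, sa, b, sb), smr_test(b, sb, a, sa))
  }
  expect_warning(deg <- smr_test(0, 0.1, 0, 0.2), "degenerate")
  expect_equal(deg$p, 1)
  expect_error(smr_test(0.1, 0, 0.1, 0.1), "positive")
})

test_that("BH adjustment equals the step-up oracle and stats::p.adjust", {
  expect_equal(bh_adjust(0.031), 0.031)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  p4 <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_adjust(p4), bh_oracle(p4), tolerance = 1e-14)
  set.seed(19)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-14)
    expect_equal(adj, p.adjust(p, "BH"), tolerance = 1e-14)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
})

test_that("the quadratic-form tail matches chi-square in the 1-weight case", {
  expect_equal(comethQTL:::p_quadform(3.5, 1),
               pchisq(3.5, 1, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(comethQTL:::p_quadform(7, c(2, 2)),
               pchisq(3.5, 2, lower.tail = FALSE), tolerance = 1e-6)
  # equal-weight case reduces to a scaled chi-square with k df
  expect_equal(comethQTL:::p_quadform(10, rep(1, 5)),
               pchisq(10, 5, lower.tail = FALSE), tolerance = 1e-6)
})

test_that("HEIDI enforces instrument requirements and bounds", {
  h <- heidi_sim_stats(101, "pleio")
  res <- heidi_test(h$stats, h$lead, h$ld, sd_g = h$sd_g)
  expect_false(res$skipped)
  expect_gte(res$m, 3L)
  expect_lte(res$m, coloc_params()$heidi_max_snps)
  expect_equal(res$m, length(res$snps))
  expect_true(res$p > 0 && res$p <= 1)

  # raising the instrument threshold starves the test -> explicit skip
  strict <- coloc_params(instrument_z2_min = 1e6)
  res2 <- heidi_test(h$stats, h$lead, h$ld, strict, sd_g = h$sd_g)
  expect_true(res2$skipped)
  expect_equal(res2$reason, "too-few-instruments")
  expect_equal(res2$m, 0L)

  # cap at heidi_max_snps
  cap <- coloc_params(heidi_max_snps = 4L)
  res3 <- heidi_test(h$stats, h$lead, h$ld, cap, sd_g = h$sd_g)
  expect_lte(res3$m, 4L)
  expect_error(heidi_test(h$stats, "nonexistent", h$ld), "not in stats")
})

test_that("coloc test selection follows the anchoring rules", {
  mk_summary <- function(tissue, cpgs, ps, snps = NULL) {
    n <- length(cpgs)
    recs <- data.frame(
      cpg_id = cpgs, snp_id = snps %||% sprintf("rs%d", seq_len(n)),
      chrom = "1", cpg_pos = seq_len(n) * 1000L,
      snp_pos = seq_len(n) * 1000L + 100L, distance = 100L,
      slope = 0.1, se = 0.01, p_value = ps, n_samples = 100L)
    tissue_summary(tissue, recs)
  }
  cutoff <- 1e-10

  # significant in exactly one of two tissues -> one test anchored there
  s <- list(mk_summary("t1", "cgA", 1e-15), mk_summary("t2", "cgA", 1e-3))
  tests <- select_coloc_tests(s, cutoff)
  expect_equal(nrow(tests), 1L)
  expect_equal(tests$anchor_tissue, "t1")
  expect_equal(tests$other_tissue, "t2")

  # not a tag in a second tissue -> excluded
  s2 <- list(mk_summary("t1", "cgA", 1e-15), mk_summary("t2", "cgB", 1e-15))
  expect_equal(nrow(select_coloc_tests(s2, cutoff)), 0L)

  # significant in 3 of 4 tissues -> 3 tests, all anchored at lowest p
  s3 <- list(mk_summary("t1", "cgA", 1e-20), mk_summary("t2", "cgA", 1e-13),
             mk_summary("t3", "cgA", 1e-12), mk_summary("t4", "cgA", 0.5))
  tests3 <- select_coloc_tests(s3, cutoff)
  expect_equal(nrow(tests3), 3L)
  expect_true(all(tests3$anchor_tissue == "t1"))
  expect_setequal(tests3$other_tissue, c("t2", "t3", "t4"))
})

test_that("classification implements the rule table", {
  coloc <- data.frame(
    cpg_id = c("cgA", "cgA", "cgB", "cgB", "cgC", "cgC", "cgC"),
    anchor_tissue = "t1",
    other_tissue = c("t2", "t3", "t2", "t3", "t2", "t3", "t4"),
    lead_snp = "rs1",
    verdict = c("shared", "shared",          # cgA: all shared
                "not-shared", "not-shared",  # cgB: none shared
                "shared", "shared", "not-shared"))  # cgC: 2 of 3
  tp <- data.frame(
    cpg_id = rep(c("cgA", "cgB", "cgC"), each = 3),
    tissue = rep(c("t1", "t2", "t3"), 3),
    p_value = c(rep(1e-12, 3), rep(1e-12, 3), rep(1e-12, 3)))
  cl <- classify_methqtls(coloc, tp, coloc_params(), gw_cutoff = 8.65e-11)
  expect_equal(cl$label[cl$cpg_id == "cgA"], "common")
  expect_equal(cl$label[cl$cpg_id == "cgB"], "tissue-specific")
  expect_equal(cl$label[cl$cpg_id == "cgC"], "partially-shared")

  # shared but not significant everywhere -> shared, not common
  tp2 <- tp; tp2$p_value[tp2$cpg_id == "cgA" & tp2$tissue == "t3"] <- 1e-5
  cl2 <- classify_methqtls(coloc, tp2, coloc_params(), gw_cutoff = 8.65e-11)
  expect_equal(cl2$label[cl2$cpg_id == "cgA"], "shared")

  # common is a subset of shared by construction: every common CpG has
  # all its pairwise verdicts shared
  common_cpgs <- cl$cpg_id[cl$label == "common"]
  for (cpg in common_cpgs)
    expect_true(all(coloc$verdict[coloc$cpg_id == cpg] == "shared"))
})

test_that("classification counts are invariant to tissue relabeling", {
  h <- heidi_sim_stats(202, "pleio")
  st <- h$stats
  mk <- function(tissue, slopes, ses) {
    recs <- data.frame(cpg_id = "cg1", snp_id = st$snp_id, chrom = "1",
                       cpg_pos = 100L, snp_pos = seq_len(nrow(st)) * 10L,
                       distance = seq_len(nrow(st)) * 10L - 100L,
                       slope = slopes, se = ses,
                       p_value = 2 * pnorm(-abs(slopes / ses)),
                       n_samples = 200L)
    tissue_summary(tissue, recs)
  }
  s12 <- list(mk("t1", st$slope_a, st$se_a), mk("t2", st$slope_b, st$se_b))
  s21 <- rev(s12)
  set.seed(33)
  ld_gm <- genotype_matrix(
    matrix(rbinom(nrow(st) * 50, 2, 0.3), nrow = nrow(st),
           dimnames = list(st$snp_id, sprintf("s%d", 1:50))),
    chrom = rep("1", nrow(st)), pos = seq_len(nrow(st)) * 10L,
    ref = rep("A", nrow(st)), alt = rep("G", nrow(st)))
  cutoff <- 1e-8
  res12 <- run_coloc(s12, select_coloc_tests(s12, cutoff), ld_gm)
  res21 <- run_coloc(s21, select_coloc_tests(s21, cutoff), ld_gm)
  expect_equal(sort(table(res12$verdict)), sort(table(res21$verdict)))
})
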