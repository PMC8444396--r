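test_that("simulation is a pure function of config and seed", {
  cfg <- sim_config(n_samples = 50, n_snps = 100,
                    block_spec = data.frame(n_cpgs = 5L, span_bp = 1000L,
                                            target_cor = 0.7),
                    seed = 4)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosage, g2$dosage)
  m1 <- simulate_methylation(cfg, g1)
  m2 <- simulate_methylation(cfg, g2)
  expect_identical(m1$beta, m2$beta)
})

test_that("simulated genotypes match their drawn allele frequencies", {
  cfg <- sim_config(n_samples = 1000, n_snps = 200, seed = 6)
  gm <- simulate_genotypes(cfg)
  sp <- comethQTL:::sim_snp_params(cfg)
  emp <- rowMeans(gm$dosage) / 2
  tol <- 3 * sqrt(sp$p * (1 - sp$p) / (2 * 1000))
  expect_true(all(abs(emp - sp$p) <= tol))
  expect_true(all(gm$dosage %in% 0:2))
  expect_equal(gm$pos, sort(gm$pos))
})

test_that("null genotypes rarely fail the HWE filter (calibration)", {
  cfg <- sim_config(n_samples = 500, n_snps = 500, seed = 8)
  gm <- simulate_genotypes(cfg)
  hwe_p <- apply(gm$dosage, 1, function(d)
    hwe_exact_test(sum(d == 0), sum(d == 1), sum(d == 2)))
  expect_lte(mean(hwe_p < 0.001), 0.005)
})

test_that("within-block correlation approximates the target", {
  cfg <- sim_config(n_samples = 200, n_snps = 50,
                    block_spec = data.frame(n_cpgs = 10L, span_bp = 2000L,
                                            target_cor = 0.8),
                    seed = 12)
  gm <- simulate_genotypes(cfg)
  mm <- simulate_methylation(cfg, gm)
  r <- cor(t(mm$beta))
  mean_r <- mean(r[upper.tri(r)])
  expect_gte(mean_r, 0.7)
  expect_lte(mean_r, 0.9)
})

test_that("single-CpG blocks without noise reproduce the latent exactly", {
  cfg <- sim_config(n_samples = 30, n_snps = 20,
                    block_spec = data.frame(n_cpgs = 1L, span_bp = 10L,
                                            target_cor = 0),
                    noise_sd = 0, seed = 14)
  gm <- simulate_genotypes(cfg)
  mm <- simulate_methylation(cfg, gm)
  # reconstruct the latent stream: block parameters are drawn from the
  # structural seed first, then the tissue stream produces the latent
  bp <- comethQTL:::sim_block_params(cfg)
  set.seed(cfg$seed + 7919L + 29L)
  L <- plogis(rnorm(30, qlogis(bp[[1]]$mu), 0.35))
  expect_equal(unname(mm$beta[1, ]), pmin(pmax(L, 0), 1),
               tolerance = 1e-12)
})

test_that("an injected effect is recovered by the association fit", {
  cfg <- sim_config(n_samples = 200, n_snps = 60, chrom_length_bp = 1e6,
                    block_spec = data.frame(n_cpgs = 5L, span_bp = 1000L,
                                            target_cor = 0.8),
                    effects = data.frame(block = 1L, snp = 30L,
                                         slope = 0.2, class = "shared",
                                         home_tissue = 1L),
                    seed = 16)
  gm <- simulate_genotypes(cfg)
  mm <- simulate_methylation(cfg, gm)
  # the block latent carries the effect; every member CpG shows it
  y <- mm$beta[1, ]
  fit <- fit_association(y, gm$dosage[30, ])
  expect_lt(abs(fit$slope - 0.2), 3 * fit$se)
  expect_lt(fit$p_value, 1e-10)
})

test_that("LD proxies realize their requested correlations", {
  cfg <- sim_config(n_samples = 2000, n_snps = 20, chrom_length_bp = 1e5,
                    effects = data.frame(block = 1L, snp = 1L, slope = 0.1,
                                         class = "shared",
                                         home_tissue = 1L),
                    ld_proxy_r = c(0.8, 0.5), seed = 18,
                    block_spec = data.frame(n_cpgs = 1L, span_bp = 10L,
                                            target_cor = 0))
  gm <- simulate_genotypes(cfg)
  r <- cor(t(gm$dosage[1:3, ]))
  expect_equal(r[1, 2], 0.8, tolerance = 0.06)
  expect_equal(r[1, 3], 0.5, tolerance = 0.06)
})

test_that("multi-tissue truth tables are deterministic and class-correct", {
  cfg <- sim_config(n_samples = 40, n_snps = 60, n_tissues = 2,
                    chrom_length_bp = 1e6,
                    block_spec = data.frame(n_cpgs = rep(3L, 4), span_bp = 500L,
                                            target_cor = 0.6),
                    effects = data.frame(block = 1:2, snp = c(10L, 40L),
                                         slope = 0.1,
                                         class = c("shared", "specific"),
                                         home_tissue = c(1L, 2L)),
                    seed = 20)
  sim1 <- simulate_multitissue(cfg)
  sim2 <- simulate_multitissue(cfg)
  expect_identical(sim1$truth, sim2$truth)
  expect_equal(nrow(sim1$truth), 2L)
  expect_equal(sim1$truth$class, c("shared", "specific"))
  # shared effect: same SNP in both tissues; specific: absent elsewhere
  expect_equal(sim1$truth$snp_tissue1[1], sim1$truth$snp_tissue2[1])
  expect_true(is.na(sim1$truth$snp_tissue1[2]))
  expect_equal(sim1$truth$snp_tissue2[2], sim1$truth$snp_id[2])
  # tissues have disjoint sample ids but one SNP panel
  g1 <- sim1$tissues[[1]]$geno; g2 <- sim1$tissues[[2]]$geno
  expect_length(intersect(colnames(g1$dosage), colnames(g2$dosage)), 0L)
  expect_identical(rownames(g1$dosage), rownames(g2$dosage))
})

test_that("linkage mode at LD zero gives independent causal SNPs", {
  cfg <- sim_config(n_samples = 1500, n_snps = 30, chrom_length_bp = 1e5,
                    n_tissues = 2, linkage_ld = 0,
                    block_spec = data.frame(n_cpgs = 1L, span_bp = 10L,
                                            target_cor = 0),
                    effects = data.frame(block = 1L, snp = 1L, slope = 0.1,
                                         class = "linkage",
                                         home_tissue = 1L),
                    ld_proxy_r = c(0.7, 0.5), seed = 22)
  sim <- simulate_multitissue(cfg)
  # the partner SNP (first proxy slot) is regenerated at r = linkage_ld
  g <- sim$tissues[[1]]$geno
  expect_lt(abs(cor(g$dosage[1, ], g$dosage[2, ])), 0.08)
  expect_equal(sim$truth$snp_tissue1[1], "snp00001")
  expect_equal(sim$truth$snp_tissue2[1], "snp00002")
})
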