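# Small programmatic fixtures shared across test files.

tiny_meth <- function() {
  beta <- matrix(c(0.1, 0.2, 0.5, 0.6, 0.9, 0.8), nrow = 3, byrow = TRUE,
                 dimnames = list(c("cg1", "cg2", "cg3"), c("s1", "s2")))
  methylation_matrix(beta, chrom = c("1", "1", "2"),
                     pos = c(100L, 500L, 100L))
}

tiny_geno <- function() {
  dos <- matrix(c(0L, 1L, 2L, 1L, 0L, NA, 2L, 2L), nrow = 2, byrow = TRUE,
                dimnames = list(c("rs1", "rs2"),
                                c("s1", "s2", "s3", "s4")))
  genotype_matrix(dos, chrom = c("1", "1"), pos = c(1000L, 2000L),
                  ref = c("A", "C"), alt = c("G", "T"))
}

# A minimal VCF (v4.2) with biallelic SNPs, one multi-allelic record,
# phased/unphased GT separators and a missing genotype.
write_tiny_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1,length=100000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0|1\t1|0\t./.",
    "1\t300\trs3\tG\tA,C\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0",
    "1\t400\trs4\tT\tC\t.\tPASS\t.\tGT\t1/1\t0/0\t0/1"),
    path)
  path
}

# Simulated genotype/methylation pair with planted QC violations used by
# the genotype-filter tests.
qc_fixture <- function(seed = 5L, n = 60L) {
  set.seed(seed)
  n_snps <- 30L
  dos <- matrix(rbinom(n_snps * n, 2L, 0.3), nrow = n_snps)
  rownames(dos) <- sprintf("rs%03d", seq_len(n_snps))
  colnames(dos) <- sprintf("s%03d", seq_len(n))
  dos[1L, seq_len(ceiling(0.2 * n))] <- NA          # high missingness
  dos[2L, ] <- rep(c(0L, 2L), length.out = n)       # het deficit -> HWE
  dos[3L, ] <- c(1L, rep(0L, n - 1L))               # rare -> low MAF
  dos[, 1L] <- NA                                   # bad sample
  genotype_matrix(dos, chrom = rep("1", n_snps),
                  pos = seq_len(n_snps) * 100L,
                  ref = rep("A", n_snps), alt = rep("G", n_snps))
}

# Per-SNP summary statistics for both tissues plus the LD reference, as
# consumed by heidi_test(); built from a two-tissue simulation with one
# causal SNP ("pleio") or two linked causal SNPs ("link").
heidi_sim_stats <- function(seed, mode = c("pleio", "link"),
                            n = 200L, slope = 0.15) {
  mode <- match.arg(mode)
  cfg <- sim_config(
    n_samples = n, n_snps = 12L, chrom_length_bp = 60000,
    block_spec = data.frame(n_cpgs = 1L, span_bp = 100L, target_cor = 0),
    effects = data.frame(block = 1L, snp = 1L, slope = slope,
                         class = ifelse(mode == "pleio", "shared",
                                        "linkage"),
                         home_tissue = 1L),
    n_tissues = 2L,
    ld_proxy_r = c(0.85, 0.8, 0.75, 0.7, 0.65, 0.6, 0.55, 0.5),
    seed = seed)
  sim <- simulate_multitissue(cfg)
  st <- NULL
  for (t in 1:2) {
    y <- sim$tissues[[t]]$meth$beta[1L, ]
    gm <- sim$tissues[[t]]$geno
    fits <- lapply(rownames(gm$dosage), function(s)
      fit_association(y, gm$dosage[s, ]))
    df <- data.frame(snp_id = rownames(gm$dosage),
                     slope = sapply(fits, `[[`, "slope"),
                     se = sapply(fits, `[[`, "se"),
                     n = sapply(fits, `[[`, "n"))
    names(df)[2:4] <- paste0(c("slope_", "se_", "n_"), c("a", "b")[t])
    st <- if (is.null(st)) df else cbind(st, df[, 2:4])
  }
  ld_ref <- pool_genotypes(list(sim$tissues[[1L]]$geno,
                                sim$tissues[[2L]]$geno))
  list(stats = st, ld = ld_matrix(ld_ref),
       sd_g = apply(ld_ref$dosage, 1L, sd), lead = "snp00001")
}
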