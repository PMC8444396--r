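#' Simulation configuration
#'
#' Describes a download-free synthetic cohort with the statistical
#' structure the pipeline assumes: SNPs in Hardy-Weinberg equilibrium
#' with uniform minor-allele frequencies, CpGs organised in
#' block-correlated groups around a shared logit-normal latent level,
#' and cis effects injected additively on the beta scale. Defaults give
#' the standard end-to-end fixture: 200 samples, 2000 SNPs on a 10 Mb
#' chromosome, 50 blocks of 10 CpGs spanning 2 kb each with a
#' within-block target correlation of 0.8 and measurement noise 0.05.
#'
#' @param n_samples samples per tissue.
#' @param n_snps number of SNPs.
#' @param maf_range range of allele frequencies, drawn uniformly.
#' @param chrom_length_bp chromosome length (positions drawn without
#'   replacement).
#' @param chrom chromosome name.
#' @param block_spec data.frame with columns `n_cpgs`, `span_bp`,
#'   `target_cor` (one row per block), or `NULL` for the default 50
#'   blocks x (10 CpGs, 2000 bp, 0.8).
#' @param effects data.frame with columns `block`, `snp`, `slope`,
#'   `class` (one of `"shared"`, `"specific"`, `"linkage"`) and
#'   `home_tissue`; `NULL` for none. See [sim_default_effects()].
#' @param noise_sd measurement noise used when a block's `target_cor`
#'   is 0.
#' @param baseline_spacing spacing of the per-CpG baseline offsets: each
#'   block's CpGs receive an evenly spaced ladder of mean offsets
#'   (`(rank - (n+1)/2) * baseline_spacing`, ranks shuffled over
#'   positions once per configuration and shared across tissues). This
#'   emulates the stable CpG-specific mean methylation of real data and
#'   makes the medoid tag-CpG reproducible across tissues.
#' @param n_tissues number of tissues (independent sample sets).
#' @param ld_proxy_r LD correlations of the proxy SNPs planted next to
#'   each effect SNP (needed for the HEIDI instrument set); empty vector
#'   for none.
#' @param linkage_ld LD between the two causal SNPs of a `"linkage"`
#'   effect.
#' @param seed RNG seed; everything is a pure function of (config, seed).
#' @return An object of class `SimConfig`.
#' @export
sim_config <- function(n_samples = 200L, n_snps = 2000L,
                       maf_range = c(0.05, 0.5), chrom_length_bp = 1e7,
                       chrom = "1", block_spec = NULL, effects = NULL,
                       noise_sd = 0.05, baseline_spacing = 0.03,
                       n_tissues = 1L,
                       ld_proxy_r = c(0.85, 0.8, 0.75, 0.7, 0.65, 0.6),
                       linkage_ld = 0.7, seed = 1L) {
  if (is.null(block_spec))
    block_spec <- data.frame(n_cpgs = rep(10L, 50L), span_bp = 2000L,
                             target_cor = 0.8)
  stopifnot(all(c("n_cpgs", "span_bp", "target_cor") %in% names(block_spec)))
  if (any(block_spec$target_cor < 0 | block_spec$target_cor >= 1))
    stopf("target correlation must lie in [0,1)")
  if (min(maf_range) <= 0 || max(maf_range) > 0.5)
    stopf("maf_range must lie in (0, 0.5]")
  if (n_snps > chrom_length_bp) stopf("more SNPs than base pairs")
  if (!is.null(effects)) {
    stopifnot(all(c("block", "snp", "slope") %in% names(effects)))
    effects$class <- effects$class %||% rep("shared", nrow(effects))
    effects$home_tissue <- effects$home_tissue %||% rep(1L, nrow(effects))
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_snps = as.integer(n_snps), maf_range = maf_range,
                 chrom_length_bp = chrom_length_bp, chrom = chrom,
                 block_spec = block_spec, effects = effects,
                 noise_sd = noise_sd, baseline_spacing = baseline_spacing,
                 n_tissues = as.integer(n_tissues),
                 ld_proxy_r = ld_proxy_r, linkage_ld = linkage_ld,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

# SNP-level parameters (frequencies, positions, alleles) are a pure
# function of the seed alone so that all tissues share one SNP panel.
sim_snp_params <- function(cfg) {
  set.seed(cfg$seed)
  p <- stats::runif(cfg$n_snps, cfg$maf_range[1L], cfg$maf_range[2L])
  pos <- sort(sample.int(cfg$chrom_length_bp, cfg$n_snps))
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, cfg$n_snps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L),
                character(1))
  list(p = p, pos = pos, ref = ref, alt = unname(alt),
       ids = sprintf("snp%05d", seq_len(cfg$n_snps)))
}

# Ids of the proxy SNPs planted immediately after an effect SNP.
proxy_indices <- function(cfg, snp_index) {
  k <- length(cfg$ld_proxy_r)
  if (k == 0L) return(integer(0))
  idx <- snp_index + seq_len(k)
  idx[idx <= cfg$n_snps]
}

#' Simulate a genotype matrix
#'
#' Per SNP, the alt-allele frequency is drawn uniformly from `maf_range`
#' and dosages are Binomial(2, p) i.i.d. across samples (exact HWE in
#' expectation). SNPs named in `effects` receive LD proxies: the
#' `length(ld_proxy_r)` SNPs following the causal SNP are regenerated
#' haplotype-wise, conditioned on the causal haplotypes at the requested
#' correlations (`linkage` effects use `linkage_ld` for the first
#' proxy, which becomes the partner causal SNP).
#'
#' @param cfg a [sim_config()].
#' @param tissue tissue index (changes the sample draw, not the SNP
#'   panel).
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(cfg, tissue = 1L) {
  sp <- sim_snp_params(cfg)
  n <- cfg$n_samples
  set.seed(cfg$seed + 7919L * as.integer(tissue) + 13L)
  h1 <- matrix(stats::rbinom(cfg$n_snps * n, 1L, sp$p),
               nrow = cfg$n_snps)
  h2 <- matrix(stats::rbinom(cfg$n_snps * n, 1L, sp$p),
               nrow = cfg$n_snps)
  if (!is.null(cfg$effects)) {
    for (e in seq_len(nrow(cfg$effects))) {
      j <- cfg$effects$snp[e]
      idx <- proxy_indices(cfg, j)
      if (length(idx) == 0L) next
      rr <- cfg$ld_proxy_r[seq_along(idx)]
      if (cfg$effects$class[e] == "linkage") rr[1L] <- cfg$linkage_ld
      p <- sp$p[j]
      for (k in seq_along(idx)) {
        # conditional haplotype allele frequencies giving correlation r
        # when both loci share frequency p: D = r p (1 - p)
        r <- rr[k]
        p1 <- p + r * (1 - p)   # P(proxy = 1 | causal hap = 1)
        p0 <- p * (1 - r)       # P(proxy = 1 | causal hap = 0)
        sp$p[idx[k]] <- p
        h1[idx[k], ] <- stats::rbinom(n, 1L, ifelse(h1[j, ] == 1L, p1, p0))
        h2[idx[k], ] <- stats::rbinom(n, 1L, ifelse(h2[j, ] == 1L, p1, p0))
      }
    }
  }
  dos <- h1 + h2
  genotype_matrix(dos, chrom = rep(cfg$chrom, cfg$n_snps), pos = sp$pos,
                  ref = sp$ref, alt = sp$alt, snp_ids = sp$ids,
                  sample_ids = sprintf("T%d_S%04d", tissue, seq_len(n)))
}

# Block-level structural parameters (positions, baseline means, per-CpG
# offsets): a pure function of the seed, shared across tissues.
sim_block_params <- function(cfg) {
  set.seed(cfg$seed + 101L)
  B <- nrow(cfg$block_spec)
  centers <- round(cfg$chrom_length_bp * seq_len(B) / (B + 1L))
  blocks <- vector("list", B)
  for (b in seq_len(B)) {
    nc <- cfg$block_spec$n_cpgs[b]
    span <- cfg$block_spec$span_bp[b]
    blocks[[b]] <- list(
      pos = centers[b] + sort(sample.int(span, nc)),
      mu = stats::runif(1L, 0.25, 0.65),
      baseline = sample((seq_len(nc) - (nc + 1) / 2) *
                          cfg$baseline_spacing),
      ids = sprintf("cg%03d_%02d", b, seq_len(nc)))
  }
  blocks
}

#' Simulate a block-correlated methylation matrix
#'
#' Per block, a latent per-sample level `L = plogis(Z)` with
#' `Z ~ N(logit(mu_b), 0.4)` is shared by all member CpGs; injected cis
#' effects add `slope * dosage` to `L` before clipping. Each CpG's beta
#' is `clip(L + baseline_c + noise, 0, 1)` where the per-CpG noise
#' standard deviation is set by the closed-form variance ratio
#' `sd(L) * sqrt((1 - rho) / rho)` so the realized within-block Pearson
#' correlation approximates the target `rho` (blocks with `rho = 0` use
#' `noise_sd` directly).
#'
#' @param cfg a [sim_config()].
#' @param gm the matching [genotype_matrix()] (for effect injection).
#' @param tissue tissue index.
#' @return a [methylation_matrix()] with attribute `block_of` (named
#'   vector: CpG id -> block index).
#' @export
simulate_methylation <- function(cfg, gm, tissue = 1L) {
  bp <- sim_block_params(cfg)
  n <- cfg$n_samples
  stopifnot(ncol(gm$dosage) == n)
  set.seed(cfg$seed + 7919L * as.integer(tissue) + 29L)
  rows <- list()
  block_of <- character(0)
  for (b in seq_along(bp)) {
    nc <- length(bp[[b]]$ids)
    rho <- cfg$block_spec$target_cor[b]
    L <- stats::plogis(stats::rnorm(n, stats::qlogis(bp[[b]]$mu), 0.35))
    if (!is.null(cfg$effects)) {
      eff <- cfg$effects[cfg$effects$block == b, , drop = FALSE]
      for (e in seq_len(nrow(eff))) {
        j <- effect_snp_for_tissue(cfg, eff[e, ], tissue)
        if (is.na(j)) next
        L <- L + eff$slope[e] * gm$dosage[j, ]
      }
    }
    sd_e <- if (rho > 0) stats::sd(L) * sqrt((1 - rho) / rho) else
      cfg$noise_sd
    beta <- matrix(rep(L, each = nc) + bp[[b]]$baseline +
                     stats::rnorm(nc * n, 0, sd_e), nrow = nc)
    beta <- pmin(pmax(beta, 0), 1)
    rownames(beta) <- bp[[b]]$ids
    rows[[b]] <- beta
    block_of <- c(block_of, stats::setNames(rep(b, nc), bp[[b]]$ids))
  }
  beta <- do.call(rbind, rows)
  colnames(beta) <- colnames(gm$dosage)
  mm <- methylation_matrix(beta,
                           chrom = rep(cfg$chrom, nrow(beta)),
                           pos = unlist(lapply(bp, `[[`, "pos")),
                           cpg_ids = rownames(beta),
                           sample_ids = colnames(beta))
  attr(mm, "block_of") <- block_of
  mm
}

# Which SNP index carries an effect in a given tissue (NA for none):
# shared -> the configured SNP everywhere; specific -> only in the home
# tissue; linkage -> the configured SNP in the home tissue, its partner
# (first proxy) elsewhere.
effect_snp_for_tissue <- function(cfg, effect, tissue) {
  cls <- effect$class
  if (cls == "shared") return(effect$snp)
  if (cls == "specific")
    return(if (tissue == effect$home_tissue) effect$snp else NA_integer_)
  if (cls == "linkage") {
    if (tissue == effect$home_tissue) return(effect$snp)
    idx <- proxy_indices(cfg, effect$snp)
    return(if (length(idx)) idx[1L] else NA_integer_)
  }
  NA_integer_
}

#' Default injected-effect table for the end-to-end fixture
#'
#' Ten effects of slope 0.1 on the first ten blocks, each on the SNP
#' nearest the block centre; the first `n_shared` are shared across all
#' tissues, the remainder tissue-specific with home tissues alternating.
#'
#' @param cfg a [sim_config()].
#' @param n_effects number of effects.
#' @param n_shared how many of them are shared.
#' @param slope effect size on the beta scale per alt allele.
#' @return effects data.frame suitable for [sim_config()].
#' @export
sim_default_effects <- function(cfg, n_effects = 10L, n_shared = 5L,
                                slope = 0.1) {
  sp <- sim_snp_params(cfg)
  B <- nrow(cfg$block_spec)
  stopifnot(n_effects <= B)
  centers <- round(cfg$chrom_length_bp * seq_len(B) / (B + 1L))
  snp <- vapply(seq_len(n_effects), function(b)
    which.min(abs(sp$pos - centers[b])), integer(1))
  data.frame(block = seq_len(n_effects), snp = snp, slope = slope,
             class = rep(c("shared", "specific"),
                         c(n_shared, n_effects - n_shared)),
             home_tissue = ifelse(seq_len(n_effects) <= n_shared, 1L,
                                  (seq_len(n_effects) %% max(cfg$n_tissues, 1L)) + 1L),
             stringsAsFactors = FALSE)
}

#' Simulate a multi-tissue design with ground truth
#'
#' Each tissue gets an independent sample set over a common SNP panel.
#' Shared effects use the same causal SNP in all tissues;
#' tissue-specific effects have slope zero outside their home tissue;
#' linkage effects drive the other tissues from a distinct partner SNP
#' in LD `linkage_ld` with the home tissue's causal SNP.
#'
#' @param cfg a [sim_config()] with `n_tissues >= 2` and non-`NULL`
#'   `effects`.
#' @return list with `tissues` (named list of `list(meth, geno)`) and
#'   `truth` (data.frame: effect id, block, per-tissue causal SNP id,
#'   slope, class).
#' @export
simulate_multitissue <- function(cfg) {
  if (cfg$n_tissues < 2L) stopf("n_tissues must be >= 2")
  if (is.null(cfg$effects)) cfg$effects <- sim_default_effects(cfg)
  sp <- sim_snp_params(cfg)
  tissues <- stats::setNames(vector("list", cfg$n_tissues),
                             sprintf("tissue%d", seq_len(cfg$n_tissues)))
  for (t in seq_len(cfg$n_tissues)) {
    gm <- simulate_genotypes(cfg, tissue = t)
    mm <- simulate_methylation(cfg, gm, tissue = t)
    tissues[[t]] <- list(meth = mm, geno = gm)
  }
  truth <- cfg$effects
  truth$effect_id <- sprintf("effect%02d", seq_len(nrow(truth)))
  for (t in seq_len(cfg$n_tissues)) {
    idx <- vapply(seq_len(nrow(truth)), function(e)
      effect_snp_for_tissue(cfg, truth[e, ], t), integer(1))
    truth[[sprintf("snp_tissue%d", t)]] <-
      ifelse(is.na(idx), NA_character_, sp$ids[idx])
  }
  truth$snp_id <- sp$ids[truth$snp]
  list(tissues = tissues, truth = truth)
}
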