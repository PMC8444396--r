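---
title: "comethQTL: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{comethQTL: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models implemented in
`comethQTL`, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the design
decisions taken where the methodology left genuine choices open. It
states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

# The two-stage methQTL model

DNA methylation at neighbouring CpGs is strongly correlated, both
because of shared regulation and because a single genetic variant often
influences a whole region. Testing every CpG independently against
every cis SNP therefore multiplies the testing burden without adding
information. `comethQTL` follows a two-stage protocol:

1. **Correlation-block calling** groups co-methylated, proximal CpGs
   into blocks — a proxy for a methylation haplotype.
2. **Association testing** regresses one representative CpG per block
   (the *tag-CpG*) on the dosages of all SNPs within a cis window.

## Correlation blocks

For CpGs $i, j$ on the same chromosome the similarity is
$s_{ij} = r_{ij} \exp(-d_{ij}^2 / (2\sigma^2))$ with $r_{ij}$ the
Pearson correlation of beta values across samples and $d_{ij}$ the
genomic distance. Louvain community detection on the weighted graph
gives the blocks. Parameters, with defaults:

| parameter | default | unit | meaning |
|---|---|---|---|
| `cluster_cor_threshold` | 0.2 | — | correlations below this (including all negative ones) contribute similarity 0 |
| `gauss_sd` | 3000 | bp | SD of the Gaussian distance weight |
| `absolute_distance_cutoff` | 500,000 | bp | similarity 0 beyond this distance |
| `max_cpgs_per_chunk` | 40,000 | CpGs | per-chromosome chunking bound (memory) |
| `louvain_resolution` | 1 | — | Louvain resolution |
| `clustering_seed` | 1 | — | seed for the stochastic Louvain pass |

Design decisions:

* **Negative correlations are zeroed**, not folded in by absolute
  value: the thresholding rule is applied literally to $r_{ij}$.
* **The Gaussian multiplies the correlation** rather than replacing it;
  "weighting" is read as multiplication.
* **Blocks are not forced to be genomically contiguous**; Louvain
  communities are taken as-is. No contiguity constraint is imposed
  anywhere in the derivation, and occasionally a distal CpG genuinely
  belongs with a block.
* **Chunk boundaries are hard**: CpG pairs in different chunks get
  similarity 0. This mirrors the memory-motivated splitting and is a
  documented edge effect — a true block straddling a chunk boundary
  will be split. Chunks are contiguous groups whose sizes differ by at
  most one.
* **Missing data**: correlations use pairwise-complete observations;
  pairs sharing fewer than 3 samples, and zero-variance CpGs, get
  similarity 0.
* An optional multiplicative `weight_mask` hook exposes
  annotation-driven similarity re-weighting without prescribing a
  scheme.

## Tag-CpG (medoid) selection

The default tag is the *medoid of medians*: compute each member CpG's
median beta across samples, then pick the CpG attaining the median of
that vector. Two tie rules make this deterministic: for even-sized
candidate sets the **lower** of the two central values is used, and
exact ties go to the **smallest genomic position**. The wording of the
source method is ambiguous between per-CpG medians across samples and
per-sample medians across CpGs; we implement the former (the literal
reading) and note that the alternative would change tags only in
pathological blocks. Alternative selection methods
(`"mean-center"`, `"first"`) are available via `select_tag_cpg()`.

## Association model

For each tag-CpG and each SNP strictly closer than `cis_window`
(default 500 kb; "closer than" is read as a strict inequality),
ordinary least squares fits

$$\beta_{\text{meth}} \sim \text{intercept} + \text{dosage} +
\text{covariates},$$

with categorical covariates expanded to indicators dropping a reference
level. Complete-case analysis is applied per (CpG, SNP) pair — no
imputation. Inference on the dosage coefficient uses the t distribution
with the pair-specific residual degrees of freedom. Pairs with
monomorphic dosage after complete-case removal, or rank-deficient
designs, are skipped with an explicit reason rather than fitted.
Dosages are encoded relative to the ALT allele as read from the input;
flipping the encoding negates the slope and leaves the SE and P-value
unchanged, so the choice does not affect significance.

The genome-wide cutoff is $\alpha / (\sum_t B_t \cdot \bar m)$ where
$B_t$ counts correlation blocks per run and $\bar m$ is the rounded
mean number of candidate SNPs per tag-CpG; $\bar m$ is computed from
the current run by default and can be supplied explicitly to reproduce
published worked examples. The replication cutoff is
$\alpha / \sum_t M_t$ over discovery methQTL counts. Lead SNPs are the
minimum-P record per CpG with ties broken by smaller $|$distance$|$,
then lexicographic SNP id.

# Cross-tissue colocalization

## Test selection

CpGs qualifying for colocalization must be tag-CpGs in at least two
tissues and genome-wide significant in at least one. The comparison is
anchored at the tissue with the smallest lead P-value; one test is run
per (CpG, anchor, other-tissue) pair.

## SMR

With $z = \text{slope}/\text{se}$ in each tissue, the SMR statistic is
$T = z_a^2 z_b^2 / (z_a^2 + z_b^2)$, referred to $\chi^2_1$. It is
symmetric in the tissues and equals, to first order, the Wald statistic
of the ratio $\text{slope}_b/\text{slope}_a$ accounting for the
estimation error in the denominator. SMR P-values are BH-adjusted
jointly over **all** tests of a run.

## HEIDI

SMR cannot distinguish one pleiotropic variant from two linked
variants. HEIDI tests homogeneity of the Wald ratios
$b_i = \text{slope}_{b,i}/\text{slope}_{a,i}$ across instrument SNPs:
under pleiotropy every $b_i$ estimates the same quantity, so
$d_i = b_i - b_{\text{lead}}$ has mean zero; linkage induces
heterogeneity. The statistic is $\sum_i z_{d_i}^2$ over the
instruments; its null distribution is a weighted sum of correlated
1-df chi-squares, evaluated from the eigenvalues of the correlation
matrix of the $d_i$ by Imhof's numerical inversion of the
characteristic function, with a Satterthwaite two-moment scaled
chi-square as fallback if the integration fails.

Instrument rules (standard HEIDI practice; the source only names the
test): cis SNPs with anchor $z^2 \ge$ `instrument_z2_min` (default 10,
roughly $P < 1.6\times10^{-3}$), excluding SNPs with $r^2 > 0.9$ with
the lead, capped at `heidi_max_snps` (20) by descending $z^2$; at least
`heidi_min_snps` (3) are required, otherwise HEIDI is skipped and the
pairwise verdict falls back to SMR alone with an explicit flag.

**Covariance model.** Generic summary-statistic HEIDI approximates the
within-tissue covariance of slope estimates at SNPs $i,j$ by
$r_{ij}\,\text{se}_i\,\text{se}_j$. That approximation is derived for
the GWAS regime where each SNP explains a negligible trait-variance
fraction. Cis methQTL instruments are strong (tens of percent of
variance), and there the heuristic misattributes the genotype-sampling
component of the variance: the marginal SE at a proxy SNP contains the
causal signal left in the residuals, which is *shared* across proxies
rather than independent. Empirically (see the acceptance script) the
heuristic inflates the null rejection rate several-fold. When dosage
standard deviations and per-tissue sample sizes are available — always
the case inside this package's pipeline — `heidi_test()` instead
derives the covariance **under HEIDI's own null** (a single causal
variant, proxied by the lead SNP $c$): writing the marginal slope at
SNP $j$ as $\hat\beta_j = \hat\gamma_j \beta + e_j$ with
$\hat\gamma_j$ the in-sample regression coefficient of $g_c$ on $g_j$,

$$\mathrm{Cov}(\hat\beta_i, \hat\beta_j) =
\beta^2\,\mathrm{Cov}(\hat\gamma_i, \hat\gamma_j) +
\frac{\sigma^2 r_{ij}}{n\,s_i s_j},$$

where $\mathrm{Cov}(\hat\gamma_i,\hat\gamma_j)$ follows from Gaussian
fourth moments of the LD structure,
$\sigma^2$ comes from the lead SNP's standard error, and $s_j$ are
reference-panel dosage SDs. The heuristic remains the documented
fallback for pure summary-statistic input. The LD reference is the
study's own genotypes pooled across tissues (cohorts of this design
genotype all donors jointly), which also halves LD sampling noise
relative to a single tissue.

## Classification

A pairwise comparison is *shared* iff SMR FDR < 0.05 **and** HEIDI
P > `heidi_p_cutoff` (default 0.05; 0.001 is the common stricter
alternative). Per CpG:

* **shared** — shared in all its pairwise comparisons;
* **common** — shared, and methQTL P below the genome-wide cutoff in
  every tissue where the CpG is a tag (so common ⊂ shared by
  construction);
* **tissue-specific** — shared in none (attributed to the anchor
  tissue);
* **partially-shared** — shared in some but not all comparisons. The
  canonical three classes do not cover this case; a fourth label keeps
  the classification total rather than silently dropping such CpGs.

The source's description of tissue specificity ("fail the SMR test, or
pass the SMR test but also pass the HEIDI test") inverts the HEIDI
polarity used in its own shared definition; we resolve the conflict as
*HEIDI P ≤ cutoff ⇒ not shared*, consistent with the shared rule.

# Quality control

Genotype QC applies, in order: (1) drop samples with > 5 % missing
calls; (2) drop SNPs failing the Hardy–Weinberg exact test at
P < 0.001, with > 10 % missingness, or MAF < 5 % (plus optional sex
chromosomes). The HWE test is the standard exact test (not mid-p),
summing the probabilities of all heterozygote configurations no more
probable than the observed one; sample-level filtering precedes
SNP-level filtering because the source lists it as its own step, and
the combined filter is idempotent. The filter order within the SNP
rules is immaterial because the rules are applied jointly to the
post-sample-filter matrix.

# Enrichment

Annotation enrichment builds the 2×2 table of (in query?, overlaps
annotation?) over a background that must contain the query (default:
all tested methQTL positions), with closed-interval overlap (a position
equal to an interval endpoint overlaps). The odds ratio is
$(ad)/(bc)$ with the 0.5 Haldane correction when any cell is zero; the
P-value is the one-sided (enrichment) Fisher exact probability, i.e.
the upper hypergeometric tail. Promoters are defined strand-aware as
1.5 kb upstream to 0.5 kb downstream of the TSS. BED input is 0-based
half-open and converted to 1-based inclusive on load; all internal
coordinates are 1-based inclusive (VCF convention), which avoids
off-by-one errors in the 500 kb window.

# The synthetic-data generator

`sim_config()` describes a stated world; everything downstream is a
pure function of (config, seed). Defaults: 200 samples per tissue,
2000 SNPs on a 10 Mb chromosome with allele frequencies uniform on
[0.05, 0.5] and Binomial(2, p) dosages (exact HWE in expectation), 50
blocks of 10 CpGs spanning 2 kb each with within-block target
correlation 0.8, measurement noise SD 0.05 for uncorrelated blocks.

Key constructions and why:

* **Block methylation** is a shared logit-normal latent
  $L = \mathrm{plogis}(\mathcal{N}(\mathrm{logit}(\mu_b), 0.35))$ with
  $\mu_b \sim U(0.25, 0.65)$, plus per-CpG noise. The noise SD is the
  closed-form variance ratio $\mathrm{sd}(L)\sqrt{(1-\rho)/\rho}$, so
  the realized within-block correlation approximates the target $\rho$
  without iterative tuning.
* **Injected effects** add $\text{slope}\times\text{dosage}$ to the
  block latent before clipping to [0, 1] — effects act on the beta
  scale because the association model regresses beta directly.
* **Per-CpG baselines** form an evenly spaced ladder (spacing 0.03
  beta units, ranks shuffled once per configuration and shared across
  tissues). Real CpGs have stable, distinct mean methylation; the
  ladder additionally makes the medoid tag-CpG reproducible across
  tissues, which the cross-tissue test selection requires. Gaussian
  baseline draws were tried first and rejected: whenever two CpG
  medians landed within the median's sampling noise, the tag flipped
  between tissues and the CpG silently dropped out of colocalization.
* **LD proxies**: each effect SNP receives a bank of proxies simulated
  haplotype-wise at fixed correlations (defaults 0.85…0.6), giving the
  HEIDI instrument set; `linkage` effects drive the second tissue from
  the first proxy at `linkage_ld` (default 0.7).
* **Multi-tissue designs** draw one SNP panel (frequencies, positions,
  alleles) from the seed and independent samples per tissue, with a
  ground-truth table (`shared` / `specific` / `linkage` per effect).

What the generator does **not** emulate: realistic recombination-map
LD structure (proxies are conditionally independent given their causal
SNP), array probe biases and batch effects, cell-type composition
heterogeneity, trans effects, and non-additive genotype effects. A
green end-to-end test therefore establishes that the pipeline recovers
effects under its own model assumptions — not that those assumptions
hold for any particular cohort.

# Numerical choices

* P-values are floored at `.Machine$double.xmin` so they remain in
  (0, 1].
* OLS uses a QR decomposition (`qr()`/`chol2inv`) rather than forming
  normal equations; the test suite checks it against an independent
  normal-equations oracle at 1e-10 and `stats::lm` agreement.
* The HWE tail sum uses a relative tolerance of 1e-12 when comparing
  configuration probabilities, guarding ties against floating-point
  loss; the enumeration oracle applies the same convention.
* Imhof integration uses `stats::integrate` with `rel.tol = 1e-8`;
  eigenvalues below 1e-10 are dropped; instruments with non-positive
  delta-method variance (possible with noisy estimated LD) are dropped,
  and the test is skipped if fewer than `heidi_min_snps` remain.
* Louvain is stochastic; each chunk's pass is seeded from
  `clustering_seed` plus a chunk counter, making runs reproducible and
  chunks independent.
* BH adjustment is the literal step-up construction (cummin from the
  largest rank), verified against `stats::p.adjust`.

# Known limitations

* Correlation blocks cannot span the hard chunk boundary; with the
  default 40,000-CpG chunks this affects at most a handful of blocks
  per chromosome on array-scale data.
* The model-based HEIDI covariance assumes the lead SNP proxies the
  causal variant well; with a badly tagged causal variant the test
  inherits the usual HEIDI behaviour. In the strong-instrument,
  n = 200 regime its null rejection at 0.05 is close to, but still
  slightly above, nominal (quantified each run by
  `scripts/acceptance.R`).
* Trans associations (beyond 500 kb) and permutation-based empirical
  P-values are out of scope.
* VCF input uses the GT field only; dosage likelihoods (DS/GP) are not
  read, and multi-allelic records are skipped with a warning rather
  than decomposed.
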