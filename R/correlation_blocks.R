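#' Correlation-block calling parameters
#'
#' Defaults are the values evaluated for Illumina EPIC/450k-scale data:
#' pairwise Pearson correlations below 0.2 are zeroed (including all
#' negative correlations), similarities are weighted by a Gaussian of the
#' genomic distance with standard deviation 3000 bp, pairs further apart
#' than 500 kb get similarity zero, and chromosomes are split into chunks
#' of at most 40,000 CpGs to bound the correlation-matrix size.
#'
#' @param cluster_cor_threshold minimum Pearson correlation kept.
#' @param gauss_sd standard deviation (bp) of the Gaussian distance weight.
#' @param absolute_distance_cutoff distance (bp) beyond which similarity
#'   is zero.
#' @param max_cpgs_per_chunk maximum CpGs per per-chromosome chunk.
#' @param clustering_seed RNG seed for Louvain community detection.
#' @param louvain_resolution Louvain resolution parameter.
#' @return An object of class `BlockParams`.
#' @export
block_params <- function(cluster_cor_threshold = 0.2, gauss_sd = 3000,
                         absolute_distance_cutoff = 500000,
                         max_cpgs_per_chunk = 40000,
                         clustering_seed = 1L, louvain_resolution = 1) {
  if (gauss_sd <= 0) stopf("gauss_sd must be positive")
  if (absolute_distance_cutoff <= 0)
    stopf("absolute_distance_cutoff must be positive")
  if (max_cpgs_per_chunk < 2) stopf("max_cpgs_per_chunk must be >= 2")
  if (louvain_resolution <= 0) stopf("louvain_resolution must be positive")
  structure(list(cluster_cor_threshold = cluster_cor_threshold,
                 gauss_sd = gauss_sd,
                 absolute_distance_cutoff = absolute_distance_cutoff,
                 max_cpgs_per_chunk = max_cpgs_per_chunk,
                 clustering_seed = as.integer(clustering_seed),
                 louvain_resolution = louvain_resolution),
            class = "BlockParams")
}

#' Split per-chromosome CpG indices into equally sized contiguous chunks
#'
#' Each chromosome's `n` CpGs are split into `ceiling(n / max)` contiguous
#' groups whose sizes differ by at most one, preserving positional order.
#'
#' @param positions_per_chrom named list of sorted position vectors (one
#'   per chromosome), or a single numeric vector.
#' @param max_cpgs_per_chunk maximum chunk size.
#' @return named list (per chromosome) of lists of index vectors into that
#'   chromosome's CpGs.
#' @export
chunk_cpgs <- function(positions_per_chrom, max_cpgs_per_chunk) {
  if (!is.list(positions_per_chrom))
    positions_per_chrom <- list(chr = positions_per_chrom)
  lapply(positions_per_chrom, function(pos) {
    n <- length(pos)
    if (n == 0L) return(list())
    k <- ceiling(n / max_cpgs_per_chunk)
    base <- n %/% k
    sizes <- rep(base, k)
    extra <- n %% k
    if (extra > 0L) sizes[seq_len(extra)] <- base + 1L
    ends <- cumsum(sizes)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    Map(function(s, e) seq.int(s, e), starts, ends)
  })
}

#' Distance-weighted pairwise CpG similarity
#'
#' For CpGs i, j in one chunk, `s_ij = r_ij * exp(-d_ij^2 / (2 sd^2))`
#' where `r_ij` is the Pearson correlation of their beta values across
#' samples (pairwise-complete) and `d_ij = |pos_i - pos_j|`. The
#' similarity is zero whenever `r_ij < cluster_cor_threshold` (negative
#' correlations included), `d_ij > absolute_distance_cutoff`, fewer than
#' three samples are jointly observed, or a CpG has zero variance. The
#' diagonal is zero.
#'
#' @param beta_chunk CpG-by-sample matrix of beta values.
#' @param positions positions of the chunk's CpGs.
#' @param params a [block_params()] object.
#' @param weight_mask optional matrix of multiplicative weights (same
#'   dimension), the hook for annotation-driven similarity re-weighting.
#' @return symmetric similarity matrix with zero diagonal, entries in
#'   \[0, 1\].
#' @export
pairwise_similarity <- function(beta_chunk, positions,
                                params = block_params(),
                                weight_mask = NULL) {
  beta_chunk <- as.matrix(beta_chunk)
  n <- nrow(beta_chunk)
  obs <- !is.na(beta_chunk)
  constant <- apply(beta_chunk, 1L, function(x)
    stats::var(x, na.rm = TRUE)) %in% c(0, NA)
  if (any(constant))
    cmq_log(sprintf("%d constant/empty CpG(s) in chunk: similarity zeroed",
                    sum(constant)))
  r <- suppressWarnings(stats::cor(t(beta_chunk),
                                   use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0
  r[constant, ] <- 0
  r[, constant] <- 0
  shared <- tcrossprod(obs * 1)        # samples jointly observed per pair
  r[shared < 3L] <- 0
  d <- abs(outer(positions, positions, "-"))
  s <- r * exp(-d^2 / (2 * params$gauss_sd^2))
  s[r < params$cluster_cor_threshold] <- 0
  s[d > params$absolute_distance_cutoff] <- 0
  if (!is.null(weight_mask)) s <- s * weight_mask
  diag(s) <- 0
  s
}

#' Call CpG correlation blocks
#'
#' Four-step procedure per chromosome chunk: (1) pairwise Pearson
#' correlation of CpG methylation, thresholded at
#' `cluster_cor_threshold`; (2) Gaussian distance weighting with hard
#' zeroing beyond `absolute_distance_cutoff`; (3) construction of the
#' weighted graph; (4) Louvain community detection. Every CpG, including
#' isolated ones, belongs to exactly one block; singleton communities
#' become single-CpG blocks. Blocks never span a chunk boundary.
#'
#' @param mm a [methylation_matrix()].
#' @param params a [block_params()] object.
#' @return data.frame of class `cpg_blocks` with one row per CpG:
#'   `block_id`, `chrom`, `cpg_id`, `pos`, ordered by block then position.
#' @export
call_blocks <- function(mm, params = block_params()) {
  stopifnot(inherits(mm, "MethylationMatrix"))
  chroms <- unique(mm$chrom)
  res <- list()
  block_counter <- 0L
  for (ch in chroms) {
    idx <- which(mm$chrom == ch)
    chunks <- chunk_cpgs(list(mm$pos[idx]), params$max_cpgs_per_chunk)[[1L]]
    for (ci in seq_along(chunks)) {
      rows <- idx[chunks[[ci]]]
      s <- pairwise_similarity(mm$beta[rows, , drop = FALSE],
                               mm$pos[rows], params)
      g <- igraph::graph_from_adjacency_matrix(s, mode = "undirected",
                                               weighted = TRUE)
      # Louvain is stochastic; seed derived from the configured seed plus
      # the chunk counter keeps runs reproducible and chunks independent
      set.seed(params$clustering_seed + length(res))
      comm <- igraph::cluster_louvain(g, resolution = params$louvain_resolution)
      memb <- igraph::membership(comm)
      res[[length(res) + 1L]] <- data.frame(
        block_id = sprintf("block_%06d", block_counter + as.integer(memb)),
        chrom = ch,
        cpg_id = rownames(mm$beta)[rows],
        pos = mm$pos[rows],
        stringsAsFactors = FALSE)
      block_counter <- block_counter + max(as.integer(memb))
    }
  }
  out <- do.call(rbind, res)
  out <- out[order(out$block_id, out$pos), ]
  rownames(out) <- NULL
  class(out) <- c("cpg_blocks", "data.frame")
  cmq_log(sprintf("called %d correlation blocks over %d CpGs",
                  length(unique(out$block_id)), nrow(out)))
  out
}

#' Summarise blocks (one row per block)
#'
#' @param blocks a `cpg_blocks` table from [call_blocks()].
#' @return data.frame with `block_id`, `chrom`, `start`, `end`, `n_cpgs`.
#' @export
block_summary <- function(blocks) {
  dt <- data.table::as.data.table(blocks)
  out <- dt[, list(chrom = chrom[1L], start = min(pos), end = max(pos),
                   n_cpgs = .N), by = "block_id"]
  as.data.frame(out)
}

#' Write blocks as BED (0-based start) plus the membership table
#'
#' @param blocks a `cpg_blocks` table with a `tag_cpg` attribute optional.
#' @param bed_path,membership_path output paths.
#' @param tags optional named vector mapping block_id to tag CpG id.
#' @return invisibly, the bed path.
#' @export
write_blocks <- function(blocks, bed_path, membership_path, tags = NULL) {
  summ <- block_summary(blocks)
  bed <- data.frame(chrom = summ$chrom, start = summ$start - 1L,
                    end = summ$end, name = summ$block_id,
                    score = summ$n_cpgs,
                    tag = if (is.null(tags)) "." else
                      unname(tags[summ$block_id]),
                    stringsAsFactors = FALSE)
  data.table::fwrite(bed, bed_path, sep = "\t", col.names = FALSE,
                     quote = FALSE)
  data.table::fwrite(as.data.frame(blocks), membership_path, sep = "\t",
                     quote = FALSE)
  invisible(bed_path)
}
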