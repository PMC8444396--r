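#' Pipeline run configuration
#'
#' @param out_dir output directory (created if absent).
#' @param tissues named list, one entry per tissue: a list with elements
#'   `meth` (path), `geno` (path), and optional `meth_format`
#'   (default "matrix-tsv") and `geno_format` (default "dosage-tsv").
#' @param covariates optional covariate TSV path (first column
#'   `sample_id`), applied to every tissue by sample-id match.
#' @param cpg_mask optional path to a file of CpG ids to drop (one per
#'   line).
#' @param qc,blocks,assoc,coloc parameter objects ([qc_params()],
#'   [block_params()], [assoc_params()], [coloc_params()]).
#' @param do_coloc run the colocalization/classification stage (needs at
#'   least two tissues).
#' @param annotations optional named character vector of BED paths for
#'   the enrichment stage.
#' @param cutoff `"auto"` (compute the genome-wide cutoff from this run)
#'   or a numeric P-value cutoff.
#' @param seed integer seed controlling every stochastic step.
#' @return An object of class `RunConfig`.
#' @export
run_config <- function(out_dir, tissues, covariates = NULL,
                       cpg_mask = NULL, qc = qc_params(),
                       blocks = block_params(), assoc = assoc_params(),
                       coloc = coloc_params(), do_coloc = length(tissues) >= 2,
                       annotations = NULL, cutoff = "auto", seed = 1L) {
  stopifnot(length(tissues) >= 1L)
  if (is.null(names(tissues)))
    names(tissues) <- sprintf("tissue%d", seq_along(tissues))
  for (t in tissues)
    for (f in c(t$meth, t$geno))
      if (!file.exists(f)) stopf("input file not found: %s", f)
  structure(list(out_dir = out_dir, tissues = tissues,
                 covariates = covariates, cpg_mask = cpg_mask,
                 qc = qc, blocks = blocks, assoc = assoc, coloc = coloc,
                 do_coloc = isTRUE(do_coloc), annotations = annotations,
                 cutoff = cutoff, seed = as.integer(seed)),
            class = "RunConfig")
}

#' Run the full methQTL pipeline
#'
#' Two-stage workflow per tissue — correlation-block calling on the
#' QC-filtered methylation matrix, then tag-CpG association against all
#' cis SNPs — followed by the genome-wide cutoff, lead-SNP selection
#' and, with two or more tissues, SMR + HEIDI colocalization and the
#' common/shared/tissue-specific classification. Every intermediate
#' table and a JSON manifest (parameters, versions, seed, per-stage
#' counts) are written to `out_dir`; a rerun with the same configuration
#' reproduces identical outputs.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "comethQTL",
                   version = as.character(utils::packageVersion("comethQTL")),
                   r_version = R.version.string,
                   seed = config$seed,
                   parameters = list(qc = unclass(config$qc),
                                     blocks = unclass(config$blocks),
                                     assoc = unclass(config$assoc),
                                     coloc = unclass(config$coloc),
                                     cutoff = config$cutoff),
                   tissues = list())
  stage <- "input"
  res <- tryCatch({
    mask <- if (is.null(config$cpg_mask)) character(0) else
      readLines(config$cpg_mask)
    covars <- if (is.null(config$covariates)) NULL else
      read_covariates(config$covariates)

    summaries <- list()
    block_counts <- integer(0)
    mean_cand <- numeric(0)
    per_tissue <- list()
    for (tn in names(config$tissues)) {
      tconf <- config$tissues[[tn]]
      stage <- paste0("read:", tn)
      mm <- read_methylation(tconf$meth,
                             format = tconf$meth_format %||% "matrix-tsv")
      gm <- read_genotypes(tconf$geno,
                           format = tconf$geno_format %||% "dosage-tsv")
      stage <- paste0("qc:", tn)
      qc <- filter_genotypes(gm, config$qc)
      mm <- filter_cpgs(mm, mask, config$qc)
      stage <- paste0("blocks:", tn)
      bp <- config$blocks
      bp$clustering_seed <- config$seed
      blocks <- call_blocks(mm, bp)
      write_blocks(blocks,
                   file.path(config$out_dir, paste0(tn, "_blocks.bed")),
                   file.path(config$out_dir, paste0(tn, "_block_members.tsv")))
      stage <- paste0("call:", tn)
      recs <- call_methqtls(mm, qc$genotypes, covars, blocks, config$assoc)
      write_methqtl_table(recs,
                          file.path(config$out_dir, paste0(tn, "_methqtl_all.tsv")))
      block_counts[tn] <- attr(recs, "n_blocks")
      mean_cand[tn] <- attr(recs, "mean_snps_per_cpg")
      per_tissue[[tn]] <- list(records = recs, genotypes = qc$genotypes)
      manifest$tissues[[tn]] <- list(
        n_cpgs = nrow(mm$beta), n_snps = nrow(qc$genotypes$dosage),
        qc = qc$report[c("n_samples_removed", "n_snps_removed")],
        n_blocks = attr(recs, "n_blocks"),
        mean_snps_per_cpg = attr(recs, "mean_snps_per_cpg"),
        n_associations = nrow(recs))
    }

    stage <- "cutoff"
    cutoff <- if (identical(config$cutoff, "auto"))
      genome_wide_cutoff(block_counts, round(mean(mean_cand)),
                         config$assoc$alpha)
    else as.numeric(config$cutoff)
    manifest$cutoff <- cutoff

    for (tn in names(per_tissue)) {
      recs <- per_tissue[[tn]]$records
      sig <- recs[recs$p_value < cutoff, ]
      write_methqtl_table(sig,
                          file.path(config$out_dir, paste0(tn, "_methqtl_significant.tsv")))
      lead <- if (nrow(recs)) select_lead_snps(recs) else recs
      write_methqtl_table(lead,
                          file.path(config$out_dir, paste0(tn, "_lead_snps.tsv")))
      manifest$tissues[[tn]]$n_significant <- nrow(sig)
      summaries[[tn]] <- tissue_summary(tn, recs)
    }

    if (config$do_coloc && length(config$tissues) >= 2L) {
      stage <- "coloc"
      tests <- select_coloc_tests(summaries, cutoff)
      # LD reference: the QC-filtered genotypes pooled over all tissues
      # (the study's own donors stand in for an external reference panel)
      ld_ref <- pool_genotypes(lapply(per_tissue, `[[`, "genotypes"))
      coloc <- run_coloc(summaries, tests, ld_ref, config$coloc)
      data.table::fwrite(as.data.frame(coloc),
                         file.path(config$out_dir, "coloc_results.tsv"),
                         sep = "\t", na = "NA", quote = FALSE)
      stage <- "classify"
      tp <- do.call(rbind, lapply(summaries, function(s)
        data.frame(cpg_id = s$lead$cpg_id, tissue = s$tissue,
                   p_value = s$lead$p_value, stringsAsFactors = FALSE)))
      classes <- classify_methqtls(coloc, tp, config$coloc, cutoff)
      data.table::fwrite(classes,
                         file.path(config$out_dir, "methqtl_classes.tsv"),
                         sep = "\t", na = "NA", quote = FALSE)
      manifest$n_coloc_tests <- nrow(coloc)
      manifest$classes <- as.list(table(classes$label))
    }

    if (!is.null(config$annotations)) {
      stage <- "enrich"
      enr <- list()
      all_snps <- unique(do.call(rbind, lapply(per_tissue, function(x)
        x$records[, c("chrom", "snp_pos")])))
      names(all_snps) <- c("chrom", "pos")
      sig_snps <- unique(do.call(rbind, lapply(per_tissue, function(x) {
        r <- x$records[x$records$p_value < cutoff, c("chrom", "snp_pos")]
        names(r) <- c("chrom", "pos"); r
      })))
      for (an in names(config$annotations)) {
        gr <- read_annotations(config$annotations[[an]], an)
        e <- overlap_enrichment(sig_snps, gr, all_snps)
        enr[[an]] <- data.frame(annotation = an,
                                odds_ratio = e$odds_ratio,
                                p_one_sided = e$p_one_sided,
                                stringsAsFactors = FALSE)
      }
      enr <- do.call(rbind, enr)
      data.table::fwrite(enr, file.path(config$out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE)
      manifest$enrichment = nrow(enr)
    }
    manifest
  }, error = function(e) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  jsonlite::write_json(res, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(res)
}

#' Write a simulated single- or multi-tissue data set to disk
#'
#' Produces the standard pipeline input formats (methylation matrix-tsv,
#' genotype dosage-tsv per tissue) plus a ground-truth effect table.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory.
#' @return named list of per-tissue file paths plus the truth table
#'   path, invisibly.
#' @export
write_simulation <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  if (cfg$n_tissues >= 2L) {
    sim <- simulate_multitissue(cfg)
    for (tn in names(sim$tissues)) {
      mp <- file.path(out_dir, paste0(tn, "_meth.tsv"))
      gp <- file.path(out_dir, paste0(tn, "_geno.tsv"))
      write_methylation(sim$tissues[[tn]]$meth, mp)
      write_genotypes(sim$tissues[[tn]]$geno, gp)
      paths[[tn]] <- list(meth = mp, geno = gp)
    }
    tp <- file.path(out_dir, "truth.tsv")
    data.table::fwrite(sim$truth, tp, sep = "\t", na = "NA", quote = FALSE)
    paths$truth <- tp
  } else {
    gm <- simulate_genotypes(cfg)
    mm <- simulate_methylation(cfg, gm)
    mp <- file.path(out_dir, "tissue1_meth.tsv")
    gp <- file.path(out_dir, "tissue1_geno.tsv")
    write_methylation(mm, mp)
    write_genotypes(gm, gp)
    paths$tissue1 <- list(meth = mp, geno = gp)
  }
  invisible(paths)
}
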