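#' Read an annotation BED file as 1-based inclusive intervals
#'
#' BED input (0-based half-open) is converted to 1-based inclusive
#' coordinates on load; chromosome names are normalized by stripping a
#' leading "chr".
#'
#' @param path BED file path.
#' @param name annotation-set label (default: file basename).
#' @return a `GRanges` with a `name` attribute (class `AnnotationSet`).
#' @export
read_annotations <- function(path, name = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomeInfoDb::seqlevels(gr) <- normalize_chrom(GenomeInfoDb::seqlevels(gr))
  attr(gr, "name") <- name %||% sub("\\.bed$", "", basename(path))
  gr
}

#' Promoter interval around a transcription start site
#'
#' 1.5 kb upstream and 0.5 kb downstream of the TSS, strand-aware:
#' on the + strand `[tss - 1500, tss + 500]`, on the - strand
#' `[tss - 500, tss + 1500]`. Coordinates below 1 are clipped to 1 with a
#' warning. Every unclipped interval has length 2001 bp.
#'
#' @param tss_pos TSS positions (1-based).
#' @param strand "+" or "-" per TSS.
#' @return data.frame with columns `start`, `end` (1-based inclusive).
#' @export
promoter_regions <- function(tss_pos, strand) {
  if (!all(strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  up <- ifelse(strand == "+", 1500L, 500L)
  down <- ifelse(strand == "+", 500L, 1500L)
  start <- tss_pos - up
  end <- tss_pos + down
  if (any(start < 1L)) {
    warnf("%d promoter interval(s) clipped at position 1", sum(start < 1L))
    start <- pmax(start, 1L)
  }
  data.frame(start = as.integer(start), end = as.integer(end))
}

positions_to_granges <- function(positions) {
  if (methods::is(positions, "GRanges")) return(positions)
  positions <- as.data.frame(positions)
  stopifnot(all(c("chrom", "pos") %in% names(positions)))
  GenomicRanges::GRanges(normalize_chrom(positions$chrom),
                         IRanges::IRanges(positions$pos, positions$pos))
}

#' Annotation-overlap enrichment with a one-sided Fisher exact test
#'
#' Builds the 2x2 table of (in query?, overlaps annotation?) over the
#' background positions (the query must be a subset of the background;
#' the non-query margin is background minus query). Overlap uses closed
#' intervals: a position equal to an interval endpoint overlaps. The
#' odds ratio is `(a d)/(b c)` with the 0.5 Haldane correction applied
#' to all cells when any cell is zero; the P-value is the one-sided
#' (enrichment, "greater") Fisher exact probability, i.e. the upper
#' hypergeometric tail.
#'
#' @param query_positions data.frame with `chrom`, `pos` (or a `GRanges`):
#'   the positions of interest (e.g. tissue-specific methQTL SNPs).
#' @param annotation an annotation `GRanges` (see [read_annotations()]).
#' @param background_positions all tested positions (superset of query).
#' @return list with `odds_ratio`, `p_one_sided` and `table` (the 2x2
#'   integer matrix).
#' @export
overlap_enrichment <- function(query_positions, annotation,
                               background_positions) {
  q <- positions_to_granges(query_positions)
  bg <- positions_to_granges(background_positions)
  if (length(q) == 0L) stopf("empty query")
  key <- function(gr) paste0(as.character(GenomicRanges::seqnames(gr)), ":",
                             GenomicRanges::start(gr))
  if (!all(key(q) %in% key(bg)))
    stopf("query positions must be a subset of the background")
  in_q <- key(bg) %in% key(q)
  hits <- GenomicRanges::countOverlaps(bg, annotation,
                                       type = "any") > 0L
  a <- sum(in_q & hits); b <- sum(in_q & !hits)
  c_ <- sum(!in_q & hits); d <- sum(!in_q & !hits)
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("query", "non-query"),
                                c("overlap", "no-overlap")))
  if (any(tab == 0)) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    or <- (a * d) / (b * c_)
  }
  # one-sided Fisher (greater) = upper hypergeometric tail at a
  p <- stats::phyper(a - 1L, m = a + c_, n = b + d, k = a + b,
                     lower.tail = FALSE)
  list(odds_ratio = or, p_one_sided = min(max(p, 0), 1), table = tab)
}
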