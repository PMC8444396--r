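`%||%` <- function(x, y) if (is.null(x)) y else x

# non-attaching data.table usage (NSE in [.data.table)
.datatable.aware <- TRUE

#' @keywords internal
cmq_log <- function(..., level = "INFO") {
  msg <- sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                 paste0(..., collapse = ""))
  message(msg)
  invisible(msg)
}

# Chromosome names are normalized by stripping a leading "chr" so that
# mixed-source inputs (UCSC-style vs Ensembl-style) interoperate.
normalize_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom), ignore.case = TRUE)
}

is_sex_chrom <- function(chrom) {
  toupper(normalize_chrom(chrom)) %in% c("X", "Y", "23", "24")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
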