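# Variant records: genomic intervals with a variant class, BED6 I/O.
# 0-based half-open internally, matching BED on disk.

variant_classes <- function() c("SNV", "Indel", "CNV")

#' Construct a variant table
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open; SNVs have `end == start + 1`) and `class` (one of `SNV`,
#'   `Indel`, `CNV`).
#' @return validated data.frame of class `variant_set`.
#' @export
new_variants <- function(df) {
  req <- c("chrom", "start", "end", "class")
  if (!all(req %in% names(df))) {
    stop("variants need columns: ", paste(req, collapse = ", "))
  }
  if (nrow(df) > 0) {
    if (any(df$start >= df$end)) stop("variant intervals must satisfy start < end")
    if (any(!df$class %in% variant_classes())) {
      stop("variant class must be one of: ", paste(variant_classes(), collapse = ", "))
    }
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  class(df) <- c("variant_set", "data.frame")
  df
}

#' Write variants as BED6
#'
#' Columns: chrom, start, end, name (= variant class), score 0, strand ".".
#'
#' @param variants a `variant_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t.",
                   variants$chrom, variants$start, variants$end, variants$class)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED variant file
#'
#' Uses `rtracklayer::import()` (BED); the BED name column is taken as the
#' variant class.
#'
#' @param path BED file path.
#' @return a `variant_set`.
#' @export
read_variants <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  new_variants(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    class = as.character(S4Vectors::mcols(gr)$name),
    stringsAsFactors = FALSE))
}

variant_granges <- function(variants) {
  GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(start = variants$start + 1L, end = variants$end))
}
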