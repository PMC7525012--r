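# Gene annotation container and GTF input/output.
#
# Coordinates are 0-based half-open internally (BED convention). GTF's
# 1-based closed coordinates are converted at the parse/write boundary.

#' lncRNA subclasses recognized by the pipeline
#'
#' The five Ensembl gene biotypes treated as lncRNA subclasses, plus
#' `protein_coding` for the coding complement.
#'
#' @return character vector of the five lncRNA biotype tokens.
#' @export
lncRNA_types <- function() {
  c("antisense", "bidirectional_promoter_lncRNA", "lincRNA",
    "non_coding", "sense_intronic")
}

all_gene_types <- function() c(lncRNA_types(), "protein_coding", "other")

#' Construct a gene annotation object
#'
#' @param genes data.frame with columns `gene_id`, `gene_type`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand` (`+`/`-`).
#' @param exons data.frame with columns `gene_id`, `chrom`, `start`, `end`;
#'   every exon must lie within its gene's span.
#' @return an object of class `lnc_annotation`: a list with elements
#'   `genes` and `exons`.
#' @export
new_annotation <- function(genes, exons) {
  req_g <- c("gene_id", "gene_type", "chrom", "start", "end", "strand")
  req_e <- c("gene_id", "chrom", "start", "end")
  if (!all(req_g %in% names(genes))) {
    stop("genes must have columns: ", paste(req_g, collapse = ", "))
  }
  if (!all(req_e %in% names(exons))) {
    stop("exons must have columns: ", paste(req_e, collapse = ", "))
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene ids in annotation: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  if (any(!genes$gene_type %in% all_gene_types())) {
    stop("unknown gene_type values: ",
         paste(setdiff(unique(genes$gene_type), all_gene_types()), collapse = ", "))
  }
  if (any(genes$start >= genes$end)) stop("gene intervals must satisfy start < end")
  if (any(exons$start >= exons$end)) stop("exon intervals must satisfy start < end")
  if (any(!exons$gene_id %in% genes$gene_id)) {
    stop("exons reference unknown gene ids")
  }
  gidx <- match(exons$gene_id, genes$gene_id)
  if (any(exons$start < genes$start[gidx] | exons$end > genes$end[gidx])) {
    stop("every exon must lie within its gene's span")
  }
  if (any(!genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  genes_with_exons <- unique(exons$gene_id)
  if (any(!genes$gene_id %in% genes_with_exons)) {
    stop("every gene needs at least one exon; missing for: ",
         paste(utils::head(setdiff(genes$gene_id, genes_with_exons), 5), collapse = ", "))
  }
  structure(list(genes = as.data.frame(genes, stringsAsFactors = FALSE),
                 exons = as.data.frame(exons, stringsAsFactors = FALSE)),
            class = "lnc_annotation")
}

#' @export
print.lnc_annotation <- function(x, ...) {
  n_lnc <- sum(x$genes$gene_type %in% lncRNA_types())
  cat("lnc_annotation:", nrow(x$genes), "genes (", n_lnc, "lncRNA,",
      sum(x$genes$gene_type == "protein_coding"), "protein-coding ),",
      nrow(x$exons), "exons on",
      length(unique(x$genes$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Which genes of an annotation are lncRNAs
#'
#' @param annotation an `lnc_annotation`.
#' @return character vector of lncRNA gene ids, in annotation order.
#' @export
lncRNA_ids <- function(annotation) {
  annotation$genes$gene_id[annotation$genes$gene_type %in% lncRNA_types()]
}

#' Protein-coding gene ids of an annotation
#' @param annotation an `lnc_annotation`.
#' @return character vector of protein-coding gene ids, in annotation order.
#' @export
coding_ids <- function(annotation) {
  annotation$genes$gene_id[annotation$genes$gene_type == "protein_coding"]
}

# GRanges view of gene bodies (1-based closed, as GenomicRanges expects).
gene_granges <- function(annotation, ids = NULL) {
  g <- annotation$genes
  if (!is.null(ids)) g <- g[match(ids, g$gene_id), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand)
  names(gr) <- g$gene_id
  gr
}

exon_granges <- function(annotation, ids = NULL) {
  e <- annotation$exons
  if (!is.null(ids)) e <- e[e$gene_id %in% ids, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = e$chrom,
    ranges = IRanges::IRanges(start = e$start + 1L, end = e$end))
  names(gr) <- e$gene_id
  gr
}

# Strand-aware promoter intervals: `width` bp upstream of the transcription
# start (5' end), clipped at position 0. 0-based half-open coordinates.
promoter_intervals <- function(annotation, ids = NULL, width = 5000) {
  g <- annotation$genes
  if (!is.null(ids)) g <- g[match(ids, g$gene_id), , drop = FALSE]
  plus <- g$strand == "+"
  start <- ifelse(plus, pmax(0, g$start - width), g$end)
  end <- ifelse(plus, g$start, g$end + width)
  data.frame(gene_id = g$gene_id, chrom = g$chrom,
             start = start, end = end, stringsAsFactors = FALSE)
}

promoter_granges <- function(annotation, ids = NULL, width = 5000) {
  p <- promoter_intervals(annotation, ids, width)
  p <- p[p$start < p$end, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = p$chrom,
    ranges = IRanges::IRanges(start = p$start + 1L, end = p$end))
  names(gr) <- p$gene_id
  gr
}

#' Write an annotation as an Ensembl-dialect GTF file
#'
#' Emits one `gene` feature per gene and one `exon` feature per exon, with
#' `gene_id` and `gene_biotype` attributes (exons also carry a
#' `transcript_id`). Coordinates are converted to GTF's 1-based closed
#' convention.
#'
#' @param annotation an `lnc_annotation`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  g <- annotation$genes
  e <- annotation$exons
  gl <- sprintf(
    "%s\tlncseed\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_biotype \"%s\";",
    g$chrom, g$start + 1L, g$end, g$strand, g$gene_id, g$gene_type)
  ge <- g[match(e$gene_id, g$gene_id), , drop = FALSE]
  el <- sprintf(
    paste0("%s\tlncseed\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; ",
           "transcript_id \"%s.t1\"; gene_biotype \"%s\";"),
    e$chrom, e$start + 1L, e$end, ge$strand, e$gene_id, e$gene_id, ge$gene_type)
  # interleave: each gene followed by its exons, in gene order
  out <- unlist(lapply(seq_len(nrow(g)), function(i) {
    c(gl[i], el[e$gene_id == g$gene_id[i]])
  }))
  writeLines(out, path)
  invisible(path)
}

#' Read a GTF annotation
#'
#' Parses a GTF via `rtracklayer::import()`, expecting `gene` and `exon`
#' features with `gene_id` and `gene_biotype` attributes, and converts to
#' the internal 0-based half-open convention. Duplicate gene ids are an
#' error.
#'
#' @param path GTF file path.
#' @return an `lnc_annotation`.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if (!all(c("type", "gene_id", "gene_biotype") %in% names(md))) {
    stop("GTF must carry type, gene_id and gene_biotype")
  }
  is_gene <- as.character(md$type) == "gene"
  is_exon <- as.character(md$type) == "exon"
  genes <- data.frame(
    gene_id = as.character(md$gene_id[is_gene]),
    gene_type = as.character(md$gene_biotype[is_gene]),
    chrom = as.character(GenomicRanges::seqnames(gr[is_gene])),
    start = GenomicRanges::start(gr[is_gene]) - 1L,
    end = GenomicRanges::end(gr[is_gene]),
    strand = as.character(GenomicRanges::strand(gr[is_gene])),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = as.character(md$gene_id[is_exon]),
    chrom = as.character(GenomicRanges::seqnames(gr[is_exon])),
    start = GenomicRanges::start(gr[is_exon]) - 1L,
    end = GenomicRanges::end(gr[is_exon]),
    stringsAsFactors = FALSE)
  new_annotation(genes, exons)
}
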