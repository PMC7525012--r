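# Variant-to-lncRNA mapping: interval intersection under three annotation
# modes, CNV validation, genomic flanking neighbors, subclass distribution.

hit_modes <- function() c("gene", "exon", "gene_plus_promoter")

# Mode-specific target intervals for the given lncRNAs, as a GRanges whose
# names are gene ids (one gene may contribute several ranges).
mode_targets <- function(annotation, ids, mode, promoter_width = 5000) {
  switch(mode,
    gene = gene_granges(annotation, ids),
    exon = exon_granges(annotation, ids),
    gene_plus_promoter = {
      b <- gene_granges(annotation, ids)
      p <- promoter_granges(annotation, ids, width = promoter_width)
      out <- c(GenomicRanges::granges(b, use.names = TRUE),
               GenomicRanges::granges(p, use.names = TRUE))
      out
    },
    stop("unknown mode: ", mode))
}

#' Identify lncRNAs overlapped by genomic variants
#'
#' Returns the lncRNAs with at least 1 bp overlap between any variant and
#' the mode-specific target region: the gene body (`"gene"`), the exon
#' union (`"exon"`), or the gene body plus a strand-aware promoter of
#' `promoter_width` bp upstream of the transcription start
#' (`"gene_plus_promoter"`).
#'
#' @param variants a `variant_set` (see [new_variants()]).
#' @param annotation an `lnc_annotation`.
#' @param mode one of `"gene"`, `"exon"`, `"gene_plus_promoter"`.
#' @param promoter_width promoter length in bp (default 5000).
#' @return an object of class `lnc_hits`: list with `mode`, `ids` (hit
#'   lncRNA ids in annotation order) and `support` (named count of distinct
#'   overlapping variants per hit).
#' @export
identify_lncRNAs <- function(variants, annotation,
                             mode = c("gene", "exon", "gene_plus_promoter"),
                             promoter_width = 5000) {
  mode <- match.arg(mode)
  stopifnot(inherits(annotation, "lnc_annotation"))
  lnc <- lncRNA_ids(annotation)
  empty <- structure(list(mode = mode, ids = character(0),
                          support = stats::setNames(integer(0), character(0))),
                     class = "lnc_hits")
  if (nrow(variants) == 0) return(empty)
  unmatched <- setdiff(unique(variants$chrom), unique(annotation$genes$chrom))
  if (length(unmatched)) {
    warning("variant chromosomes absent from annotation: ",
            paste(unmatched, collapse = ", "))
    variants <- variants[!variants$chrom %in% unmatched, , drop = FALSE]
    if (nrow(variants) == 0) return(empty)
  }
  if (length(lnc) == 0) return(empty)
  targets <- mode_targets(annotation, lnc, mode, promoter_width)
  if (length(targets) == 0) return(empty)
  ov <- GenomicRanges::findOverlaps(variant_granges(variants), targets)
  if (length(ov) == 0) return(empty)
  pair <- unique(data.frame(v = S4Vectors::queryHits(ov),
                            g = names(targets)[S4Vectors::subjectHits(ov)]))
  support <- table(pair$g)
  ids <- lnc[lnc %in% names(support)]
  structure(list(mode = mode, ids = ids,
                 support = stats::setNames(as.integer(support[ids]), ids)),
            class = "lnc_hits")
}

#' @export
print.lnc_hits <- function(x, ...) {
  cat("lnc_hits (mode = ", x$mode, "): ", length(x$ids),
      " lncRNA(s), total variant support ", sum(x$support), "\n", sep = "")
  invisible(x)
}

#' Write a hit list as TSV (gene_id, mode, n_variants)
#' @param hits an `lnc_hits`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(
    data.frame(gene_id = hits$ids, mode = hits$mode,
               n_variants = as.integer(hits$support[hits$ids])),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pairwise containment of hit lists across modes
#'
#' For every ordered mode pair (A, B) reports `100 * |A intersect B| / |B|`:
#' the percentage of B's hits contained in A. `NA` where B is empty.
#'
#' @param hits_by_mode named list of `lnc_hits` (>= 2 entries).
#' @return square numeric matrix; rows index the containing list A, columns
#'   the contained list B.
#' @export
containment_report <- function(hits_by_mode) {
  if (length(hits_by_mode) < 2) stop("need at least two hit lists")
  modes <- names(hits_by_mode) %||% vapply(hits_by_mode, `[[`, "", "mode")
  k <- length(hits_by_mode)
  m <- matrix(NA_real_, k, k, dimnames = list(containing = modes, contained = modes))
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      bi <- hits_by_mode[[b]]$ids
      if (length(bi) == 0) next
      m[a, b] <- 100 * length(intersect(hits_by_mode[[a]]$ids, bi)) / length(bi)
    }
  }
  m
}

#' Validate hit lncRNAs against an independent CNV set
#'
#' Fraction of hit lncRNAs whose gene body overlaps at least one CNV
#' interval. When `exclude` is given, the hits are first re-derived from
#' `variants` with the excluded records removed (exact match on chrom,
#' start, end and class), guarding against circularity between the variant
#' set and the validation CNVs.
#'
#' @param hits an `lnc_hits`.
#' @param annotation an `lnc_annotation`.
#' @param cnv_set a `variant_set` of validation CNVs (non-empty).
#' @param variants,exclude optional: original variants and the records to
#'   drop before re-deriving hits.
#' @param promoter_width promoter length used when re-deriving
#'   `gene_plus_promoter` hits.
#' @return list with `fraction`, `n_hits`, `validated_ids`.
#' @export
cnv_validation <- function(hits, annotation, cnv_set, variants = NULL,
                           exclude = NULL, promoter_width = 5000) {
  if (nrow(cnv_set) == 0) stop("cnv_set must be non-empty")
  if (!is.null(exclude)) {
    if (is.null(variants)) stop("re-deriving hits with 'exclude' requires 'variants'")
    key <- function(v) paste(v$chrom, v$start, v$end, v$class)
    keep <- !(key(variants) %in% key(exclude))
    hits <- identify_lncRNAs(new_variants(variants[keep, , drop = FALSE]),
                             annotation, mode = hits$mode,
                             promoter_width = promoter_width)
  }
  if (length(hits$ids) == 0) {
    return(list(fraction = NA_real_, n_hits = 0L, validated_ids = character(0)))
  }
  bodies <- gene_granges(annotation, hits$ids)
  cnv_set <- cnv_set[cnv_set$chrom %in% annotation$genes$chrom, , drop = FALSE]
  ov <- GenomicRanges::findOverlaps(bodies, variant_granges(cnv_set))
  validated <- hits$ids[sort(unique(S4Vectors::queryHits(ov)))]
  list(fraction = length(validated) / length(hits$ids),
       n_hits = length(hits$ids), validated_ids = validated)
}

#' Protein-coding genomic neighbors of lncRNAs
#'
#' Neighbors are protein-coding genes overlapping the flanked interval
#' `[start - flank, end + flank)` of each lncRNA, clipped at 0.
#'
#' @param hits an `lnc_hits` or a character vector of lncRNA ids.
#' @param annotation an `lnc_annotation`.
#' @param flank flanking width in bp (default 50000, i.e. +/- 50 kb).
#' @return named list mapping each lncRNA id to a sorted character vector of
#'   protein-coding neighbor gene ids.
#' @export
genomic_neighbors <- function(hits, annotation, flank = 50000) {
  if (flank < 0) stop("flank must be >= 0")
  ids <- if (inherits(hits, "lnc_hits")) hits$ids else as.character(hits)
  if (any(!ids %in% annotation$genes$gene_id)) {
    stop("unknown gene ids: ",
         paste(utils::head(setdiff(ids, annotation$genes$gene_id), 5), collapse = ", "))
  }
  out <- stats::setNames(vector("list", length(ids)), ids)
  if (length(ids) == 0) return(out)
  g <- annotation$genes[match(ids, annotation$genes$gene_id), , drop = FALSE]
  windows <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = pmax(0, g$start - flank) + 1L,
                              end = g$end + flank))
  coding <- gene_granges(annotation, coding_ids(annotation))
  ov <- GenomicRanges::findOverlaps(windows, coding)
  for (i in seq_along(ids)) out[[i]] <- character(0)
  if (length(ov)) {
    sp <- split(names(coding)[S4Vectors::subjectHits(ov)],
                ids[S4Vectors::queryHits(ov)])
    for (nm in names(sp)) out[[nm]] <- sort(unique(sp[[nm]]))
  }
  out
}

#' Subclass distribution of hit lncRNAs
#'
#' @param hits an `lnc_hits`.
#' @param annotation an `lnc_annotation`.
#' @return data.frame with `subclass`, `count`, `proportion` (proportions
#'   sum to 1 over the hit lncRNAs; zero rows when there are no hits).
#' @export
subclass_distribution <- function(hits, annotation) {
  g <- annotation$genes
  sub <- g$gene_type[match(hits$ids, g$gene_id)]
  tab <- table(factor(sub, levels = lncRNA_types()))
  tab <- tab[tab > 0]
  data.frame(subclass = names(tab), count = as.integer(tab),
             proportion = as.numeric(tab) / max(1L, length(hits$ids)),
             stringsAsFactors = FALSE)
}
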