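# Competing-endogenous-RNA inference: protein-coding genes sharing
# significantly many miRNA regulators with each lncRNA.

#' Shared-miRNA hypergeometric test for one pair
#'
#' `shared` is the size of the intersection of the two miRNA-regulator
#' sets; the p-value is the upper-tail hypergeometric probability
#' `P(X >= shared)` with population `universe_size`, success count
#' `|lnc_mirnas|`, and draw count `|gene_mirnas|`. Either set empty gives
#' `shared = 0`, `p = 1`.
#'
#' @param lnc_mirnas,gene_mirnas character vectors of miRNA ids.
#' @param universe_size number of distinct miRNAs in the interaction table.
#' @return list with `shared` and `p`.
#' @export
shared_mirna_test <- function(lnc_mirnas, gene_mirnas, universe_size) {
  lnc_mirnas <- unique(lnc_mirnas); gene_mirnas <- unique(gene_mirnas)
  if (length(lnc_mirnas) == 0 || length(gene_mirnas) == 0) {
    return(list(shared = 0L, p = 1))
  }
  if (universe_size < max(length(lnc_mirnas), length(gene_mirnas))) {
    stop("universe_size smaller than a regulator set")
  }
  shared <- length(intersect(lnc_mirnas, gene_mirnas))
  list(shared = shared,
       p = hyper_upper_tail(shared, length(lnc_mirnas), universe_size,
                            length(gene_mirnas)))
}

#' ceRNA neighbors of lncRNAs
#'
#' Scores every (lncRNA, protein-coding gene) pair with the shared-miRNA
#' hypergeometric test, taking the miRNA universe as all distinct miRNAs in
#' the interaction table. Benjamini-Hochberg FDR is applied jointly across
#' all tested pairs. A pair is retained iff `shared >= min_shared`,
#' `p <= alpha` and `fdr <= alpha`.
#'
#' @param interactions data.frame with columns `miRNA_id`, `gene_id`
#'   (duplicate edges are collapsed).
#' @param lnc_ids lncRNA ids to query; ids without any interaction are
#'   skipped with a warning.
#' @param annotation an `lnc_annotation` (supplies the protein-coding set).
#' @param min_shared minimum shared regulator count (default 2).
#' @param alpha threshold applied to both p and FDR (default 0.01).
#' @return data.frame of retained pairs (`lncRNA`, `gene`, `shared`, `p`,
#'   `fdr`), sorted by p; the full scored table is attached as attribute
#'   `"scored"`.
#' @export
cerna_neighbors <- function(interactions, lnc_ids, annotation,
                            min_shared = 2, alpha = 0.01) {
  if (nrow(interactions) == 0) stop("interaction table is empty")
  edges <- unique(interactions[, c("miRNA_id", "gene_id")])
  M <- length(unique(edges$miRNA_id))
  with_edges <- unique(edges$gene_id)
  absent <- setdiff(lnc_ids, with_edges)
  if (length(absent)) {
    warning("lncRNA(s) absent from the interaction table, skipped: ",
            paste(utils::head(absent, 10), collapse = ", "))
  }
  lnc <- intersect(lnc_ids, with_edges)
  coding <- intersect(coding_ids(annotation), with_edges)
  empty <- data.frame(lncRNA = character(0), gene = character(0),
                      shared = integer(0), p = numeric(0), fdr = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(lnc) == 0 || length(coding) == 0) {
    attr(empty, "scored") <- empty
    return(empty)
  }
  # 0/1 incidence of genes x miRNAs; shared counts by matrix product
  mirs <- sort(unique(edges$miRNA_id))
  genes <- c(lnc, coding)
  inc <- matrix(0L, length(genes), length(mirs),
                dimnames = list(genes, mirs))
  keep <- edges$gene_id %in% genes
  inc[cbind(match(edges$gene_id[keep], genes),
            match(edges$miRNA_id[keep], mirs))] <- 1L
  sizes <- rowSums(inc)
  S <- inc[lnc, , drop = FALSE] %*% t(inc[coding, , drop = FALSE])
  long <- data.frame(
    lncRNA = rep(lnc, times = length(coding)),
    gene = rep(coding, each = length(lnc)),
    shared = as.integer(S),
    stringsAsFactors = FALSE)
  long <- long[long$lncRNA != long$gene, , drop = FALSE]
  long$p <- hyper_upper_tail(long$shared, sizes[long$lncRNA], M,
                             sizes[long$gene])
  long$fdr <- bh_fdr(long$p)
  kept <- long[long$shared >= min_shared & long$p <= alpha & long$fdr <= alpha, ,
               drop = FALSE]
  kept <- kept[order(kept$p, kept$lncRNA, kept$gene), , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "scored") <- long
  kept
}

#' Collapse a ceRNA pair table to per-lncRNA neighbor sets
#'
#' @param pairs data.frame from [cerna_neighbors()].
#' @param lnc_ids lncRNA ids the result should cover (absent ids map to an
#'   empty set).
#' @return named list of sorted protein-coding neighbor ids.
#' @export
cerna_neighbor_sets <- function(pairs, lnc_ids = unique(pairs$lncRNA)) {
  out <- stats::setNames(rep(list(character(0)), length(lnc_ids)), lnc_ids)
  sp <- split(pairs$gene, pairs$lncRNA)
  for (nm in intersect(names(sp), lnc_ids)) out[[nm]] <- sort(unique(sp[[nm]]))
  out
}
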