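# Over-representation analysis against GMT gene-set collections, the
# cross-brain-region comparison matrix, and the known-gene proportion
# comparison. GMT input/output lives here too.

#' Read / write GMT gene-set files
#'
#' Standard GMT: one set per line, tab-separated as
#' `term_id<TAB>description<TAB>gene1<TAB>gene2...`. Within-set duplicate
#' gene ids are collapsed on read.
#'
#' @param path GMT file path.
#' @return for `read_gmt()`: list with `sets` (named list of character
#'   vectors) and `desc` (named character descriptions).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(ids)) stop("duplicate set ids in GMT: ", path)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  if (any(lengths(sets) == 0)) stop("GMT contains empty sets: ", path)
  list(sets = sets,
       desc = stats::setNames(vapply(parts, `[[`, "", 2), ids))
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional description column (recycled).
#' @return for `write_gmt()`: `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  desc <- rep_len(descriptions %||% "na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis of a gene list
#'
#' For each term with at least `min_set_size` universe genes, the upper-tail
#' hypergeometric probability `P(X >= k)` of the 2x2 counts
#' (N universe genes, K in the term, n in the list, k in both) is computed,
#' with Benjamini-Hochberg FDR across all tested terms. Genes outside the
#' universe are dropped (counted in attribute `"n_dropped"`); skipped small
#' terms are listed in attribute `"skipped_terms"`.
#'
#' @param genes character gene list.
#' @param sets named list of character vectors (or the `sets` element of
#'   [read_gmt()]).
#' @param universe character universe of gene ids.
#' @param min_set_size smallest universe-intersected term tested
#'   (default 3).
#' @return data.frame with `term_id`, `k`, `K`, `n`, `N`, `fold`, `p`,
#'   `fdr`, sorted by p (ties by term id).
#' @export
ora <- function(genes, sets, universe, min_set_size = 3) {
  universe <- unique(universe)
  genes <- unique(genes)
  eff <- intersect(genes, universe)
  n_dropped <- length(genes) - length(eff)
  if (length(eff) == 0) stop("no genes from the list are in the universe")
  N <- length(universe); n <- length(eff)
  su <- lapply(sets, intersect, y = universe)
  Ks <- lengths(su)
  skipped <- names(sets)[Ks < min_set_size]
  keep <- Ks >= min_set_size
  su <- su[keep]
  res <- data.frame(
    term_id = names(su),
    k = vapply(su, function(s) length(intersect(eff, s)), integer(1)),
    K = lengths(su), n = n, N = N,
    row.names = NULL, stringsAsFactors = FALSE)
  res$fold <- (res$k / n) / (res$K / N)
  res$p <- hyper_upper_tail(res$k, res$K, N, n)
  res$fdr <- bh_fdr(res$p)
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_dropped") <- n_dropped
  attr(res, "skipped_terms") <- skipped
  res
}

#' Term-by-region enrichment comparison matrix
#'
#' Runs [ora()] per region on its neighbor gene set; rows are the union of
#' each region's `top_k` terms with `p < alpha`; a cell holds `-log10(p)`
#' when the term passes `p < alpha` in that region and `NA` otherwise.
#' Regions with an empty gene list or zero passing terms produce an
#' all-`NA` column with a warning.
#'
#' @param neighbors_by_region named list (>= 2 regions) of gene id vectors.
#' @param sets,universe,min_set_size passed to [ora()].
#' @param top_k terms retained per region (default 15).
#' @param alpha per-region p threshold (default 0.05).
#' @return numeric matrix, terms x regions.
#' @export
region_comparison <- function(neighbors_by_region, sets, universe,
                              top_k = 15, alpha = 0.05, min_set_size = 3) {
  if (length(neighbors_by_region) < 2) stop("need at least 2 regions")
  regions <- names(neighbors_by_region)
  oras <- lapply(regions, function(r) {
    g <- intersect(neighbors_by_region[[r]], universe)
    if (length(g) == 0) {
      warning("region '", r, "' has no universe genes; empty column")
      return(NULL)
    }
    ora(g, sets, universe, min_set_size = min_set_size)
  })
  names(oras) <- regions
  selected <- lapply(oras, function(o) {
    if (is.null(o)) return(character(0))
    utils::head(o$term_id[o$p < alpha], top_k)
  })
  for (r in regions) {
    if (!is.null(oras[[r]]) && length(selected[[r]]) == 0) {
      warning("region '", r, "' has no terms passing p < ", alpha)
    }
  }
  terms <- sort(unique(unlist(selected)))
  m <- matrix(NA_real_, length(terms), length(regions),
              dimnames = list(terms, regions))
  for (r in regions) {
    o <- oras[[r]]
    if (is.null(o)) next
    pass <- o[o$p < alpha & o$term_id %in% terms, , drop = FALSE]
    m[pass$term_id, r] <- -log10(pass$p)
  }
  m
}

#' Known-gene proportion comparison between two lncRNA groups
#'
#' Per lncRNA, the proportion of its neighbor genes found in the known
#' disease-gene list (`NA` when it has no neighbors); the hit and
#' background groups are then compared with the two-sided rank-sum test of
#' [compare_groups()].
#'
#' @param hit_sets,background_sets named lists of neighbor gene vectors
#'   (one entry per lncRNA).
#' @param known_genes non-empty character vector.
#' @return list with `hit` / `background` (named proportion vectors), `p`
#'   and `medians`.
#' @export
known_gene_proportion <- function(hit_sets, background_sets, known_genes) {
  if (length(known_genes) == 0) stop("known gene list is empty")
  prop <- function(s) {
    if (length(s) == 0) NA_real_ else length(intersect(s, known_genes)) / length(s)
  }
  ph <- vapply(hit_sets, prop, numeric(1))
  pb <- vapply(background_sets, prop, numeric(1))
  if (all(is.na(ph))) stop("all hit-group proportions are NA (no neighbors)")
  if (all(is.na(pb))) stop("all background-group proportions are NA (no neighbors)")
  cg <- compare_groups(ph, pb, labels = c("hit", "background"))
  list(hit = ph, background = pb, p = cg$p, medians = cg$medians)
}
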