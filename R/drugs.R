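# Drug repositioning: rank drugs by over-representation of their induced
# pathway sets within the disease-altered pathway list.

#' Disease-altered pathway list
#'
#' Pathways passing the FDR threshold in the neighbor-gene ORA results,
#' deduplicated across the result tables that feed it. The permissive
#' default (0.5) is deliberate: it yields an altered list of workable size
#' for the downstream drug enrichment.
#'
#' @param ora_results a data.frame from [ora()] or a list of several (one
#'   per neighbor category); each needs `term_id` and `fdr` columns.
#' @param fdr_max FDR threshold (default 0.5).
#' @return character vector of pathway ids (first-seen order).
#' @export
altered_pathways <- function(ora_results, fdr_max = 0.5) {
  if (is.data.frame(ora_results)) ora_results <- list(ora_results)
  rows <- do.call(rbind, lapply(ora_results, function(o)
    o[, c("term_id", "fdr"), drop = FALSE]))
  out <- unique(rows$term_id[rows$fdr <= fdr_max])
  if (length(out) == 0) {
    stop("no pathways pass FDR <= ", fdr_max,
         "; consider raising the threshold")
  }
  out
}

#' Rank drugs by pathway-set enrichment in the altered list
#'
#' Per drug, a 2x2 table over the background pathways (in drug set x in
#' altered list) is tested one-sided for enrichment; the p-value is the
#' hypergeometric upper tail, identical to the one-sided (greater) Fisher
#' exact test. Benjamini-Hochberg FDR is applied across drugs and the table
#' is sorted by ascending p (ties broken by drug id). Drug-set pathways
#' outside the background are dropped and counted; a drug left empty is
#' flagged with `p = 1`.
#'
#' @param altered character vector of altered pathway ids (subset of
#'   `background`).
#' @param drug_sets named list mapping drug id to pathway ids.
#' @param background all pathway ids of the reference collection.
#' @return data.frame with `drug`, `overlap` (a), `b`, `c`, `d`, `set_size`,
#'   `dropped`, `empty`, `p`, `fdr`.
#' @export
drug_enrichment <- function(altered, drug_sets, background) {
  background <- unique(background)
  altered <- unique(altered)
  if (any(!altered %in% background)) {
    stop("altered pathways outside the background: ",
         paste(utils::head(setdiff(altered, background), 5), collapse = ", "))
  }
  if (length(drug_sets) == 0) stop("need at least one drug set")
  N <- length(background); n <- length(altered)
  rows <- lapply(names(drug_sets), function(d) {
    full <- unique(drug_sets[[d]])
    s <- intersect(full, background)
    K <- length(s)
    a <- length(intersect(s, altered))
    empty <- K == 0
    p <- if (empty) 1 else hyper_upper_tail(a, K, N, n)
    data.frame(drug = d, overlap = a, b = K - a, c = n - a,
               d = N - K - n + a, set_size = K,
               dropped = length(full) - K, empty = empty, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- bh_fdr(res$p)
  res <- res[order(res$p, res$drug), , drop = FALSE]
  rownames(res) <- NULL
  res
}
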