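# Unsigned weighted co-expression networks (WGCNA-style): robust variance
# filtering, outlier sample removal, soft-threshold selection by scale-free
# topology fit, adjacency construction, and neighbor extraction.

#' Filter genes by median absolute deviation
#'
#' Retains the `ceiling(keep_fraction * G)` genes with the largest
#' `MAD = median(|x - median(x)|)` across samples (unscaled, no consistency
#' constant), dropping low-variation genes first.
#'
#' @param values genes x samples matrix.
#' @param keep_fraction fraction of genes to keep, in (0, 1\].
#' @return the filtered matrix (original row order preserved).
#' @export
mad_filter <- function(values, keep_fraction = 0.75) {
  if (keep_fraction <= 0 || keep_fraction > 1) {
    stop("keep_fraction must lie in (0, 1]")
  }
  n_keep <- ceiling(keep_fraction * nrow(values))
  if (n_keep < 3) stop("fewer than 3 genes would remain after the MAD filter")
  mads <- apply(values, 1, function(r) stats::median(abs(r - stats::median(r))))
  keep <- sort(order(mads, decreasing = TRUE)[seq_len(n_keep)])
  values[keep, , drop = FALSE]
}

#' Remove outlier samples by hierarchical clustering
#'
#' Average-linkage clustering on Euclidean sample distance; the tree is cut
#' at the `cut_height_quantile` quantile of the merge heights and samples
#' left as singleton branches above the cut are removed. At most 10% of the
#' samples are ever removed (the most distant ones are dropped first when
#' the cap binds).
#'
#' @param values genes x samples matrix (>= 4 samples).
#' @param cut_height_quantile quantile of merge heights for the cut
#'   (default 0.99).
#' @param max_remove_fraction hard cap on the removed fraction (default 0.1).
#' @return list with `values` (filtered matrix) and `removed` (sample
#'   names, possibly empty).
#' @export
remove_outlier_samples <- function(values, cut_height_quantile = 0.99,
                                   max_remove_fraction = 0.1) {
  n <- ncol(values)
  if (n < 4) stop("need at least 4 samples")
  d <- stats::dist(t(values))
  h <- stats::hclust(d, method = "average")
  cut <- stats::quantile(h$height, cut_height_quantile, names = FALSE)
  cl <- stats::cutree(h, h = cut)
  sizes <- table(cl)
  removed <- colnames(values)[cl %in% as.integer(names(sizes)[sizes == 1])]
  cap <- floor(max_remove_fraction * n)
  if (length(removed) > cap) {
    avg_d <- colMeans(as.matrix(d))
    removed <- names(sort(avg_d[removed], decreasing = TRUE))[seq_len(cap)]
  }
  list(values = values[, setdiff(colnames(values), removed), drop = FALSE],
       removed = removed)
}

# Scale-free topology fit: R^2 of log10 p(k) vs log10 k over nbreaks
# equal-width connectivity bins, sign-flipped when the slope is positive.
# Empty bins are kept at their midpoints with p(k) = 0 (offset by 1e-9 in
# log space), matching the reference WGCNA formulation.
scale_free_fit <- function(k, nbreaks = 10) {
  k <- k[is.finite(k)]
  if (length(unique(k)) < 3) return(0)
  bin <- cut(k, nbreaks)
  dk <- tapply(k, bin, mean)
  pk <- as.vector(tapply(k, bin, length) / length(k))
  br <- seq(min(k), max(k), length.out = nbreaks + 1)
  mids <- (br[-1] + br[-(nbreaks + 1)]) / 2
  dk <- ifelse(is.na(dk) | dk == 0, mids, dk)
  pk <- ifelse(is.na(pk), 0, pk)
  fit <- stats::lm(log10(pk + 1e-9) ~ log10(dk))
  r2 <- summary(fit)$r.squared
  if (stats::coef(fit)[2] > 0) r2 <- -r2
  unname(r2)
}

#' Choose the soft-threshold power for an unsigned network
#'
#' For each candidate power beta the unsigned adjacency `|cor|^beta` is
#' formed, per-gene connectivity `k_i = sum_j a_ij` computed, and the
#' scale-free fit R^2 evaluated (signed negative when the log-log slope is
#' positive). Returns the smallest beta whose fit reaches `target_r2`, or
#' the best-fitting beta with a warning when none does.
#'
#' @param values genes x samples matrix (>= 8 samples, no constant gene).
#' @param powers candidate integer powers (default 1:20).
#' @param target_r2 scale-free fit target (default 0.85).
#' @param nbreaks connectivity bins for the fit (default 10).
#' @return list with `beta`, `fit_r2` (at the chosen beta) and `table`
#'   (power, fit_r2, mean_k, max_k).
#' @export
pick_soft_threshold <- function(values, powers = 1:20, target_r2 = 0.85,
                                nbreaks = 10) {
  if (ncol(values) < 8) stop("need at least 8 samples to pick a soft threshold")
  sds <- apply(values, 1, stats::sd)
  if (any(sds == 0)) {
    stop("constant gene(s) after filtering: ",
         paste(utils::head(rownames(values)[sds == 0], 5), collapse = ", "))
  }
  C <- abs(stats::cor(t(values)))
  tab <- do.call(rbind, lapply(powers, function(b) {
    A <- C^b
    diag(A) <- 0
    k <- rowSums(A)
    data.frame(power = b, fit_r2 = scale_free_fit(k, nbreaks),
               mean_k = mean(k), max_k = max(k))
  }))
  hit <- which(tab$fit_r2 >= target_r2)
  if (length(hit)) {
    i <- hit[1]
  } else {
    i <- which.max(tab$fit_r2)
    warning("no candidate power reached target fit R^2 = ", target_r2,
            "; using the best-fitting power ", tab$power[i],
            " (R^2 = ", round(tab$fit_r2[i], 3), ")")
  }
  list(beta = tab$power[i], fit_r2 = tab$fit_r2[i], table = tab)
}

#' Build an unsigned weighted adjacency network
#'
#' `a_ij = |pearson(x_i, x_j)|^beta`, diagonal set to 1.
#'
#' @param values genes x samples matrix (no constant gene).
#' @param beta soft power (>= 1).
#' @param tissue optional tissue label stored on the network.
#' @param fit_r2 optional scale-free fit statistic to record.
#' @return object of class `coexpr_network`: list with `tissue`,
#'   `gene_ids`, `beta`, `adjacency`, `fit_r2`.
#' @export
build_adjacency <- function(values, beta, tissue = NA_character_,
                            fit_r2 = NA_real_) {
  if (beta < 1) stop("beta must be >= 1")
  sds <- apply(values, 1, stats::sd)
  if (any(sds == 0)) {
    stop("constant gene(s) make correlations undefined: ",
         paste(utils::head(rownames(values)[sds == 0], 5), collapse = ", "))
  }
  A <- abs(stats::cor(t(values)))^beta
  diag(A) <- 1
  structure(list(tissue = tissue, gene_ids = rownames(values), beta = beta,
                 adjacency = A, fit_r2 = fit_r2),
            class = "coexpr_network")
}

#' @export
print.coexpr_network <- function(x, ...) {
  cat("coexpr_network (tissue = ", x$tissue, "): ", length(x$gene_ids),
      " genes, beta = ", x$beta,
      if (!is.na(x$fit_r2)) paste0(", scale-free fit R^2 = ", round(x$fit_r2, 3)),
      "\n", sep = "")
  invisible(x)
}

# Sample-size-based default soft power for unsigned networks, used when no
# candidate reaches the scale-free fit target (standard WGCNA practice).
default_power <- function(n_samples) {
  if (n_samples < 20) 9L else if (n_samples < 30) 8L
  else if (n_samples < 40) 7L else 6L
}

#' Full per-tissue network construction
#'
#' Convenience wrapper: subset the expression matrix to one tissue's
#' samples, apply the MAD filter and outlier-sample removal, pick the soft
#' threshold, and build the adjacency. When no candidate power reaches the
#' scale-free fit target the sample-size-based default power for unsigned
#' networks is used (9/8/7/6 for < 20 / < 30 / < 40 / >= 40 samples) rather
#' than the best-fitting power, which on weakly scale-free data tends to
#' run away to the top of the candidate range.
#'
#' @param expr an `expr_matrix`.
#' @param tissue tissue label present in the sample map.
#' @param keep_fraction MAD filter keep fraction (default 0.75).
#' @param powers,target_r2 passed to [pick_soft_threshold()].
#' @return a `coexpr_network`.
#' @export
build_tissue_network <- function(expr, tissue, keep_fraction = 0.75,
                                 powers = 1:20, target_r2 = 0.85) {
  cols <- names(expr$sample_tissue)[expr$sample_tissue == tissue]
  if (length(cols) == 0) stop("no samples for tissue: ", tissue)
  v <- expr$values[, cols, drop = FALSE]
  v <- mad_filter(v, keep_fraction)
  v <- remove_outlier_samples(v)$values
  # re-apply: a removed sample can leave a gene constant
  sds <- apply(v, 1, stats::sd)
  v <- v[sds > 0, , drop = FALSE]
  st <- suppressWarnings(
    pick_soft_threshold(v, powers = powers, target_r2 = target_r2))
  if (!any(st$table$fit_r2 >= target_r2)) {
    beta <- default_power(ncol(v))
    i <- match(beta, st$table$power)
    fit <- if (is.na(i)) NA_real_ else st$table$fit_r2[i]
    return(build_adjacency(v, beta, tissue = tissue, fit_r2 = fit))
  }
  build_adjacency(v, st$beta, tissue = tissue, fit_r2 = st$fit_r2)
}

#' Co-expression neighbors of lncRNAs
#'
#' Neighbors of a lncRNA are the protein-coding genes whose adjacency to it
#' reaches `adjacency_min`. lncRNAs absent from the network (filtered out or
#' never present) are reported with a warning and skipped.
#'
#' @param net a `coexpr_network`.
#' @param lnc_ids lncRNA ids to query.
#' @param annotation an `lnc_annotation` (supplies the protein-coding set).
#' @param adjacency_min adjacency threshold (default 0.1; use a stricter
#'   value, e.g. 0.3, for the high-reliability analysis).
#' @return named list mapping each present lncRNA to its sorted
#'   protein-coding neighbor ids.
#' @export
coexpr_neighbors <- function(net, lnc_ids, annotation, adjacency_min = 0.1) {
  absent <- setdiff(lnc_ids, net$gene_ids)
  if (length(absent)) {
    warning("lncRNA(s) absent from the ", net$tissue, " network, skipped: ",
            paste(utils::head(absent, 10), collapse = ", "))
  }
  present <- intersect(lnc_ids, net$gene_ids)
  coding <- intersect(net$gene_ids, coding_ids(annotation))
  out <- stats::setNames(vector("list", length(present)), present)
  for (id in present) {
    a <- net$adjacency[id, coding]
    out[[id]] <- sort(names(a)[a >= adjacency_min])
  }
  out
}
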