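# Expression container, tissue-specificity and brain-expression metrics,
# group comparisons, and differential-expression calling for lncRNAs.

#' Construct an expression matrix object
#'
#' @param values non-negative numeric matrix, genes x samples (TPM-like),
#'   with row and column names.
#' @param sample_tissue named character vector mapping every sample (column)
#'   to a tissue label.
#' @param brain_tissues subset of tissue labels counted as brain.
#' @return an object of class `expr_matrix`.
#' @export
new_expression <- function(values, sample_tissue, brain_tissues = character(0)) {
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene row names and sample column names")
  }
  if (any(values < 0)) stop("expression values must be >= 0")
  missing <- setdiff(colnames(values), names(sample_tissue))
  if (length(missing)) {
    stop("samples without a tissue label: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  structure(list(values = values,
                 sample_tissue = sample_tissue[colnames(values)],
                 brain_tissues = intersect(brain_tissues, unique(sample_tissue))),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$values), "genes x", ncol(x$values), "samples,",
      length(unique(x$sample_tissue)), "tissues (",
      length(x$brain_tissues), "brain )\n")
  invisible(x)
}

#' Write / read an expression matrix and its sample map
#'
#' The expression TSV has a `gene_id` column followed by one column per
#' sample; the sample map TSV has columns `sample_id`, `tissue`,
#' `is_brain`.
#'
#' @param expr an `expr_matrix`.
#' @param path expression TSV path.
#' @param sample_path sample map TSV path (`NULL` skips it).
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, sample_path = NULL) {
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sample_path)) {
    utils::write.table(
      data.frame(sample_id = colnames(expr$values),
                 tissue = unname(expr$sample_tissue),
                 is_brain = unname(expr$sample_tissue) %in% expr$brain_tissues),
      sample_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path, sample_path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$gene_id
  sm <- utils::read.delim(sample_path, stringsAsFactors = FALSE)
  new_expression(values, stats::setNames(sm$tissue, sm$sample_id),
                 brain_tissues = unique(sm$tissue[sm$is_brain]))
}

#' Per-tissue median expression
#'
#' Collapses samples to their tissue median, mirroring consortium-style
#' per-tissue median TPM tables.
#'
#' @param expr an `expr_matrix`.
#' @return numeric matrix, genes x tissues.
#' @export
tissue_medians <- function(expr) {
  tissues <- unique(expr$sample_tissue)
  out <- vapply(tissues, function(t) {
    cols <- names(expr$sample_tissue)[expr$sample_tissue == t]
    apply(expr$values[, cols, drop = FALSE], 1, stats::median)
  }, numeric(nrow(expr$values)))
  dimnames(out) <- list(rownames(expr$values), tissues)
  out
}

#' Tissue-specificity index tau
#'
#' `tau = sum_i(1 - x_i / max(x)) / (N - 1)` over the per-tissue expression
#' vector: 0 for uniform expression, 1 for single-tissue expression.
#' All-zero genes yield `NA`.
#'
#' @param x numeric vector of per-tissue values (>= 2 tissues, non-negative)
#'   or a genes x tissues matrix (rows are scored independently).
#' @return tau in \[0, 1\] (or a named vector for matrix input).
#' @examples
#' tau_index(c(5, 5, 5, 5))  # 0
#' tau_index(c(1, 0, 0, 0))  # 1
#' tau_index(c(8, 2, 2, 2))  # 0.75
#' @export
tau_index <- function(x) {
  if (is.matrix(x)) {
    return(apply(x, 1, tau_index))
  }
  if (length(x) < 2) stop("tau needs at least two tissues")
  if (any(x < 0, na.rm = TRUE)) stop("tau is defined for non-negative values")
  mx <- max(x)
  if (!is.finite(mx) || mx == 0) return(NA_real_)
  sum(1 - x / mx) / (length(x) - 1)
}

#' Brain tissue expression index
#'
#' Median expression over brain tissues divided by the median over all
#' tissues; `NA` when the overall median is 0.
#'
#' @param x per-tissue numeric vector (named) or genes x tissues matrix.
#' @param brain_tissues non-empty subset of the tissue names of `x`.
#' @return ratio >= 0 (or a named vector for matrix input).
#' @export
brain_index <- function(x, brain_tissues) {
  if (is.matrix(x)) {
    return(apply(x, 1, brain_index, brain_tissues = brain_tissues))
  }
  if (length(brain_tissues) == 0) stop("brain_tissues must be non-empty")
  if (any(!brain_tissues %in% names(x))) {
    stop("brain_tissues must be a subset of the tissue names")
  }
  overall <- stats::median(x)
  if (overall == 0) return(NA_real_)
  stats::median(x[brain_tissues]) / overall
}

#' Two-sided Wilcoxon rank-sum comparison of two groups
#'
#' Exact test when both groups have at most `exact_max` values and there are
#' no ties; otherwise the normal approximation with midranks for ties and
#' continuity correction.
#'
#' @param x,y numeric vectors (NAs removed; >= 2 values each afterwards).
#' @param labels length-2 character, names for the groups in the output.
#' @param exact_max largest per-group size for the exact branch (default 25).
#' @return list with `p`, per-group medians, sizes and `exact` flag.
#' @export
compare_groups <- function(x, y, labels = c("group1", "group2"),
                           exact_max = 25) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0) stop("group '", labels[1], "' is empty after NA removal")
  if (length(y) == 0) stop("group '", labels[2], "' is empty after NA removal")
  if (length(x) < 2 || length(y) < 2) {
    stop("both groups need at least 2 values after NA removal")
  }
  ties <- any(duplicated(c(x, y)))
  exact <- length(x) <= exact_max && length(y) <= exact_max && !ties
  wt <- stats::wilcox.test(x, y, alternative = "two.sided",
                           exact = exact, correct = TRUE)
  out <- list(p = wt$p.value,
              medians = stats::setNames(c(stats::median(x), stats::median(y)), labels),
              n = stats::setNames(c(length(x), length(y)), labels),
              exact = exact)
  out
}

#' Per-gene differential-expression test between two sample groups
#'
#' Fold change is computed on group means with a pseudocount:
#' `FC = (mean_case + eps) / (mean_control + eps)`. A gene is called when
#' `FC > fc_min` or `FC < 1 / fc_min` (strict) and the two-sided rank-sum
#' p-value is `< alpha`.
#'
#' @param values genes x samples matrix.
#' @param case_samples,control_samples column names (>= 2 each).
#' @param fc_min fold-change threshold (default 1.5).
#' @param alpha p-value threshold (default 0.05).
#' @param pseudocount stabilizer added to both group means (default 0.1).
#' @return data.frame with `gene_id`, `mean_case`, `mean_control`, `fc`,
#'   `p`, `de`.
#' @export
de_test <- function(values, case_samples, control_samples,
                    fc_min = 1.5, alpha = 0.05, pseudocount = 0.1) {
  if (length(case_samples) < 2 || length(control_samples) < 2) {
    stop("each group needs at least 2 samples")
  }
  stopifnot(all(c(case_samples, control_samples) %in% colnames(values)))
  ca <- values[, case_samples, drop = FALSE]
  co <- values[, control_samples, drop = FALSE]
  mc <- rowMeans(ca); mo <- rowMeans(co)
  fc <- (mc + pseudocount) / (mo + pseudocount)
  p <- vapply(seq_len(nrow(values)), function(i) {
    xi <- ca[i, ]; yi <- co[i, ]
    ties <- any(duplicated(c(xi, yi)))
    exact <- length(xi) <= 25 && length(yi) <= 25 && !ties
    stats::wilcox.test(xi, yi, exact = exact, correct = TRUE)$p.value
  }, numeric(1))
  data.frame(gene_id = rownames(values), mean_case = mc, mean_control = mo,
             fc = fc, p = p, de = (fc > fc_min | fc < 1 / fc_min) & p < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call differentially expressed lncRNAs
#'
#' Runs [de_test()] and retains only the genes whose annotation biotype is
#' one of the five lncRNA subclasses.
#'
#' @inheritParams de_test
#' @param annotation an `lnc_annotation`.
#' @return character vector of DE lncRNA ids; the full per-gene table is
#'   attached as attribute `"table"`.
#' @export
call_de_lncRNAs <- function(values, case_samples, control_samples, annotation,
                            fc_min = 1.5, alpha = 0.05, pseudocount = 0.1) {
  tab <- de_test(values, case_samples, control_samples,
                 fc_min = fc_min, alpha = alpha, pseudocount = pseudocount)
  ids <- intersect(tab$gene_id[tab$de], lncRNA_ids(annotation))
  attr(ids, "table") <- tab
  ids
}
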