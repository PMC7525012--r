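# Shared fixtures and independent brute-force oracles.

# Hand-built annotation: `genes` is a list of lists with fields
# id, type, chrom, start, end, strand, exons (list of c(start, end));
# exons default to one interior exon spanning most of the gene.
toy_annotation <- function(genes) {
  gdf <- do.call(rbind, lapply(genes, function(g) {
    data.frame(gene_id = g$id, gene_type = g$type, chrom = g$chrom,
               start = g$start, end = g$end, strand = g$strand %||% "+",
               stringsAsFactors = FALSE)
  }))
  edf <- do.call(rbind, lapply(genes, function(g) {
    ex <- g$exons %||% list(c(g$start + 1, g$end - 1))
    do.call(rbind, lapply(ex, function(e) {
      data.frame(gene_id = g$id, chrom = g$chrom, start = e[1], end = e[2],
                 stringsAsFactors = FALSE)
    }))
  }))
  new_annotation(gdf, edf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_variants <- function(...) {
  rows <- list(...)
  new_variants(do.call(rbind, lapply(rows, function(r) {
    data.frame(chrom = r[[1]], start = as.integer(r[[2]]),
               end = as.integer(r[[3]]),
               class = if (length(r) >= 4) r[[4]] else "SNV",
               stringsAsFactors = FALSE)
  })))
}

# O(n*m) brute-force variant-to-lncRNA intersection, the oracle for
# identify_lncRNAs. Half-open interval arithmetic, no interval library.
brute_hits <- function(variants, annotation, mode, promoter_width = 5000) {
  g <- annotation$genes
  lnc <- g[g$gene_type %in% lncRNA_types(), , drop = FALSE]
  support <- integer(0)
  for (i in seq_len(nrow(lnc))) {
    targets <- switch(mode,
      gene = list(c(lnc$start[i], lnc$end[i])),
      exon = {
        e <- annotation$exons[annotation$exons$gene_id == lnc$gene_id[i], ]
        lapply(seq_len(nrow(e)), function(j) c(e$start[j], e$end[j]))
      },
      gene_plus_promoter = {
        pr <- if (lnc$strand[i] == "+") {
          c(max(0, lnc$start[i] - promoter_width), lnc$start[i])
        } else c(lnc$end[i], lnc$end[i] + promoter_width)
        out <- list(c(lnc$start[i], lnc$end[i]))
        if (pr[1] < pr[2]) out <- c(out, list(pr))
        out
      })
    n <- 0L
    for (v in seq_len(nrow(variants))) {
      if (variants$chrom[v] != lnc$chrom[i]) next
      hit <- any(vapply(targets, function(t) {
        variants$start[v] < t[2] && t[1] < variants$end[v]
      }, logical(1)))
      if (hit) n <- n + 1L
    }
    if (n > 0) support[lnc$gene_id[i]] <- n
  }
  support
}

# Exhaustive hypergeometric upper tail: enumerate every size-n draw from a
# universe of N elements whose first K are successes; P(overlap >= k).
enum_hyper_tail <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) sum(d <= K)) >= k)
}

# One default-size synthetic bundle + pipeline run, generated once per test
# session and cached (several files assert against it).
.fixture_cache <- new.env(parent = emptyenv())
default_fixture <- function() {
  if (is.null(.fixture_cache$bundle)) {
    cfg <- synthetic_config(seed = 101)
    .fixture_cache$bundle <- generate_synthetic_data(cfg)
  }
  .fixture_cache$bundle
}
default_pipeline <- function() {
  if (is.null(.fixture_cache$pipeline)) {
    .fixture_cache$pipeline <- suppressWarnings(run_pipeline(default_fixture()))
  }
  .fixture_cache$pipeline
}
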