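# Integration: high-reliability neighbor intersection, the per-lncRNA
# report, and the end-to-end pipeline orchestrator.

normalize_sets <- function(x, lnc_ids) {
  out <- stats::setNames(rep(list(character(0)), length(lnc_ids)), lnc_ids)
  for (nm in intersect(names(x), lnc_ids)) out[[nm]] <- unique(x[[nm]])
  out
}

#' High-reliability functional neighbor genes
#'
#' A gene is high-reliability when it appears in at least two of the three
#' neighbor categories (genomic, ceRNA, co-expression). In the default
#' `"pooled"` mode each category is first unioned across lncRNAs and
#' membership is counted per gene; in `"per_lncRNA"` mode a gene qualifies
#' only if some single lncRNA has it in >= 2 of its own categories (the
#' stricter reading), and the reported memberships are still pooled.
#'
#' @param genomic,cerna,coexpr named lists mapping lncRNA id to gene id
#'   vectors (`cerna` may also be a pair data.frame from
#'   [cerna_neighbors()]). Use the stringent-threshold co-expression sets
#'   here.
#' @param mode `"pooled"` (default) or `"per_lncRNA"`.
#' @return list with `genes` (sorted high-reliability ids) and `membership`
#'   (data.frame `gene`, `in_genomic`, `in_cerna`, `in_coexpr`,
#'   `n_categories` over all genes seen in any category).
#' @export
high_reliability <- function(genomic, cerna, coexpr,
                             mode = c("pooled", "per_lncRNA")) {
  mode <- match.arg(mode)
  if (is.data.frame(cerna)) cerna <- cerna_neighbor_sets(cerna)
  lncs <- unique(c(names(genomic), names(cerna), names(coexpr)))
  if (length(lncs) == 0 ||
      (sum(lengths(genomic)) + sum(lengths(cerna)) + sum(lengths(coexpr))) == 0) {
    stop("need at least one lncRNA with a non-empty neighbor category")
  }
  G <- sort(unique(unlist(genomic)))
  C <- sort(unique(unlist(cerna)))
  X <- sort(unique(unlist(coexpr)))
  all_genes <- sort(unique(c(G, C, X)))
  membership <- data.frame(
    gene = all_genes,
    in_genomic = all_genes %in% G,
    in_cerna = all_genes %in% C,
    in_coexpr = all_genes %in% X,
    stringsAsFactors = FALSE)
  membership$n_categories <- rowSums(membership[, c("in_genomic", "in_cerna",
                                                    "in_coexpr")])
  genes <- if (mode == "pooled") {
    membership$gene[membership$n_categories >= 2]
  } else {
    gn <- normalize_sets(genomic, lncs)
    cn <- normalize_sets(cerna, lncs)
    xn <- normalize_sets(coexpr, lncs)
    sort(unique(unlist(lapply(lncs, function(l) {
      u <- unique(c(gn[[l]], cn[[l]], xn[[l]]))
      cnt <- (u %in% gn[[l]]) + (u %in% cn[[l]]) + (u %in% xn[[l]])
      u[cnt >= 2]
    }))))
  }
  list(genes = genes, membership = membership, mode = mode)
}

#' Assemble the per-lncRNA pipeline report
#'
#' One row per hit lncRNA: subclass, variant support, tissue-specificity
#' tau, brain expression index, neighbor counts per category and the number
#' of its neighbors in the high-reliability set. A manifest recording every
#' threshold is attached as attribute `"manifest"`.
#'
#' @param hits an `lnc_hits`.
#' @param annotation an `lnc_annotation`.
#' @param tau,brain named numeric vectors (per gene).
#' @param genomic,cerna,coexpr named neighbor-set lists (default-threshold
#'   co-expression sets).
#' @param high_rel result of [high_reliability()].
#' @param thresholds named list of thresholds to record in the manifest.
#' @return data.frame report.
#' @export
assemble_report <- function(hits, annotation, tau, brain, genomic, cerna,
                            coexpr, high_rel, thresholds = list()) {
  stages <- list(hits = hits, annotation = annotation, tau = tau,
                 brain = brain, genomic = genomic, cerna = cerna,
                 coexpr = coexpr, high_rel = high_rel)
  for (nm in names(stages)) {
    if (is.null(stages[[nm]])) stop("missing stage output: ", nm)
  }
  if (is.data.frame(cerna)) cerna <- cerna_neighbor_sets(cerna, hits$ids)
  ids <- hits$ids
  g <- annotation$genes
  gn <- normalize_sets(genomic, ids)
  cn <- normalize_sets(cerna, ids)
  xn <- normalize_sets(coexpr, ids)
  hr <- high_rel$genes
  report <- data.frame(
    gene_id = ids,
    subclass = g$gene_type[match(ids, g$gene_id)],
    n_variants = as.integer(hits$support[ids]),
    tau = unname(tau[ids]),
    brain_index = unname(brain[ids]),
    n_genomic = lengths(gn)[ids],
    n_cerna = lengths(cn)[ids],
    n_coexpr = lengths(xn)[ids],
    n_high_reliability = vapply(ids, function(l)
      length(intersect(unique(c(gn[[l]], cn[[l]], xn[[l]])), hr)), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(report, "manifest") <- list(
    package_version = as.character(utils::packageVersion("lncseed")),
    mode = hits$mode, n_hits = length(ids), thresholds = thresholds)
  report
}

#' Run the full pipeline on an input bundle
#'
#' Executes every stage in order on a bundle from
#' [generate_synthetic_data()] or [read_pipeline_inputs()]: variant-to-
#' lncRNA intersection in all three modes with the containment report and
#' CNV validation (against the CNV-class records), genomic / ceRNA /
#' co-expression neighbor extraction, expression metrics with hit-vs-
#' background comparisons, per-brain-region ORA, the known-gene proportion
#' comparison, the altered pathway list and drug ranking, and the
#' high-reliability intersection plus final report.
#'
#' @param data input bundle (list with `annotation`, `variants`, `expr`,
#'   `interactions`, `pathways`, `drugs`, `known_genes`, `scores`).
#' @param mode hit-identification mode used downstream (default `"gene"`).
#' @param flank genomic neighbor flank in bp (default 50000).
#' @param coexpr_tissue tissue for the primary co-expression network
#'   (default `"cortex"`; falls back to the first brain tissue present).
#' @param adjacency_min,stringent_min default and stringent co-expression
#'   adjacency thresholds (defaults 0.1 / 0.3).
#' @param min_shared,cerna_alpha ceRNA thresholds (defaults 2 / 0.01).
#' @param fdr_max altered-pathway FDR threshold (default 0.5).
#' @param top_k,region_alpha region-comparison parameters (defaults
#'   15 / 0.05).
#' @param hr_mode high-reliability pooling mode (default `"pooled"`).
#' @return named list with every stage's output, the final `report` and a
#'   `manifest`.
#' @export
run_pipeline <- function(data, mode = "gene", flank = 50000,
                         coexpr_tissue = "cortex", adjacency_min = 0.1,
                         stringent_min = 0.3, min_shared = 2,
                         cerna_alpha = 0.01, fdr_max = 0.5, top_k = 15,
                         region_alpha = 0.05, hr_mode = "pooled") {
  ann <- data$annotation
  expr <- data$expr

  # -- variant mapping ------------------------------------------------------
  hits_by_mode <- stats::setNames(
    lapply(hit_modes(), function(m) identify_lncRNAs(data$variants, ann, m)),
    hit_modes())
  hits <- hits_by_mode[[mode]]
  containment <- containment_report(hits_by_mode)
  cnvs <- data$variants[data$variants$class == "CNV", , drop = FALSE]
  cnv_val <- if (nrow(cnvs) > 0) {
    list(direct = cnv_validation(hits, ann, new_variants(cnvs)),
         excluded = cnv_validation(hits, ann, new_variants(cnvs),
                                   variants = data$variants, exclude = cnvs))
  } else NULL
  subclass <- subclass_distribution(hits, ann)
  genomic <- genomic_neighbors(hits, ann, flank = flank)

  # -- expression metrics ---------------------------------------------------
  med <- tissue_medians(expr)
  tau <- tau_index(med)
  brain <- brain_index(med, intersect(expr$brain_tissues, colnames(med)))
  background <- setdiff(lncRNA_ids(ann), hits$ids)
  scores <- stats::setNames(data$scores$score, data$scores$gene_id)
  comparisons <- list(
    importance = compare_groups(scores[hits$ids], scores[background],
                                labels = c("hit", "background")),
    tau = compare_groups(tau[hits$ids], tau[background],
                         labels = c("hit", "background")),
    brain_index = compare_groups(brain[hits$ids], brain[background],
                                 labels = c("hit", "background")))

  # -- co-expression networks (one per brain region) ------------------------
  brain_regions <- intersect(expr$brain_tissues, unique(expr$sample_tissue))
  if (!coexpr_tissue %in% brain_regions) coexpr_tissue <- brain_regions[1]
  networks <- stats::setNames(
    lapply(brain_regions, function(t) build_tissue_network(expr, t)),
    brain_regions)
  coexpr_by_region <- lapply(networks, function(net)
    suppressWarnings(coexpr_neighbors(net, hits$ids, ann, adjacency_min)))
  coexpr_default <- coexpr_by_region[[coexpr_tissue]]
  coexpr_stringent <- suppressWarnings(
    coexpr_neighbors(networks[[coexpr_tissue]], hits$ids, ann, stringent_min))

  # -- ceRNA ----------------------------------------------------------------
  cerna_pairs <- suppressWarnings(
    cerna_neighbors(data$interactions, hits$ids, ann,
                    min_shared = min_shared, alpha = cerna_alpha))
  cerna_sets <- cerna_neighbor_sets(cerna_pairs, hits$ids)

  # -- enrichment -----------------------------------------------------------
  universe <- coding_ids(ann)
  neighbor_lists <- list(
    genomic = unique(unlist(genomic)),
    cerna = unique(unlist(cerna_sets)),
    coexpr = unique(unlist(coexpr_default)))
  oras <- lapply(neighbor_lists, function(g) {
    g <- intersect(g, universe)
    if (length(g) == 0) return(NULL)
    ora(g, data$pathways, universe)
  })
  region_genes <- lapply(coexpr_by_region, function(s) unique(unlist(s)))
  region_matrix <- if (length(region_genes) >= 2) {
    suppressWarnings(region_comparison(region_genes, data$pathways, universe,
                                       top_k = top_k, alpha = region_alpha))
  } else NULL
  known <- suppressWarnings(tryCatch(
    known_gene_proportion(genomic, genomic_neighbors(background, ann, flank),
                          data$known_genes),
    error = function(e) NULL))

  # -- drugs ----------------------------------------------------------------
  altered <- altered_pathways(Filter(Negate(is.null), oras), fdr_max = fdr_max)
  drug_rank <- drug_enrichment(altered, data$drugs, names(data$pathways))

  # -- integration ----------------------------------------------------------
  hr <- high_reliability(genomic, cerna_sets, coexpr_stringent, mode = hr_mode)
  thresholds <- list(mode = mode, flank = flank,
                     coexpr_tissue = coexpr_tissue,
                     adjacency_min = adjacency_min,
                     stringent_min = stringent_min, min_shared = min_shared,
                     cerna_alpha = cerna_alpha, fdr_max = fdr_max,
                     top_k = top_k, region_alpha = region_alpha,
                     hr_mode = hr_mode)
  report <- assemble_report(hits, ann, tau, brain, genomic, cerna_sets,
                            coexpr_default, hr, thresholds = thresholds)
  list(hits_by_mode = hits_by_mode, hits = hits, containment = containment,
       cnv_validation = cnv_val, subclass = subclass, genomic = genomic,
       tau = tau, brain = brain, comparisons = comparisons,
       networks = networks, coexpr_by_region = coexpr_by_region,
       coexpr = coexpr_default, coexpr_stringent = coexpr_stringent,
       cerna_pairs = cerna_pairs, cerna = cerna_sets, oras = oras,
       region_matrix = region_matrix, known_gene = known,
       altered_pathways = altered, drug_rank = drug_rank,
       high_reliability = hr, report = report,
       manifest = attr(report, "manifest"))
}
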