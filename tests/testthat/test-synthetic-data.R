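test_that("configuration is validated", {
  expect_s3_class(synthetic_config(), "synthetic_config")
  expect_error(synthetic_config(n_lncRNA = 0), "positive count")
  expect_error(synthetic_config(planted_hit_fraction = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_config(within_module_cor = 1), "\\(0, 1\\)")
  expect_error(synthetic_config(pathway_size_range = c(10, 5)), "min <= max")
})

test_that("annotation generator: counts, subclasses, exon containment, sizing", {
  cfg <- synthetic_config(seed = 5, n_lncRNA = 10, n_protein_coding = 20,
                          chrom_length = 2e6, n_chromosomes = 1)
  ann <- generate_annotation(cfg)$annotation
  expect_equal(nrow(ann$genes), 30)
  expect_equal(length(lncRNA_ids(ann)), 10)
  expect_true(all(ann$genes$gene_type[match(lncRNA_ids(ann), ann$genes$gene_id)]
                  %in% lncRNA_types()))
  # every exon strictly inside its gene span (forced by the constructor,
  # re-checked directly)
  gi <- match(ann$exons$gene_id, ann$genes$gene_id)
  expect_true(all(ann$exons$start >= ann$genes$start[gi] &
                  ann$exons$end <= ann$genes$end[gi]))
  expect_true(all(table(ann$exons$gene_id) >= 1))
  expect_true(all(ann$genes$gene_id %in% ann$exons$gene_id))
  # infeasible packing
  expect_error(
    generate_annotation(synthetic_config(chrom_length = 1000, n_lncRNA = 500)),
    "chromosome too short")
})

test_that("antisense lncRNAs overlap a coding gene on the opposite strand; lincRNAs are intergenic", {
  ann <- default_fixture()$annotation
  g <- ann$genes
  coding <- g[g$gene_type == "protein_coding", ]
  for (i in which(g$gene_type == "antisense")) {
    host <- coding[coding$chrom == g$chrom[i] &
                   coding$start < g$end[i] & g$start[i] < coding$end, ]
    expect_gt(nrow(host), 0)
    expect_true(any(host$strand != g$strand[i]))
  }
  for (i in which(g$gene_type == "lincRNA")) {
    ov <- coding$chrom == g$chrom[i] &
      coding$start < g$end[i] & g$start[i] < coding$end
    expect_false(any(ov))
  }
})

test_that("variant generator plants the exact hit fraction and real overlaps", {
  cfg <- synthetic_config(seed = 7, n_lncRNA = 10, n_protein_coding = 20,
                          chrom_length = 2e6, planted_hit_fraction = 0.5)
  ann <- generate_annotation(cfg)$annotation
  v <- generate_variants(cfg, ann)
  expect_length(v$planted_lncRNA_hits, 5)
  # every planted lncRNA overlaps >= 1 variant: brute-force re-intersection
  support <- brute_hits(v$variants, ann, "gene")
  expect_true(all(v$planted_lncRNA_hits %in% names(support)))
  # boundary: no planting
  cfg0 <- synthetic_config(seed = 7, n_lncRNA = 10, n_protein_coding = 20,
                           chrom_length = 2e6, planted_hit_fraction = 0)
  expect_length(generate_variants(cfg0, ann)$planted_lncRNA_hits, 0)
  expect_true(all(v$variants$class %in% c("SNV", "Indel", "CNV")))
})

test_that("expression generator: module correlation, degenerate limit, sizing", {
  cfg <- synthetic_config(seed = 11, n_tissues = 1, samples_per_tissue = 50,
                          n_modules = 1, module_size = 20,
                          within_module_cor = 0.8)
  ge <- generate_expression(cfg, default_fixture()$annotation)
  mod <- ge$modules[[1]]
  cm <- cor(t(ge$expr$values[mod, ]))
  expect_gte(mean(cm[upper.tri(cm)]), 0.6)
  expect_lte(mean(cm[upper.tri(cm)]), 0.9)
  expect_true(all(ge$expr$values >= 0))
  # noise_sd = 0, single factor: module correlations exactly 1
  cfg0 <- synthetic_config(seed = 11, n_tissues = 1, samples_per_tissue = 10,
                           n_modules = 1, module_size = 10, noise_sd = 0)
  ge0 <- generate_expression(cfg0, default_fixture()$annotation)
  cm0 <- cor(t(ge0$expr$values[ge0$modules[[1]], ]))
  expect_equal(unname(cm0[upper.tri(cm0)]), rep(1, sum(upper.tri(cm0))),
               tolerance = 1e-12)
  expect_error(
    generate_expression(synthetic_config(n_modules = 30, module_size = 20),
                        default_fixture()$annotation),
    "sizing error")
})

test_that("interaction generator injects shared miRNAs for planted pairs", {
  d <- default_fixture()
  pp <- d$ground_truth$planted_cerna_pairs
  expect_gt(nrow(pp), 0)
  targets <- split(d$interactions$miRNA_id, d$interactions$gene_id)
  for (i in seq_len(nrow(pp))) {
    shared <- length(intersect(targets[[pp$lncRNA[i]]], targets[[pp$gene[i]]]))
    expect_gte(shared, 3)
  }
  # boundary: no planting adds nothing beyond the random edges
  cfg0 <- synthetic_config(seed = 3, n_planted_cerna_pairs = 0)
  i0 <- generate_interactions(cfg0, d$annotation)
  expect_equal(nrow(i0$planted_cerna_pairs), 0)
  expect_lte(nrow(i0$interactions), cfg0$n_mirnas * cfg0$targets_per_mirna)
})

test_that("gene-set and drug generator: counts, planted overlap, sizing", {
  d <- default_fixture()
  cfg <- d$config
  expect_length(d$pathways, cfg$n_pathways)
  expect_length(d$drugs, cfg$n_drugs)
  sizes <- lengths(d$pathways)
  expect_true(all(sizes >= cfg$pathway_size_range[1] &
                  sizes <= cfg$pathway_size_range[2]))
  gt <- d$ground_truth
  for (dr in gt$planted_effective_drugs) {
    planted <- c(gt$planted_enriched_pathways,
                 gt$region_specific_pathway[!is.na(gt$region_specific_pathway)])
    expect_gte(length(intersect(d$drugs[[dr]], planted)),
               length(d$drugs[[dr]]) / 2)
  }
  expect_error(
    generate_genesets_and_drugs(
      synthetic_config(pathway_size_range = c(10, 5000)), d$annotation),
    "sizing error")
})

test_that("non-planted drug overlap is hypergeometric-null (one-sided KS over seeds)", {
  # null world: no planted hits threaded through, fixed reference altered set
  d <- default_fixture()
  altered <- sprintf("pw_%03d", 1:8)
  ps <- vapply(1:200, function(s) {
    cfg <- synthetic_config(seed = 1000 + s)
    gs <- generate_genesets_and_drugs(cfg, d$annotation)
    dr <- gs$drugs[[cfg$n_drugs]]  # never planted
    k <- length(intersect(dr, altered))
    phyper(k - 1, length(dr), cfg$n_pathways - length(dr), length(altered),
           lower.tail = FALSE)
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif", alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
})

test_that("generated files are byte-identical under the same seed", {
  cfg <- synthetic_config(seed = 202, n_lncRNA = 20, n_protein_coding = 40,
                          chrom_length = 3e6, n_variants = 80,
                          samples_per_tissue = 8, module_size = 10,
                          targets_per_mirna = 3, n_planted_cerna_pairs = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_synthetic_data(cfg, d1)
  generate_synthetic_data(cfg, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_equal(f1, f2)
  expect_equal(unname(tools::md5sum(file.path(d1, f1))),
               unname(tools::md5sum(file.path(d2, f2))))
})

test_that("referential integrity: every referenced id exists in the annotation", {
  d <- default_fixture()
  ids <- d$annotation$genes$gene_id
  expect_true(all(d$interactions$gene_id %in% ids))
  expect_true(all(unlist(d$pathways) %in% ids))
  expect_true(all(d$known_genes %in% ids))
  expect_true(all(names(d$drugs) == names(d$drugs)))
  expect_true(all(unlist(d$drugs) %in% names(d$pathways)))
  gt <- d$ground_truth
  expect_true(all(gt$planted_lncRNA_hits %in% ids))
  expect_true(all(unlist(gt$planted_modules) %in% ids))
  expect_true(all(gt$planted_cerna_pairs$lncRNA %in% ids))
  expect_true(all(gt$planted_cerna_pairs$gene %in% ids))
  expect_true(all(gt$planted_enriched_pathways %in% names(d$pathways)))
  expect_true(all(gt$planted_effective_drugs %in% names(d$drugs)))
})

test_that("round trip through files preserves the bundle", {
  cfg <- synthetic_config(seed = 303, n_lncRNA = 15, n_protein_coding = 30,
                          chrom_length = 3e6, n_variants = 60,
                          samples_per_tissue = 6, module_size = 8,
                          targets_per_mirna = 3, n_planted_cerna_pairs = 5,
                          pathway_size_range = c(5, 15))
  dir <- withr::local_tempdir()
  d <- generate_synthetic_data(cfg, dir)
  r <- read_pipeline_inputs(dir)
  expect_equal(r$annotation$genes, d$annotation$genes)
  expect_equal(r$annotation$exons[order(r$annotation$exons$gene_id,
                                        r$annotation$exons$start), ],
               d$annotation$exons[order(d$annotation$exons$gene_id,
                                        d$annotation$exons$start), ],
               ignore_attr = TRUE)
  expect_equal(as.data.frame(r$variants), as.data.frame(d$variants))
  expect_equal(r$expr$values, d$expr$values)
  expect_equal(r$expr$sample_tissue, d$expr$sample_tissue)
  expect_equal(sort(r$expr$brain_tissues), sort(d$expr$brain_tissues))
  expect_equal(r$interactions, d$interactions)
  expect_equal(r$pathways, d$pathways)
  expect_equal(r$drugs, d$drugs)
  expect_equal(r$known_genes, d$known_genes)
})
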