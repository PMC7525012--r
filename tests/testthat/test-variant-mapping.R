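simple_ann <- function() {
  toy_annotation(list(
    list(id = "L1", type = "lincRNA", chrom = "chr1", start = 50, end = 200),
    list(id = "L2", type = "antisense", chrom = "chr1", start = 1000,
         end = 2000, strand = "-"),
    list(id = "P1", type = "protein_coding", chrom = "chr1", start = 300,
         end = 500)))
}

test_that("identify_lncRNAs: half-open overlap and boundary behavior", {
  ann <- simple_ann()
  h <- identify_lncRNAs(toy_variants(list("chr1", 100, 101)), ann, "gene")
  expect_equal(h$ids, "L1")
  expect_equal(unname(h$support["L1"]), 1L)
  # [200, 201) touches the half-open end of [50, 200): no hit
  h2 <- identify_lncRNAs(toy_variants(list("chr1", 200, 201)), ann, "gene")
  expect_false("L1" %in% h2$ids)
  # coding genes never reported
  h3 <- identify_lncRNAs(toy_variants(list("chr1", 400, 401)), ann, "gene")
  expect_length(h3$ids, 0)
})

test_that("minus-strand promoter is 5 kb downstream-in-coordinates of the gene end", {
  ann <- simple_ann()
  # L2 is [1000, 2000) on '-': promoter = [2000, 7000)
  v <- toy_variants(list("chr1", 6999, 7000))
  expect_false("L2" %in% identify_lncRNAs(v, ann, "gene")$ids)
  expect_false("L2" %in% identify_lncRNAs(v, ann, "exon")$ids)
  expect_true("L2" %in% identify_lncRNAs(v, ann, "gene_plus_promoter")$ids)
  # one base past the promoter end: no hit in any mode
  v2 <- toy_variants(list("chr1", 7000, 7001))
  expect_false("L2" %in% identify_lncRNAs(v2, ann, "gene_plus_promoter")$ids)
})

test_that("exon mode hits only exon bases", {
  ann <- toy_annotation(list(
    list(id = "L1", type = "lincRNA", chrom = "chr1", start = 0, end = 1000,
         exons = list(c(100, 200), c(700, 800)))))
  expect_true("L1" %in%
    identify_lncRNAs(toy_variants(list("chr1", 150, 151)), ann, "exon")$ids)
  intronic <- toy_variants(list("chr1", 400, 401))
  expect_false("L1" %in% identify_lncRNAs(intronic, ann, "exon")$ids)
  expect_true("L1" %in% identify_lncRNAs(intronic, ann, "gene")$ids)
})

test_that("empty variant sets and chromosome mismatches are handled", {
  ann <- simple_ann()
  empty <- new_variants(data.frame(chrom = character(), start = integer(),
                                   end = integer(), class = character()))
  h <- identify_lncRNAs(empty, ann, "gene")
  expect_length(h$ids, 0)
  expect_warning(identify_lncRNAs(toy_variants(list("chrX", 10, 11)), ann, "gene"),
                 "chrX")
})

test_that("duplicate gene ids are rejected at construction", {
  expect_error(toy_annotation(list(
    list(id = "A", type = "lincRNA", chrom = "chr1", start = 0, end = 100),
    list(id = "A", type = "lincRNA", chrom = "chr1", start = 200, end = 300))),
    "duplicate gene ids")
})

test_that("identify_lncRNAs agrees with the brute-force all-pairs oracle", {
  set.seed(42)
  n_genes <- 60; n_var <- 300
  types <- sample(c(lncRNA_types(), "protein_coding"), n_genes, replace = TRUE)
  genes <- lapply(seq_len(n_genes), function(i) {
    s <- sample(0:9e5, 1); len <- sample(500:5000, 1)
    ex_s <- s + sample(1:100, 1); ex_e <- s + len - sample(1:100, 1)
    list(id = sprintf("g%03d", i), type = types[i],
         chrom = sample(c("chr1", "chr2"), 1), start = s, end = s + len,
         strand = sample(c("+", "-"), 1), exons = list(c(ex_s, ex_e)))
  })
  ann <- toy_annotation(genes)
  st <- sample(0:1e6, n_var); len <- sample(c(1, 10, 5000), n_var, replace = TRUE)
  v <- new_variants(data.frame(
    chrom = sample(c("chr1", "chr2"), n_var, replace = TRUE),
    start = st, end = st + len,
    class = sample(c("SNV", "Indel", "CNV"), n_var, replace = TRUE)))
  for (mode in c("gene", "exon", "gene_plus_promoter")) {
    h <- identify_lncRNAs(v, ann, mode)
    oracle <- brute_hits(v, ann, mode)
    expect_equal(sort(h$ids), sort(names(oracle)), info = mode)
    expect_equal(h$support[sort(h$ids)], oracle[sort(names(oracle))],
                 info = mode)
  }
})

test_that("containment_report covers identity, disjoint and NA cases", {
  mk <- function(ids, mode = "gene") {
    structure(list(mode = mode, ids = ids,
                   support = stats::setNames(rep(1L, length(ids)), ids)),
              class = "lnc_hits")
  }
  m <- containment_report(list(a = mk(c("x", "y")), b = mk(c("x", "y"))))
  expect_equal(m["a", "b"], 100)
  m2 <- containment_report(list(a = mk(c("x", "y")), b = mk(c("p", "q", "r", "s"))))
  expect_equal(m2["a", "b"], 0)
  m3 <- containment_report(list(a = mk(c("x")), b = mk(character(0))))
  expect_true(is.na(m3["a", "b"]))
  expect_error(containment_report(list(a = mk("x"))), "at least two")
})

test_that("cnv_validation counts body overlaps and honors exclusion", {
  # 10 lncRNAs at 10 kb spacing; CNVs overlap the first 7
  genes <- lapply(1:10, function(i)
    list(id = sprintf("L%02d", i), type = "lincRNA", chrom = "chr1",
         start = i * 10000, end = i * 10000 + 1000))
  ann <- toy_annotation(genes)
  snvs <- new_variants(data.frame(
    chrom = "chr1", start = sapply(1:10, function(i) i * 10000 + 5),
    end = sapply(1:10, function(i) i * 10000 + 6), class = "SNV"))
  hits <- identify_lncRNAs(snvs, ann, "gene")
  expect_length(hits$ids, 10)
  cnvs <- new_variants(data.frame(chrom = "chr1", start = 9000, end = 75500,
                                  class = "CNV"))
  val <- cnv_validation(hits, ann, cnvs)
  expect_equal(val$fraction, 0.7)
  # brute-force cross-check
  brute <- sum(sapply(genes, function(g) g$start < 75500 && 9000 < g$end)) / 10
  expect_equal(val$fraction, brute)
  # saturation and zero
  expect_equal(cnv_validation(hits, ann,
    new_variants(data.frame(chrom = "chr1", start = 0, end = 2e5,
                            class = "CNV")))$fraction, 1)
  expect_equal(cnv_validation(hits, ann,
    new_variants(data.frame(chrom = "chr1", start = 5e5, end = 6e5,
                            class = "CNV")))$fraction, 0)
  # exclusion: dropping one lncRNA's only supporting variant removes it
  all_v <- rbind(as.data.frame(snvs))
  val2 <- cnv_validation(hits, ann, cnvs, variants = new_variants(all_v),
                         exclude = all_v[1, , drop = FALSE])
  expect_equal(val2$n_hits, 9)
  expect_error(cnv_validation(hits, ann, new_variants(
    data.frame(chrom = character(), start = integer(), end = integer(),
               class = character()))), "non-empty")
})

test_that("genomic_neighbors respects the flank and is monotone in it", {
  ann <- toy_annotation(list(
    list(id = "L1", type = "lincRNA", chrom = "chr1", start = 100000,
         end = 101000),
    list(id = "P_near", type = "protein_coding", chrom = "chr1",
         start = 111000, end = 112000),   # 10 kb away
    list(id = "P_far", type = "protein_coding", chrom = "chr1",
         start = 161001, end = 162001),   # 60 kb away
    list(id = "P_inside", type = "protein_coding", chrom = "chr1",
         start = 100500, end = 100600)))
  nb <- genomic_neighbors("L1", ann, flank = 50000)
  expect_setequal(nb$L1, c("P_near", "P_inside"))
  nb0 <- genomic_neighbors("L1", ann, flank = 0)
  expect_equal(nb0$L1, "P_inside")
  nb_all <- genomic_neighbors("L1", ann, flank = 70000)
  expect_true(all(nb$L1 %in% nb_all$L1))
  expect_true(all(nb0$L1 %in% nb$L1))
  expect_error(genomic_neighbors("L1", ann, flank = -1), ">= 0")
})

test_that("subclass_distribution proportions sum to one", {
  ann <- toy_annotation(c(
    lapply(1:6, function(i) list(id = paste0("li", i), type = "lincRNA",
                                 chrom = "chr1", start = i * 1000,
                                 end = i * 1000 + 500)),
    lapply(1:4, function(i) list(id = paste0("as", i), type = "antisense",
                                 chrom = "chr1", start = 20000 + i * 1000,
                                 end = 20000 + i * 1000 + 500))))
  v <- new_variants(data.frame(chrom = "chr1", start = 0, end = 30000,
                               class = "CNV"))
  hits <- identify_lncRNAs(v, ann, "gene")
  d <- subclass_distribution(hits, ann)
  expect_equal(sum(d$proportion), 1)
  expect_equal(d$proportion[d$subclass == "lincRNA"], 0.6)
  expect_equal(d$proportion[d$subclass == "antisense"], 0.4)
})
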