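# lncseed

Genome-variant-derived functional annotation of long non-coding RNAs
(lncRNAs), and pathway-level drug repositioning — with a synthetic-data
generator that plants ground truth so the whole pipeline can be validated
end to end.

## What it does, for whom

Disease cohorts yield genomic variants; many fall in lncRNA loci whose
function is unknown. For analysts holding (i) a gene annotation, (ii) a
variant set, (iii) an expression compendium with tissue labels, (iv) an
miRNA–target table, and (v) pathway / drug-pathway gene-set collections,
`lncseed` runs the full variant-to-function chain:

1. **Identify** hit lncRNAs by interval intersection (gene body, exon
   union, or gene + 5 kb strand-aware promoter), with containment
   reporting across modes and validation against an independent CNV set.
2. **Characterize** them: tissue-specificity index
   τ = Σᵢ(1 − xᵢ/max x)/(N−1), brain expression index
   (median over brain tissues ÷ median over all tissues), and
   importance-score comparison of hits vs background lncRNAs
   (two-sided Wilcoxon rank-sum, exact for small tie-free groups).
3. **Collect three neighbor classes** per hit lncRNA: genomic neighbors
   (protein-coding genes within ±50 kb), ceRNA partners (≥ 2 shared miRNA
   regulators, hypergeometric p and joint BH FDR ≤ 0.01), and
   co-expression neighbors from per-brain-region unsigned WGCNA-style
   networks (adjacency |cor|^β ≥ 0.1; β chosen by scale-free topology
   fit).
4. **Enrich**: hypergeometric ORA of each neighbor class against GMT
   collections over the protein-coding universe, plus a term × brain-region
   −log₁₀(p) comparison matrix.
5. **Integrate**: high-reliability neighbors = genes in ≥ 2 of the three
   classes (stringent co-expression threshold 0.3), exported with Venn
   memberships, plus a per-lncRNA report.
6. **Reposition drugs**: pathways with ORA FDR ≤ 0.5 form the altered
   list; each drug's induced pathway set is tested one-sided (Fisher
   exact = hypergeometric tail) against it over the full pathway
   background, BH-corrected across drugs.

## Worked example

```r
library(lncseed)

cfg    <- synthetic_config(seed = 101)   # 200 genes, 6 tissues x 20 samples
bundle <- generate_synthetic_data(cfg)   # in memory; pass dir= to write files
res    <- run_pipeline(bundle)

bundle$annotation
#> lnc_annotation: 200 genes ( 60 lncRNA, 140 protein-coding ), 406 exons on 2 chromosome(s)
res$hits
#> lnc_hits (mode = gene): 39 lncRNA(s), total variant support 77
round(res$containment, 2)
#>                     contained
#> containing             gene exon gene_plus_promoter
#>   gene               100.00  100             100.00
#>   exon                66.67  100              66.67
#>   gene_plus_promoter 100.00  100             100.00
```

Gene-mode hits contain 100% of exon-mode hits (forced by exon ⊂ gene;
the pipeline measures it rather than assuming it), while exon-mode
recovers only 66.67% of gene-mode hits — intronic variants are invisible
to exon-level annotation.

```r
res$comparisons$tau$medians          # hit vs background lncRNAs
#>        hit background
#> 0.54414443 0.03240162
signif(res$comparisons$tau$p, 3)     # planted tissue-specificity detected
#> [1] 2.26e-07
signif(res$comparisons$importance$p, 3)  # planted low-importance detected
#> [1] 0.00113

res$networks$cortex
#> coexpr_network (tissue = cortex): 150 genes, beta = 9, scale-free fit R^2 = 0.001

head(res$drug_rank[, c("drug", "overlap", "set_size", "p", "fdr")], 4)
#>      drug overlap set_size          p       fdr
#> 1 drug_01       4        8 0.04069878 0.1356626
#> 2 drug_02       4        8 0.04069878 0.1356626
#> 3 drug_03       4        8 0.04069878 0.1356626
#> 4 drug_08       3        8 0.18777291 0.4694323

length(res$high_reliability$genes)
#> [1] 16
head(res$report, 3)
#>   gene_id       subclass n_variants       tau brain_index n_genomic n_cerna n_coexpr n_high_reliability
#> 1   G0003        lincRNA          1 0.5173001   0.9458823         0       0       12                  4
#> 2   G0006 sense_intronic          3 0.5462686   1.0359860         0       1       12                  5
#> 3   G0007     non_coding          2 0.5541354   0.9949942         1       0       13                  5
```

The three planted drugs (`drug_01..03`) rank first; the ground truth in
`bundle$ground_truth` lets you check every stage the same way
(`bundle$ground_truth$planted_lncRNA_hits` are all among `res$hits$ids`,
planted ceRNA pairs are all recovered in `res$cerna_pairs`, and so on —
the test suite asserts exactly that).

## Command line

A thin CLI wraps the same functions (`inst/cli/lncseed.R`; installed under
`system.file("cli", "lncseed.R", package = "lncseed")`):

```sh
Rscript inst/cli/lncseed.R simulate --out demo --seed 11
Rscript inst/cli/lncseed.R identify --variants demo/variants.bed \
    --gtf demo/genes.gtf --mode gene --out demo/hits.tsv
Rscript inst/cli/lncseed.R run --dir demo        # full pipeline -> demo/results/
```

## Layout

* `R/` — implementation: `synthetic.R` (generators + ground truth),
  `variant_mapping.R`, `expression.R`, `coexpression.R`, `cerna.R`,
  `enrichment.R`, `drugs.R`, `integration.R` (pipeline + report).
* `vignettes/lncseed-methods.Rmd` — model, assumptions, parameter
  rationale, synthetic-world design, numerical choices, limitations.
* `tests/testthat/` — unit + property tests per module, brute-force and
  enumeration oracles, and `test-acceptance.R` (one block per acceptance
  criterion).
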