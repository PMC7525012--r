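---
title: "lncseed: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncseed: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(lncseed)
```

## The problem

Long non-coding RNAs (lncRNAs) rarely come with functional annotation.
When genomic variants from affected individuals fall inside lncRNA loci,
two questions follow: *which* lncRNAs are hit, and *what might they do*?
`lncseed` implements a genome-variant-to-function pipeline that answers the
second question by proxy: it collects three independent classes of
protein-coding "functional neighbor" genes for each hit lncRNA — genomic
neighbors (cis candidates), competing-endogenous-RNA (ceRNA) partners
(shared miRNA regulators), and weighted co-expression neighbors — runs
over-representation analysis (ORA) on each class, intersects them into a
high-reliability set, and finally ranks drugs whose induced pathway sets
are over-represented in the disease-altered pathway list.

Every stage is exercisable end to end on synthetic data with planted
ground truth, so the package can demonstrate — not merely assert — that
each inference step recovers what was put in.

## Stage by stage

### Variant-to-lncRNA intersection

Coordinates are 0-based half-open internally (the BED convention); GTF
input is converted at parse time. Overlap means at least one shared base;
no reciprocal-overlap fraction is required, for CNVs or anything else.
Three annotation modes are supported: the gene body, the exon union, and
the gene body plus a strand-aware promoter (5 kb upstream of the
transcription start, clipped at zero, deliberately not clipped by
neighboring genes). Because exons are contained in gene bodies, the
exon-mode hit list is a subset of the gene-mode list by construction —
the pipeline's containment report makes that a measured 100%, and the hit
sets nest monotonically across the three modes.

Validation against an independent CNV set counts the fraction of hit
lncRNAs whose *gene body* overlaps at least one CNV; a CNV touching only
a promoter does not count. To guard against circularity the validation
can first re-derive the hit list from the variant set minus the CNV
records (exact-match exclusion).

### Expression characterization

Per-tissue expression is collapsed to the tissue median before any index
is computed. The tissue-specificity index is

$$\tau = \frac{\sum_{i=1}^{N}(1 - x_i/\max_j x_j)}{N - 1} \in [0, 1],$$

0 for uniform and 1 for single-tissue expression; all-zero genes yield
`NA` rather than a value. The brain expression index is the median over
brain tissues divided by the median over all tissues (`NA` when the
overall median is zero). Both are invariant to rescaling the expression
vector.

Group comparisons use the two-sided Wilcoxon rank-sum test: exact when
both groups have at most 25 values and no ties, otherwise the normal
approximation with midranks and continuity correction. Differential
expression calls use fold change on group means with a pseudocount of
0.1 TPM — `FC = (mean_case + 0.1)/(mean_control + 0.1)` — and require
`FC > 1.5` or `FC < 1/1.5` (strict) *and* rank-sum `p < 0.05`. The
pseudocount and the mean-based FC are package choices; the thresholds are
the conventional ones. Under a pure null the caller's false-call rate is
bounded by the p-threshold (the FC gate only removes calls), which the
test suite verifies on 1,000 null genes.

### Co-expression networks

One unsigned weighted network per brain region, built from that region's
samples only:

1. **MAD filter** — keep the top 75% of genes by median absolute
   deviation (unscaled `median(|x - median(x)|)`), dropping
   low-variation genes that would contribute only correlation noise.
2. **Outlier samples** — average-linkage clustering on Euclidean sample
   distance; the tree is cut at the 0.99 quantile of merge heights and
   singleton branches above the cut are removed, never more than 10% of
   samples. On i.i.d. data this removes nothing almost always.
3. **Soft threshold** — for each candidate power $\beta \in 1..20$ the
   unsigned adjacency $a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$ is formed
   and the scale-free fit computed as the $R^2$ of
   $\log_{10} p(k)$ on $\log_{10} k$ over 10 equal-width connectivity
   bins, keeping empty bins at their midpoints with
   $p(k) + 10^{-9}$ inside the log (the formulation of the reference
   WGCNA implementation), sign-flipped when the slope is positive. The
   smallest $\beta$ reaching $R^2 \ge 0.85$ wins.
4. **Fallback power** — when no candidate reaches the target (common on
   small desk-scale matrices, whose sampling-noise correlations flatten
   the topology), the best-fitting power is *not* used: on weakly
   scale-free data it runs away to the top of the candidate range and
   annihilates all adjacencies. Instead the sample-size-based default
   power for unsigned networks is taken (9 / 8 / 7 / 6 for fewer than
   20 / 30 / 40 / more samples), which is standard WGCNA practice. The
   spec-level `pick_soft_threshold()` still exposes the best-fit
   fallback with a warning; the substitution happens only in the
   pipeline wrapper `build_tissue_network()` and is recorded on the
   returned network.

A lncRNA's co-expression neighbors are the protein-coding genes whose
adjacency to it reaches a threshold: 0.1 by default, 0.3 for the
stringent run that feeds the high-reliability intersection. Neighbor
definition by direct adjacency (rather than module co-membership) is a
deliberate design choice: it is simpler, monotone in both $\beta$ and the
threshold, and directly testable. Module detection (TOM, dynamic tree
cut, eigengenes) is out of scope.

### ceRNA inference

For each (lncRNA, protein-coding gene) pair the shared miRNA-regulator
count is tested against the hypergeometric upper tail
$P(X \ge \text{shared})$ with the universe equal to the number of
distinct miRNAs in the interaction table — made explicit because the
upstream databases never state theirs. Benjamini–Hochberg FDR is applied
jointly across *all* tested pairs, not per lncRNA. A pair is kept iff
shared $\ge 2$, $p \le 0.01$ and FDR $\le 0.01$. We compute the
hypergeometric p ourselves rather than consuming a precomputed pair
p-value, since the provenance of the latter is ambiguous in the sources
this emulates.

### Enrichment and the region comparison

ORA uses the plain hypergeometric upper tail on the 2×2 counts with BH
FDR across the collection. The universe is all protein-coding genes of
the annotation — explicit and closed, unlike web-service defaults. Terms
with fewer than 3 universe genes are skipped for stability. The EASE
variant (k−1 in the tail) used by some web servers is deliberately not
implemented; with desk-scale counts it only inflates conservatism and
its provenance is the tool, not the method.

The brain-region comparison runs ORA per region on that region's
co-expression neighbors; rows are the union of each region's top 15
terms with `p < 0.05`, cells hold `-log10(p)` where the term passes in
that region and `NA` otherwise. The statistic is a package choice (the
emulated figure's color scale is unstated).

### Drug repositioning

The disease-altered pathway list is the union, across the three neighbor
categories, of pathways with ORA FDR ≤ 0.5 — permissive by design, so the
list has workable size; the threshold and the union (rather than a single
category) are both exposed as arguments. Each drug's induced pathway set
is then tested one-sided (enrichment) against the altered list over the
full pathway background with Fisher's exact test — computed as the
hypergeometric tail, which is the same number, and cross-checked against
`fisher.test()` in the suite — with BH FDR across drugs.

### High-reliability neighbors

A gene is high-reliability when it appears in at least two of
{genomic, ceRNA, stringent co-expression}. By default the categories are
pooled across lncRNAs before counting (the inclusive reading of a Venn
over three gene sets); the stricter per-lncRNA mode — a gene must occur
in two categories *of the same lncRNA* — is available via
`mode = "per_lncRNA"`. Both are implemented because the emulated analysis
does not say which it used.

## The synthetic world

The generator plants every structure the pipeline is supposed to find,
under a single master seed with one RNG stream per generator (keyed by
generator name), so adding a generator never shifts another's output and
identical configurations produce byte-identical files.

* **Genome**: 2 chromosomes × 10 Mb, 200 genes (60 lncRNA across the five
  subclasses, 140 protein-coding), gene lengths 2–20 kb, minimum 1 kb
  gaps. Antisense lncRNAs are placed overlapping a protein-coding host on
  the opposite strand; lincRNAs are strictly intergenic; the remaining
  subclasses are placed intergenic as a simplification. Each gene gets
  1–3 exons strictly inside its span.
* **Variants**: half the lncRNAs are planted hits with 1–3 variants
  inside the gene body; the rest of the 300 records fall uniformly.
  Classes SNV (1 bp) / Indel (2–50 bp) / CNV (10–100 kb) at 70/20/10%.
* **Expression**: 6 tissues (3 brain regions, 3 non-brain) × 20 samples.
  A gene in module $m$ is
  $5 + \sqrt{\rho}\, f_{mt} + \sigma\sqrt{1-\rho}\,\varepsilon$, with
  $f_{mt}$ a per-tissue standard-normal factor and
  $\rho = 0.95$ by default; non-module genes get noise at 0.6 the scale,
  so the MAD filter separates them cleanly. Values are truncated at zero
  (the baseline of 5 makes truncation negligible) and rounded to 4
  decimals. The default modules are deliberately *tight* ($\rho = 0.95$):
  module recovery should not hinge on which soft power the data-driven
  selection lands on, and with $\rho = 0.95$ a within-module adjacency
  clears the 0.1 neighbor threshold for every candidate power up to 20.
  Real co-expression modules are looser; a green recovery test here
  establishes the plumbing, not performance on weak modules. The last
  module is active only in the first brain region — a planted
  region-specific signal for the region-comparison test. Planted-hit
  lncRNAs also receive a +6 TPM baseline in one random tissue (elevated
  tissue specificity, driving τ toward ~0.5 against a ~0 background).
* **Interactions**: 150 miRNAs × 10 targets each. Planted ceRNA pairs
  couple a planted-hit lncRNA with a coding gene from its own
  co-expression module where it has one — real ceRNA partners tend to be
  co-expressed, and without this convergence the three neighbor
  categories would almost never intersect at desk scale, leaving the
  high-reliability stage structurally empty. The number of injected
  shared miRNAs is calibrated from the configuration alone (smallest
  count driving the expected pair p below $10^{-8}$), so planted pairs
  survive the joint-FDR threshold with a wide margin while the spec-level
  minimum of 3 shared regulators always holds.
* **Gene sets and drugs**: 50 pathways of 10–40 coding genes. Four
  planted pathways draw 60% of their members from the genomic-neighbor
  pool of the planted hits; one more draws from the region-specific
  module. Three planted drugs take at least half of their 8 pathways from
  the planted set; the rest are uniform. The known-disease-gene list
  draws 70% from the planted-hit neighbor pool.
* **Importance scores**: planted-hit lncRNAs from Beta(1.5, 5), all other
  genes from Beta(3, 3) — hits score lower, emulating the reduced
  essentiality of the hit class. Scores are consumed from a file, never
  computed: the scoring model itself is out of scope.

What the generator does **not** emulate: realistic genome coordinates or
sequence content, read-level noise, batch effects, correlated miRNA
targeting, GO-style term hierarchy, or weak/overlapping co-expression
modules. Green tests establish correctness of the machinery on a world
whose effect sizes are deliberately clear, not sensitivity on marginal
real data.

## Numerical choices and degenerate inputs

* Hypergeometric tails via `phyper(k - 1, ..., lower.tail = FALSE)`;
  one-sided Fisher p-values are the same quantity by identity.
* BH FDR is the package's own step-up implementation (cummin over the
  reverse-sorted scaled p-values), verified against hand computation.
* Output tables sort by p with ties broken by id, so ranking is
  deterministic and input-order invariant.
* τ of an all-zero gene, the brain index under an all-zero overall
  median, and the known-gene proportion of a lncRNA without neighbors are
  `NA`, not 0 — absence of signal is not uniformity.
* Constant genes make correlations undefined: the network builders fail
  with the offending gene named rather than propagating `NA`s. Duplicate
  gene ids fail at parse time rather than being silently merged.
* Uniformity checks on discrete tail p-values use the *one-sided*
  Kolmogorov–Smirnov test (`alternative = "greater"`): such p-values are
  super-uniform by construction (an atom at p = 1 when the overlap is
  zero), so a two-sided KS would reject every correctly calibrated
  discrete test; the one-sided test rejects exactly the anti-conservative
  failures one cares about.
* All seeds derived from the master seed stay below $2^{31}$.

## Known limitations

* Co-expression neighbor extraction is β-sensitive by construction; the
  fixed adjacency thresholds (0.1 / 0.3) are calibrated for desk-scale
  fixtures and should be re-examined on real matrices (both are
  arguments everywhere they appear).
* The altered-pathway list inherits every upstream threshold; with very
  permissive FDR (0.5) it is a screening signature, not a claim of
  per-pathway significance.
* The per-lncRNA high-reliability mode is strictly harder to satisfy
  than the pooled default; on sparse desk-scale data it often returns an
  empty set, which is valid output.
* Coordinate-assembly conversion (liftOver) is out of scope; all inputs
  are assumed to share one assembly.
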