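# Synthetic data generation with planted ground truth.
#
# Every generator draws from its own RNG stream keyed by (seed, stream name)
# so the generators are independently reproducible, and the full set of
# files is byte-identical under the same configuration.

#' Configuration for the synthetic-data generators
#'
#' Defaults describe the standard fixture: 2 chromosomes of 10 Mb, 200 genes
#' (60 lncRNA + 140 protein-coding), 6 tissues (3 brain regions + 3
#' non-brain) with 20 samples each, 4 planted co-expression modules of 20
#' genes at within-module correlation 0.95 (deliberately tight, so module
#' recovery is robust to the data-driven soft threshold), an miRNA-target
#' table with 10 planted ceRNA pairs, and 50 pathways / 10 drugs with
#' planted enrichment.
#'
#' @param seed master integer seed (< 2^31).
#' @param n_chromosomes,chrom_length genome shape (bp per chromosome).
#' @param n_lncRNA,n_protein_coding gene counts.
#' @param n_variants total variant count; `planted_hit_fraction` of lncRNAs
#'   receive at least one overlapping variant, the remainder are uniform.
#' @param planted_hit_fraction proportion of lncRNAs planted as hits, in
#'   \[0, 1\].
#' @param n_tissues,samples_per_tissue expression design; the first
#'   `ceiling(n_tissues / 2)` tissues are brain regions.
#' @param n_modules,module_size,within_module_cor planted co-expression
#'   module structure; `within_module_cor` in (0, 1) is the target pairwise
#'   Pearson correlation inside a module.
#' @param n_mirnas,targets_per_mirna,n_planted_cerna_pairs miRNA-target
#'   table shape and number of planted ceRNA (lncRNA, coding gene) pairs.
#' @param n_pathways,pathway_size_range,n_drugs,pathways_per_drug gene-set
#'   and drug-set collection shape.
#' @param noise_sd expression noise scale (expression units; 0 gives
#'   noiseless module genes).
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chromosomes = 2L,
                             chrom_length = 10e6,
                             n_lncRNA = 60L,
                             n_protein_coding = 140L,
                             n_variants = 300L,
                             planted_hit_fraction = 0.5,
                             n_tissues = 6L,
                             samples_per_tissue = 20L,
                             n_modules = 4L,
                             module_size = 20L,
                             within_module_cor = 0.95,
                             n_mirnas = 150L,
                             targets_per_mirna = 10L,
                             n_planted_cerna_pairs = 10L,
                             n_pathways = 50L,
                             pathway_size_range = c(10L, 40L),
                             n_drugs = 10L,
                             pathways_per_drug = 8L,
                             noise_sd = 1) {
  cfg <- list(seed = as.integer(seed),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.numeric(chrom_length),
              n_lncRNA = as.integer(n_lncRNA),
              n_protein_coding = as.integer(n_protein_coding),
              n_variants = as.integer(n_variants),
              planted_hit_fraction = planted_hit_fraction,
              n_tissues = as.integer(n_tissues),
              samples_per_tissue = as.integer(samples_per_tissue),
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              within_module_cor = within_module_cor,
              n_mirnas = as.integer(n_mirnas),
              targets_per_mirna = as.integer(targets_per_mirna),
              n_planted_cerna_pairs = as.integer(n_planted_cerna_pairs),
              n_pathways = as.integer(n_pathways),
              pathway_size_range = as.integer(pathway_size_range),
              n_drugs = as.integer(n_drugs),
              pathways_per_drug = as.integer(pathways_per_drug),
              noise_sd = noise_sd)
  counts <- c("n_chromosomes", "chrom_length", "n_lncRNA", "n_protein_coding",
              "n_variants", "n_tissues", "samples_per_tissue", "n_modules",
              "module_size", "n_mirnas", "targets_per_mirna", "n_pathways",
              "n_drugs", "pathways_per_drug")
  for (f in counts) {
    if (length(cfg[[f]]) != 1 || is.na(cfg[[f]]) || cfg[[f]] <= 0) {
      stop("synthetic_config: '", f, "' must be a positive count")
    }
  }
  if (cfg$n_planted_cerna_pairs < 0) stop("n_planted_cerna_pairs must be >= 0")
  if (cfg$planted_hit_fraction < 0 || cfg$planted_hit_fraction > 1) {
    stop("planted_hit_fraction must lie in [0, 1]")
  }
  if (cfg$within_module_cor <= 0 || cfg$within_module_cor >= 1) {
    stop("within_module_cor must lie in (0, 1)")
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(cfg$pathway_size_range) != 2 ||
      cfg$pathway_size_range[1] > cfg$pathway_size_range[2] ||
      cfg$pathway_size_range[1] < 1) {
    stop("pathway_size_range must be (min, max) with 1 <= min <= max")
  }
  structure(cfg, class = "synthetic_config")
}

brain_region_names <- function() {
  c("cortex", "frontal_cortex_BA9", "anterior_cingulate_BA24", "cerebellum",
    "hippocampus", "hypothalamus", "amygdala")
}

nonbrain_tissue_names <- function() {
  c("liver", "lung", "heart", "kidney", "muscle", "skin", "pancreas",
    "spleen", "thyroid", "stomach")
}

synthetic_tissues <- function(cfg) {
  n_brain <- min(ceiling(cfg$n_tissues / 2), length(brain_region_names()))
  n_other <- cfg$n_tissues - n_brain
  if (n_other > length(nonbrain_tissue_names())) {
    stop("n_tissues too large for the built-in tissue name pool")
  }
  tissues <- c(brain_region_names()[seq_len(n_brain)],
               nonbrain_tissue_names()[seq_len(n_other)])
  list(tissues = tissues, brain = tissues[seq_len(n_brain)])
}

#' Generate a synthetic gene annotation
#'
#' Places non-overlapping gene bodies on both strands across the configured
#' chromosomes (lincRNAs and the other intergenic subclasses in intergenic
#' slots; antisense lncRNAs deliberately overlapping a protein-coding host
#' gene on the opposite strand), assigns each lncRNA one of the five
#' subclasses, and gives every gene 1-3 exons strictly inside its span.
#'
#' @param cfg a `synthetic_config`.
#' @param path optional GTF output path; `NULL` skips writing.
#' @return list with `annotation` (an `lnc_annotation`) and `path`.
#' @export
generate_annotation <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_rng(cfg$seed, "annotation", {
    min_len <- 2000; max_len <- 20000; min_gap <- 1000
    # subclass mix: intergenic classes dominate, antisense a large minority
    sub_probs <- c(lincRNA = 0.50, antisense = 0.25,
                   bidirectional_promoter_lncRNA = 0.10, non_coding = 0.10,
                   sense_intronic = 0.05)
    n_sub <- floor(sub_probs * cfg$n_lncRNA)
    n_sub["lincRNA"] <- n_sub["lincRNA"] + (cfg$n_lncRNA - sum(n_sub))
    subclasses <- sample(rep(names(n_sub), n_sub))
    n_anti <- sum(subclasses == "antisense")

    # slot-placed genes: all coding + non-antisense lncRNAs
    types_slot <- c(rep("protein_coding", cfg$n_protein_coding),
                    subclasses[subclasses != "antisense"])
    types_slot <- sample(types_slot)
    n_slot <- length(types_slot)
    chrom_of <- sort(rep_len(seq_len(cfg$n_chromosomes), n_slot))
    lens <- round(stats::runif(n_slot, min_len, max_len))

    genes <- vector("list", cfg$n_chromosomes)
    for (ch in seq_len(cfg$n_chromosomes)) {
      idx <- which(chrom_of == ch)
      need <- sum(lens[idx]) + (length(idx) + 1) * min_gap
      if (need > cfg$chrom_length) {
        stop("chromosome too short: chr", ch, " needs >= ", need,
             " bp to place ", length(idx), " genes with ", min_gap,
             " bp gaps, but chrom_length is ", format(cfg$chrom_length, scientific = FALSE))
      }
      slack <- cfg$chrom_length - need
      # distribute slack over the n+1 gaps by stick breaking
      w <- stats::runif(length(idx) + 1)
      extra <- floor(slack * w / sum(w))
      pos <- min_gap + extra[1]
      rows <- vector("list", length(idx))
      for (j in seq_along(idx)) {
        i <- idx[j]
        rows[[j]] <- data.frame(
          gene_type = types_slot[i], chrom = paste0("chr", ch),
          start = pos, end = pos + lens[i],
          strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
        pos <- pos + lens[i] + min_gap + extra[j + 1]
      }
      genes[[ch]] <- do.call(rbind, rows)
    }
    genes <- do.call(rbind, genes)

    # antisense lncRNAs overlap a protein-coding host on the opposite strand
    hosts <- which(genes$gene_type == "protein_coding")
    if (n_anti > 0 && length(hosts) == 0) {
      stop("antisense lncRNAs require at least one protein-coding gene")
    }
    if (n_anti > 0) {
      hsel <- sample(hosts, n_anti, replace = n_anti > length(hosts))
      hl <- genes$end[hsel] - genes$start[hsel]
      astart <- genes$start[hsel] + floor(stats::runif(n_anti, 0, 0.4) * hl)
      alen <- pmax(500, round(stats::runif(n_anti, 0.3, 0.9) * hl))
      aend <- pmin(astart + alen, cfg$chrom_length)
      anti <- data.frame(
        gene_type = "antisense", chrom = genes$chrom[hsel],
        start = astart, end = aend,
        strand = ifelse(genes$strand[hsel] == "+", "-", "+"),
        stringsAsFactors = FALSE)
      genes <- rbind(genes, anti)
    }
    o <- order(genes$chrom, genes$start, genes$end)
    genes <- genes[o, , drop = FALSE]
    rownames(genes) <- NULL
    genes$gene_id <- sprintf("G%04d", seq_len(nrow(genes)))
    genes <- genes[, c("gene_id", "gene_type", "chrom", "start", "end", "strand")]

    # 1-3 exons strictly inside each gene span
    exons <- lapply(seq_len(nrow(genes)), function(i) {
      n_ex <- sample(1:3, 1)
      lo <- genes$start[i] + 1; hi <- genes$end[i] - 1
      pts <- sort(sample(seq(lo, hi), 2 * n_ex))
      data.frame(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
                 start = pts[seq(1, 2 * n_ex, by = 2)],
                 end = pts[seq(2, 2 * n_ex, by = 2)],
                 stringsAsFactors = FALSE)
    })
    exons <- do.call(rbind, exons)
    ann <- new_annotation(genes, exons)
    if (!is.null(path)) write_annotation(ann, path)
    list(annotation = ann, path = path)
  })
}

#' Generate synthetic variants with planted lncRNA hits
#'
#' A fraction `planted_hit_fraction` of lncRNAs (rounded) is planted: each
#' planted lncRNA receives 1-3 variants placed inside its gene body.
#' Remaining variants are uniform over the genome. Each record carries one
#' of the classes SNV (1 bp), Indel (2-50 bp) or CNV (10-100 kb).
#'
#' @param cfg a `synthetic_config`.
#' @param annotation an `lnc_annotation` from [generate_annotation()].
#' @param path optional BED output path.
#' @return list with `variants` (a `variant_set`), `planted_lncRNA_hits`
#'   (gene ids) and `path`.
#' @export
generate_variants <- function(cfg, annotation, path = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"), inherits(annotation, "lnc_annotation"))
  with_rng(cfg$seed, "variants", {
    lnc <- lncRNA_ids(annotation)
    n_planted <- round(cfg$planted_hit_fraction * length(lnc))
    planted <- sort(if (n_planted > 0) sample(lnc, n_planted) else character(0))
    g <- annotation$genes

    draw_class <- function(n) sample(variant_classes(), n, replace = TRUE,
                                     prob = c(0.7, 0.2, 0.1))
    class_len <- function(cl) {
      vapply(cl, function(x) switch(x,
        SNV = 1L, Indel = sample(2:50, 1), CNV = sample(10000:100000, 1)),
        integer(1))
    }
    rows <- list()
    for (id in planted) {
      gi <- g[g$gene_id == id, ]
      nv <- sample(1:3, 1)
      cl <- draw_class(nv)
      st <- sample(seq(gi$start, gi$end - 1), nv, replace = TRUE)
      en <- pmin(st + class_len(cl), cfg$chrom_length)
      rows[[length(rows) + 1]] <- data.frame(chrom = gi$chrom, start = st,
                                             end = en, class = cl,
                                             stringsAsFactors = FALSE)
    }
    planted_df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 class = character(), stringsAsFactors = FALSE)
    n_rand <- max(0, cfg$n_variants - nrow(planted_df))
    if (n_rand > 0) {
      cl <- draw_class(n_rand)
      chrom <- paste0("chr", sample(seq_len(cfg$n_chromosomes), n_rand, replace = TRUE))
      st <- floor(stats::runif(n_rand, 0, cfg$chrom_length - 1))
      en <- pmin(st + class_len(cl), cfg$chrom_length)
      planted_df <- rbind(planted_df,
                          data.frame(chrom = chrom, start = st, end = en,
                                     class = cl, stringsAsFactors = FALSE))
    }
    v <- planted_df[order(planted_df$chrom, planted_df$start, planted_df$end), ,
                    drop = FALSE]
    rownames(v) <- NULL
    v <- new_variants(v)
    if (!is.null(path)) write_variants(v, path)
    list(variants = v, planted_lncRNA_hits = planted, path = path)
  })
}

#' Generate a synthetic expression matrix with planted modules
#'
#' Gene expression follows a latent-factor model: a gene in module m of
#' tissue t is `base + sqrt(rho) * f_mt + noise_sd * sqrt(1 - rho) * e`,
#' where `f_mt` is a per-sample standard normal factor and
#' `rho = within_module_cor`, so within-module pairwise correlation is
#' approximately `rho` (exactly 1 when `noise_sd = 0`). Non-module genes are
#' independent lower-variance noise. Values are shifted to a TPM-like
#' positive scale and truncated at 0. Modules other than the last are active
#' in every tissue; the last module is active only in the first brain region
#' (a planted region-specific signal). When `planted_lncRNAs` is supplied,
#' planted lncRNAs are spread across modules and each also receives an
#' elevated baseline in one random tissue (a planted tissue-specificity
#' signal).
#'
#' @param cfg a `synthetic_config`.
#' @param annotation an `lnc_annotation`.
#' @param planted_lncRNAs optional lncRNA ids to embed in modules.
#' @param path,sample_path optional output paths (expression TSV and
#'   sample-to-tissue map TSV).
#' @return list with `expr` (an `expr_matrix`), `modules` (module id to gene
#'   ids), `module_tissues` (module id to active tissue labels) and paths.
#' @export
generate_expression <- function(cfg, annotation, planted_lncRNAs = NULL,
                                path = NULL, sample_path = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"), inherits(annotation, "lnc_annotation"))
  with_rng(cfg$seed, "expression", {
    gene_ids <- annotation$genes$gene_id
    G <- length(gene_ids)
    if (cfg$n_modules * cfg$module_size > G) {
      stop("module sizing error: n_modules * module_size (",
           cfg$n_modules * cfg$module_size, ") exceeds gene count (", G, ")")
    }
    ts <- synthetic_tissues(cfg)
    tissues <- ts$tissues

    # module membership: planted lncRNAs spread across modules first,
    # remaining seats filled with protein-coding genes, then other genes
    planted_lncRNAs <- intersect(planted_lncRNAs %||% character(0), gene_ids)
    seats <- cfg$n_modules * cfg$module_size
    lnc_in <- utils::head(planted_lncRNAs, min(length(planted_lncRNAs),
                                               cfg$n_modules * floor(cfg$module_size / 2)))
    pool <- setdiff(coding_ids(annotation), lnc_in)
    fill <- sample(pool, min(seats - length(lnc_in), length(pool)))
    rest <- setdiff(gene_ids, c(lnc_in, fill))
    extra <- sample(rest, seats - length(lnc_in) - length(fill))
    members <- character(seats)
    # deal lncRNAs round-robin over modules, then fill the rest
    mod_of <- rep(seq_len(cfg$n_modules), each = cfg$module_size)
    half <- floor(cfg$module_size / 2)
    slot_matrix <- vapply(seq_len(cfg$n_modules),
                          function(m) which(mod_of == m)[seq_len(half)],
                          integer(half))
    lnc_slots <- as.vector(t(slot_matrix))[seq_along(lnc_in)]
    members[lnc_slots] <- lnc_in
    members[members == ""] <- sample(c(fill, extra))
    modules <- split(members, mod_of)
    names(modules) <- sprintf("module_%02d", seq_len(cfg$n_modules))
    module_tissues <- lapply(seq_len(cfg$n_modules), function(m) {
      if (cfg$n_modules > 1 && m == cfg$n_modules) ts$brain[1] else tissues
    })
    names(module_tissues) <- names(modules)
    module_of <- rep(NA_integer_, G); names(module_of) <- gene_ids
    for (m in seq_along(modules)) module_of[modules[[m]]] <- m

    # planted tissue-specificity: each planted lncRNA gets one boosted tissue
    boost_tissue <- if (length(planted_lncRNAs)) {
      stats::setNames(sample(tissues, length(planted_lncRNAs), replace = TRUE),
                      planted_lncRNAs)
    } else stats::setNames(character(0), character(0))

    base <- 5; boost <- 6; bg_sd_scale <- 0.6
    rho <- cfg$within_module_cor
    n_samp <- cfg$samples_per_tissue
    cols <- list(); col_tissue <- character(0)
    for (t in tissues) {
      f <- matrix(stats::rnorm(cfg$n_modules * n_samp), cfg$n_modules, n_samp)
      eps <- matrix(stats::rnorm(G * n_samp), G, n_samp)
      x <- matrix(base, G, n_samp)
      for (i in seq_len(G)) {
        m <- module_of[i]
        if (!is.na(m) && t %in% module_tissues[[m]]) {
          x[i, ] <- x[i, ] + sqrt(rho) * f[m, ] +
            cfg$noise_sd * sqrt(1 - rho) * eps[i, ]
        } else {
          x[i, ] <- x[i, ] + bg_sd_scale * cfg$noise_sd * eps[i, ]
        }
      }
      bt <- names(boost_tissue)[boost_tissue == t]
      if (length(bt)) x[match(bt, gene_ids), ] <- x[match(bt, gene_ids), ] + boost
      cols[[t]] <- x
      col_tissue <- c(col_tissue, rep(t, n_samp))
    }
    values <- do.call(cbind, cols)
    values <- round(pmax(values, 0), 4)
    rownames(values) <- gene_ids
    colnames(values) <- paste0(col_tissue, "_s",
                               sprintf("%02d", sequence(rep(n_samp, length(tissues)))))
    expr <- new_expression(values,
                           stats::setNames(col_tissue, colnames(values)),
                           brain_tissues = ts$brain)
    if (!is.null(path)) write_expression(expr, path, sample_path)
    list(expr = expr, modules = modules, module_tissues = module_tissues,
         path = path, sample_path = sample_path)
  })
}

# Smallest number of injected shared miRNAs that drives the planted pair's
# hypergeometric upper-tail p below `target`, given expected random set
# sizes. The injection count is calibrated from the configuration alone.
cerna_injection_size <- function(cfg, n_genes, target = 1e-8, min_inject = 3L) {
  exp_random <- cfg$n_mirnas * cfg$targets_per_mirna / n_genes
  for (j in min_inject:min(cfg$n_mirnas, 50L)) {
    s <- round(j + exp_random)
    p <- hyper_upper_tail(j, s, cfg$n_mirnas, s)
    if (p <= target) return(j)
  }
  stop("cannot calibrate ceRNA injection: miRNA universe too small")
}

#' Generate a synthetic miRNA-target interaction table
#'
#' Each miRNA targets `targets_per_mirna` random genes. For every planted
#' ceRNA pair (a planted-hit lncRNA and a protein-coding partner), a set of
#' shared miRNAs is injected into both target lists; the injection size is
#' calibrated so the pair passes the shared-count and hypergeometric
#' criteria with a wide margin.
#'
#' @param cfg a `synthetic_config`.
#' @param annotation an `lnc_annotation`.
#' @param planted_lncRNAs lncRNA ids eligible as planted ceRNA partners
#'   (defaults to all lncRNAs).
#' @param partner_pool optional named list mapping lncRNA id to preferred
#'   protein-coding partner ids (e.g. the lncRNA's co-expression module
#'   members, so the ceRNA and co-expression neighbor categories converge
#'   as they do for real transcripts); pairs fall back to random coding
#'   partners where the pool is empty.
#' @param path optional TSV output path (columns `miRNA_id`, `gene_id`).
#' @return list with `interactions` (data.frame), `planted_cerna_pairs`
#'   (data.frame `lncRNA`, `gene`) and `path`.
#' @export
generate_interactions <- function(cfg, annotation, planted_lncRNAs = NULL,
                                  partner_pool = NULL, path = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"), inherits(annotation, "lnc_annotation"))
  with_rng(cfg$seed, "interactions", {
    gene_ids <- annotation$genes$gene_id
    mirnas <- sprintf("mir_%03d", seq_len(cfg$n_mirnas))
    edges <- data.frame(
      miRNA_id = rep(mirnas, each = cfg$targets_per_mirna),
      gene_id = unlist(lapply(mirnas, function(m)
        sample(gene_ids, cfg$targets_per_mirna))),
      stringsAsFactors = FALSE)

    lnc_pool <- intersect(planted_lncRNAs %||% lncRNA_ids(annotation), gene_ids)
    coding <- coding_ids(annotation)
    n_pairs <- min(cfg$n_planted_cerna_pairs, length(lnc_pool), length(coding))
    pairs <- data.frame(lncRNA = character(0), gene = character(0),
                        stringsAsFactors = FALSE)
    if (n_pairs > 0) {
      lncs <- sample(lnc_pool, n_pairs, replace = n_pairs > length(lnc_pool))
      used <- character(0)
      partners <- vapply(lncs, function(l) {
        pref <- setdiff(intersect(partner_pool[[l]] %||% character(0), coding),
                        used)
        g <- if (length(pref)) sample(pref, 1) else
          sample(setdiff(coding, used), 1)
        used <<- c(used, g)
        g
      }, character(1))
      pairs <- data.frame(lncRNA = lncs, gene = unname(partners),
                          stringsAsFactors = FALSE)
      j <- cerna_injection_size(cfg, length(gene_ids))
      inj <- lapply(seq_len(n_pairs), function(i) {
        shared <- sample(mirnas, j)
        data.frame(miRNA_id = rep(shared, 2),
                   gene_id = rep(c(pairs$lncRNA[i], pairs$gene[i]), each = j),
                   stringsAsFactors = FALSE)
      })
      edges <- rbind(edges, do.call(rbind, inj))
    }
    edges <- unique(edges)
    edges <- edges[order(edges$miRNA_id, edges$gene_id), , drop = FALSE]
    rownames(edges) <- NULL
    if (!is.null(path)) {
      utils::write.table(edges, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    list(interactions = edges, planted_cerna_pairs = pairs, path = path)
  })
}

#' Generate synthetic pathway and drug gene-set collections
#'
#' Builds `n_pathways` pathway gene sets over the protein-coding genes.
#' A handful of planted pathways over-sample the genomic-neighbor genes of
#' the planted-hit lncRNAs (so the neighbor-gene ORA recovers them); one
#' additional planted pathway draws from the region-specific co-expression
#' module when `region_module_genes` is given. Drug pathway sets are built
#' over the pathway ids; planted drugs draw at least half their set from the
#' planted pathways. A known-disease-gene list enriched for planted-hit
#' neighbors is generated alongside.
#'
#' @param cfg a `synthetic_config`.
#' @param annotation an `lnc_annotation`.
#' @param planted_lncRNAs planted-hit lncRNA ids (drives the enrichment
#'   planting); `NULL` plants against a random coding pool.
#' @param region_module_genes optional gene ids of the region-specific
#'   module.
#' @param pathway_path,drug_path,known_path optional output paths (GMT, GMT,
#'   one-column TSV).
#' @return list with `pathways` / `drugs` (named lists of character
#'   vectors), `known_genes`, `planted_enriched_pathways`,
#'   `region_specific_pathway`, `planted_effective_drugs`, and paths.
#' @export
generate_genesets_and_drugs <- function(cfg, annotation, planted_lncRNAs = NULL,
                                        region_module_genes = NULL,
                                        pathway_path = NULL, drug_path = NULL,
                                        known_path = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"), inherits(annotation, "lnc_annotation"))
  with_rng(cfg$seed, "genesets", {
    coding <- coding_ids(annotation)
    rng <- cfg$pathway_size_range
    if (rng[2] > length(coding)) {
      stop("pathway sizing error: max pathway size (", rng[2],
           ") exceeds protein-coding gene count (", length(coding), ")")
    }
    # pool of planted-hit neighbor genes that planted pathways over-sample
    pool <- if (length(planted_lncRNAs)) {
      sort(unique(unlist(genomic_neighbors(planted_lncRNAs, annotation))))
    } else character(0)
    if (length(pool) < 5) pool <- sort(sample(coding, min(25, length(coding))))

    n_planted <- min(4L, cfg$n_pathways)
    region_genes <- intersect(region_module_genes %||% character(0), coding)
    has_region <- length(region_genes) >= 3 && cfg$n_pathways > n_planted

    sizes <- sample(seq(rng[1], rng[2]), cfg$n_pathways, replace = TRUE)
    ids <- sprintf("pw_%03d", seq_len(cfg$n_pathways))
    pathways <- vector("list", cfg$n_pathways)
    for (i in seq_len(cfg$n_pathways)) {
      if (i <= n_planted) {
        n_from_pool <- min(length(pool), ceiling(0.6 * sizes[i]))
        g <- sample(pool, n_from_pool)
        g <- c(g, sample(setdiff(coding, g), sizes[i] - n_from_pool))
      } else if (has_region && i == n_planted + 1L) {
        n_from_mod <- min(length(region_genes), ceiling(0.6 * sizes[i]))
        g <- sample(region_genes, n_from_mod)
        g <- c(g, sample(setdiff(coding, g), sizes[i] - n_from_mod))
      } else {
        g <- sample(coding, sizes[i])
      }
      pathways[[i]] <- sort(g)
    }
    names(pathways) <- ids
    planted_paths <- ids[seq_len(n_planted)]
    region_path <- if (has_region) ids[n_planted + 1L] else NA_character_

    # drugs: planted drugs over-sample the planted (+ region) pathways
    n_pd <- min(3L, cfg$n_drugs)
    drug_ids <- sprintf("drug_%02d", seq_len(cfg$n_drugs))
    planted_targets <- c(planted_paths, if (has_region) region_path)
    drugs <- vector("list", cfg$n_drugs)
    for (i in seq_len(cfg$n_drugs)) {
      if (i <= n_pd) {
        take <- min(length(planted_targets),
                    max(ceiling(cfg$pathways_per_drug / 2), 1L),
                    cfg$pathways_per_drug)
        g <- sample(planted_targets, take)
        g <- c(g, sample(setdiff(ids, g),
                         min(cfg$pathways_per_drug - take, cfg$n_pathways - take)))
      } else {
        g <- sample(ids, min(cfg$pathways_per_drug, cfg$n_pathways))
      }
      drugs[[i]] <- sort(g)
    }
    names(drugs) <- drug_ids
    planted_drugs <- drug_ids[seq_len(n_pd)]

    # known disease genes, enriched for the planted-hit neighbor pool
    n_known <- max(10L, round(0.15 * length(coding)))
    from_pool <- min(length(pool), round(0.7 * n_known))
    known <- sort(unique(c(sample(pool, from_pool),
                           sample(setdiff(coding, pool),
                                  min(n_known - from_pool,
                                      length(setdiff(coding, pool)))))))

    if (!is.null(pathway_path)) {
      write_gmt(pathways, pathway_path, descriptions = rep("synthetic pathway", length(pathways)))
    }
    if (!is.null(drug_path)) {
      write_gmt(drugs, drug_path, descriptions = rep("drug-induced pathway set", length(drugs)))
    }
    if (!is.null(known_path)) {
      utils::write.table(data.frame(gene_id = known), known_path, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    list(pathways = pathways, drugs = drugs, known_genes = known,
         planted_enriched_pathways = planted_paths,
         region_specific_pathway = region_path,
         planted_effective_drugs = planted_drugs,
         pathway_path = pathway_path, drug_path = drug_path,
         known_path = known_path)
  })
}

# Per-gene importance scores (probability-like, in [0, 1]); planted-hit
# lncRNAs are drawn from a low-importance Beta, everything else from a
# symmetric one, emulating the lower essentiality of the hit class.
generate_scores <- function(cfg, annotation, planted_lncRNAs = NULL,
                            path = NULL) {
  with_rng(cfg$seed, "scores", {
    ids <- annotation$genes$gene_id
    sc <- stats::rbeta(length(ids), 3, 3)
    hit <- ids %in% (planted_lncRNAs %||% character(0))
    sc[hit] <- stats::rbeta(sum(hit), 1.5, 5)
    sc <- round(sc, 4)
    df <- data.frame(gene_id = ids, score = sc, stringsAsFactors = FALSE)
    if (!is.null(path)) {
      utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    df
  })
}

#' Generate the complete synthetic input bundle
#'
#' Runs every generator in order (annotation, variants, expression,
#' interactions, gene sets and drugs, importance scores), threading the
#' planted-hit lncRNA set through the downstream generators, and optionally
#' writes all files plus a ground-truth JSON to `dir`. With the same
#' configuration the written files are byte-identical across runs.
#'
#' @param cfg a `synthetic_config`.
#' @param dir optional output directory (created if needed); `NULL` keeps
#'   everything in memory.
#' @return list with elements `config`, `annotation`, `variants`, `expr`,
#'   `interactions`, `pathways`, `drugs`, `known_genes`, `scores`,
#'   `ground_truth` and `paths`.
#' @export
generate_synthetic_data <- function(cfg = synthetic_config(), dir = NULL) {
  p <- function(f) if (is.null(dir)) NULL else file.path(dir, f)
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ann <- generate_annotation(cfg, p("genes.gtf"))
  var <- generate_variants(cfg, ann$annotation, p("variants.bed"))
  expr <- generate_expression(cfg, ann$annotation,
                              planted_lncRNAs = var$planted_lncRNA_hits,
                              path = p("expression.tsv"),
                              sample_path = p("samples.tsv"))
  # planted ceRNA partners come from the lncRNA's own co-expression module
  # (where it has one), so the neighbor categories can converge on genes
  coding <- coding_ids(ann$annotation)
  pool <- lapply(stats::setNames(var$planted_lncRNA_hits,
                                 var$planted_lncRNA_hits), function(l) {
    m <- Filter(function(mod) l %in% mod, expr$modules)
    if (length(m)) intersect(m[[1]], coding) else character(0)
  })
  inter <- generate_interactions(cfg, ann$annotation,
                                 planted_lncRNAs = var$planted_lncRNA_hits,
                                 partner_pool = pool,
                                 path = p("mirna_targets.tsv"))
  region_mod <- expr$modules[[length(expr$modules)]]
  gs <- generate_genesets_and_drugs(cfg, ann$annotation,
                                    planted_lncRNAs = var$planted_lncRNA_hits,
                                    region_module_genes = region_mod,
                                    pathway_path = p("pathways.gmt"),
                                    drug_path = p("drugs.gmt"),
                                    known_path = p("known_genes.tsv"))
  scores <- generate_scores(cfg, ann$annotation,
                            planted_lncRNAs = var$planted_lncRNA_hits,
                            path = p("scores.tsv"))
  gt <- list(
    planted_lncRNA_hits = var$planted_lncRNA_hits,
    planted_modules = lapply(expr$modules, sort),
    module_tissues = expr$module_tissues,
    planted_cerna_pairs = inter$planted_cerna_pairs,
    planted_enriched_pathways = gs$planted_enriched_pathways,
    region_specific_pathway = gs$region_specific_pathway,
    planted_effective_drugs = gs$planted_effective_drugs)
  if (!is.null(dir)) {
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = FALSE, pretty = TRUE, digits = NA)
  }
  list(config = cfg,
       annotation = ann$annotation,
       variants = var$variants,
       expr = expr$expr,
       interactions = inter$interactions,
       pathways = gs$pathways,
       drugs = gs$drugs,
       known_genes = gs$known_genes,
       scores = scores,
       ground_truth = gt,
       paths = if (is.null(dir)) NULL else list(
         dir = dir, annotation = p("genes.gtf"), variants = p("variants.bed"),
         expression = p("expression.tsv"), samples = p("samples.tsv"),
         interactions = p("mirna_targets.tsv"), pathways = p("pathways.gmt"),
         drugs = p("drugs.gmt"), known_genes = p("known_genes.tsv"),
         scores = p("scores.tsv"),
         ground_truth = p("ground_truth.json")))
}

#' Read a previously generated synthetic input bundle from disk
#'
#' Counterpart of [generate_synthetic_data()] with a directory argument:
#' reads the standard file names back into the in-memory bundle layout.
#'
#' @param dir directory written by [generate_synthetic_data()].
#' @return list shaped like the [generate_synthetic_data()] return value
#'   (without `config`).
#' @export
read_pipeline_inputs <- function(dir) {
  ann <- read_annotation(file.path(dir, "genes.gtf"))
  variants <- read_variants(file.path(dir, "variants.bed"))
  expr <- read_expression(file.path(dir, "expression.tsv"),
                          file.path(dir, "samples.tsv"))
  inter <- utils::read.delim(file.path(dir, "mirna_targets.tsv"),
                             stringsAsFactors = FALSE)
  pathways <- read_gmt(file.path(dir, "pathways.gmt"))$sets
  drugs <- read_gmt(file.path(dir, "drugs.gmt"))$sets
  known <- utils::read.delim(file.path(dir, "known_genes.tsv"),
                             stringsAsFactors = FALSE)$gene_id
  scores <- utils::read.delim(file.path(dir, "scores.tsv"),
                              stringsAsFactors = FALSE)
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) jsonlite::read_json(gt_path, simplifyVector = TRUE) else NULL
  list(annotation = ann, variants = variants, expr = expr,
       interactions = inter, pathways = pathways, drugs = drugs,
       known_genes = known, scores = scores, ground_truth = gt)
}
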