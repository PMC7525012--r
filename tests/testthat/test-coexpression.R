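test_that("mad_filter keeps the requested count and drops flat genes first", {
  set.seed(2)
  v <- matrix(rnorm(8 * 10), 8, 10,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:10)))
  expect_equal(nrow(mad_filter(v, 0.75)), 6)
  # a constant gene has MAD 0 and is dropped before any varying gene
  v["g3", ] <- 1
  kept <- rownames(mad_filter(v, 7 / 8))
  expect_false("g3" %in% kept)
  expect_identical(mad_filter(v, 1), v)
  expect_error(mad_filter(v[1:3, ], 0.5), "fewer than 3")
  expect_error(mad_filter(v, 0), "\\(0, 1\\]")
})

test_that("remove_outlier_samples: constructed outlier out, clean data intact", {
  set.seed(5)
  v <- matrix(rnorm(30 * 20, mean = 5), 30, 20,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:20)))
  v[, "s7"] <- v[, "s7"] * 100
  r <- remove_outlier_samples(v)
  expect_equal(r$removed, "s7")
  expect_false("s7" %in% colnames(r$values))
  # 4 identical samples: nothing to remove
  v4 <- matrix(1:40, 10, 4, dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  expect_length(remove_outlier_samples(v4)$removed, 0)
  expect_error(remove_outlier_samples(v4[, 1:3]), "at least 4")
})

test_that("remove_outlier_samples rarely removes anything from i.i.d. data", {
  for (s in 1:20) {
    set.seed(400 + s)
    v <- matrix(rnorm(40 * 50), 40, 50,
                dimnames = list(paste0("g", 1:40), paste0("s", 1:50)))
    expect_lte(length(remove_outlier_samples(v)$removed), 1)
  }
})

test_that("pick_soft_threshold honors its contract on modular data", {
  cfg <- synthetic_config(seed = 21, n_tissues = 1, samples_per_tissue = 20,
                          n_modules = 4, module_size = 20,
                          within_module_cor = 0.8)
  ge <- generate_expression(cfg, default_fixture()$annotation)
  st <- suppressWarnings(pick_soft_threshold(ge$expr$values))
  expect_true(st$beta %in% 1:20)
  expect_equal(nrow(st$table), 20)
  expect_gte(st$beta, 3)
  expect_error(pick_soft_threshold(ge$expr$values[, 1:4]), "at least 8")
  vc <- ge$expr$values; vc[1, ] <- 2
  expect_error(suppressWarnings(pick_soft_threshold(vc)), "constant")
})

test_that("build_adjacency: unsigned powers, symmetry, brute-force agreement", {
  # exact arithmetic on constructed correlations
  x <- c(1, 2, 3, 4)
  v <- rbind(a = x, b = 2 * x + 1, c = -3 * x)
  colnames(v) <- paste0("s", 1:4)
  net <- build_adjacency(v, beta = 2)
  expect_equal(net$adjacency["a", "b"], 1)   # perfectly correlated
  expect_equal(net$adjacency["a", "c"], 1)   # unsigned: |-1|^2
  expect_equal(diag(net$adjacency), c(a = 1, b = 1, c = 1))
  set.seed(12)
  v2 <- matrix(rnorm(20 * 15), 20, 15,
               dimnames = list(paste0("g", 1:20), paste0("s", 1:15)))
  for (beta in c(1, 2, 6)) {
    A <- build_adjacency(v2, beta)$adjacency
    expect_true(isSymmetric(A))
    expect_true(all(A >= 0 & A <= 1 + 1e-12))
    # independent per-pair recomputation
    for (pair in list(c(1, 2), c(3, 17), c(9, 20))) {
      i <- pair[1]; j <- pair[2]
      expect_equal(A[i, j], abs(cor(v2[i, ], v2[j, ]))^beta,
                   tolerance = 1e-10)
    }
  }
  expect_equal(build_adjacency(rbind(a = x, b = c(1, 3, 2, 4)),
                               beta = 1)$adjacency["a", "b"],
               abs(cor(x, c(1, 3, 2, 4))))
  vbad <- v2; vbad[5, ] <- 7
  expect_error(build_adjacency(vbad, 2), "g5")
  expect_error(build_adjacency(v2, 0), ">= 1")
})

test_that("coexpr_neighbors: thresholds, monotonicity, absent lncRNAs", {
  ann <- toy_annotation(list(
    list(id = "L1", type = "lincRNA", chrom = "chr1", start = 0, end = 100),
    list(id = "P1", type = "protein_coding", chrom = "chr1", start = 200, end = 300),
    list(id = "P2", type = "protein_coding", chrom = "chr1", start = 400, end = 500),
    list(id = "P3", type = "protein_coding", chrom = "chr1", start = 600, end = 700)))
  A <- matrix(c(1, 0.5, 0.2, 0.05,
                0.5, 1, 0.3, 0.1,
                0.2, 0.3, 1, 0.2,
                0.05, 0.1, 0.2, 1), 4, 4,
              dimnames = list(c("L1", "P1", "P2", "P3"),
                              c("L1", "P1", "P2", "P3")))
  net <- structure(list(tissue = "cortex", gene_ids = rownames(A), beta = 2,
                        adjacency = A, fit_r2 = NA_real_),
                   class = "coexpr_network")
  nb <- coexpr_neighbors(net, "L1", ann, adjacency_min = 0.1)
  expect_setequal(nb$L1, c("P1", "P2"))
  strict <- coexpr_neighbors(net, "L1", ann, adjacency_min = 0.3)
  expect_equal(strict$L1, "P1")
  expect_true(all(strict$L1 %in% nb$L1))
  expect_warning(coexpr_neighbors(net, c("L1", "L9"), ann), "L9")
})

test_that("neighbor sets shrink in both beta and the adjacency threshold", {
  set.seed(31)
  cfg <- synthetic_config(seed = 31, n_tissues = 1, samples_per_tissue = 20,
                          n_modules = 2, module_size = 15)
  d <- default_fixture()
  ge <- generate_expression(cfg, d$annotation,
                            planted_lncRNAs = d$ground_truth$planted_lncRNA_hits)
  lncs <- intersect(lncRNA_ids(d$annotation), unlist(ge$modules))
  for (beta in c(2, 4)) {
    net_lo <- build_adjacency(ge$expr$values, beta)
    net_hi <- build_adjacency(ge$expr$values, beta + 4)
    for (th in c(0.1, 0.3)) {
      nb_lo <- suppressWarnings(coexpr_neighbors(net_lo, lncs, d$annotation, th))
      nb_hi <- suppressWarnings(coexpr_neighbors(net_hi, lncs, d$annotation, th))
      nb_strict <- suppressWarnings(coexpr_neighbors(net_lo, lncs, d$annotation, th + 0.2))
      for (l in names(nb_lo)) {
        expect_true(all(nb_hi[[l]] %in% nb_lo[[l]]))
        expect_true(all(nb_strict[[l]] %in% nb_lo[[l]]))
      }
    }
  }
})

test_that("per-tissue networks are built independently from their own samples", {
  d <- default_fixture()
  net <- build_tissue_network(d$expr, "cortex")
  expect_s3_class(net, "coexpr_network")
  expect_true(isSymmetric(net$adjacency))
  expect_equal(unname(diag(net$adjacency)), rep(1, length(net$gene_ids)))
  # permuting another tissue's sample block leaves the cortex network alone
  e2 <- d$expr
  liver <- names(e2$sample_tissue)[e2$sample_tissue == "liver"]
  e2$values[, liver] <- e2$values[, sample(liver), drop = FALSE]
  net2 <- build_tissue_network(e2, "cortex")
  expect_equal(net$adjacency, net2$adjacency)
  expect_equal(net$beta, net2$beta)
})
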