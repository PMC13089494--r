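test_that("qc_filter applies strict cell bounds then the gene detection floor", {
  m <- toy_counts()
  out <- suppressWarnings(qc_filter(m))
  # (800, 800), (700, 800), (900, 40000), (6500, 6700), (1000, 39999):
  # strict bounds keep exactly cells 1 and 5
  expect_setequal(rownames(out), c("c1", "c5"))
  # with 2 surviving cells no gene reaches 9 detections: empty with warning
  expect_warning(out2 <- qc_filter(m), "empty")
  expect_equal(ncol(out2), 0)
  # relaxed gene floor: genes detected in both survivors are kept
  out3 <- qc_filter(m, min_cells_per_gene = 2)
  expect_equal(ncol(out3), 800)
})

test_that("gene boundary 'eight or fewer' removes genes detected in 8 cells", {
  withr::local_seed(1)
  m <- matrix(rpois(30 * 50, 5) + 1L, 30, 50,
              dimnames = list(paste0("c", 1:30), sprintf("g%02d", 1:50)))
  m[, 1] <- 0L; m[1:8, 1] <- 1L    # detected in exactly 8 cells
  m[, 2] <- 0L; m[1:9, 2] <- 1L    # detected in exactly 9 cells
  out <- qc_filter(m, min_genes = 0, max_genes = 1e6, max_umis = 1e9)
  expect_false("g01" %in% colnames(out))
  expect_true("g02" %in% colnames(out))
})

test_that("qc_filter is order-stable under cell permutation", {
  withr::local_seed(42)
  m <- matrix(rpois(40 * 200, 2), 40, 200,
              dimnames = list(paste0("c", 1:40), sprintf("g%03d", 1:200)))
  perm <- sample(nrow(m))
  a <- qc_filter(m, min_genes = 100, max_genes = 200, max_umis = 1e6,
                 min_cells_per_gene = 3)
  b <- qc_filter(m[perm, ], min_genes = 100, max_genes = 200, max_umis = 1e6,
                 min_cells_per_gene = 3)
  expect_setequal(rownames(a), rownames(b))
  expect_equal(a[sort(rownames(a)), sort(colnames(a))],
               b[sort(rownames(b)), sort(colnames(b))])
})

test_that("log-normalization matches its closed form and zero cells stay zero", {
  m <- matrix(c(10, 30, 60, 0, 0, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), c("g1", "g2", "g3")))
  out <- normalize_log(m, scale = 100)
  expect_equal(out["a", ], c(g1 = log1p(10), g2 = log1p(30), g3 = log1p(60)))
  expect_equal(out["b", ], c(g1 = 0, g2 = 0, g3 = 0))
  # expm1 re-scaling recovers the within-cell proportions exactly
  prop <- expm1(out["a", ]) / sum(expm1(out["a", ]))
  expect_equal(prop, c(g1 = 0.1, g2 = 0.3, g3 = 0.6))
})

test_that("HVG selection finds planted variable genes and never prefers constants", {
  withr::local_seed(3)
  n <- 200
  flat <- matrix(rnorm(n * 500, 5, 0.1), n, 500)
  hot <- matrix(rnorm(n * 10, 5, 4), n, 10)
  m <- cbind(hot, flat)
  colnames(m) <- c(sprintf("hot%02d", 1:10), sprintf("flat%03d", 1:500))
  rownames(m) <- paste0("c", 1:n)
  sel <- select_hvgs(m, 10)
  expect_setequal(sel, sprintf("hot%02d", 1:10))
  # constant gene ranks behind any varying gene
  m2 <- cbind(m, const = 1)
  expect_false("const" %in% select_hvgs(m2, ncol(m2) - 1))
  expect_equal(sort(select_hvgs(m2, ncol(m2))), sort(colnames(m2)))
  expect_error(select_hvgs(m, ncol(m) + 1))
})

test_that("pca_embed reconstructs low-rank data and projects held-out cells", {
  withr::local_seed(5)
  basis <- matrix(rnorm(2 * 40), 2, 40)
  scores_true <- matrix(rnorm(300 * 2), 300, 2)
  x <- scores_true %*% basis
  dimnames(x) <- list(paste0("c", 1:300), paste0("g", 1:40))
  e <- pca_embed(x, D = 2)
  recon <- e$scores %*% t(e$loadings)
  xs <- sweep(sweep(x, 2, e$gene_center, "-"), 2, e$gene_scale, "/")
  expect_lt(max(abs(recon - xs)), 1e-8)
  expect_equal(crossprod(e$loadings), diag(2), tolerance = 1e-6)
  # out-of-sample projection of training rows equals their scores
  expect_equal(project_embedding(e, x[11:20, ]), e$scores[11:20, ])
  # balancing with equal label sizes and full sample matches up to sign
  labs <- rep(c("a", "b"), each = 150)
  eb <- pca_embed(x, D = 2, balance_labels = labs, balance_to = 150)
  flip <- sign(diag(stats::cor(e$scores, eb$scores)))
  expect_equal(sweep(eb$scores, 2, flip, "*"), e$scores, tolerance = 1e-6)
})

test_that("graph clustering separates blobs, is deterministic and validates k", {
  x <- two_blobs(n_per = 80, d = 5, gap = 25)
  cl <- cluster_graph(x, k_neighbors = 15, resolution = 1, seed = 1)
  expect_equal(length(unique(cl)), 2)
  expect_equal(length(unique(cl[1:80])), 1)
  expect_equal(cl, cluster_graph(x, k_neighbors = 15, resolution = 1, seed = 1))
  expect_error(cluster_graph(x, k_neighbors = 160), "k_neighbors")
})

test_that("UMI downsampling hits targets exactly and never increases entries", {
  m <- matrix(c(10, 30, 60), 1, 3,
              dimnames = list("c1", c("g1", "g2", "g3")))
  out <- downsample_umis(m, donor_totals = 10, targets = 10, seed = 1)
  expect_equal(sum(out), 10)
  out0 <- downsample_umis(m, donor_totals = 0, targets = 0, seed = 1)
  expect_equal(sum(out0), 0)
  # target above the current total leaves the cell unchanged
  expect_equal(downsample_umis(m, donor_totals = 500, targets = 500, seed = 1),
               matrix(as.integer(m), 1, 3, dimnames = dimnames(m)))
  # Monte-Carlo: per-gene fractions unbiased within 3 SE
  reps <- t(vapply(1:2000, function(i) {
    as.numeric(downsample_umis(m, donor_totals = 10, targets = 10, seed = i))
  }, numeric(3)))
  p <- c(.1, .3, .6)
  se <- sqrt(p * (1 - p) / 10 / 2000)
  expect_true(all(abs(colMeans(reps / 10) - p) < 3 * se))
  expect_true(all(reps <= matrix(c(10, 30, 60), 2000, 3, byrow = TRUE)))
})

test_that("differential expression recovers a planted difference and is antisymmetric", {
  withr::local_seed(9)
  nA <- 20; nB <- 20
  m <- matrix(rpois((nA + nB) * 6, 5), nA + nB, 6,
              dimnames = list(paste0("c", 1:(nA + nB)), paste0("g", 1:6)))
  m[1:nA, 1] <- rpois(nA, 60)      # up in A
  m[(nA + 1):(nA + nB), 2] <- rpois(nB, 60)  # up in B
  A <- paste0("c", 1:nA); B <- paste0("c", (nA + 1):(nA + nB))
  deg <- differential_expression(m, A, B)
  expect_equal(deg$gene, "g1")
  degBA <- differential_expression(m, B, A)
  expect_equal(degBA$gene, "g2")
  fullAB <- differential_expression(m, A, B, keep_all = TRUE)
  fullBA <- differential_expression(m, B, A, keep_all = TRUE)
  ord <- match(fullAB$gene, fullBA$gene)
  expect_equal(fullAB$log2FC, -fullBA$log2FC[ord], tolerance = 1e-12)
  expect_equal(fullAB$p, fullBA$p[ord], tolerance = 1e-12)
  # a gene silent in both groups is excluded
  m2 <- cbind(m, dead = 0L)
  expect_false("dead" %in% differential_expression(m2, A, B, keep_all = TRUE)$gene)
  expect_error(differential_expression(m, A, c(B, A[1])), "overlap")
})

test_that("extreme separation passes all three DE thresholds", {
  m <- matrix(0L, 40, 3, dimnames = list(paste0("c", 1:40), c("hi", "x", "y")))
  m[1:20, "hi"] <- 50L
  m[, "x"] <- 5L; m[, "y"] <- 3L
  deg <- differential_expression(m, paste0("c", 1:20), paste0("c", 21:40))
  expect_true("hi" %in% deg$gene)
  expect_true(all(deg$p < 0.05 & deg$log2FC > 0.75 & deg$pct1 > 0.25))
})

test_that("proportions sum to one per replicate and respect the denominator class", {
  cells <- tibble::tibble(
    sample = c("s1", "s1", "s1", "s1", "s2", "s2"),
    class = c("GABAergic", "GABAergic", "glutamatergic", "GABAergic",
              "GABAergic", "GABAergic"),
    subclass = c("Pvalb", "Sst", "L4", "Pvalb", "Sst", "Sst")
  )
  p <- subclass_proportions(cells, "subclass")
  sums <- tapply(p$fraction, p$sample, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  pg <- subclass_proportions(cells, "subclass", within = "GABAergic")
  expect_equal(pg$fraction[pg$sample == "s1" & pg$label == "Pvalb"], 2 / 3)
  expect_false("L4" %in% pg$label)
  expect_error(subclass_proportions(cells, "subclass", within = "nope"),
               "empty denominator")
})
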