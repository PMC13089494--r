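test_that("ortholog subsetting aligns columns under species-a naming", {
  a <- matrix(1:12, 3, 4, dimnames = list(paste0("a", 1:3),
                                          c("gA", "gB", "gC", "gD")))
  b <- matrix(1:9, 3, 3, dimnames = list(paste0("b", 1:3),
                                         c("hC", "hA", "hZ")))
  map <- tibble::tibble(gene_a = c("gA", "gC", "gD", "gB"),
                        gene_b = c("hA", "hC", "hMissing", "hB"))
  out <- ortholog_subset(a, b, map)
  expect_equal(colnames(out$a), c("gA", "gC"))
  expect_equal(colnames(out$b), c("gA", "gC"))
  expect_equal(unname(out$b[, "gA"]), unname(b[, "hA"]))
  expect_error(ortholog_subset(a, b, dplyr::bind_rows(map, map[1, ])),
               "one-to-one")
  expect_error(ortholog_subset(a, b, map[0, ]), "empty")
})

test_that("integration leaves identical datasets unshifted and removes constant offsets", {
  withr::local_seed(11)
  x <- matrix(rnorm(120 * 30), 120, 30,
              dimnames = list(paste0("c", 1:120), paste0("g", 1:30)))
  same <- integrate_embed(list(a = x, b = x[1:119, ]), D = 5, mnn_k = 10)
  expect_lt(sqrt(sum(same$shifts$b^2)), 0.3)
  # dataset B = A + constant gene offset: centroid gap shrinks after shift
  y <- x + matrix(5, nrow(x), ncol(x))
  rownames(y) <- paste0("d", 1:120)
  emb <- integrate_embed(list(a = x, b = y), D = 5, mnn_k = 10)
  pre <- centroid_gap_unshifted(x, y, D = 5)
  post <- sqrt(sum((colMeans(emb$scores[emb$dataset == "a", ]) -
                    colMeans(emb$scores[emb$dataset == "b", ]))^2))
  expect_lt(post, pre)
  expect_error(integrate_embed(list(a = x)), "2 datasets")
})

test_that("integration recovers a shared low-rank structure across batches", {
  withr::local_seed(12)
  basis <- qr.Q(qr(matrix(rnorm(40 * 3), 40, 3)))
  lat_a <- matrix(rnorm(150 * 3, sd = 3), 150, 3)
  lat_b <- matrix(rnorm(150 * 3, sd = 3), 150, 3)
  mk <- function(lat, tag) {
    m <- lat %*% t(basis) + matrix(rnorm(150 * 40, sd = 0.05), 150, 40)
    dimnames(m) <- list(paste0(tag, seq_len(nrow(m))), paste0("g", 1:40))
    m
  }
  emb <- integrate_embed(list(a = mk(lat_a, "a"), b = mk(lat_b, "b")), D = 3)
  # the joint scores carry the full latent coordinates of each dataset
  cc_a <- stats::cancor(emb$scores[emb$dataset == "a", ], lat_a)$cor
  cc_b <- stats::cancor(emb$scores[emb$dataset == "b", ], lat_b)$cor
  expect_true(all(cc_a > 0.95))
  expect_true(all(cc_b > 0.95))
})

test_that("cluster overlap matches the min-fraction formula and its bounds", {
  # i spread (0.6, 0.4), j spread (0.2, 0.8) over two clusters -> 0.6
  sub <- c(rep("i", 10), rep("j", 10))
  clu <- c(rep(1, 6), rep(2, 4), rep(1, 2), rep(2, 8))
  o <- cluster_overlap_fraction(sub, clu)
  expect_equal(o["i", "j"], 0.6)
  expect_equal(o["i", "i"], 1)
  expect_equal(o, t(o))
  # identical distributions give 1; disjoint clusters give 0
  o2 <- cluster_overlap_fraction(c("a", "a", "b", "b"), c(1, 2, 1, 2))
  expect_equal(o2["a", "b"], 1)
  o3 <- cluster_overlap_fraction(c("a", "a", "b", "b"), c(1, 1, 2, 2))
  expect_equal(o3["a", "b"], 0)
  expect_true(all(o >= 0 & o <= 1))
})

test_that("overlap equals 1 only for coinciding cluster distributions", {
  withr::local_seed(13)
  for (rep in 1:20) {
    sub <- sample(c("x", "y"), 40, replace = TRUE)
    clu <- sample(1:3, 40, replace = TRUE)
    if (length(unique(sub)) < 2) next
    o <- cluster_overlap_fraction(sub, clu)
    fx <- prop.table(table(clu[sub == "x"] == 1))
    px <- prop.table(table(factor(clu[sub == "x"], 1:3)))
    py <- prop.table(table(factor(clu[sub == "y"], 1:3)))
    expect_equal(unname(o["x", "y"] == 1), unname(all(abs(px - py) < 1e-12)))
  }
})

test_that("balanced transfer depletes per-subclass pools before reuse", {
  withr::local_seed(14)
  # subclass pool of 250 under cap 100 must draw 100, 100, 50, then reset
  ref <- matrix(rnorm(300 * 5), 300, 5,
                dimnames = list(paste0("r", 1:300), paste0("g", 1:5)))
  labs <- c(rep("big", 250), rep("small", 50))
  q <- matrix(rnorm(10 * 5), 10, 5,
              dimnames = list(paste0("q", 1:10), paste0("g", 1:5)))
  tr <- balanced_label_transfer(ref, labs, q, n_iter = 4, cap = 100, D = 3,
                                k_vote = 5, seed = 1)
  big <- tr$audit[tr$audit$subclass == "big", ]
  expect_equal(big$drawn, c(100L, 100L, 50L, 100L))
  expect_equal(big$reset, c(FALSE, FALSE, TRUE, FALSE))
  expect_true(all(rowSums(tr$prob) - 1 < 1e-9))
})

test_that("transfer is perfect on well-separated subclasses", {
  withr::local_seed(15)
  mk <- function(center, tag, n = 60) {
    m <- matrix(rnorm(n * 8), n, 8) + matrix(center, n, 8, byrow = TRUE)
    dimnames(m) <- list(paste0(tag, seq_len(n)), paste0("g", 1:8))
    m
  }
  ref <- rbind(mk(rep(0, 8), "a"), mk(rep(10, 8), "b"))
  labs <- rep(c("alpha", "beta"), each = 60)
  query <- mk(rep(10, 8), "q", n = 40)
  tr <- balanced_label_transfer(ref, labs, query, n_iter = 3, cap = 30,
                                D = 4, k_vote = 10, seed = 2)
  expect_true(all(tr$predicted == "beta"))
  expect_true(all(tr$prob[, "beta"] > 0.9))
})

test_that("averaging identical iterations reproduces the single-iteration probabilities", {
  withr::local_seed(16)
  ref <- matrix(rnorm(40 * 4), 40, 4,
                dimnames = list(paste0("r", 1:40), paste0("g", 1:4)))
  labs <- rep(c("a", "b"), each = 20)
  q <- matrix(rnorm(6 * 4), 6, 4,
              dimnames = list(paste0("q", 1:6), paste0("g", 1:4)))
  # cap covers the full pool, so every iteration draws the identical set
  t1 <- balanced_label_transfer(ref, labs, q, n_iter = 1, cap = 20, D = 2,
                                k_vote = 5, seed = 3)
  t2 <- balanced_label_transfer(ref, labs, q, n_iter = 2, cap = 20, D = 2,
                                k_vote = 5, seed = 3)
  expect_equal(t1$prob, t2$prob, tolerance = 1e-12)
})

test_that("confusion matrices are row-normalized with predicted rows", {
  cm <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"))
  expect_equal(rowSums(cm), c(a = 1, b = 1))
  expect_equal(cm["b", "a"], 0.5)   # one of two b-predictions is truly a
  perfect <- confusion_matrix(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(perfect, diag(3), ignore_attr = TRUE)
  onerow <- confusion_matrix(c("a", "b", "c"), c("a", "a", "a"))
  expect_equal(sum(onerow["a", ]), 1)
  expect_equal(sum(onerow["b", ]), 0)
  # zero-prediction rows stay all-zero, others sum to 1 within 1e-12
  expect_true(all(abs(rowSums(onerow) - c(1, 0, 0)) < 1e-12))
})

test_that("pairwise silhouette behaves at the identity, separation and symmetry limits", {
  withr::local_seed(17)
  same <- matrix(rnorm(200 * 3), 200, 3)
  labs <- rep(c("a", "b"), each = 100)
  expect_lt(abs(silhouette_pairwise(same, labs, c("a", "b"))), 0.05)
  far <- rbind(matrix(rnorm(50 * 3, sd = .1), 50, 3),
               matrix(rnorm(50 * 3, sd = .1) + 100, 50, 3))
  flabs <- rep(c("a", "b"), each = 50)
  expect_gt(silhouette_pairwise(far, flabs, c("a", "b")), 0.99)
  expect_equal(silhouette_pairwise(far, flabs, c("a", "b")),
               silhouette_pairwise(far, flabs, c("b", "a")))
  # invariance under rigid rotation
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(silhouette_pairwise(far %*% R, flabs, c("a", "b")),
               silhouette_pairwise(far, flabs, c("a", "b")), tolerance = 1e-9)
})

test_that("loading correlations detect identity, orthogonality and sign flips", {
  # Helmert contrasts: orthogonal, zero-mean loading vectors, so Pearson
  # correlation equals the cosine exactly
  h <- stats::contr.helmert(30)
  h <- sweep(h, 2, sqrt(colSums(h^2)), "/")
  rownames(h) <- paste0("g", 1:30)
  mk_emb <- function(cols) {
    structure(list(loadings = h[, cols, drop = FALSE], D = length(cols)),
              class = "cc_embedding")
  }
  map <- tibble::tibble(gene_a = paste0("g", 1:30), gene_b = paste0("g", 1:30))
  e_a <- mk_emb(1:4)
  cc <- loading_correlations(e_a, e_a, map, top = 4)
  expect_equal(unname(diag(cc)), rep(1, 4), tolerance = 1e-12)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-12)
  # fully orthogonal loading sets: all correlations vanish
  cc0 <- loading_correlations(e_a, mk_emb(5:8), map, top = 4)
  expect_lt(max(abs(cc0)), 1e-12)
  # sign flip of one component negates its row
  e_b <- mk_emb(1:4)
  e_b$loadings[, 2] <- -e_b$loadings[, 2]
  cc2 <- loading_correlations(e_a, e_b, map, top = 4)
  expect_equal(unname(cc2[2, ]), unname(-cc[2, ]), tolerance = 1e-12)
})

test_that("profile correlations reproduce hand-computed Spearman values", {
  # profiles over 5 genes engineered per label
  norm <- rbind(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5),
                c(5, 4, 3, 2, 1), c(5, 4, 3, 2, 1),
                c(1, 3, 2, 5, 4), c(1, 3, 2, 5, 4))
  dimnames(norm) <- list(paste0("c", 1:6), paste0("g", 1:5))
  labels <- rep(c("up", "down", "mix"), each = 2)
  pc <- profile_correlations(norm, labels, n_hvg = 5)
  get <- function(a, b) pc$rho[(pc$label_a == a & pc$label_b == b) |
                               (pc$label_a == b & pc$label_b == a)]
  expect_equal(get("up", "up"), 1)
  expect_equal(get("down", "up"), -1)
  # ranks (1,2,3,4,5) vs (1,3,2,5,4): rho = 1 - 6*4/(5*24) = 0.8
  expect_equal(get("mix", "up"), 0.8)
})
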