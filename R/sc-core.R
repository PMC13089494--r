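# Single-nucleus preprocessing: QC, normalization, HVG selection, (balanced)
# PCA embedding, graph clustering, UMI downsampling, differential expression
# and composition summaries.

#' Quality-control filter for a count matrix
#'
#' Keeps cells whose detected-gene count lies strictly between `min_genes`
#' and `max_genes` and whose total UMI count is strictly below `max_umis`;
#' then keeps genes detected (count > 0) in at least `min_cells_per_gene` of
#' the surviving cells. Cells are filtered before genes.
#'
#' @param m Cells x genes count matrix (dense or sparse) with dimnames.
#' @param min_genes,max_genes Strict bounds on detected genes per cell.
#' @param max_umis Strict upper bound on UMIs per cell.
#' @param min_cells_per_gene Minimum surviving cells a gene must be detected
#'   in (9 means "detected in more than eight cells").
#' @return The filtered matrix (possibly empty, with a warning).
#' @export
qc_filter <- function(m, min_genes = 700, max_genes = 6500, max_umis = 40000,
                      min_cells_per_gene = 9) {
  validate_counts(m)
  ngene <- cell_n_detected(m)
  numi <- cell_totals(m)
  keep_cells <- ngene > min_genes & ngene < max_genes & numi < max_umis
  m2 <- m[keep_cells, , drop = FALSE]
  keep_genes <- gene_n_detected(m2) >= min_cells_per_gene
  out <- m2[, keep_genes, drop = FALSE]
  if (nrow(out) == 0 || ncol(out) == 0) {
    rlang::warn("qc_filter produced an empty matrix")
  }
  out
}

#' Log-normalize counts to a fixed library size
#'
#' Per cell: `ln(1 + count / total * scale)`. Cells with zero total map to
#' all-zero rows.
#'
#' @param m Cells x genes count matrix.
#' @param scale Target library size (counts per 10k by default).
#' @return Dense numeric matrix of the same shape.
#' @export
normalize_log <- function(m, scale = 1e4) {
  tot <- cell_totals(m)
  tot[tot == 0] <- 1
  out <- log1p(as.matrix(m) / tot * scale)
  dimnames(out) <- dimnames(m)
  out
}

#' Select highly variable genes
#'
#' Ranks genes by standardized dispersion: per-gene variance of the
#' normalized matrix divided by a loess mean-variance trend (falling back to
#' variance/mean for very small gene sets). Ties break deterministically by
#' gene id.
#'
#' @param m Normalized (cells x genes) matrix.
#' @param n Number of genes to return (`n <= ncol(m)`).
#' @return Character vector of `n` gene ids, highest dispersion first.
#' @export
select_hvgs <- function(m, n = 3000) {
  if (n > ncol(m)) rlang::abort("n exceeds the number of genes")
  mu <- colMeans(m)
  v <- apply(m, 2, stats::var)
  disp <- rep(0, length(v))
  pos <- mu > 0 & v > 0
  if (sum(pos) >= 20 && diff(range(log10(mu[pos]))) < 0.5) {
    # no mean-variance trend estimable on a near-constant mean range
    disp[pos] <- v[pos]
  } else if (sum(pos) >= 20) {
    fit <- tryCatch(
      stats::loess(log10(v[pos]) ~ log10(mu[pos]), span = 0.5, degree = 2),
      error = function(e) NULL)
    if (!is.null(fit)) {
      disp[pos] <- v[pos] / pmax(10^stats::fitted(fit), 1e-12)
    } else {
      disp[pos] <- v[pos] / mu[pos]
    }
  } else {
    disp[pos] <- v[pos] / pmax(mu[pos], 1e-12)
  }
  ord <- order(-disp, colnames(m))
  colnames(m)[ord[seq_len(n)]]
}

#' PCA embedding with optional label-balanced fitting
#'
#' Centers and unit-scales genes, then computes `D` principal components.
#' When `balance_labels` is given, the loadings (and the gene centering and
#' scaling used for projection) are computed on a per-label random downsample
#' of at most `balance_to` cells (default: the size of the smallest label),
#' and all cells are projected onto those components — so abundant labels do
#' not dominate the axes.
#'
#' @param m Normalized cells x genes matrix.
#' @param D Number of components (`D <= min(cells, genes)` of the fit set).
#' @param balance_labels Optional per-cell label vector (length `nrow(m)`).
#' @param balance_to Per-label cap for the fit subsample.
#' @param seed Seed for the balancing draw.
#' @return A `cc_embedding`: list with `scores` (cells x D), `loadings`
#'   (genes x D, orthonormal columns), `gene_center`, `gene_scale`, `D`.
#' @export
pca_embed <- function(m, D = 30, balance_labels = NULL, balance_to = NULL,
                      seed = 1) {
  m <- as.matrix(m)
  fit_idx <- seq_len(nrow(m))
  if (!is.null(balance_labels)) {
    stopifnot(length(balance_labels) == nrow(m))
    sizes <- table(balance_labels)
    if (any(sizes == 0)) rlang::abort("label with zero cells")
    if (is.null(balance_to)) balance_to <- min(sizes)
    fit_idx <- withr::with_seed(seed, {
      unlist(lapply(split(seq_len(nrow(m)), balance_labels), function(ii) {
        if (length(ii) <= balance_to) ii else sample(ii, balance_to)
      }), use.names = FALSE)
    })
    fit_idx <- sort(fit_idx)
  }
  fit <- m[fit_idx, , drop = FALSE]
  ctr <- colMeans(fit)
  scl <- apply(fit, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  D <- min(D, nrow(fit) - 1L, ncol(fit))
  xs <- sweep(sweep(fit, 2, ctr, "-"), 2, scl, "/")
  sv <- svd(xs, nu = 0, nv = D)
  loadings <- sv$v
  rownames(loadings) <- colnames(m)
  e <- structure(list(loadings = loadings, gene_center = ctr,
                      gene_scale = scl, D = D), class = "cc_embedding")
  e$scores <- project_embedding(e, m)
  e
}

#' Project cells into a fitted embedding
#'
#' Applies the stored gene centering/scaling and loadings to new (or the
#' original) normalized data.
#'
#' @param e A `cc_embedding` from [pca_embed()].
#' @param m Normalized cells x genes matrix over the same genes.
#' @return Cells x D score matrix.
#' @export
project_embedding <- function(e, m) {
  m <- as.matrix(m)[, names(e$gene_center), drop = FALSE]
  xs <- sweep(sweep(m, 2, e$gene_center, "-"), 2, e$gene_scale, "/")
  s <- xs %*% e$loadings
  rownames(s) <- rownames(m)
  s
}

#' Graph-based clustering of an embedding
#'
#' Builds an exact k-nearest-neighbour graph on the embedding scores,
#' reweights edges by shared-neighbour (Jaccard) similarity with the usual
#' 1/15 pruning, and partitions the weighted graph with the Leiden algorithm
#' (modularity objective), seeded for reproducibility.
#'
#' @param e A `cc_embedding`, or a plain score matrix.
#' @param k_neighbors Neighbours per cell (`<` number of cells).
#' @param resolution Leiden resolution parameter.
#' @param seed RNG seed.
#' @return Integer cluster labels (length = cells).
#' @export
cluster_graph <- function(e, k_neighbors = 15, resolution = 1, seed = 1) {
  scores <- if (inherits(e, "cc_embedding")) e$scores else as.matrix(e)
  n <- nrow(scores)
  if (k_neighbors >= n) rlang::abort("k_neighbors must be below the cell count")
  nn <- knn_search(scores, scores, k_neighbors + 1L)  # self included
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k_neighbors + 1L),
                            j = as.vector(nn$idx), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)
  tri <- Matrix::summary(methods::as(shared, "TsparseMatrix"))
  tri <- tri[tri$i < tri$j, ]
  jac <- tri$x / (2 * (k_neighbors + 1L) - tri$x)
  keep <- jac >= 1 / 15
  g <- igraph::graph_from_data_frame(
    data.frame(from = tri$i[keep], to = tri$j[keep], weight = jac[keep]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  part <- withr::with_seed(seed, {
    igraph::cluster_leiden(g, objective_function = "modularity",
                           weights = igraph::E(g)$weight,
                           resolution = resolution, n_iterations = 5)
  })
  as.integer(igraph::membership(part))[order(as.integer(igraph::V(g)$name))]
}

#' Downsample cell UMI totals to an empirical donor distribution
#'
#' For each cell a target total is drawn from `donor_totals`. Cells already at
#' or below their target are unchanged; otherwise the cell's UMIs are
#' resampled without replacement down to the target (proportional reduction
#' preserving the relative expression profile in expectation). Totals equal
#' `min(target, original)` exactly, and no entry ever increases.
#'
#' @param m Cells x genes count matrix.
#' @param donor_totals Nonempty numeric vector of donor UMI totals.
#' @param seed RNG seed.
#' @param targets Optional explicit per-cell targets (overrides the draw).
#' @return Integer count matrix of the same shape.
#' @export
downsample_umis <- function(m, donor_totals, seed = 1, targets = NULL) {
  if (length(donor_totals) == 0) rlang::abort("donor_totals is empty")
  if (any(donor_totals < 0)) rlang::abort("negative donor totals")
  m <- as.matrix(m)
  withr::with_seed(seed, {
    n <- nrow(m)
    if (is.null(targets)) {
      targets <- sample(donor_totals, n, replace = TRUE)
    }
    stopifnot(length(targets) == n)
    out <- m
    for (i in seq_len(n)) {
      ci <- m[i, ]
      tot <- sum(ci)
      t_i <- floor(targets[i])
      if (t_i >= tot) next
      if (t_i == 0) { out[i, ] <- 0L; next }
      pool <- rep.int(seq_along(ci), ci)
      kept <- sample(pool, t_i)
      out[i, ] <- tabulate(kept, nbins = length(ci))
    }
    storage.mode(out) <- "integer"
    dimnames(out) <- dimnames(m)
    out
  })
}

#' Differential expression between two cell groups
#'
#' Per gene: two-sided Wilcoxon rank-sum P on log-normalized expression,
#' `log2FC = log2((mean_A + 1) / (mean_B + 1))` of the normalized (linear,
#' `expm1` of log-normalized) expression, and
#' detection fractions `pct1`/`pct2` from raw counts. The returned table
#' keeps genes with `log2FC > lfc_min`, `pct1 > pct_min` and unadjusted
#' `p < alpha`, sorted by decreasing log2FC; a Benjamini-Hochberg column is
#' reported but not used for filtering.
#'
#' @param m Cells x genes raw count matrix.
#' @param groupA,groupB Disjoint cell-id (or index) vectors.
#' @param lfc_min,pct_min,alpha Filter thresholds.
#' @param norm Optional precomputed normalized matrix (defaults to
#'   [normalize_log()] of `m`).
#' @param keep_all Return all tested genes (unfiltered) when `TRUE`.
#' @return Tibble `gene`, `log2FC`, `pct1`, `pct2`, `p`, `p_adj`.
#' @export
differential_expression <- function(m, groupA, groupB, lfc_min = 0.75,
                                    pct_min = 0.25, alpha = 0.05,
                                    norm = NULL, keep_all = FALSE) {
  ia <- resolve_cells(m, groupA)
  ib <- resolve_cells(m, groupB)
  if (length(intersect(ia, ib)) > 0) rlang::abort("groups overlap")
  if (length(ia) == 0 || length(ib) == 0) rlang::abort("empty group")
  if (is.null(norm)) norm <- normalize_log(m)
  ma <- as.matrix(m)[ia, , drop = FALSE]
  mb <- as.matrix(m)[ib, , drop = FALSE]
  na <- norm[ia, , drop = FALSE]
  nb <- norm[ib, , drop = FALSE]
  expressed <- colSums(ma) + colSums(mb) > 0
  genes <- colnames(m)[expressed]
  p <- vapply(genes, function(g) {
    suppressWarnings(stats::wilcox.test(na[, g], nb[, g], exact = FALSE)$p.value)
  }, 0)
  p[is.na(p)] <- 1
  out <- tibble::tibble(
    gene = genes,
    log2FC = log2((colMeans(expm1(na[, genes, drop = FALSE])) + 1) /
                  (colMeans(expm1(nb[, genes, drop = FALSE])) + 1)),
    pct1 = colMeans(ma[, genes, drop = FALSE] > 0),
    pct2 = colMeans(mb[, genes, drop = FALSE] > 0),
    p = p,
    p_adj = stats::p.adjust(p, method = "BH")
  )
  if (!keep_all) {
    out <- dplyr::filter(out, .data$log2FC > lfc_min, .data$pct1 > pct_min,
                         .data$p < alpha)
  }
  dplyr::arrange(out, dplyr::desc(.data$log2FC))
}

resolve_cells <- function(m, ids) {
  if (is.numeric(ids)) return(as.integer(ids))
  match(ids, rownames(m))
}

#' Per-replicate label proportions
#'
#' Computes, for each replicate sample, the fraction of cells carrying each
#' label at the requested level, optionally restricting the denominator to
#' one class (e.g. GABAergic subclass fractions of the GABAergic population).
#' Fractions sum to 1 within each replicate.
#'
#' @param cells Cell-metadata tibble with columns `sample`, `class`,
#'   `subclass` (and optionally others).
#' @param level `"class"` or `"subclass"`.
#' @param within Optional class name restricting the denominator.
#' @return Tibble `sample`, `label`, `n`, `fraction`.
#' @export
subclass_proportions <- function(cells, level = c("subclass", "class"),
                                 within = NULL) {
  level <- match.arg(level)
  if (!is.null(within)) {
    cells <- dplyr::filter(cells, .data$class == within)
    if (nrow(cells) == 0) rlang::abort("empty denominator population")
  }
  cells |>
    dplyr::count(.data$sample, label = .data[[level]], name = "n") |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}
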