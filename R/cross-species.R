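# Cross-species operations: ortholog subsetting, lightweight integration,
# the cluster-overlap statistic, balanced iterative label transfer, confusion
# matrices, silhouette distances, and loading/profile correlations.

#' Restrict two count matrices to one-to-one orthologs
#'
#' Subsets both matrices to ortholog pairs present in both, aligning columns
#' in identical order under species-a gene naming.
#'
#' @param a,b Cells x genes count matrices.
#' @param map Tibble with columns `gene_a`, `gene_b` (strictly one-to-one).
#' @return List of the two aligned matrices (`a`, `b`); `b`'s columns are
#'   renamed to species-a ids.
#' @export
ortholog_subset <- function(a, b, map) {
  if (nrow(map) == 0) rlang::abort("empty ortholog map")
  if (anyDuplicated(map$gene_a) > 0 || anyDuplicated(map$gene_b) > 0) {
    rlang::abort("ortholog map is not one-to-one")
  }
  keep <- map$gene_a %in% colnames(a) & map$gene_b %in% colnames(b)
  map <- map[keep, ]
  map <- map[order(map$gene_a), ]
  a2 <- a[, map$gene_a, drop = FALSE]
  b2 <- b[, map$gene_b, drop = FALSE]
  colnames(b2) <- map$gene_a
  list(a = a2, b = b2)
}

#' Joint embedding of multiple datasets with a global MNN shift
#'
#' Z-scores each dataset per gene, computes a joint PCA to `D` components,
#' then applies to every non-reference dataset a single global translation:
#' the mean displacement across its mutual-nearest-neighbour pairs (k =
#' `mnn_k`) with the largest dataset. This removes a global batch offset
#' while leaving within-dataset geometry untouched; it is deterministic.
#'
#' @param parts Named list of normalized cells x genes matrices with aligned
#'   gene columns.
#' @param D Number of joint components.
#' @param mnn_k Neighbours per direction for MNN pairing.
#' @return List: `scores` (all cells x D, shifted), `dataset` (factor tag per
#'   row), `shifts` (per-dataset translation vectors), `embedding` (the joint
#'   `cc_embedding` before shifting).
#' @export
integrate_embed <- function(parts, D = 30, mnn_k = 20) {
  if (length(parts) < 2) rlang::abort("need at least 2 datasets")
  if (is.null(names(parts))) names(parts) <- paste0("dataset", seq_along(parts))
  gene_sets <- lapply(parts, colnames)
  if (length(unique(lapply(gene_sets, identity))) > 1) {
    shared <- Reduce(intersect, gene_sets)
    if (length(shared) < 2) rlang::abort("datasets share too few genes")
    parts <- lapply(parts, function(p) p[, shared, drop = FALSE])
  }
  zs <- lapply(parts, function(p) {
    p <- as.matrix(p)
    ctr <- colMeans(p)
    scl <- apply(p, 2, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    sweep(sweep(p, 2, ctr, "-"), 2, scl, "/")
  })
  joint <- do.call(rbind, zs)
  dataset <- factor(rep(names(parts), vapply(zs, nrow, 0L)),
                    levels = names(parts))
  D <- min(D, nrow(joint) - 1L, ncol(joint))
  sv <- svd(scale(joint, center = TRUE, scale = FALSE), nu = 0, nv = D)
  loadings <- sv$v
  scores <- scale(joint, center = TRUE, scale = FALSE) %*% loadings
  rownames(scores) <- unlist(lapply(parts, rownames), use.names = FALSE)

  sizes <- table(dataset)
  ref_name <- names(sizes)[which.max(sizes)]
  ref_idx <- which(dataset == ref_name)
  shifts <- stats::setNames(vector("list", length(parts)), names(parts))
  for (nm in names(parts)) {
    if (nm == ref_name) { shifts[[nm]] <- rep(0, D); next }
    qi <- which(dataset == nm)
    k <- min(mnn_k, length(ref_idx), length(qi))
    fwd <- knn_search(scores[qi, , drop = FALSE], scores[ref_idx, , drop = FALSE], k)
    rev <- knn_search(scores[ref_idx, , drop = FALSE], scores[qi, , drop = FALSE], k)
    # mutual pairs: (q, r) with r in q's knn and q in r's knn
    pairs <- NULL
    rev_sets <- split(rev$idx, row(rev$idx))
    for (i in seq_along(qi)) {
      for (j in fwd$idx[i, ]) {
        if (i %in% rev_sets[[j]]) pairs <- rbind(pairs, c(i, j))
      }
    }
    if (is.null(pairs) || nrow(pairs) == 0) {
      shifts[[nm]] <- rep(0, D)
      next
    }
    disp <- scores[ref_idx[pairs[, 2]], , drop = FALSE] -
      scores[qi[pairs[, 1]], , drop = FALSE]
    sh <- colMeans(disp)
    scores[qi, ] <- sweep(scores[qi, , drop = FALSE], 2, sh, "+")
    shifts[[nm]] <- sh
  }
  list(scores = scores, dataset = dataset, shifts = shifts,
       loadings = loadings)
}

#' Cluster-overlap fraction between subclasses
#'
#' For each pair of subclasses (i, j) sums, across integrated clusters, the
#' minimum of their within-cluster fractions:
#' `O(i, j) = sum_c min(n_ic / n_i, n_jc / n_j)`. Equals 1 iff the two
#' subclasses have identical cluster distributions, 0 iff they occupy
#' disjoint clusters; symmetric with unit diagonal.
#'
#' @param subclass_labels,cluster_labels Equal-length label vectors.
#' @return Symmetric numeric matrix (subclass x subclass) in \[0, 1\].
#' @export
cluster_overlap_fraction <- function(subclass_labels, cluster_labels) {
  stopifnot(length(subclass_labels) == length(cluster_labels))
  tab <- table(subclass_labels, cluster_labels)
  if (any(rowSums(tab) == 0)) rlang::abort("empty subclass")
  frac <- sweep(tab, 1, rowSums(tab), "/")
  s <- nrow(frac)
  out <- matrix(0, s, s, dimnames = list(rownames(frac), rownames(frac)))
  for (i in seq_len(s)) {
    for (j in seq_len(s)) {
      out[i, j] <- sum(pmin(frac[i, ], frac[j, ]))
    }
  }
  out
}

#' Balanced iterative reference-based label transfer
#'
#' Runs `n_iter` iterations. Each iteration draws at most `cap` cells per
#' subclass without replacement from a depleting per-subclass pool (pools
#' reset once exhausted, so every reference cell is used before any is
#' reused), fits a PCA embedding on the draw, projects the query, and votes
#' among the `k_vote` nearest reference cells with inverse-distance weights.
#' Final probabilities are the mean over iterations; the predicted label is
#' the argmax with lexicographic tie-breaking.
#'
#' @param ref_norm Normalized reference matrix (cells x genes).
#' @param ref_labels Reference subclass labels (length `nrow(ref_norm)`).
#' @param query_norm Normalized query matrix over the same genes.
#' @param n_iter Iterations.
#' @param cap Per-subclass cells drawn per iteration.
#' @param D Embedding dimensionality.
#' @param k_vote Reference neighbours voting per query cell.
#' @param seed RNG seed.
#' @return A `cc_transfer` list: `prob` (query x labels, rows sum to 1),
#'   `predicted`, `n_iter`, and `audit` (tibble of per-iteration per-subclass
#'   draw sizes and pool resets).
#' @export
balanced_label_transfer <- function(ref_norm, ref_labels, query_norm,
                                    n_iter = 100, cap = 100, D = 30,
                                    k_vote = 30, seed = 1) {
  if (cap < 1) rlang::abort("cap must be >= 1")
  labels <- sort(unique(ref_labels))
  if (length(labels) < 2) rlang::abort("need >= 2 reference subclasses")
  ref_norm <- as.matrix(ref_norm)
  query_norm <- as.matrix(query_norm)[, colnames(ref_norm), drop = FALSE]
  nq <- nrow(query_norm)
  probs <- matrix(0, nq, length(labels), dimnames = list(rownames(query_norm), labels))
  pools <- split(seq_len(nrow(ref_norm)), ref_labels)
  avail <- pools
  audit <- vector("list", n_iter)
  withr::with_seed(seed, {
    for (it in seq_len(n_iter)) {
      draw <- integer(0)
      rec <- tibble::tibble(iteration = it, subclass = names(pools),
                            drawn = 0L, reset = FALSE)
      for (li in seq_along(pools)) {
        lab <- names(pools)[li]
        take <- min(cap, length(avail[[lab]]))
        if (take > 0) {
          sel <- if (length(avail[[lab]]) == 1) avail[[lab]] else sample(avail[[lab]], take)
          avail[[lab]] <- setdiff(avail[[lab]], sel)
        } else {
          sel <- integer(0)
        }
        if (length(avail[[lab]]) == 0) {
          # pool exhausted: reset to the cells not in the current draw, or to
          # the full pool when one draw covers it entirely
          avail[[lab]] <- setdiff(pools[[lab]], sel)
          if (length(avail[[lab]]) == 0) avail[[lab]] <- pools[[lab]]
          rec$reset[li] <- TRUE
        }
        rec$drawn[li] <- length(sel)
        draw <- c(draw, sel)
      }
      audit[[it]] <- rec
      e <- pca_embed(ref_norm[draw, , drop = FALSE], D = D)
      qs <- project_embedding(e, query_norm)
      k <- min(k_vote, length(draw))
      nn <- knn_search(qs, e$scores, k)
      w <- 1 / (nn$dist + 1e-8)
      w <- w / rowSums(w)
      draw_labels <- ref_labels[draw]
      for (li in seq_along(labels)) {
        hit <- matrix(draw_labels[nn$idx] == labels[li], nrow = nq)
        probs[, li] <- probs[, li] + rowSums(w * hit)
      }
    }
  })
  probs <- probs / n_iter
  probs <- probs / rowSums(probs)
  pred <- labels[max.col(probs, ties.method = "first")]
  structure(list(prob = probs, predicted = pred, n_iter = n_iter,
                 labels = labels, audit = dplyr::bind_rows(audit)),
            class = "cc_transfer")
}

#' Row-normalized confusion matrix
#'
#' Rows are predicted labels, columns true labels; each row sums to 1 (rows
#' with no predictions are all-zero).
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @param labels Label universe (default: union of both, sorted).
#' @param row_normalize Divide rows by their totals.
#' @return Numeric matrix (predicted x true).
#' @export
confusion_matrix <- function(true_labels, predicted_labels, labels = NULL,
                             row_normalize = TRUE) {
  if (is.null(labels)) labels <- sort(unique(c(true_labels, predicted_labels)))
  tab <- table(factor(predicted_labels, levels = labels),
               factor(true_labels, levels = labels))
  out <- matrix(as.numeric(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
  if (row_normalize) {
    rs <- rowSums(out)
    nz <- rs > 0
    out[nz, ] <- out[nz, , drop = FALSE] / rs[nz]
  }
  out
}

#' Average silhouette between two groups in an embedding
#'
#' Standard silhouette restricted to the two groups (Euclidean distance on
#' the embedding scores); singletons score 0; returns the mean over all cells
#' of both groups. Near 0 for indistinguishable groups, near 1 for distant
#' tight clusters.
#'
#' @param scores Cells x D score matrix.
#' @param labels Per-cell labels.
#' @param pair Character vector of the two labels to compare.
#' @return Mean silhouette width in \[-1, 1\].
#' @export
silhouette_pairwise <- function(scores, labels, pair) {
  stopifnot(length(pair) == 2)
  ia <- which(labels == pair[1])
  ib <- which(labels == pair[2])
  if (length(ia) == 0 || length(ib) == 0) rlang::abort("empty group")
  idx <- c(ia, ib)
  grp <- rep(c(1L, 2L), c(length(ia), length(ib)))
  x <- as.matrix(scores)[idx, , drop = FALSE]
  d <- as.matrix(stats::dist(x))
  s <- vapply(seq_along(idx), function(i) {
    own <- which(grp == grp[i]); own <- setdiff(own, i)
    oth <- which(grp != grp[i])
    if (length(own) == 0) return(0)
    a <- mean(d[i, own])
    b <- mean(d[i, oth])
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}

#' Correlations between PC gene loadings of two embeddings
#'
#' Pearson correlations between the loading vectors of the first `top`
#' components of each embedding, restricted to one-to-one orthologs.
#'
#' @param e_a,e_b Fitted `cc_embedding` objects.
#' @param map Ortholog tibble `gene_a`, `gene_b`.
#' @param top Number of leading components from each side.
#' @return `top` x `top` matrix; rows = components of `e_a`, columns = of
#'   `e_b`.
#' @export
loading_correlations <- function(e_a, e_b, map, top = 4) {
  keep <- map$gene_a %in% rownames(e_a$loadings) &
    map$gene_b %in% rownames(e_b$loadings)
  map <- map[keep, ]
  if (nrow(map) < 2) rlang::abort("fewer than 2 shared genes")
  la <- e_a$loadings[map$gene_a, seq_len(top), drop = FALSE]
  lb <- e_b$loadings[map$gene_b, seq_len(top), drop = FALSE]
  out <- stats::cor(la, lb)
  dimnames(out) <- list(paste0("a_PC", seq_len(top)), paste0("b_PC", seq_len(top)))
  out
}

#' Spearman correlations between subclass-average expression profiles
#'
#' Averages (optionally within-group z-scored) normalized expression over the
#' top `n_hvg` highly variable genes per subclass, then computes Spearman
#' correlations between all label pairs.
#'
#' @param norm Normalized cells x genes matrix.
#' @param labels Per-cell subclass labels.
#' @param n_hvg HVGs used for the profiles.
#' @param zscore_within Optional per-cell group vector; expression is z-scored
#'   per gene within each group before averaging.
#' @return Tibble `label_a`, `label_b`, `rho` for all unordered pairs
#'   (including the unit diagonal).
#' @export
profile_correlations <- function(norm, labels, n_hvg = 3000,
                                 zscore_within = NULL) {
  labs <- sort(unique(labels))
  if (length(labs) < 2) rlang::abort("need >= 2 labels")
  n_hvg <- min(n_hvg, ncol(norm))
  hvgs <- select_hvgs(norm, n_hvg)
  x <- as.matrix(norm)[, hvgs, drop = FALSE]
  if (!is.null(zscore_within)) {
    for (g in unique(zscore_within)) {
      idx <- which(zscore_within == g)
      sub <- x[idx, , drop = FALSE]
      mu <- colMeans(sub)
      sdv <- apply(sub, 2, stats::sd)
      sdv[sdv == 0 | !is.finite(sdv)] <- 1
      x[idx, ] <- sweep(sweep(sub, 2, mu, "-"), 2, sdv, "/")
    }
  }
  prof <- vapply(labs, function(l) colMeans(x[labels == l, , drop = FALSE]),
                 numeric(ncol(x)))
  pairs <- expand.grid(a = seq_along(labs), b = seq_along(labs))
  pairs <- pairs[pairs$a <= pairs$b, ]
  tibble::tibble(
    label_a = labs[pairs$a], label_b = labs[pairs$b],
    rho = vapply(seq_len(nrow(pairs)), function(i) {
      stats::cor(prof[, pairs$a[i]], prof[, pairs$b[i]], method = "spearman")
    }, 0)
  )
}
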