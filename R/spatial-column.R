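# Spatial pseudocolumn analysis: QC and unit conversion, pseudocolumn
# pooling, multi-round kNN label assignment against a dissociated reference,
# and laminar statistics (subpial density profiles, Gini confinement, density
# ratios, depth-axis partial correlations).

#' Spatial quality control and micron conversion
#'
#' Keeps cells with at least `min_genes` detected genes and at least
#' `min_umis` UMIs, and converts platform coordinates to microns
#' (`units / units_per_um`).
#'
#' @param m Cells x genes count matrix.
#' @param cells Tibble with `cell_id`, `x_units`, `y_units` (y = depth axis,
#'   increasing away from the pia) and any metadata.
#' @param min_genes,min_umis Inclusive lower bounds ("fewer than" removed).
#' @param units_per_um Platform units per micron (2 for the targeted chip
#'   format).
#' @return List: filtered `counts` and `cells` with added `x_um`, `depth_um`.
#' @export
stereo_qc <- function(m, cells, min_genes = 50, min_umis = 100,
                      units_per_um = 2) {
  if (units_per_um <= 0) rlang::abort("units_per_um must be positive")
  stopifnot(nrow(cells) == nrow(m))
  keep <- cell_n_detected(m) >= min_genes & cell_totals(m) >= min_umis
  cells <- cells[keep, , drop = FALSE]
  cells$x_um <- cells$x_units / units_per_um
  cells$depth_um <- cells$y_units / units_per_um
  list(counts = m[keep, , drop = FALSE], cells = tibble::as_tibble(cells))
}

#' Pool ROIs into a pseudocolumn
#'
#' The largest ROI (by area) defines the target width and height; every other
#' ROI's x and depth coordinates are scaled to that extent, cells are pooled,
#' and the normalized subpial fraction (`depth_um / height`) is recomputed.
#'
#' @param rois List of QC'd ROIs as returned by [stereo_qc()] (each with
#'   `counts` and `cells` holding `x_um`, `depth_um`).
#' @return A `cc_column` list: `counts` (pooled), `cells` (with `x_um`,
#'   `depth_um`, `subpial_frac`, `roi`), `width_um`, `height_um`.
#' @export
build_pseudocolumn <- function(rois) {
  if (length(rois) == 0) rlang::abort("no ROIs")
  ext <- purrr::map(rois, function(r) {
    w <- max(r$cells$x_um) - min(r$cells$x_um)
    h <- max(r$cells$depth_um) - min(r$cells$depth_um)
    if (!is.finite(w) || !is.finite(h) || w <= 0 || h <= 0) {
      rlang::abort("ROI with zero extent")
    }
    c(w = w, h = h)
  })
  areas <- vapply(ext, function(e) e["w"] * e["h"], 0)
  tgt <- ext[[which.max(areas)]]
  pooled <- purrr::imap(rois, function(r, i) {
    e <- ext[[as.integer(i)]]
    cl <- r$cells
    cl$x_um <- (cl$x_um - min(cl$x_um)) * tgt["w"] / e["w"]
    cl$depth_um <- (cl$depth_um - min(cl$depth_um)) * tgt["h"] / e["h"]
    cl$roi <- as.integer(i)
    cl
  })
  cells <- dplyr::bind_rows(pooled)
  cells$subpial_frac <- cells$depth_um / tgt["h"]
  counts <- do.call(rbind, lapply(rois, function(r) as.matrix(r$counts)))
  rownames(counts) <- cells$cell_id <- make.unique(cells$cell_id)
  structure(list(counts = counts, cells = cells,
                 width_um = unname(tgt["w"]), height_um = unname(tgt["h"])),
            class = "cc_column")
}

#' Multi-round kNN label assignment against a dissociated reference
#'
#' Assigns reference labels to spatial cells over several rounds with
#' decreasing agreement thresholds. Each round jointly embeds the currently
#' unassigned spatial cells with the reference ([integrate_embed()]; in round
#' 1 the reference is randomly downsampled to the query count), takes each
#' query cell's `k` nearest reference neighbours, and assigns the plurality
#' label when its neighbour fraction meets the round's threshold. Assigned
#' cells are removed before the next round; later rounds use the full
#' reference. Plurality ties leave the cell unassigned that round.
#'
#' @param query_norm Normalized spatial cells x genes matrix.
#' @param ref_norm Normalized reference matrix over the same genes.
#' @param ref_labels Reference label vector.
#' @param thresholds Non-increasing per-round agreement fractions
#'   (class-level default `c(1, 1, 0.75)`; use `c(1, 0.75, 0.5)` for
#'   subclasses).
#' @param k Reference neighbours consulted per query cell.
#' @param D Integration dimensionality.
#' @param seed RNG seed (round-1 downsampling).
#' @return Tibble `cell_id`, `label` (NA when unassigned), `round` (NA when
#'   unassigned).
#' @export
assign_labels_multiround <- function(query_norm, ref_norm, ref_labels,
                                     thresholds = c(1, 1, 0.75), k = 50,
                                     D = 30, seed = 1) {
  if (any(diff(thresholds) > 0)) rlang::abort("thresholds must be non-increasing")
  query_norm <- as.matrix(query_norm)
  ref_norm <- as.matrix(ref_norm)[, colnames(query_norm), drop = FALSE]
  nq <- nrow(query_norm)
  label <- rep(NA_character_, nq)
  round_assigned <- rep(NA_integer_, nq)
  withr::with_seed(seed, {
    for (r in seq_along(thresholds)) {
      un <- which(is.na(label))
      if (length(un) == 0) break
      if (r == 1 && nrow(ref_norm) > length(un)) {
        ridx <- sort(sample(nrow(ref_norm), length(un)))
      } else {
        ridx <- seq_len(nrow(ref_norm))
      }
      if (k > length(ridx)) rlang::abort("k exceeds the (downsampled) reference size")
      emb <- integrate_embed(list(ref = ref_norm[ridx, , drop = FALSE],
                                  query = query_norm[un, , drop = FALSE]),
                             D = D)
      rs <- emb$scores[emb$dataset == "ref", , drop = FALSE]
      qs <- emb$scores[emb$dataset == "query", , drop = FALSE]
      nn <- knn_search(qs, rs, k)
      labs <- ref_labels[ridx]
      for (i in seq_along(un)) {
        votes <- table(labs[nn$idx[i, ]])
        best <- max(votes)
        if (sum(votes == best) > 1) next          # plurality tie
        if (best / k >= thresholds[r]) {
          label[un[i]] <- names(votes)[which.max(votes)]
          round_assigned[un[i]] <- r
        }
      }
    }
  })
  tibble::tibble(cell_id = rownames(query_norm) %||% as.character(seq_len(nq)),
                 label = label, round = round_assigned)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Subpial kernel density profile of a subclass
#'
#' Gaussian kernel density of the normalized subpial depth of one label,
#' reflected at the boundaries 0 and 1 so the profile integrates to 1 over
#' the column.
#'
#' @param col A `cc_column` (or any list with `cells$subpial_frac` and
#'   `cells$label`-bearing column named by `label_col`).
#' @param label Label whose profile to compute (>= 2 cells).
#' @param bandwidth_frac Kernel bandwidth on the normalized depth scale.
#' @param label_col Column of `col$cells` holding labels.
#' @param n_grid Evaluation grid size.
#' @return Tibble `subpial_frac`, `density`.
#' @export
subpial_density_profile <- function(col, label, bandwidth_frac = 0.05,
                                    label_col = "subclass", n_grid = 256) {
  x <- col$cells$subpial_frac[col$cells[[label_col]] %in% label]
  x <- x[!is.na(x)]
  if (length(x) < 2) rlang::abort("need >= 2 cells of the label")
  # reflection at both boundaries
  aug <- c(x, -x, 2 - x)
  d <- stats::density(aug, bw = bandwidth_frac, from = 0, to = 1, n = n_grid)
  dens <- d$y * 3  # augmented sample has 3x the mass on [0,1]'s reflection
  dens <- dens / (sum(dens) * (d$x[2] - d$x[1]))  # exact renormalization
  tibble::tibble(subpial_frac = d$x, density = dens)
}

#' Gini index of laminar confinement
#'
#' Bins one label's normalized subpial depths into `n_bins` equal-width bins
#' and computes the Gini index of the bin counts,
#' `sum_ij |c_i - c_j| / (2 B sum c)`: 0 for a depth-uniform population, up
#' to `(B - 1) / B` when confined to a single bin.
#'
#' @inheritParams subpial_density_profile
#' @param n_bins Number of depth bins.
#' @return Gini index in `[0, (B - 1) / B]`.
#' @export
gini_subpial <- function(col, label, n_bins = 20, label_col = "subclass") {
  x <- col$cells$subpial_frac[col$cells[[label_col]] %in% label]
  x <- x[!is.na(x)]
  if (length(x) == 0) rlang::abort("no cells of the label")
  bins <- pmin(pmax(ceiling(x * n_bins), 1), n_bins)
  gini_counts(tabulate(bins, nbins = n_bins))
}

#' Gini index of a count vector
#'
#' @param counts Non-negative bin counts.
#' @return `sum_ij |c_i - c_j| / (2 B sum c)`.
#' @export
gini_counts <- function(counts) {
  B <- length(counts)
  tot <- sum(counts)
  if (tot == 0) rlang::abort("zero total count")
  sum(abs(outer(counts, counts, "-"))) / (2 * B * tot)
}

#' Ratio of target densities below vs. above a reference median depth
#'
#' Splits the column at the median subpial depth of `reference_label`, and
#' returns the ratio of the target label's extent-normalized densities:
#' `(n_below / extent_below) / (n_above / extent_above)`, extents measured on
#' the normalized depth interval \[0, 1\]. A depth-uniform target gives 1
#' regardless of the split.
#'
#' @inheritParams subpial_density_profile
#' @param target_label,reference_label Labels present in the column.
#' @return The density ratio (0 when no target cell lies below the split).
#' @export
density_ratio_below_above <- function(col, target_label, reference_label,
                                      label_col = "subclass") {
  sp <- col$cells$subpial_frac
  labv <- col$cells[[label_col]]
  tgt <- sp[!is.na(labv) & labv == target_label]
  ref <- sp[!is.na(labv) & labv == reference_label]
  if (length(tgt) == 0 || length(ref) == 0) rlang::abort("label absent from column")
  split <- stats::median(ref)
  if (split <= 0 || split >= 1) rlang::abort("degenerate split depth")
  below <- sum(tgt > split)   # below the pia-relative split = deeper
  above <- sum(tgt <= split)
  (below / (1 - split)) / (above / split)
}

#' Partial Spearman correlations of depth with two vertex distances
#'
#' Rank-transforms depth and the two transcriptomic vertex distances, then
#' computes each depth-distance partial correlation controlling for the
#' alternate distance:
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`.
#' Significance comes from a permutation null that permutes depth only,
#' keeping the (dist_b, dist_c) pairs intact;
#' `p = (1 + #\{|r_perm| >= |r_obs|\}) / (1 + n_perm)`.
#'
#' @param depth,dist_b,dist_c Equal-length numeric vectors (n >= 10), none
#'   constant.
#' @param n_perm Permutations.
#' @param seed RNG seed.
#' @return Tibble with `axis` (`"b"`, `"c"`), `rho_partial`, `p`.
#' @export
depth_axis_partial_correlation <- function(depth, dist_b, dist_c,
                                           n_perm = 10000, seed = 1) {
  n <- length(depth)
  stopifnot(length(dist_b) == n, length(dist_c) == n)
  if (n < 10) rlang::abort("need >= 10 observations")
  if (stats::sd(depth) == 0 || stats::sd(dist_b) == 0 || stats::sd(dist_c) == 0) {
    rlang::abort("constant variable")
  }
  rd <- rank(depth); rb <- rank(dist_b); rc <- rank(dist_c)
  obs_b <- partial_cor(rd, rb, rc)
  obs_c <- partial_cor(rd, rc, rb)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      rp <- sample(rd)
      c(partial_cor(rp, rb, rc), partial_cor(rp, rc, rb))
    }, c(0, 0))
  })
  tibble::tibble(
    axis = c("b", "c"),
    rho_partial = c(obs_b, obs_c),
    p = c((1 + sum(abs(perm[1, ]) >= abs(obs_b))) / (1 + n_perm),
          (1 + sum(abs(perm[2, ]) >= abs(obs_c))) / (1 + n_perm))
  )
}

partial_cor <- function(x, y, z) {
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  den <- sqrt((1 - rxz^2) * (1 - ryz^2))
  if (den == 0) return(NA_real_)
  (rxy - rxz * ryz) / den
}
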