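# Archetypal geometry of expression continua: principal convex hull analysis
# (PCHA), automated vertex-count selection, vertex distances / barycentric
# weights, and a continuum-vs-discrete shuffle test.

#' Principal convex hull (archetypal) analysis
#'
#' Fits K archetypes to embedded cells by minimizing
#' `||X' - X' C S||^2` over `C` (cells x K, columns non-negative with sums in
#' `[1 - delta, 1 + delta]`) and `S` (K x cells, columns on the simplex),
#' where `X'` is the internally centered data transposed to dims x cells.
#' Archetypes are convex (delta-relaxed) combinations of data points; each
#' cell is reconstructed as a convex mixture of archetypes. Optimization is
#' alternating projected gradient with per-block adaptive step sizes and a
#' backtracking line search, so the SSE is non-increasing across iterations;
#' initialization is furthest-sum seeding.
#'
#' @param X Cells x D score matrix.
#' @param noc Number of archetypes K (>= 1, <= cells).
#' @param delta Relaxation of the archetype simplex constraint (0 keeps
#'   archetypes inside the convex hull).
#' @param max_iter,tol Convergence controls (relative SSE change).
#' @param seed Seed for the furthest-sum start.
#' @param init_C Optional warm-start C matrix (cells x K).
#' @param init_S Optional warm-start S matrix (K x cells); default assigns
#'   each cell to its nearest initial archetype.
#' @return A `cc_polytope`: `K`, `archetypes` (K x D, original space), `S`
#'   (K x cells), `C`, `delta`, `sse`, `ev` (`1 - sse/tss`), `sse_path`,
#'   `center`, `converged`, `n_iter`.
#' @export
pcha_fit <- function(X, noc, delta = 0, max_iter = 300, tol = 1e-6, seed = 1,
                     init_C = NULL, init_S = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) rlang::abort("non-finite values in X")
  n <- nrow(X); d <- ncol(X)
  if (noc < 1 || noc > n) rlang::abort("noc must be in [1, cells]")
  center <- colMeans(X)
  Xt <- t(X) - center            # d x n, centered
  tss <- sum(Xt^2)

  C <- if (!is.null(init_C)) {
    stopifnot(nrow(init_C) == n, ncol(init_C) == noc)
    init_C
  } else {
    seeds_idx <- withr::with_seed(seed, furthest_sum(Xt, noc))
    Cm <- matrix(0, n, noc)
    Cm[cbind(seeds_idx, seq_len(noc))] <- 1
    Cm
  }
  A <- Xt %*% C                  # d x K archetypes (centered space)
  if (!is.null(init_S)) {
    stopifnot(nrow(init_S) == noc, ncol(init_S) == n)
    S <- init_S
  } else {
    # init S: nearest archetype
    S <- matrix(1e-3, noc, n)
    nearest <- knn_search(t(Xt), t(A), 1)$idx[, 1]
    S[cbind(nearest, seq_len(n))] <- 1
    S <- sweep(S, 2, colSums(S), "/")
  }

  sse <- sum((Xt - A %*% S)^2)
  sse_path <- sse
  muS <- 1; muC <- 1
  it <- 0; converged <- FALSE
  while (it < max_iter) {
    it <- it + 1
    # --- S update (line-searched projected gradient)
    R <- A %*% S - Xt
    gS <- crossprod(A, R)        # K x n
    # remove each column's component along the current point so small steps
    # stay tangent to the simplex (clamp-renormalize preserves descent)
    gS <- gS - rep(colSums(gS * S), each = nrow(gS))
    for (ls in 1:20) {
      S_new <- project_simplex_cols(S - muS * gS)
      sse_new <- sum((Xt - A %*% S_new)^2)
      if (sse_new <= sse) { S <- S_new; sse <- sse_new; muS <- muS * 1.2; break }
      muS <- muS / 2
    }
    # --- C update
    R <- A %*% S - Xt
    gC <- crossprod(Xt, R %*% t(S))   # n x K
    gC <- gC - rep(colSums(gC * C), each = nrow(gC))
    for (ls in 1:20) {
      C_new <- project_band_cols(C - muC * gC, delta)
      A_new <- Xt %*% C_new
      sse_new <- sum((Xt - A_new %*% S)^2)
      if (sse_new <= sse) {
        C <- C_new; A <- A_new; sse <- sse_new; muC <- muC * 1.2; break
      }
      muC <- muC / 2
    }
    sse_path <- c(sse_path, sse)
    prev <- sse_path[length(sse_path) - 1]
    if (prev - sse < tol * max(prev, 1e-12)) { converged <- TRUE; break }
  }
  arch <- t(A) + matrix(center, noc, d, byrow = TRUE)
  colnames(arch) <- colnames(X)
  structure(list(K = as.integer(noc), archetypes = arch, S = S, C = C,
                 delta = delta, sse = sse, ev = 1 - sse / tss, tss = tss,
                 sse_path = sse_path, center = center,
                 converged = converged, n_iter = it),
            class = "cc_polytope")
}

# Furthest-sum seeding: greedily pick points maximizing summed distance to
# the already-picked set (random first pick, then first pick replaced).
furthest_sum <- function(Xt, K) {
  n <- ncol(Xt)
  if (K >= n) return(seq_len(K))
  picked <- sample.int(n, 1)
  for (j in seq_len(K)) {
    sumd <- rep(0, n)
    for (p in picked) {
      sumd <- sumd + sqrt(colSums((Xt - Xt[, p])^2))
    }
    sumd[picked] <- -Inf
    nxt <- which.max(sumd)
    if (j == 1) picked <- nxt else picked <- c(picked, nxt)
  }
  picked[seq_len(K)]
}

# Column-wise projection onto the simplex (clamp negatives, renormalize).
project_simplex_cols <- function(M) {
  M[M < 0] <- 0
  cs <- colSums(M)
  zero <- cs == 0
  if (any(zero)) { M[, zero] <- 1 / nrow(M); cs[zero] <- 1 }
  sweep(M, 2, cs, "/")
}

# Column-wise projection onto {x >= 0, sum(x) in [1-delta, 1+delta]}.
project_band_cols <- function(M, delta) {
  M[M < 0] <- 0
  cs <- colSums(M)
  zero <- cs == 0
  if (any(zero)) { M[, zero] <- 1 / nrow(M); cs[zero] <- 1 }
  target <- pmin(pmax(cs, 1 - delta), 1 + delta)
  sweep(M, 2, target / cs, "*")
}

#' Automated vertex-count selection by the explained-variance elbow
#'
#' Fits [pcha_fit()] for every candidate vertex count (best of `n_restarts`
#' furthest-sum starts plus one warm start that extends the previous
#' candidate's best solution with the furthest point, which makes the best
#' explained variance non-decreasing in K). The selected K maximizes the
#' perpendicular distance of the point `(K, ev(K))` to the chord joining the
#' first and last candidates; ties go to the smallest K.
#'
#' @param X Cells x D score matrix.
#' @param candidates Integer candidate counts (>= 3 values).
#' @param delta Simplex relaxation passed to the fits.
#' @param n_restarts Random restarts per candidate.
#' @param seed Base seed; restart r of candidate K uses `seed + 1000 K + r`.
#' @param ... Passed to [pcha_fit()].
#' @return A `cc_vertex_selection`: `K` (selected), `profile` tibble
#'   (`K`, `sse`, `ev`, `chord_distance`), and `fits` (best fit per K).
#' @export
select_vertex_count <- function(X, candidates = 2:10, delta = 0,
                                n_restarts = 5, seed = 1, ...) {
  candidates <- sort(unique(as.integer(candidates)))
  if (length(candidates) < 3) rlang::abort("need >= 3 candidate vertex counts")
  fits <- vector("list", length(candidates))
  prev_best <- NULL
  for (ci in seq_along(candidates)) {
    K <- candidates[ci]
    best <- NULL
    for (r in seq_len(n_restarts)) {
      f <- pcha_fit(X, noc = K, delta = delta, seed = seed + 1000L * K + r, ...)
      if (is.null(best) || f$sse < best$sse) best <- f
    }
    if (!is.null(prev_best)) {
      warm <- augment_C(prev_best, X, K)
      if (!is.null(warm)) {
        # warm start reproduces the previous solution exactly (new archetypes
        # carry zero mixture weight), so best ev is non-decreasing in K
        f <- pcha_fit(X, noc = K, delta = delta, seed = seed,
                      init_C = warm$C, init_S = warm$S, ...)
        if (f$sse < best$sse) best <- f
      }
    }
    fits[[ci]] <- best
    prev_best <- best
  }
  ev <- vapply(fits, function(f) f$ev, 0)
  dist <- chord_distances(candidates, ev)
  K_star <- candidates[which.max(dist)]  # first max = smallest K on ties
  profile <- tibble::tibble(K = candidates,
                            sse = vapply(fits, function(f) f$sse, 0),
                            ev = ev, chord_distance = dist)
  structure(list(K = K_star, profile = profile, fits = fits),
            class = "cc_vertex_selection")
}

# Warm start for K archetypes from a (K - gap) fit: copy C and add unit
# columns on the points currently worst reconstructed; S gains zero rows for
# the new archetypes so the initial SSE equals the previous fit's.
augment_C <- function(fit, X, K) {
  K0 <- fit$K
  if (K <= K0) return(NULL)
  Xt <- t(as.matrix(X)) - fit$center
  resid <- colSums((Xt - (Xt %*% fit$C) %*% fit$S)^2)
  extra <- order(-resid)[seq_len(K - K0)]
  C <- cbind(fit$C, matrix(0, nrow(fit$C), K - K0))
  C[cbind(extra, K0 + seq_len(K - K0))] <- 1
  S <- rbind(fit$S, matrix(0, K - K0, ncol(fit$S)))
  list(C = C, S = S)
}

#' Perpendicular distances to the first-last chord
#'
#' Distance of each point `(x_i, y_i)` to the straight line through the first
#' and last points — the "kneedle"-style elbow criterion. Degenerate chords
#' (first = last point) give all-zero distances.
#'
#' @param x,y Equal-length numeric vectors.
#' @return Numeric vector of distances.
#' @export
chord_distances <- function(x, y) {
  n <- length(x)
  p1 <- c(x[1], y[1]); p2 <- c(x[n], y[n])
  v <- p2 - p1
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(rep(0, n))
  vapply(seq_len(n), function(i) {
    w <- c(x[i], y[i]) - p1
    abs(v[1] * w[2] - v[2] * w[1]) / nv
  }, 0)
}

#' Vertex distances and barycentric weights
#'
#' Euclidean distance from every cell to every archetype (full embedding
#' space). For triangles (K = 3) additionally computes barycentric
#' coordinates in a specified component plane, clamped to \[0, 1\] and
#' renormalized for cells outside the triangle; interior cells are
#' reconstructed exactly.
#'
#' @param X Cells x D score matrix the polytope was fitted on.
#' @param p A `cc_polytope`.
#' @param plane Length-2 component indices for the barycentric plane
#'   (default `c(1, 2)` when K = 3; an error for other K).
#' @return Tibble with `dist_<k>` columns and, for K = 3, `bary_1..3`.
#' @export
vertex_geometry <- function(X, p, plane = NULL) {
  X <- as.matrix(X)
  K <- p$K
  if (!is.null(plane) && K != 3) rlang::abort("plane is only valid for K = 3")
  d2 <- outer(rowSums(X^2), rowSums(p$archetypes^2), "+") -
    2 * X %*% t(p$archetypes)
  d2[d2 < 0] <- 0
  out <- tibble::as_tibble(sqrt(d2), .name_repair = "minimal")
  names(out) <- paste0("dist_", seq_len(K))
  if (K == 3) {
    if (is.null(plane)) plane <- c(1, 2)
    V <- p$archetypes[, plane, drop = FALSE]
    P <- X[, plane, drop = FALSE]
    T <- cbind(V[1, ] - V[3, ], V[2, ] - V[3, ])
    det_t <- T[1, 1] * T[2, 2] - T[1, 2] * T[2, 1]
    if (abs(det_t) < 1e-12) rlang::abort("degenerate triangle in the requested plane")
    rel <- sweep(P, 2, V[3, ], "-")
    l1 <- (T[2, 2] * rel[, 1] - T[1, 2] * rel[, 2]) / det_t
    l2 <- (-T[2, 1] * rel[, 1] + T[1, 1] * rel[, 2]) / det_t
    b <- cbind(l1, l2, 1 - l1 - l2)
    b[b < 0] <- 0
    b[b > 1] <- 1
    b <- b / rowSums(b)
    out$bary_1 <- b[, 1]; out$bary_2 <- b[, 2]; out$bary_3 <- b[, 3]
  }
  out
}

#' Continuum-vs-discrete shuffle test between two subclasses
#'
#' Tests whether two subclasses form a genuine expression continuum rather
#' than discrete clusters blurred by noisy gene expression. The statistic is
#' the kernel-density minimum along the centroid-difference axis between the
#' two subclass medians, divided by the smaller of the densities at the two
#' medians (near 1 = continuum, near 0 = density gap). The null preserves
#' per-gene marginals but destroys gene-gene covariance: within each subclass
#' every gene's values are independently permuted across that subclass's
#' cells, and the statistic recomputed.
#'
#' @param norm Normalized cells x genes matrix.
#' @param labels Per-cell subclass labels.
#' @param pair The two subclass labels to test (each with >= 10 cells).
#' @param n_shuffles Null permutations.
#' @param seed RNG seed.
#' @return A `cc_shuffle_test` list: `statistic`, `null` (length
#'   `n_shuffles`), `p` (`(1 + #\{T_null >= T_obs\}) / (1 + n_shuffles)`).
#' @export
continuum_shuffle_test <- function(norm, labels, pair, n_shuffles = 100,
                                   seed = 1) {
  stopifnot(length(pair) == 2)
  ia <- which(labels == pair[1]); ib <- which(labels == pair[2])
  if (length(ia) < 10 || length(ib) < 10) rlang::abort("subclass with < 10 cells")
  x <- as.matrix(norm)
  xa <- x[ia, , drop = FALSE]; xb <- x[ib, , drop = FALSE]
  t_obs <- continuum_statistic(xa, xb)
  nulls <- withr::with_seed(seed, {
    vapply(seq_len(n_shuffles), function(s) {
      pa <- apply(xa, 2, sample)
      pb <- apply(xb, 2, sample)
      continuum_statistic(pa, pb)
    }, 0)
  })
  p <- (1 + sum(nulls >= t_obs)) / (1 + n_shuffles)
  structure(list(statistic = t_obs, null = nulls, p = p, pair = pair),
            class = "cc_shuffle_test")
}

# Density-trough statistic along the centroid-difference axis.
continuum_statistic <- function(xa, xb) {
  u <- colMeans(xa) - colMeans(xb)
  nu <- sqrt(sum(u^2))
  if (nu == 0) return(1)
  u <- u / nu
  pa <- as.numeric(xa %*% u)
  pb <- as.numeric(xb %*% u)
  ma <- stats::median(pa); mb <- stats::median(pb)
  lo <- min(ma, mb); hi <- max(ma, mb)
  dens <- stats::density(c(pa, pb), n = 512,
                         from = lo - 0.05 * (hi - lo + 1e-9),
                         to = hi + 0.05 * (hi - lo + 1e-9))
  d_at <- function(v) stats::approx(dens$x, dens$y, xout = v, rule = 2)$y
  between <- dens$x >= lo & dens$x <= hi
  trough <- if (any(between)) min(dens$y[between]) else min(d_at(lo), d_at(hi))
  ref <- min(d_at(ma), d_at(mb))
  if (ref <= 0) return(1)
  min(trough / ref, 1)
}
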