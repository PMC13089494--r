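# Shared fixtures, built in code at test time.

# Small labeled count matrix with explicit per-cell (genes, umis) design.
toy_counts <- function() {
  m <- matrix(0L, 5, 7000,
              dimnames = list(paste0("c", 1:5), sprintf("g%04d", 1:7000)))
  fill_cell <- function(i, n_genes, n_umis) {
    m[i, seq_len(n_genes)] <<- 1L
    extra <- n_umis - n_genes
    if (extra > 0) m[i, 1] <<- m[i, 1] + as.integer(extra)
  }
  fill_cell(1, 800, 100 + 700)      # detected 800, umis >= detected
  fill_cell(2, 700, 800)
  fill_cell(3, 900, 40000)
  fill_cell(4, 6500, 6700)
  fill_cell(5, 1000, 39999)
  m
}

# Two well-separated Gaussian blobs in D dims.
two_blobs <- function(n_per = 100, d = 5, gap = 20, seed = 7) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * d), n_per, d),
               matrix(rnorm(n_per * d) + gap, n_per, d))
    rownames(x) <- paste0("p", seq_len(2 * n_per))
    x
  })
}

# Points drawn from the simplex spanned by K given vertices; alpha < 1
# concentrates mass toward the vertices (specialist-rich sampling).
simplex_points <- function(vertices, n, seed = 1, alpha = 1) {
  withr::with_seed(seed, {
    k <- nrow(vertices)
    w <- matrix(rgamma(n * k, alpha), n, k)
    w <- w / rowSums(w)
    w %*% vertices
  })
}

# Same-pipeline centroid gap without the MNN shift (oracle for the
# integration test).
centroid_gap_unshifted <- function(x, y, D) {
  zs <- lapply(list(x, y), function(p) scale(p))
  joint <- rbind(zs[[1]], zs[[2]])
  sv <- svd(scale(joint, scale = FALSE), nu = 0, nv = D)
  s <- scale(joint, scale = FALSE) %*% sv$v
  sqrt(sum((colMeans(s[1:nrow(x), ]) - colMeans(s[-(1:nrow(x)), ]))^2))
}

# Minimal pseudocolumn from explicit subpial fractions and labels.
toy_column <- function(subpial_frac, labels) {
  structure(list(
    cells = tibble::tibble(cell_id = paste0("c", seq_along(subpial_frac)),
                           subpial_frac = subpial_frac, subclass = labels),
    width_um = 400, height_um = 1200
  ), class = "cc_column")
}

# Pixel mask of all 5-15 um annuli around the given centers.
ring_pixel_mask <- function(f, centers) {
  ny <- nrow(f$image); nx <- ncol(f$image)
  px <- f$px_size_um
  xs <- ((seq_len(nx)) - 0.5) * px
  ys <- ((seq_len(ny)) - 0.5) * px
  m <- matrix(FALSE, ny, nx)
  for (i in seq_len(nrow(centers))) {
    d2 <- outer((ys - centers$y_um[i])^2, (xs - centers$x_um[i])^2, "+")
    m <- m | (d2 >= 25 & d2 <= 225)
  }
  m
}

# Small histology field with a flat or custom image and straight pia at y=0.
toy_field <- function(image, px_size_um = 2,
                      pv = tibble::tibble(x_um = numeric(0), y_um = numeric(0)),
                      layers = NULL) {
  ny <- nrow(image); nx <- ncol(image)
  if (is.null(layers)) {
    layers <- list(all = tibble::tibble(
      x_um = c(0, nx * px_size_um, nx * px_size_um, 0),
      y_um = c(0, 0, ny * px_size_um, ny * px_size_um)))
  }
  structure(list(
    image = image, px_size_um = px_size_um,
    pial_polyline = tibble::tibble(x_um = c(0, nx * px_size_um), y_um = 0),
    cortical_mask = matrix(TRUE, ny, nx),
    layer_polygons = layers,
    pv_centroids = pv
  ), class = "cc_histofield")
}
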