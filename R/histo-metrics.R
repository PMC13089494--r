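# Immunofluorescence quantification: morphological background correction,
# arc-length areal profiles along the pial surface, layer densities, and
# PV-centered perineuronal-net enrichment against a depth-matched null.

#' Background subtraction and percentile normalization
#'
#' Removes smooth background by grayscale morphological opening with a disk
#' structuring element, clips negatives, and normalizes to the given
#' percentile of the corrected signal within the cortical mask. Constant
#' offsets are removed exactly; structures smaller than the disk are
#' preserved.
#'
#' @param f A `cc_histofield` (image, `px_size_um`, `cortical_mask`, ...).
#' @param radius_um Structuring-element radius in microns (>= 1 pixel).
#' @param percentile Normalization percentile of in-mask corrected values.
#' @return The corrected image matrix (same shape, roughly in \[0, 1\]).
#' @export
background_subtract_normalize <- function(f, radius_um = 50, percentile = 99.5) {
  if (sum(f$cortical_mask) == 0) rlang::abort("empty cortical mask")
  r_px <- radius_um / f$px_size_um
  if (r_px < 1) rlang::abort("structuring element below one pixel")
  size <- 2L * as.integer(floor(r_px)) + 1L
  kern <- EBImage::makeBrush(size, shape = "disc")
  opened <- EBImage::opening(f$image, kern)
  corrected <- pmax(f$image - opened, 0)
  q <- stats::quantile(corrected[f$cortical_mask], percentile / 100,
                       names = FALSE, type = 7)
  # sparse foregrounds can put the percentile at zero; fall back to the max
  if (q <= 0) q <- max(corrected[f$cortical_mask])
  if (q <= 0) return(corrected * 0)
  corrected / q
}

# Arc-length coordinate of points projected onto the pial polyline.
# Returns list(arc, dist): cumulative arc-length of the nearest polyline
# point and the projection distance ("depth").
project_to_polyline <- function(px, py, polyline) {
  vx <- polyline$x_um; vy <- polyline$y_um
  m <- length(vx)
  if (m < 2) rlang::abort("degenerate polyline")
  seglen <- sqrt(diff(vx)^2 + diff(vy)^2)
  cum <- c(0, cumsum(seglen))
  best_d2 <- rep(Inf, length(px))
  best_arc <- rep(0, length(px))
  for (s in seq_len(m - 1)) {
    ax <- vx[s]; ay <- vy[s]
    dx <- vx[s + 1] - ax; dy <- vy[s + 1] - ay
    L2 <- dx^2 + dy^2
    t <- ((px - ax) * dx + (py - ay) * dy) / L2
    t <- pmin(pmax(t, 0), 1)
    qx <- ax + t * dx; qy <- ay + t * dy
    d2 <- (px - qx)^2 + (py - qy)^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_arc[upd] <- cum[s] + t[upd] * seglen[s]
  }
  list(arc = best_arc, dist = sqrt(best_d2))
}

#' Areal PV density and median intensity along the pial surface
#'
#' Projects PV centroids and in-mask cortical pixels onto the nearest point
#' of the pial polyline, assigns arc-length coordinates, and summarizes
#' fixed-width arc bins: PV density as cells per mm^2 (counts normalized to
#' the bin's in-mask pixel area) and median intensity across the bin's
#' pixels (`NA` for empty bins).
#'
#' @param f A `cc_histofield`.
#' @param bin_width_um Arc-length bin width (> 0).
#' @param image Intensity image to summarize (default the field's image; pass
#'   a [background_subtract_normalize()] output for corrected intensities).
#' @return Tibble `bin_start_um`, `n_cells`, `area_mm2`, `density_per_mm2`,
#'   `median_intensity`.
#' @export
arc_length_profile <- function(f, bin_width_um, image = f$image) {
  if (bin_width_um <= 0) rlang::abort("bin_width_um must be positive")
  px <- f$px_size_um
  ny <- nrow(image); nx <- ncol(image)
  # pixel centers, restricted to the cortical mask
  keep <- which(f$cortical_mask)
  pix_y <- ((keep - 1) %% ny + 1 - 0.5) * px
  pix_x <- ((keep - 1) %/% ny + 1 - 0.5) * px
  proj_pix <- project_to_polyline(pix_x, pix_y, f$pial_polyline)
  proj_pv <- project_to_polyline(f$pv_centroids$x_um, f$pv_centroids$y_um,
                                 f$pial_polyline)
  max_arc <- max(proj_pix$arc, proj_pv$arc, 0)
  breaks <- seq(0, max_arc + bin_width_um, by = bin_width_um)
  bin_pix <- findInterval(proj_pix$arc, breaks, rightmost.closed = FALSE)
  bin_pv <- findInterval(proj_pv$arc, breaks, rightmost.closed = FALSE)
  nb <- length(breaks) - 1
  vals <- image[keep]
  tibble::tibble(
    bin_start_um = breaks[seq_len(nb)],
    n_cells = vapply(seq_len(nb), function(b) sum(bin_pv == b), 0),
    area_mm2 = vapply(seq_len(nb), function(b) sum(bin_pix == b), 0) *
      (px^2 / 1e6),
    median_intensity = vapply(seq_len(nb), function(b) {
      v <- vals[bin_pix == b]
      if (length(v) == 0) NA_real_ else stats::median(v)
    }, 0)
  ) |>
    dplyr::mutate(density_per_mm2 = ifelse(.data$area_mm2 > 0,
                                           .data$n_cells / .data$area_mm2, 0))
}

# Even-odd rule point-in-polygon.
point_in_polygon <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (poly_y[i] > py) != (poly_y[j] > py)
    xint <- (poly_x[j] - poly_x[i]) * (py - poly_y[i]) /
      (poly_y[j] - poly_y[i]) + poly_x[i]
    inside <- xor(inside, cross & (px < xint))
    j <- i
  }
  inside
}

polygon_area_mm2 <- function(poly) {
  x <- poly$x_um; y <- poly$y_um
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x * y[j] - x[j] * y)) / 2 / 1e6
}

#' Layer-specific centroid densities
#'
#' Counts PV centroids inside each layer polygon (a centroid on a shared
#' boundary is counted for the first containing polygon in declared order)
#' and divides by the polygon area in mm^2.
#'
#' @param f A `cc_histofield` with `layer_polygons` and `pv_centroids`.
#' @return Tibble `layer`, `n_cells`, `area_mm2`, `density_per_mm2`.
#' @export
layer_densities <- function(f) {
  assigned <- rep(NA_character_, nrow(f$pv_centroids))
  for (nm in names(f$layer_polygons)) {
    poly <- f$layer_polygons[[nm]]
    if (polygon_area_mm2(poly) == 0) rlang::abort("zero-area layer polygon")
    hit <- point_in_polygon(f$pv_centroids$x_um, f$pv_centroids$y_um,
                            poly$x_um, poly$y_um)
    take <- is.na(assigned) & hit
    assigned[take] <- nm
  }
  tibble::tibble(
    layer = names(f$layer_polygons),
    n_cells = vapply(names(f$layer_polygons),
                     function(nm) sum(assigned == nm, na.rm = TRUE), 0,
                     USE.NAMES = FALSE),
    area_mm2 = unname(vapply(f$layer_polygons, polygon_area_mm2, 0)),
    density_per_mm2 = .data$n_cells / .data$area_mm2
  )
}

# Median intensity within an annulus [r_in, r_out] around (cx, cy); NA if
# any part of the bounding box leaves the image or the annulus has no mask
# pixels.
annulus_median <- function(image, mask, px, cx, cy, r_in, r_out) {
  ny <- nrow(image); nx <- ncol(image)
  xs <- floor((cx - r_out) / px + 0.5):ceiling((cx + r_out) / px + 0.5)
  ys <- floor((cy - r_out) / px + 0.5):ceiling((cy + r_out) / px + 0.5)
  if (min(xs) < 1 || max(xs) > nx || min(ys) < 1 || max(ys) > ny) return(NA_real_)
  dx <- (xs - 0.5) * px - cx
  dy <- (ys - 0.5) * px - cy
  d2 <- outer(dy^2, dx^2, "+")
  hit <- d2 >= r_in^2 & d2 <= r_out^2 & mask[ys, xs]
  if (!any(hit)) return(NA_real_)
  stats::median(image[ys, xs][hit])
}

#' PV-centered perineuronal-net enrichment vs. a depth-matched null
#'
#' For each PV centroid, enrichment is the median intensity in a perisomatic
#' annulus (`r_in_um`-`r_out_um`) minus the median in a surrounding local
#' background annulus (`bg_in_um`-`bg_out_um`). The null samples, per PV
#' cell, `n_null_per_cell` cortical points whose depth (distance to the pial
#' surface) is drawn from the observed PV depths with small uniform jitter
#' and whose arc-length position is uniform, excluding points within
#' `r_out_um` of any PV centroid; the same metric is computed there. Cells or
#' null points whose background annulus exits the image/mask are dropped
#' (symmetric censoring).
#'
#' @param f A `cc_histofield`.
#' @param image Corrected intensity image ([background_subtract_normalize()]
#'   output; defaults to correcting the field's image).
#' @param r_in_um,r_out_um Perisomatic annulus radii.
#' @param bg_in_um,bg_out_um Local background annulus radii.
#' @param n_null_per_cell Null points per PV cell.
#' @param depth_jitter_um Uniform jitter half-width for null depths.
#' @param seed RNG seed.
#' @return A list: `observed` (per-cell enrichments), `null` (null
#'   enrichments), `median_difference` (median observed - median null), and
#'   `null_se` (bootstrap-free SE of the null median difference estimate,
#'   `sd(null)/sqrt(n)` scaled for the median).
#' @export
pv_pnn_association <- function(f, image = background_subtract_normalize(f),
                               r_in_um = 5, r_out_um = 15, bg_in_um = 25,
                               bg_out_um = 50, n_null_per_cell = 10,
                               depth_jitter_um = 5, seed = 1) {
  px <- f$px_size_um
  pv <- f$pv_centroids
  obs <- vapply(seq_len(nrow(pv)), function(i) {
    a <- annulus_median(image, f$cortical_mask, px, pv$x_um[i], pv$y_um[i],
                        r_in_um, r_out_um)
    b <- annulus_median(image, f$cortical_mask, px, pv$x_um[i], pv$y_um[i],
                        bg_in_um, bg_out_um)
    a - b
  }, 0)
  obs <- obs[!is.na(obs)]

  depths <- project_to_polyline(pv$x_um, pv$y_um, f$pial_polyline)$dist
  poly <- f$pial_polyline
  seglen <- sqrt(diff(poly$x_um)^2 + diff(poly$y_um)^2)
  cum <- c(0, cumsum(seglen))
  total_arc <- cum[length(cum)]
  nulls <- withr::with_seed(seed, {
    out <- numeric(0)
    n_target <- nrow(pv) * n_null_per_cell
    tries <- 0
    while (length(out) < n_target && tries < 20 * n_target) {
      tries <- tries + 1
      dpt <- sample(depths, 1) + stats::runif(1, -depth_jitter_um, depth_jitter_um)
      if (dpt < 0) next
      s <- stats::runif(1, 0, total_arc)
      seg <- findInterval(s, cum, rightmost.closed = TRUE)
      seg <- min(max(seg, 1), length(seglen))
      t <- (s - cum[seg]) / seglen[seg]
      bx <- poly$x_um[seg] + t * (poly$x_um[seg + 1] - poly$x_um[seg])
      by <- poly$y_um[seg] + t * (poly$y_um[seg + 1] - poly$y_um[seg])
      # inward unit normal (chosen as +90 deg rotation; fields have the pia
      # on top with depth increasing in +y)
      nxv <- -(poly$y_um[seg + 1] - poly$y_um[seg]) / seglen[seg]
      nyv <- (poly$x_um[seg + 1] - poly$x_um[seg]) / seglen[seg]
      cx <- bx + nxv * dpt * sign(nyv + 1e-12)
      cy <- by + abs(nyv) * dpt
      if (nrow(pv) > 0) {
        if (min((pv$x_um - cx)^2 + (pv$y_um - cy)^2) < r_out_um^2) next
      }
      a <- annulus_median(image, f$cortical_mask, px, cx, cy, r_in_um, r_out_um)
      b <- annulus_median(image, f$cortical_mask, px, cx, cy, bg_in_um, bg_out_um)
      if (is.na(a) || is.na(b)) next
      out <- c(out, a - b)
    }
    out
  })
  if (length(nulls) == 0) rlang::abort("no valid null points")
  list(observed = obs, null = nulls,
       median_difference = stats::median(obs) - stats::median(nulls),
       null_se = 1.2533 * stats::sd(nulls) / sqrt(length(nulls)))
}
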