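# Synthetic data generator: emulates the statistical structure of the three
# input modalities (snRNA-seq atlas, spatial pseudocolumn, histology field)
# plus a toy gene annotation, with recorded ground truth for recovery tests.

#' Subclass taxonomy used by the synthetic generator
#'
#' Three classes (glutamatergic, GABAergic, non-neuronal). The glutamatergic
#' class contains four intratelencephalic (IT) subclasses named per species
#' (layer-named in mouse, letter-named in opossum, mirroring how continuum
#' subclasses are labeled when layer identity is ambiguous) plus two
#' projection subclasses; the GABAergic class covers the five interneuron
#' subclasses whose proportions the presets control.
#'
#' @param species `"mouse"` or `"opossum"`.
#' @param gabaergic_proportions Named simplex vector over the GABAergic
#'   subclasses; defaults to the preset of `species`.
#' @return A tibble with columns `class`, `subclass`, `prop_within_class`.
#' @export
cc_taxonomy <- function(species = c("mouse", "opossum"),
                        gabaergic_proportions = NULL) {
  species <- match.arg(species)
  it <- it_subclass_names(species)
  if (is.null(gabaergic_proportions)) {
    gabaergic_proportions <- default_gaba_proportions(species)
  }
  glut <- tibble::tibble(
    class = "glutamatergic",
    subclass = c(it, "L5PT", "L6CT"),
    prop_within_class = c(rep(0.175, 4), 0.15, 0.15)
  )
  gaba <- tibble::tibble(
    class = "GABAergic",
    subclass = names(gabaergic_proportions),
    prop_within_class = unname(gabaergic_proportions)
  )
  nn <- tibble::tibble(
    class = "non-neuronal",
    subclass = c("Oligo", "Astro"),
    prop_within_class = c(0.5, 0.5)
  )
  dplyr::bind_rows(glut, gaba, nn)
}

it_subclass_names <- function(species) {
  if (species == "mouse") c("L23", "L4", "L5IT", "L6IT") else c("IT_A", "IT_B", "IT_C", "IT_D")
}

default_gaba_proportions <- function(species) {
  if (species == "mouse") {
    c(Pvalb = 0.35, Sst = 0.27, Vip = 0.17, Lamp5 = 0.13, Frem1 = 0.08)
  } else {
    c(Pvalb = 0.50, Sst = 0.28, Vip = 0.10, Lamp5 = 0.08, Frem1 = 0.04)
  }
}

default_depth_law <- function(species) {
  it <- it_subclass_names(species)
  law <- list()
  law[[it[1]]] <- c(mean = 200, sd = 80)
  law[[it[2]]] <- c(mean = 450, sd = 60)
  law[[it[3]]] <- c(mean = 700, sd = 90)
  law[[it[4]]] <- c(mean = 950, sd = 90)
  law[["L5PT"]] <- c(mean = 700, sd = 70)
  law[["L6CT"]] <- c(mean = 1000, sd = 70)
  law[["Pvalb"]] <- c(mean = 600, sd = 250)
  law[["Sst"]] <- c(mean = 600, sd = 250)
  law[["Vip"]] <- c(mean = 250, sd = 150)
  law[["Lamp5"]] <- c(mean = 150, sd = 100)
  law[["Frem1"]] <- c(mean = 250, sd = 150)
  law[["Oligo"]] <- c(mean = 1000, sd = 150)
  law[["Astro"]] <- c(mean = 600, sd = 300)
  law
}

#' Generator configuration with species presets
#'
#' Builds the configuration object consumed by all four generators. The two
#' species presets differ only in: GABAergic subclass proportions (Pvalb 0.35
#' in mouse vs. 0.50 in opossum), the concentration of IT archetype mixture
#' weights (vertex-peaked in mouse; spread across the A-B-C face in opossum),
#' sequencing depth (opossum shallower), PV cell density (opossum 1.2x), and
#' perineuronal-net placement (`pv_centered` in mouse, `deep_layer_random` in
#' opossum). Everything else is shared so cross-preset contrasts isolate those
#' differences.
#'
#' @param species `"mouse"` or `"opossum"` preset.
#' @param n_cells,n_genes Atlas size (cells x genes).
#' @param it_archetypes Number of IT archetype programs (one per modeled
#'   cortical layer 2/3, 4, 5, 6).
#' @param archetype_concentration Base Dirichlet parameters (length
#'   `it_archetypes`) for IT mixture weights.
#' @param archetype_vertex_bonus Added to the Dirichlet parameter of a cell's
#'   own subclass archetype; large values pin subclasses to vertices.
#' @param noise_sd Gaussian sd added to latent log-expression.
#' @param nb_dispersion Negative-binomial size parameter shared by all genes.
#' @param library_size_meanlog,library_size_sdlog Log-normal per-cell library
#'   size (total UMIs) parameters for the atlas modality.
#' @param spatial_library_meanlog Log-normal meanlog for the shallower spatial
#'   modality.
#' @param gabaergic_proportions Named simplex vector over GABAergic
#'   subclasses; overrides the preset.
#' @param depth_law Named list, subclass -> `c(mean, sd)` subpial depth (um).
#' @param column_height_um,column_width_um Pseudocolumn extent.
#' @param pv_density_per_mm2 PV centroid density for histology fields.
#' @param pnn_mode `"pv_centered"`, `"deep_layer_random"`, or `"none"`.
#' @param marker_strength Latent log-expression boost of subclass/archetype
#'   marker blocks.
#' @param program_seed Seed fixing the species' gene programs (the "biology");
#'   kept separate from `seed` so independently seeded atlases of one species
#'   share marker structure and can serve as reference/query pairs.
#' @param sample_counts If `FALSE`, skip count sampling and return rounded
#'   expected counts (used to test the noise-free geometry of the latent
#'   space).
#' @param keep_latent Store the dense latent log-expression matrix in the
#'   truth record (memory permitting).
#' @param n_samples Number of replicate samples cells are assigned to.
#' @param seed Integer seed for all stochastic draws.
#' @return A `cc_config` list.
#' @export
generator_config <- function(species = c("mouse", "opossum"),
                             n_cells = 5000,
                             n_genes = 2000,
                             it_archetypes = 4,
                             archetype_concentration = NULL,
                             archetype_vertex_bonus = NULL,
                             noise_sd = 0.3,
                             nb_dispersion = 2,
                             library_size_meanlog = NULL,
                             library_size_sdlog = 0.35,
                             spatial_library_meanlog = log(800),
                             gabaergic_proportions = NULL,
                             depth_law = NULL,
                             column_height_um = 1200,
                             column_width_um = 400,
                             pv_density_per_mm2 = NULL,
                             pnn_mode = NULL,
                             marker_strength = 3,
                             program_seed = NULL,
                             sample_counts = TRUE,
                             keep_latent = FALSE,
                             n_samples = 4,
                             seed = 1) {
  species <- match.arg(species)
  if (is.null(archetype_concentration)) {
    archetype_concentration <- if (species == "mouse") {
      rep(0.2, it_archetypes)
    } else {
      c(rep(0.8, it_archetypes - 1), 0.2)
    }
  }
  if (is.null(archetype_vertex_bonus)) {
    archetype_vertex_bonus <- if (species == "mouse") 6 else 2
  }
  if (is.null(library_size_meanlog)) {
    library_size_meanlog <- if (species == "mouse") log(6000) else log(4000)
  }
  if (is.null(gabaergic_proportions)) {
    gabaergic_proportions <- default_gaba_proportions(species)
  }
  if (is.null(depth_law)) depth_law <- default_depth_law(species)
  if (is.null(pv_density_per_mm2)) {
    pv_density_per_mm2 <- if (species == "mouse") 300 else 360
  }
  if (is.null(pnn_mode)) {
    pnn_mode <- if (species == "mouse") "pv_centered" else "deep_layer_random"
  }
  if (is.null(program_seed)) {
    program_seed <- if (species == "mouse") 101L else 202L
  }
  cfg <- list(
    species = species, n_cells = as.integer(n_cells),
    n_genes = as.integer(n_genes), it_archetypes = as.integer(it_archetypes),
    archetype_concentration = archetype_concentration,
    archetype_vertex_bonus = archetype_vertex_bonus,
    noise_sd = noise_sd, nb_dispersion = nb_dispersion,
    library_size_meanlog = library_size_meanlog,
    library_size_sdlog = library_size_sdlog,
    spatial_library_meanlog = spatial_library_meanlog,
    gabaergic_proportions = gabaergic_proportions,
    depth_law = depth_law,
    column_height_um = column_height_um, column_width_um = column_width_um,
    pv_density_per_mm2 = pv_density_per_mm2, pnn_mode = pnn_mode,
    marker_strength = marker_strength, program_seed = as.integer(program_seed),
    sample_counts = sample_counts, keep_latent = keep_latent,
    n_samples = as.integer(n_samples), seed = as.integer(seed)
  )
  class(cfg) <- c("cc_config", "list")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$n_cells < 0 || cfg$n_genes <= 0) rlang::abort("cell/gene counts must be positive")
  if (cfg$it_archetypes < 1) rlang::abort("it_archetypes must be >= 1")
  if (abs(sum(cfg$gabaergic_proportions) - 1) > 1e-9) {
    rlang::abort("gabaergic_proportions must sum to 1 within 1e-9")
  }
  if (any(cfg$gabaergic_proportions < 0)) rlang::abort("negative proportion")
  if (cfg$nb_dispersion <= 0) rlang::abort("nb_dispersion must be positive")
  if (cfg$noise_sd < 0) rlang::abort("noise_sd must be nonnegative")
  if (any(cfg$archetype_concentration <= 0)) rlang::abort("Dirichlet parameters must be positive")
  if (!cfg$pnn_mode %in% c("pv_centered", "deep_layer_random", "none")) {
    rlang::abort("unknown pnn_mode")
  }
  invisible(cfg)
}

#' IT-continuum preset
#'
#' A reduced configuration producing only the four-archetype IT continuum
#' (glutamatergic IT cells, no other classes), sized for archetype-geometry
#' experiments: 2,000 cells by 300 genes at default noise.
#'
#' @inheritParams generator_config
#' @param ... Passed to [generator_config()].
#' @return A `cc_config` with attribute `it_only = TRUE`.
#' @export
preset_it_continuum <- function(species = "mouse", n_cells = 2000,
                                n_genes = 300, seed = 1, ...) {
  cfg <- generator_config(species = species, n_cells = n_cells,
                          n_genes = n_genes, seed = seed, ...)
  cfg$it_only <- TRUE
  cfg
}

# Fixed per-species gene programs: a baseline vector plus disjoint marker
# blocks for each non-IT subclass and each IT archetype. Drawn under
# program_seed so they are invariant across dataset seeds.
gene_programs <- function(cfg) {
  tax <- cc_taxonomy(cfg$species, cfg$gabaergic_proportions)
  it <- it_subclass_names(cfg$species)
  non_it <- setdiff(tax$subclass, it)
  units <- c(paste0("arch", seq_len(cfg$it_archetypes)), non_it)
  block <- max(5L, as.integer(round(cfg$n_genes * 0.01)))
  needed <- block * length(units)
  if (needed > cfg$n_genes) block <- max(2L, cfg$n_genes %/% (length(units) + 1L))
  progs <- withr::with_seed(cfg$program_seed, {
    base <- stats::rnorm(cfg$n_genes, 0, 0.5)
    m <- matrix(rep(base, length(units)), nrow = length(units), byrow = TRUE)
    rownames(m) <- units
    for (i in seq_along(units)) {
      idx <- ((i - 1L) * block + 1L):(i * block)
      idx <- idx[idx <= cfg$n_genes]
      m[i, idx] <- m[i, idx] + cfg$marker_strength
    }
    m
  })
  list(programs = progs, it_units = paste0("arch", seq_len(cfg$it_archetypes)),
       gene_ids = sprintf("gene%04d", seq_len(cfg$n_genes)))
}

# Latent log-expression -> NB counts, chunked over cells.
sample_counts_from_latent <- function(latent, cfg, lib_meanlog) {
  n <- nrow(latent)
  libs <- stats::rlnorm(n, meanlog = lib_meanlog, sdlog = cfg$library_size_sdlog)
  rates <- softplus(latent)
  p <- rates / rowSums(rates)
  mu <- p * libs
  if (cfg$sample_counts) {
    cnt <- matrix(stats::rnbinom(length(mu), mu = as.numeric(t(mu)),
                                 size = cfg$nb_dispersion),
                  nrow = n, byrow = TRUE)
  } else {
    cnt <- round(mu)
  }
  storage.mode(cnt) <- "integer"
  cnt
}

#' Generate a synthetic single-nucleus atlas
#'
#' Draws subclass labels from the configured class/subclass proportions,
#' builds latent log-expression (IT cells as convex mixtures of archetype
#' programs with Dirichlet weights; other subclasses as discrete marker
#' programs), adds Gaussian noise, and samples negative-binomial UMI counts
#' against log-normal library sizes. Identical configuration and seed give
#' bit-identical output.
#'
#' @param config A [generator_config()] object.
#' @return A list with `counts` (cells x genes integer matrix), `cells`
#'   (tibble: cell_id, sample, species, class, subclass), and `truth`
#'   (archetype weights for IT cells, generative proportions, and the latent
#'   matrix when `keep_latent`).
#' @export
generate_atlas <- function(config) {
  validate_config(config)
  gp <- gene_programs(config)
  withr::with_seed(config$seed, {
    tax <- cc_taxonomy(config$species, config$gabaergic_proportions)
    if (isTRUE(config$it_only)) {
      tax <- tax[tax$subclass %in% it_subclass_names(config$species), ]
      tax$prop_within_class <- 1 / nrow(tax)
      class_probs <- c(glutamatergic = 1)
    } else {
      class_probs <- c(glutamatergic = 0.55, GABAergic = 0.25, `non-neuronal` = 0.20)
    }
    n <- config$n_cells
    cls <- sample_labels(n, class_probs)
    sub <- character(n)
    for (cl in unique(cls)) {
      idx <- which(cls == cl)
      tt <- tax[tax$class == cl, ]
      probs <- stats::setNames(tt$prop_within_class / sum(tt$prop_within_class),
                               tt$subclass)
      sub[idx] <- sample_labels(length(idx), probs)
    }
    out <- build_expression(cls, sub, gp, config, config$library_size_meanlog)
    cells <- tibble::tibble(
      cell_id = rownames(out$counts),
      sample = sample(sprintf("%s_rep%d", config$species, seq_len(config$n_samples)),
                      n, replace = TRUE),
      species = config$species, class = cls, subclass = sub
    )
    truth <- list(
      weights = out$weights, subclass = sub,
      proportions = list(class = class_probs,
                         gabaergic = config$gabaergic_proportions),
      latent = out$latent, config = config
    )
    list(counts = out$counts, cells = cells, truth = truth)
  })
}

# Shared latent/count construction for atlas and spatial generators.
# `weights_override` supplies depth-conditioned IT weights (spatial modality).
build_expression <- function(cls, sub, gp, config, lib_meanlog,
                             weights_override = NULL) {
  n <- length(sub)
  K <- config$it_archetypes
  it_names <- it_subclass_names(config$species)
  A <- gp$programs[gp$it_units, , drop = FALSE]
  is_it <- sub %in% it_names
  W <- matrix(NA_real_, n, K, dimnames = list(NULL, gp$it_units))
  if (any(is_it)) {
    if (is.null(weights_override)) {
      for (k in seq_len(K)) {
        idx <- which(is_it & sub == it_names[k])
        if (length(idx) == 0) next
        alpha <- config$archetype_concentration
        alpha[k] <- alpha[k] + config$archetype_vertex_bonus
        W[idx, ] <- rdirichlet(length(idx), alpha)
      }
    } else {
      W[is_it, ] <- weights_override[is_it, , drop = FALSE]
    }
  }
  latent <- matrix(0, n, config$n_genes)
  if (any(is_it)) latent[is_it, ] <- W[is_it, , drop = FALSE] %*% A
  for (sc in setdiff(unique(sub), it_names)) {
    idx <- which(sub == sc)
    latent[idx, ] <- matrix(rep(gp$programs[sc, ], length(idx)),
                            nrow = length(idx), byrow = TRUE)
  }
  if (config$noise_sd > 0) {
    latent <- latent + matrix(stats::rnorm(n * config$n_genes, 0, config$noise_sd),
                              n, config$n_genes)
  }
  counts <- sample_counts_from_latent(latent, config, lib_meanlog)
  rownames(counts) <- sprintf("cell%05d", seq_len(n))
  colnames(counts) <- gp$gene_ids
  list(counts = counts, weights = W,
       latent = if (isTRUE(config$keep_latent)) latent else NULL)
}

#' Generate a synthetic spatial pseudocolumn
#'
#' Cells receive an (x, depth) coordinate: depth is drawn from the configured
#' per-subclass depth law (truncated normal within the column), and IT cells'
#' archetype mixture weights are drawn from a depth-conditioned Dirichlet so
#' transcriptomic identity covaries with laminar position. Coordinates are
#' emitted in platform units (2 units per micron) so the spatial QC conversion
#' is exercised downstream; the truth record keeps microns.
#'
#' @param config A [generator_config()]; `depth_law` must cover every
#'   generated subclass.
#' @param n_cells Number of cells in the column (defaults to
#'   `config$n_cells`).
#' @return A list with `counts`, `cells` (tibble including `x_units`,
#'   `y_units` platform coordinates), and `truth` (depth in microns, archetype
#'   weights, config).
#' @export
generate_spatial <- function(config, n_cells = config$n_cells) {
  validate_config(config)
  gp <- gene_programs(config)
  withr::with_seed(config$seed + 77L, {
    tax <- cc_taxonomy(config$species, config$gabaergic_proportions)
    class_probs <- c(glutamatergic = 0.55, GABAergic = 0.25, `non-neuronal` = 0.20)
    n <- as.integer(n_cells)
    if (n == 0) {
      empty <- matrix(0L, 0, config$n_genes,
                      dimnames = list(character(0), gp$gene_ids))
      return(list(counts = empty,
                  cells = tibble::tibble(cell_id = character(0),
                                         x_units = numeric(0), y_units = numeric(0),
                                         species = character(0), subclass = character(0)),
                  truth = list(depth_um = numeric(0), weights = NULL,
                               config = config)))
    }
    cls <- sample_labels(n, class_probs)
    sub <- character(n)
    for (cl in unique(cls)) {
      idx <- which(cls == cl)
      tt <- tax[tax$class == cl, ]
      probs <- stats::setNames(tt$prop_within_class / sum(tt$prop_within_class),
                               tt$subclass)
      sub[idx] <- sample_labels(length(idx), probs)
    }
    missing_law <- setdiff(unique(sub), names(config$depth_law))
    if (length(missing_law) > 0) {
      rlang::abort(paste0("depth_law missing for subclass: ",
                          paste(missing_law, collapse = ", ")))
    }
    H <- config$column_height_um
    depth <- numeric(n)
    for (sc in unique(sub)) {
      idx <- which(sub == sc)
      law <- config$depth_law[[sc]]
      depth[idx] <- rtruncnorm(length(idx), law["mean"], law["sd"], 0, H)
    }
    x <- stats::runif(n, 0, config$column_width_um)

    # Depth-conditioned IT archetype weights: Dirichlet concentration follows
    # Gaussian bumps at each archetype's home depth.
    it_names <- it_subclass_names(config$species)
    K <- config$it_archetypes
    mu_k <- vapply(it_names[seq_len(K)], function(s) config$depth_law[[s]]["mean"], 0)
    tau <- 150
    is_it <- sub %in% it_names
    W <- matrix(NA_real_, n, K)
    if (any(is_it)) {
      g <- exp(-outer(depth[is_it], mu_k, function(d, m) (d - m)^2) / (2 * tau^2))
      g <- g / rowSums(g)
      conc_total <- 8
      idx <- which(is_it)
      for (i in seq_along(idx)) {
        W[idx[i], ] <- rdirichlet(1, pmax(conc_total * g[i, ], 0.02))
      }
    }
    out <- build_expression(cls, sub, gp, config, config$spatial_library_meanlog,
                            weights_override = W)
    cells <- tibble::tibble(
      cell_id = rownames(out$counts),
      x_units = x * 2, y_units = depth * 2,
      species = config$species, class = cls, subclass = sub
    )
    truth <- list(depth_um = depth, weights = out$weights, subclass = sub,
                  latent = out$latent, config = config)
    list(counts = out$counts, cells = cells, truth = truth)
  })
}

#' Generate a synthetic histology field
#'
#' Builds a single-channel fluorescence image (additive vertical background
#' gradient plus Gaussian noise), PV centroids from a Poisson process with
#' layer-specific intensities, and — depending on `pnn_mode` — annular
#' perineuronal-net intensity (5-15 um) painted either at PV centroids
#' (`pv_centered`) or at random deep-layer sites away from PV centroids
#' (`deep_layer_random`).
#'
#' @param config A [generator_config()] with `pv_density_per_mm2 > 0`.
#' @param width_um,height_um Field extent in microns.
#' @param px_size_um Pixel size (microns per pixel).
#' @param ring_amplitude Added intensity inside painted annuli.
#' @param background_noise_sd Gaussian pixel noise sd.
#' @return A list with `field` (a `cc_histofield`: image, px_size_um,
#'   pial_polyline, cortical_mask, layer_polygons, pv_centroids) and `truth`
#'   (background image, ring centers, generative density, pnn_mode).
#' @export
generate_histo <- function(config, width_um = 2000, height_um = 1200,
                           px_size_um = 2, ring_amplitude = 0.5,
                           background_noise_sd = 0.05) {
  validate_config(config)
  if (config$pv_density_per_mm2 <= 0) rlang::abort("pv_density_per_mm2 must be > 0")
  withr::with_seed(config$seed + 131L, {
    nx <- as.integer(width_um / px_size_um)
    ny <- as.integer(height_um / px_size_um)
    yy <- matrix(rep(seq_len(ny), nx), ny, nx)
    background <- 0.2 + 0.2 * (yy / ny)
    img <- background
    if (background_noise_sd > 0) {
      img <- img + matrix(stats::rnorm(ny * nx, 0, background_noise_sd), ny, nx)
    }

    # laminar bands as fractions of the column height (anchored on a
    # 1200-um column: L1 to 100, L2/3 to 400, L4 to 550, L5 to 800)
    fr <- c(0, 100, 400, 550, 800, 1200) / 1200
    bounds <- fr * height_um
    layers <- list(
      L1 = bounds[1:2], L23 = bounds[2:3], L4 = bounds[3:4],
      L5 = bounds[4:5], L6 = bounds[5:6]
    )
    layer_polygons <- purrr::imap(layers, function(b, nm) {
      tibble::tibble(x_um = c(0, width_um, width_um, 0),
                     y_um = c(b[1], b[1], b[2], b[2]))
    })
    # Layer-specific PV intensity; weights renormalized so the field-wide
    # expectation equals pv_density_per_mm2.
    weight <- c(L1 = 0.05, L23 = 0.9, L4 = 1.3, L5 = 1.3, L6 = 0.9)
    area_mm2 <- vapply(layers, function(b) (b[2] - b[1]) * width_um / 1e6, 0)
    scale <- config$pv_density_per_mm2 * sum(area_mm2) / sum(weight * area_mm2)
    lam <- weight * scale * area_mm2
    pv <- purrr::imap(layers, function(b, nm) {
      k <- stats::rpois(1, lam[nm])
      tibble::tibble(x_um = stats::runif(k, 0, width_um),
                     y_um = stats::runif(k, b[1], b[2]))
    })
    pv_centroids <- dplyr::bind_rows(pv)

    ring_centers <- NULL
    if (config$pnn_mode == "pv_centered") {
      ring_centers <- pv_centroids
    } else if (config$pnn_mode == "deep_layer_random") {
      k <- nrow(pv_centroids)
      cand <- tibble::tibble(x_um = stats::runif(3 * k, 0, width_um),
                             y_um = stats::runif(3 * k, 0.58 * height_um,
                                                 height_um - 20))
      if (nrow(pv_centroids) > 0) {
        nn <- knn_search(as.matrix(cand), as.matrix(pv_centroids), 1)
        cand <- cand[nn$dist[, 1] > 30, ]
      }
      ring_centers <- utils::head(cand, k)
    }
    if (!is.null(ring_centers) && nrow(ring_centers) > 0) {
      img <- paint_annuli(img, ring_centers, px_size_um,
                          r_in_um = 5, r_out_um = 15, amplitude = ring_amplitude)
    }
    img[img < 0] <- 0

    field <- structure(list(
      image = img, px_size_um = px_size_um,
      pial_polyline = tibble::tibble(x_um = seq(0, width_um, length.out = 21),
                                     y_um = 0),
      cortical_mask = matrix(TRUE, ny, nx),
      layer_polygons = layer_polygons,
      pv_centroids = pv_centroids
    ), class = "cc_histofield")
    truth <- list(background = background, ring_centers = ring_centers,
                  pv_density_per_mm2 = config$pv_density_per_mm2,
                  field_area_mm2 = width_um * height_um / 1e6,
                  pnn_mode = config$pnn_mode, config = config)
    list(field = field, truth = truth)
  })
}

# Add `amplitude` to all pixels whose distance to a center is in
# [r_in_um, r_out_um]; vectorized over the bounding box of each annulus.
paint_annuli <- function(img, centers, px_size_um, r_in_um, r_out_um, amplitude) {
  ny <- nrow(img); nx <- ncol(img)
  r_px <- r_out_um / px_size_um
  for (i in seq_len(nrow(centers))) {
    cx <- centers$x_um[i] / px_size_um
    cy <- centers$y_um[i] / px_size_um
    xs <- max(1L, floor(cx - r_px)):min(nx, ceiling(cx + r_px))
    ys <- max(1L, floor(cy - r_px)):min(ny, ceiling(cy + r_px))
    if (length(xs) == 0 || length(ys) == 0) next
    # pixel centers at (j - 0.5) * px in each axis
    dx <- (xs - 0.5) * px_size_um - centers$x_um[i]
    dy <- (ys - 0.5) * px_size_um - centers$y_um[i]
    d2 <- outer(dy^2, dx^2, "+")
    hit <- d2 >= r_in_um^2 & d2 <= r_out_um^2
    img[ys, xs][hit] <- img[ys, xs][hit] + amplitude
  }
  img
}

#' Generate a toy gene annotation plus read intervals
#'
#' Lays out non-overlapping genes along a single toy chromosome on both
#' strands with a controlled inter-gene spacing, assigns biotypes and 3' UTR
#' presence, and places read intervals at a configured offset downstream of
#' each gene's 3' end (plus optional intragenic reads, which downstream
#' profiling must exclude).
#'
#' @param config A [generator_config()] (only its seed is used).
#' @param n_genes_per_strand Genes per strand.
#' @param gene_length_bp Gene length.
#' @param gap_bp Spacing between consecutive same-strand genes, measured as
#'   `next start - previous end`.
#' @param read_offset_bp Distance of placed intergenic reads downstream of the
#'   3' end (0 = first base past the gene).
#' @param reads_per_gene Intergenic reads per gene (0 = none).
#' @param intragenic_reads_per_gene Reads placed inside each gene body.
#' @param read_length_bp Read interval length.
#' @param utr3_spike_bp Length assigned to the short-UTR half of genes (the
#'   annotation-artifact spike); the rest get `utr3_long_bp`.
#' @param utr3_long_bp Length assigned to long-UTR genes.
#' @param chrom_length_bp Toy chromosome length.
#' @return List with `genes` (gene-model tibble), `reads` (interval tibble),
#'   and `chrom_lengths` (named vector).
#' @export
generate_annotation_fixture <- function(config = generator_config(),
                                        n_genes_per_strand = 6,
                                        gene_length_bp = 2000,
                                        gap_bp = 12000,
                                        read_offset_bp = 2000,
                                        reads_per_gene = 20,
                                        intragenic_reads_per_gene = 5,
                                        read_length_bp = 100,
                                        utr3_spike_bp = 3,
                                        utr3_long_bp = 1000,
                                        chrom_length_bp = NULL) {
  withr::with_seed(config$seed + 57L, {
    per <- gene_length_bp + gap_bp
    if (is.null(chrom_length_bp)) {
      chrom_length_bp <- (n_genes_per_strand + 2L) * per
    }
    mk_strand <- function(strand, offset) {
      # consecutive same-strand genes satisfy next_start - end == gap_bp
      start <- offset + (seq_len(n_genes_per_strand) - 1L) * per + 1L
      start <- start - (seq_len(n_genes_per_strand) - 1L)
      tibble::tibble(
        gene_id = sprintf("g_%s_%02d", ifelse(strand == "+", "p", "m"),
                          seq_len(n_genes_per_strand)),
        chrom = "chrT", strand = strand,
        start = start, end = start + gene_length_bp - 1L,
        biotype = rep(c("protein_coding", "lncRNA"),
                      length.out = n_genes_per_strand),
        has_utr3 = rep(c(TRUE, FALSE), length.out = n_genes_per_strand)
      )
    }
    # Offset minus-strand genes by half a period so strands interleave
    # without same-strand overlap.
    genes <- dplyr::bind_rows(mk_strand("+", 0L), mk_strand("-", per %/% 2L))
    genes$utr3_length <- ifelse(!genes$has_utr3, 0L,
                                rep(c(utr3_spike_bp, utr3_long_bp),
                                    length.out = nrow(genes)))
    reads <- NULL
    if (reads_per_gene > 0 || intragenic_reads_per_gene > 0) {
      reads <- purrr::map(seq_len(nrow(genes)), function(i) {
        g <- genes[i, ]
        out <- list()
        if (reads_per_gene > 0) {
          if (g$strand == "+") {
            rs <- rep(g$end + read_offset_bp + 1L, reads_per_gene)
            out$inter <- tibble::tibble(chrom = g$chrom, start = rs,
                                        end = rs + read_length_bp - 1L,
                                        strand = g$strand)
          } else {
            re <- rep(g$start - read_offset_bp - 1L, reads_per_gene)
            out$inter <- tibble::tibble(chrom = g$chrom,
                                        start = re - read_length_bp + 1L,
                                        end = re, strand = g$strand)
          }
        }
        if (intragenic_reads_per_gene > 0) {
          rs <- as.integer(stats::runif(intragenic_reads_per_gene, g$start,
                                        g$end - read_length_bp))
          out$intra <- tibble::tibble(chrom = g$chrom, start = rs,
                                      end = rs + read_length_bp - 1L,
                                      strand = g$strand)
        }
        dplyr::bind_rows(out)
      })
      reads <- dplyr::bind_rows(reads)
    } else {
      reads <- tibble::tibble(chrom = character(0), start = integer(0),
                              end = integer(0), strand = character(0))
    }
    list(genes = genes, reads = reads,
         chrom_lengths = c(chrT = chrom_length_bp))
  })
}
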