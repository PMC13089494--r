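# Workflow orchestration and file I/O glue: dataset readers/writers in
# standard plain-text formats (MTX + TSV, GTF/BED, TIFF + CSV) and the three
# end-to-end workflows (atlas comparison, spatial column, histology).

#' Write a counts + cell-metadata dataset
#'
#' Writes MatrixMarket counts plus gene and cell TSVs and a key-value
#' `config.txt` recording the generator seed when available.
#'
#' @param counts Cells x genes count matrix.
#' @param cells Cell-metadata tibble.
#' @param dir Output directory (created).
#' @param seed Seed recorded in `config.txt` (optional).
#' @return `dir`, invisibly.
#' @export
write_count_dataset <- function(counts, cells, dir, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                          "generalMatrix"), "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble::tibble(gene_id = colnames(counts)),
                   file.path(dir, "genes.tsv"))
  readr::write_tsv(cells, file.path(dir, "cells.tsv"))
  writeLines(c(sprintf("seed=%s", ifelse(is.null(seed), "NA", seed)),
               sprintf("n_cells=%d", nrow(counts)),
               sprintf("n_genes=%d", ncol(counts))),
             file.path(dir, "config.txt"))
  invisible(dir)
}

#' Write a histology field
#'
#' Stores the image (and mask) as single-channel TIFF plus centroid, pial
#' polyline and layer-polygon CSVs.
#'
#' @param field A `cc_histofield`.
#' @param dir Output directory.
#' @param seed Seed recorded alongside.
#' @return `dir`, invisibly.
#' @export
write_histo_field <- function(field, dir, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img <- field$image / max(field$image, 1e-9)
  tiff::writeTIFF(img, file.path(dir, "image.tiff"), bits.per.sample = 16)
  tiff::writeTIFF(field$cortical_mask * 1, file.path(dir, "mask.tiff"))
  readr::write_csv(field$pv_centroids, file.path(dir, "pv_centroids.csv"))
  readr::write_csv(field$pial_polyline, file.path(dir, "pial_polyline.csv"))
  layers <- dplyr::bind_rows(purrr::imap(field$layer_polygons,
                                         function(p, nm) dplyr::mutate(p, layer = nm)))
  readr::write_csv(layers, file.path(dir, "layer_polygons.csv"))
  writeLines(c(sprintf("seed=%s", ifelse(is.null(seed), "NA", seed)),
               sprintf("px_size_um=%s", field$px_size_um),
               sprintf("image_scale=%s", max(field$image, 1e-9))),
             file.path(dir, "config.txt"))
  invisible(dir)
}

#' Load a dataset from disk into package types
#'
#' Parses a written dataset and validates the type invariants (non-negative
#' counts, unique ids, ordered intervals).
#'
#' @param path Dataset directory (or GTF/BED file for `kind = "annotation"`,
#'   given as `c(gtf, bed)`).
#' @param kind `"counts"`, `"spatial"`, `"annotation"`, or `"histo"`.
#' @return The typed object: list(counts, cells), gene/read tibbles, or a
#'   `cc_histofield`.
#' @export
load_dataset <- function(path, kind = c("counts", "spatial", "annotation", "histo")) {
  kind <- match.arg(kind)
  if (kind %in% c("counts", "spatial")) {
    mtx_path <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx_path)) rlang::abort(paste0("missing ", mtx_path))
    m <- tryCatch(Matrix::readMM(mtx_path), error = function(e) {
      rlang::abort(paste0("corrupt MTX file ", mtx_path, ": ", conditionMessage(e)))
    })
    genes <- readr::read_tsv(file.path(path, "genes.tsv"), show_col_types = FALSE)
    cells <- readr::read_tsv(file.path(path, "cells.tsv"), show_col_types = FALSE)
    m <- as.matrix(m)
    if (min(m) < 0) rlang::abort(paste0("negative count entry in ", mtx_path))
    dimnames(m) <- list(cells$cell_id, genes$gene_id)
    validate_counts(m)
    if (kind == "spatial" && !all(c("x_units", "y_units") %in% names(cells))) {
      rlang::abort("spatial dataset lacks x_units/y_units columns")
    }
    return(list(counts = m, cells = cells))
  }
  if (kind == "annotation") {
    genes <- read_gene_gtf(path[[1]])
    reads <- if (length(path) > 1) read_reads_bed(path[[2]]) else NULL
    return(list(genes = genes, reads = reads))
  }
  img <- tiff::readTIFF(file.path(path, "image.tiff"))
  cfgl <- read_kv(file.path(path, "config.txt"))
  img <- img * as.numeric(cfgl[["image_scale"]] %||% 1)
  mask <- tiff::readTIFF(file.path(path, "mask.tiff")) > 0.5
  layers_df <- readr::read_csv(file.path(path, "layer_polygons.csv"),
                               show_col_types = FALSE)
  structure(list(
    image = img,
    px_size_um = as.numeric(cfgl[["px_size_um"]] %||% 1),
    pial_polyline = readr::read_csv(file.path(path, "pial_polyline.csv"),
                                    show_col_types = FALSE),
    cortical_mask = mask,
    layer_polygons = split(dplyr::select(layers_df, -"layer"), layers_df$layer),
    pv_centroids = readr::read_csv(file.path(path, "pv_centroids.csv"),
                                   show_col_types = FALSE)
  ), class = "cc_histofield")
}

read_kv <- function(path) {
  if (!file.exists(path)) return(list())
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(x) paste(x[-1], collapse = "=")),
                  vapply(kv, `[[`, "", 1))
}

subclass_class_map <- function(species) {
  tax <- cc_taxonomy(species)
  stats::setNames(tax$class, tax$subclass)
}

#' End-to-end atlas workflow on synthetic data
#'
#' Generates a labeled reference atlas and an unlabeled query atlas of the
#' same species preset (independent seeds, shared gene programs), applies QC
#' and normalization, clusters the query, transfers subclass labels from the
#' reference by balanced iterative transfer, and summarizes GABAergic
#' subclass proportions from the transferred labels.
#'
#' @param species Species preset.
#' @param n_cells Query atlas size (the reference matches it).
#' @param seed Seed; the reference uses a fixed offset of it.
#' @param n_hvg HVGs used for embedding and transfer.
#' @param D Embedding dimensionality.
#' @param transfer_iter Balanced-transfer iterations.
#' @param cluster Also Leiden-cluster the query embedding.
#' @return List: `proportions` (per-replicate GABAergic subclass fractions
#'   from transferred labels), `pvalb_pct` (mean Pvalb percentage of the
#'   GABAergic population), `accuracy` (against generative labels),
#'   `clusters`, `cells`.
#' @export
run_atlas_workflow <- function(species, n_cells = 10000, seed = 1,
                               n_hvg = 500, D = 30, transfer_iter = 20,
                               cluster = TRUE) {
  cfg_q <- generator_config(species = species, n_cells = n_cells, seed = seed)
  cfg_r <- generator_config(species = species, n_cells = n_cells,
                            seed = seed + 900000L)
  query <- generate_atlas(cfg_q)
  ref <- generate_atlas(cfg_r)
  qm <- qc_filter(query$counts)
  rm_ <- qc_filter(ref$counts)
  shared <- intersect(colnames(qm), colnames(rm_))
  qn <- normalize_log(qm[, shared, drop = FALSE])
  rn <- normalize_log(rm_[, shared, drop = FALSE])
  hvgs <- select_hvgs(rn, min(n_hvg, ncol(rn)))
  ref_cells <- ref$cells[match(rownames(rm_), ref$cells$cell_id), ]
  query_cells <- query$cells[match(rownames(qm), query$cells$cell_id), ]
  clusters <- NULL
  if (cluster) {
    emb <- pca_embed(qn[, hvgs, drop = FALSE], D = D)
    clusters <- cluster_graph(emb, k_neighbors = 15, resolution = 1, seed = seed)
  }
  tr <- balanced_label_transfer(rn[, hvgs, drop = FALSE], ref_cells$subclass,
                                qn[, hvgs, drop = FALSE],
                                n_iter = transfer_iter, cap = 100, D = D,
                                k_vote = 30, seed = seed)
  cmap <- subclass_class_map(species)
  assigned <- tibble::tibble(
    cell_id = rownames(qm),
    sample = query_cells$sample,
    class = unname(cmap[tr$predicted]),
    subclass = tr$predicted,
    true_subclass = query_cells$subclass
  )
  props <- subclass_proportions(assigned, level = "subclass", within = "GABAergic")
  pvalb <- props |>
    dplyr::filter(.data$label == "Pvalb") |>
    dplyr::pull(.data$fraction)
  list(proportions = props,
       pvalb_pct = 100 * sum(props$n[props$label == "Pvalb"]) /
         sum(props$n),
       pvalb_pct_by_sample = 100 * mean(pvalb),
       accuracy = mean(assigned$subclass == assigned$true_subclass),
       clusters = clusters, cells = assigned)
}

#' End-to-end spatial-column workflow on synthetic data
#'
#' Generates a spatial column and a matching dissociated reference, applies
#' spatial QC and pseudocolumn pooling, assigns subclass labels by the
#' multi-round kNN procedure, and computes the laminar statistics: Gini
#' indices per glutamatergic subclass, the upper-IT below/above density
#' ratio, and depth-axis partial Spearman correlations against a fitted
#' triangle's vertex distances.
#'
#' @param species Species preset.
#' @param n_cells Spatial cells generated.
#' @param n_ref Reference atlas cells.
#' @param seed Seed.
#' @param n_perm Permutations for the partial-correlation test.
#' @return List: `column`, `labels`, `gini`, `density_ratio`,
#'   `partial_correlation`, `assignment_rate`.
#' @export
run_spatial_workflow <- function(species, n_cells = 3000, n_ref = 4000,
                                 seed = 1, n_perm = 500) {
  cfg_s <- generator_config(species = species, n_cells = n_cells, seed = seed)
  cfg_r <- generator_config(species = species, n_cells = n_ref,
                            seed = seed + 900000L)
  sp <- generate_spatial(cfg_s)
  ref <- generate_atlas(cfg_r)
  qc <- stereo_qc(sp$counts, sp$cells)
  col <- build_pseudocolumn(list(qc))
  rm_ <- qc_filter(ref$counts, min_genes = 0, max_genes = Inf,
                   max_umis = Inf, min_cells_per_gene = 1)
  shared <- intersect(colnames(col$counts), colnames(rm_))
  qn <- normalize_log(col$counts[, shared, drop = FALSE])
  rn <- normalize_log(rm_[, shared, drop = FALSE])
  hvgs <- select_hvgs(rn, min(300, length(shared)))
  ref_cells <- ref$cells[match(rownames(rm_), ref$cells$cell_id), ]
  lab <- assign_labels_multiround(qn[, hvgs, drop = FALSE],
                                  rn[, hvgs, drop = FALSE],
                                  ref_cells$subclass,
                                  thresholds = c(1, 0.75, 0.5),
                                  k = 50, D = 10, seed = seed)
  col$cells$subclass_pred <- lab$label
  it <- it_subclass_names(species)
  glut <- c(it, "L5PT", "L6CT")
  gini <- tibble::tibble(
    subclass = glut,
    gini = vapply(glut, function(s) {
      if (sum(col$cells$subclass_pred == s, na.rm = TRUE) == 0) return(NA_real_)
      gini_subpial(col, s, label_col = "subclass_pred")
    }, 0)
  )
  ratio <- density_ratio_below_above(col, target_label = it[1],
                                     reference_label = it[2],
                                     label_col = "subclass_pred")
  # triangle geometry on the upper three IT subclasses
  it3 <- it[1:3]
  keep <- which(col$cells$subclass_pred %in% it3)
  pc <- pca_embed(qn[keep, hvgs, drop = FALSE], D = 5)
  tri <- pcha_fit(pc$scores, noc = 3, delta = 0.1, seed = seed)
  geom <- vertex_geometry(pc$scores, tri)
  # order vertices by the mean depth of their nearest cells: A (shallow),
  # B (middle), C (deep)
  depth_keep <- col$cells$subpial_frac[keep]
  nearest <- max.col(-as.matrix(geom[, 1:3]))
  vdepth <- vapply(1:3, function(k) mean(depth_keep[nearest == k]), 0)
  ord <- order(vdepth)
  ia <- which(col$cells$subclass_pred[keep] == it[1])
  pcor <- depth_axis_partial_correlation(
    depth_keep[ia],
    dist_b = as.matrix(geom)[ia, ord[2]],
    dist_c = as.matrix(geom)[ia, ord[3]],
    n_perm = n_perm, seed = seed)
  list(column = col, labels = lab, gini = gini, density_ratio = ratio,
       partial_correlation = pcor,
       assignment_rate = mean(!is.na(lab$label)))
}

#' End-to-end histology workflow on paired synthetic fields
#'
#' Generates one field per species preset with identical geometry, computes
#' layer-specific and whole-column PV densities, the cross-species density
#' excess, and the PV-centered PNN enrichment summary per field.
#'
#' @param seed Seed (shared by the pair).
#' @param n_null_per_cell Null points per PV cell for the PNN metric.
#' @param pnn Also compute the PNN association metric (the slowest step).
#' @return List: `densities` (per species x layer), `pv_excess_pct`
#'   (100 * (opossum/mouse - 1) of whole-column density), `pnn` (per-species
#'   enrichment summaries when requested).
#' @export
run_histology_workflow <- function(seed = 1, n_null_per_cell = 5, pnn = TRUE) {
  fields <- purrr::map(c(mouse = "mouse", opossum = "opossum"), function(sp) {
    generate_histo(generator_config(species = sp, seed = seed))
  })
  dens <- purrr::imap(fields, function(fl, sp) {
    dplyr::mutate(layer_densities(fl$field), species = sp)
  })
  dens_tbl <- dplyr::bind_rows(dens)
  whole <- dens_tbl |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(density = sum(.data$n_cells) / sum(.data$area_mm2))
  excess <- 100 * (whole$density[whole$species == "opossum"] /
                   whole$density[whole$species == "mouse"] - 1)
  pnn_res <- NULL
  if (pnn) {
    pnn_res <- purrr::imap(fields, function(fl, sp) {
      img <- background_subtract_normalize(fl$field)
      r <- pv_pnn_association(fl$field, image = img,
                              n_null_per_cell = n_null_per_cell, seed = seed)
      tibble::tibble(species = sp, median_difference = r$median_difference,
                     null_se = r$null_se)
    })
    pnn_res <- dplyr::bind_rows(pnn_res)
  }
  list(densities = dens_tbl, pv_excess_pct = excess, pnn = pnn_res)
}

#' Run a configured workflow end-to-end
#'
#' Thin orchestration over the three workflow runners. Identical
#' configuration gives an identical report.
#'
#' @param workflow `"atlas"`, `"spatial"`, `"histology"`, or `"all"`.
#' @param seed Seed for all stages.
#' @param outdir Optional directory; numeric report tables are written there
#'   as TSV plus a JSON summary.
#' @param ... Overrides passed to the workflow runners.
#' @return Named list of workflow results.
#' @export
run_pipeline <- function(workflow = c("all", "atlas", "spatial", "histology"),
                         seed = 1, outdir = NULL, ...) {
  workflow <- match.arg(workflow)
  extra <- list(...)
  res <- list()
  if (workflow %in% c("all", "atlas")) {
    args <- utils::modifyList(list(species = "opossum", n_cells = 3000,
                                   seed = seed, transfer_iter = 5), extra)
    args <- args[names(args) %in% names(formals(run_atlas_workflow))]
    res$atlas <- tryCatch(do.call(run_atlas_workflow, args),
                          error = function(e) rlang::abort(
                            paste0("atlas stage failed: ", conditionMessage(e))))
  }
  if (workflow %in% c("all", "spatial")) {
    args <- utils::modifyList(list(species = "opossum", n_cells = 2000,
                                   n_ref = 2500, seed = seed, n_perm = 200),
                              extra)
    args <- args[names(args) %in% names(formals(run_spatial_workflow))]
    res$spatial <- tryCatch(do.call(run_spatial_workflow, args),
                            error = function(e) rlang::abort(
                              paste0("spatial stage failed: ", conditionMessage(e))))
  }
  if (workflow %in% c("all", "histology")) {
    res$histology <- tryCatch(run_histology_workflow(seed = seed),
                              error = function(e) rlang::abort(
                                paste0("histology stage failed: ",
                                       conditionMessage(e))))
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    summary <- list(seed = seed, workflow = workflow)
    if (!is.null(res$atlas)) {
      readr::write_tsv(res$atlas$proportions,
                       file.path(outdir, "atlas_proportions.tsv"))
      summary$pvalb_pct <- res$atlas$pvalb_pct
    }
    if (!is.null(res$spatial)) {
      readr::write_tsv(res$spatial$gini, file.path(outdir, "spatial_gini.tsv"))
      summary$density_ratio <- res$spatial$density_ratio
    }
    if (!is.null(res$histology)) {
      readr::write_tsv(res$histology$densities,
                       file.path(outdir, "layer_densities.tsv"))
      summary$pv_excess_pct <- res$histology$pv_excess_pct
    }
    jsonlite::write_json(summary, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
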