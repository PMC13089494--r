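test_that("configuration invariants are enforced", {
  expect_error(generator_config(gabaergic_proportions = c(Pvalb = 0.6, Sst = 0.5)),
               "sum to 1")
  expect_error(generator_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(generator_config(noise_sd = -1), "noise_sd")
  expect_error(generator_config(archetype_concentration = c(0, 1, 1, 1)),
               "Dirichlet")
  # presets differ only in the documented fields
  m <- generator_config("mouse"); o <- generator_config("opossum")
  differing <- c("species", "archetype_concentration", "archetype_vertex_bonus",
                 "library_size_meanlog", "gabaergic_proportions",
                 "pv_density_per_mm2", "pnn_mode", "program_seed",
                 "depth_law")  # depth_law keys follow species IT naming
  same <- setdiff(names(m), differing)
  expect_equal(m[same], o[same])
  expect_equal(o$gabaergic_proportions[["Pvalb"]], 0.50)
  expect_equal(m$gabaergic_proportions[["Pvalb"]], 0.35)
  expect_equal(o$pv_density_per_mm2 / m$pv_density_per_mm2, 1.2)
})

test_that("all four generators are bit-identical under a repeated seed", {
  cfg <- generator_config("opossum", n_cells = 300, n_genes = 100, seed = 5)
  expect_identical(generate_atlas(cfg), generate_atlas(cfg))
  expect_identical(generate_spatial(cfg), generate_spatial(cfg))
  small <- generator_config("mouse", n_cells = 100, seed = 5,
                            pv_density_per_mm2 = 100)
  expect_identical(generate_histo(small, width_um = 400, height_um = 300),
                   generate_histo(small, width_um = 400, height_um = 300))
  expect_identical(generate_annotation_fixture(cfg),
                   generate_annotation_fixture(cfg))
  # a different seed changes the draw
  cfg2 <- generator_config("opossum", n_cells = 300, n_genes = 100, seed = 6)
  expect_false(identical(generate_atlas(cfg)$counts,
                         generate_atlas(cfg2)$counts))
})

test_that("noise-free latent IT expression lies exactly in the archetype span", {
  cfg <- preset_it_continuum("mouse", n_cells = 200, n_genes = 120,
                             noise_sd = 0, sample_counts = FALSE,
                             keep_latent = TRUE, seed = 7)
  a <- generate_atlas(cfg)
  expect_equal(unname(rowSums(a$truth$weights)), rep(1, 200), tolerance = 1e-12)
  # latent = W %*% A exactly, hence rank <= number of archetypes
  expect_lte(qr(a$truth$latent)$rank, cfg$it_archetypes)
  expect_equal(dim(a$truth$latent), c(200, 120))
})

test_that("subclass composition converges to the configured proportions", {
  cfg <- generator_config("opossum", n_cells = 20000, seed = 8)
  a <- generate_atlas(cfg)
  gaba <- a$cells[a$cells$class == "GABAergic", ]
  p_hat <- mean(gaba$subclass == "Pvalb")
  p <- 0.50
  se <- sqrt(p * (1 - p) / nrow(gaba))
  expect_lt(abs(p_hat - p), 3 * se)
})

test_that("spatial depth laws confine subclasses and zero cells are allowed", {
  cfg <- generator_config("mouse", n_cells = 4000, seed = 9)
  sp <- generate_spatial(cfg)
  # L4-like subclass: >= 95% of cells within mean +/- 2 sd (truncated normal)
  l4 <- sp$truth$depth_um[sp$cells$subclass == "L4"]
  law <- cfg$depth_law[["L4"]]
  inside <- mean(abs(l4 - law["mean"]) <= 2 * law["sd"])
  expect_gte(inside, 0.95)
  # coordinates are platform units, twice the micron truth
  expect_equal(sp$cells$y_units, sp$truth$depth_um * 2)
  empty <- generate_spatial(cfg, n_cells = 0)
  expect_equal(nrow(empty$cells), 0)
  expect_equal(nrow(empty$counts), 0)
  # missing depth law errors
  cfg_bad <- generator_config("mouse", n_cells = 200, seed = 9)
  cfg_bad$depth_law[["L4"]] <- NULL
  expect_error(generate_spatial(cfg_bad), "depth_law")
})

test_that("IT archetype weights covary with depth in the spatial modality", {
  cfg <- generator_config("mouse", n_cells = 6000, seed = 10)
  sp <- generate_spatial(cfg)
  it <- !is.na(sp$truth$weights[, 1])
  # weight on the deepest archetype increases with depth
  rho <- cor(sp$truth$depth_um[it], sp$truth$weights[it, 4],
             method = "spearman")
  expect_gt(rho, 0.5)
  rho1 <- cor(sp$truth$depth_um[it], sp$truth$weights[it, 1],
              method = "spearman")
  expect_lt(rho1, -0.5)
})

test_that("histology fields match their configured density and ring placement", {
  gen <- generate_histo(generator_config("mouse", seed = 11,
                                         pv_density_per_mm2 = 200,
                                         pnn_mode = "pv_centered"),
                        width_um = 1500, height_um = 900,
                        background_noise_sd = 0)
  n <- nrow(gen$field$pv_centroids)
  expected <- 200 * gen$truth$field_area_mm2
  expect_lt(abs(n - expected), 3 * sqrt(expected))
  # annuli at PV centroids exceed the image median
  ring_vals <- vapply(seq_len(min(n, 50)), function(i) {
    crosscortex:::annulus_median(gen$field$image, gen$field$cortical_mask,
                                 gen$field$px_size_um,
                                 gen$field$pv_centroids$x_um[i],
                                 gen$field$pv_centroids$y_um[i], 5, 15)
  }, 0)
  ring_vals <- ring_vals[!is.na(ring_vals)]
  expect_true(all(ring_vals > stats::median(gen$field$image)))
  # pnn_mode none with zero noise: image equals the background exactly
  quiet <- generate_histo(generator_config("mouse", seed = 11,
                                           pnn_mode = "none"),
                          width_um = 400, height_um = 300,
                          background_noise_sd = 0)
  expect_equal(quiet$field$image, quiet$truth$background)
  # displaced rings stay away from PV centroids
  disp <- generate_histo(generator_config("opossum", seed = 12),
                         width_um = 1000, height_um = 1200)
  nn <- knn_search(as.matrix(disp$truth$ring_centers),
                   as.matrix(disp$field$pv_centroids), 1)
  expect_gt(min(nn$dist), 15)
})

test_that("written datasets round-trip through the loaders", {
  cfg <- generator_config("mouse", n_cells = 150, n_genes = 80, seed = 13)
  a <- generate_atlas(cfg)
  dir <- withr::local_tempdir()
  write_count_dataset(a$counts, a$cells, file.path(dir, "atlas"), seed = 13)
  back <- load_dataset(file.path(dir, "atlas"), "counts")
  expect_equal(unname(back$counts), unname(a$counts))
  expect_equal(back$cells$subclass, a$cells$subclass)

  sp <- generate_spatial(cfg)
  write_count_dataset(sp$counts, sp$cells, file.path(dir, "spatial"), seed = 13)
  backs <- load_dataset(file.path(dir, "spatial"), "spatial")
  expect_equal(backs$cells$x_units, sp$cells$x_units)

  gen <- generate_histo(generator_config("mouse", seed = 13,
                                         pv_density_per_mm2 = 100),
                        width_um = 300, height_um = 200)
  write_histo_field(gen$field, file.path(dir, "histo"), seed = 13)
  backh <- load_dataset(file.path(dir, "histo"), "histo")
  expect_equal(dim(backh$image), dim(gen$field$image))
  expect_equal(backh$px_size_um, gen$field$px_size_um)
  expect_equal(nrow(backh$pv_centroids), nrow(gen$field$pv_centroids))
  expect_equal(backh$image, gen$field$image, tolerance = 2e-4)
})

test_that("corrupt or invalid datasets are rejected with located errors", {
  dir <- withr::local_tempdir()
  cfg <- generator_config("mouse", n_cells = 20, n_genes = 10, seed = 14)
  a <- generate_atlas(cfg)
  write_count_dataset(a$counts, a$cells, file.path(dir, "ok"))
  # corrupt MTX header
  writeLines(c("%%MatrixMarket garbage", "oops"),
             file.path(dir, "ok", "matrix.mtx"))
  expect_error(load_dataset(file.path(dir, "ok"), "counts"), "matrix.mtx")
  expect_error(load_dataset(file.path(dir, "missing"), "counts"), "missing")
})
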