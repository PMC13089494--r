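test_that("spatial QC applies inclusive thresholds and micron conversion", {
  m <- matrix(0L, 4, 200,
              dimnames = list(paste0("c", 1:4), sprintf("g%03d", 1:200)))
  m[1, 1:49] <- 20L          # 49 genes, 980 UMIs: removed (genes)
  m[2, 1:50] <- 2L           # 50 genes, 100 UMIs: kept (boundaries inclusive)
  m[3, 1:60] <- 1L           # 60 genes, 60 UMIs: removed (UMIs)
  m[4, 1:120] <- 3L          # kept
  cells <- tibble::tibble(cell_id = paste0("c", 1:4),
                          x_units = c(200, 100, 50, 400),
                          y_units = c(0, 600, 100, 2400))
  out <- stereo_qc(m, cells)
  expect_setequal(out$cells$cell_id, c("c2", "c4"))
  expect_equal(out$cells$x_um[out$cells$cell_id == "c2"], 50)
  expect_equal(out$cells$depth_um[out$cells$cell_id == "c4"], 1200)
  expect_error(stereo_qc(m, cells, units_per_um = 0), "units_per_um")
})

test_that("pseudocolumn scaling stretches ROIs to the largest and pools cells", {
  mk_roi <- function(x, depth, tag) {
    n <- length(x)
    m <- matrix(1L, n, 3,
                dimnames = list(paste0(tag, seq_len(n)), c("g1", "g2", "g3")))
    list(counts = m,
         cells = tibble::tibble(cell_id = rownames(m), x_um = x,
                                depth_um = depth))
  }
  big <- mk_roi(c(0, 400), c(0, 1200), "b")
  small <- mk_roi(c(0, 200), c(0, 600), "s")
  col <- build_pseudocolumn(list(big, small))
  expect_equal(nrow(col$cells), 4)
  expect_equal(col$height_um, 1200)
  # the small ROI's depths double
  expect_equal(col$cells$depth_um[col$cells$cell_id == "s2"], 1200)
  expect_true(all(col$cells$subpial_frac >= 0 & col$cells$subpial_frac <= 1))
  # single ROI passes through unchanged
  one <- build_pseudocolumn(list(big))
  expect_equal(one$cells$depth_um, c(0, 1200))
  degenerate <- mk_roi(c(1, 1), c(0, 5), "d")
  expect_error(build_pseudocolumn(list(degenerate)), "zero extent")
})

test_that("multi-round assignment respects thresholds and never reverses labels", {
  withr::local_seed(31)
  mk <- function(center, tag, n) {
    m <- matrix(rnorm(n * 10, sd = 0.5), n, 10) +
      matrix(center, n, 10, byrow = TRUE)
    dimnames(m) <- list(paste0(tag, seq_len(n)), paste0("g", 1:10))
    m
  }
  ref <- rbind(mk(rep(0, 10), "ra", 100), mk(rep(8, 10), "rb", 100))
  ref_labels <- rep(c("A", "B"), each = 100)
  # perfectly separated query: everything assigned in round 1, no errors
  query <- rbind(mk(rep(0, 10), "qa", 40), mk(rep(8, 10), "qb", 40))
  out <- assign_labels_multiround(query, ref, ref_labels,
                                  thresholds = c(1, 1, 0.75), k = 20, D = 3,
                                  seed = 1)
  expect_true(all(out$round == 1))
  expect_equal(out$label, rep(c("A", "B"), each = 40))
  expect_error(assign_labels_multiround(query, ref, ref_labels,
                                        thresholds = c(0.5, 0.75)),
               "non-increasing")
})

test_that("cells failing early rounds are picked up when thresholds drop", {
  withr::local_seed(32)
  # construct neighbour labels directly around an 80/20 mixture zone
  ref <- rbind(matrix(rnorm(160 * 6, sd = 3), 160, 6),
               matrix(rnorm(40 * 6, sd = 3), 40, 6))
  dimnames(ref) <- list(paste0("r", 1:200), paste0("g", 1:6))
  ref_labels <- c(rep("A", 160), rep("B", 40))
  query <- matrix(rnorm(30 * 6, sd = 3), 30, 6,
                  dimnames = list(paste0("q", 1:30), paste0("g", 1:6)))
  out <- assign_labels_multiround(query, ref, ref_labels,
                                  thresholds = c(1, 1, 0.5), k = 30, D = 3,
                                  seed = 2)
  # with intermixed reference labels no cell reaches 100% agreement, so all
  # assignments happen in the final round (or not at all)
  expect_true(all(is.na(out$round) | out$round == 3))
  expect_gt(sum(!is.na(out$label)), 0)
})

test_that("subpial density profiles integrate to one and track the data", {
  withr::local_seed(33)
  col <- toy_column(rep(0.5, 50), rep("x", 50))
  prof <- subpial_density_profile(col, "x")
  expect_equal(prof$subpial_frac[which.max(prof$density)], 0.5,
               tolerance = 0.02)
  step <- prof$subpial_frac[2] - prof$subpial_frac[1]
  expect_equal(sum(prof$density) * step, 1, tolerance = 1e-3)
  # uniform sample: flat within tolerance at large n
  colu <- toy_column(runif(20000), rep("u", 20000))
  pu <- subpial_density_profile(colu, "u")
  inner <- pu$density[pu$subpial_frac > 0.1 & pu$subpial_frac < 0.9]
  expect_true(all(abs(inner - 1) < 0.15))
  expect_error(subpial_density_profile(toy_column(0.3, "x"), "x"), "2 cells")
})

test_that("Gini confinement matches closed forms and is scale invariant", {
  expect_equal(gini_counts(c(4, 0, 0, 0)), 0.75)
  expect_equal(gini_counts(rep(7, 20)), 0)
  expect_equal(gini_counts(c(100, rep(0, 19))), 0.95)
  expect_equal(gini_counts(c(40, 0, 0, 0)), gini_counts(c(4, 0, 0, 0)))
  expect_error(gini_counts(c(0, 0)), "zero")
  # via the column interface: all cells in one of 20 bins
  col <- toy_column(rep(0.025, 30), rep("x", 30))
  expect_equal(gini_subpial(col, "x", n_bins = 20), 0.95)
  colu <- toy_column((1:20 - 0.5) / 20, rep("u", 20))
  expect_equal(gini_subpial(colu, "u", n_bins = 20), 0)
})

test_that("density ratio normalizes by extent and handles edge cases", {
  # reference median at 0.4; 6 target cells below (deeper), 2 above
  col <- toy_column(c(rep(0.4, 5), rep(0.7, 6), rep(0.2, 2)),
                    c(rep("ref", 5), rep("tgt", 8)))
  expect_equal(density_ratio_below_above(col, "tgt", "ref"), 2.0)
  # no target cells below the split
  col0 <- toy_column(c(rep(0.5, 3), rep(0.2, 4)),
                     c(rep("ref", 3), rep("tgt", 4)))
  expect_equal(density_ratio_below_above(col0, "tgt", "ref"), 0)
  # uniform target: ratio 1 regardless of the reference median
  withr::local_seed(34)
  colu <- toy_column(c(runif(40000), rep(0.3, 5)),
                     c(rep("tgt", 40000), rep("ref", 5)))
  expect_equal(density_ratio_below_above(colu, "tgt", "ref"), 1,
               tolerance = 0.05)
  expect_error(density_ratio_below_above(col, "tgt", "nope"), "absent")
})

test_that("partial Spearman isolates each axis and calibrates under the null", {
  withr::local_seed(35)
  n <- 200
  b <- runif(n); cvar <- runif(n)
  r <- depth_axis_partial_correlation(b, b, cvar, n_perm = 200, seed = 1)
  expect_equal(r$rho_partial[r$axis == "b"], 1, tolerance = 1e-9)
  expect_lt(r$p[r$axis == "b"], 0.01)
  # both distances drive depth: both partials positive
  d2 <- b + cvar + rnorm(n, sd = 0.2)
  r2 <- depth_axis_partial_correlation(d2, b, cvar, n_perm = 200, seed = 1)
  expect_true(all(r2$rho_partial > 0))
  expect_error(depth_axis_partial_correlation(rep(1, 20), runif(20), runif(20)),
               "constant")
  expect_error(depth_axis_partial_correlation(runif(5), runif(5), runif(5)),
               ">= 10")
})

test_that("partial correlation reduces to plain Spearman for an independent covariate", {
  withr::local_seed(36)
  n <- 400
  x <- runif(n); y <- x + rnorm(n, sd = 0.3); z <- runif(n)
  r <- depth_axis_partial_correlation(y, x, z, n_perm = 50, seed = 1)
  plain <- spearman_correlation(y, x)
  expect_equal(r$rho_partial[r$axis == "b"], plain, tolerance = 0.05)
})
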