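# broom-style tidiers and ggplot2 autoplot/plot helpers for result objects.

#' Tidy a fitted polytope
#'
#' One row per archetype with its coordinates in the embedding space.
#'
#' @param x A `cc_polytope` from [pcha_fit()].
#' @param ... Unused.
#' @return Tibble `archetype`, one column per embedding dimension.
#' @export
tidy.cc_polytope <- function(x, ...) {
  out <- tibble::as_tibble(x$archetypes, .name_repair = "minimal")
  if (is.null(colnames(x$archetypes))) {
    names(out) <- paste0("dim", seq_len(ncol(out)))
  }
  dplyr::mutate(out, archetype = dplyr::row_number(), .before = 1)
}

#' One-line summary of a fitted polytope
#'
#' @param x A `cc_polytope`.
#' @param ... Unused.
#' @return Tibble `K`, `delta`, `sse`, `ev`, `n_iter`, `converged`.
#' @export
glance.cc_polytope <- function(x, ...) {
  tibble::tibble(K = x$K, delta = x$delta, sse = x$sse, ev = x$ev,
                 n_iter = x$n_iter, converged = x$converged)
}

#' @export
print.cc_polytope <- function(x, ...) {
  cat(sprintf("Principal convex hull fit: K = %d, delta = %g, ev = %.4f (%s after %d iterations)\n",
              x$K, x$delta, x$ev,
              if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}

#' Tidy a vertex-count selection
#'
#' @param x A `cc_vertex_selection` from [select_vertex_count()].
#' @param ... Unused.
#' @return The per-candidate profile tibble (`K`, `sse`, `ev`,
#'   `chord_distance`).
#' @export
tidy.cc_vertex_selection <- function(x, ...) x$profile

#' @export
glance.cc_vertex_selection <- function(x, ...) {
  tibble::tibble(K = x$K, n_candidates = nrow(x$profile))
}

#' Tidy a label-transfer result
#'
#' @param x A `cc_transfer` from [balanced_label_transfer()].
#' @param ... Unused.
#' @return Tibble `cell_id`, `predicted`, `max_prob`, plus one probability
#'   column per reference label.
#' @export
tidy.cc_transfer <- function(x, ...) {
  probs <- tibble::as_tibble(x$prob, .name_repair = "minimal")
  dplyr::bind_cols(
    tibble::tibble(cell_id = rownames(x$prob) %||% as.character(seq_len(nrow(x$prob))),
                   predicted = x$predicted,
                   max_prob = apply(x$prob, 1, max)),
    probs
  )
}

#' @export
glance.cc_shuffle_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p = x$p, n_shuffles = length(x$null))
}

#' Plot the explained-variance elbow of a vertex-count selection
#'
#' @param object A `cc_vertex_selection`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cc_vertex_selection <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$K, y = .data$ev)) +
    ggplot2::geom_line(color = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = object$profile[object$profile$K == object$K, ],
                        color = "red", size = 3) +
    ggplot2::labs(x = "vertex count K", y = "explained variance",
                  title = sprintf("Elbow-selected K = %d", object$K)) +
    ggplot2::theme_minimal()
}

#' Plot a fitted polytope over the embedded cells
#'
#' @param object A `cc_polytope`.
#' @param X The cells x D scores the fit used.
#' @param dims Two component indices to display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cc_polytope <- function(object, X, dims = c(1, 2), ...) {
  X <- as.matrix(X)
  cells <- tibble::tibble(x = X[, dims[1]], y = X[, dims[2]])
  arch <- tibble::tibble(x = object$archetypes[, dims[1]],
                         y = object$archetypes[, dims[2]])
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_point(data = arch, color = "red", size = 3, shape = 17) +
    ggplot2::labs(x = sprintf("component %d", dims[1]),
                  y = sprintf("component %d", dims[2])) +
    ggplot2::theme_minimal()
}

#' Plot subpial density profiles
#'
#' @param profiles Tibble from [subpial_density_profile()], optionally with a
#'   `label` column stacking several subclasses.
#' @return A ggplot (depth on the vertical axis, pia on top).
#' @export
plot_density_profiles <- function(profiles) {
  p <- ggplot2::ggplot(profiles,
                       ggplot2::aes(x = .data$density, y = .data$subpial_frac))
  if ("label" %in% names(profiles)) {
    p <- p + ggplot2::geom_path(ggplot2::aes(color = .data$label))
  } else {
    p <- p + ggplot2::geom_path()
  }
  p + ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "density", y = "subpial depth (fraction)") +
    ggplot2::theme_minimal()
}

#' Heatmap of a confusion or overlap matrix
#'
#' @param m Numeric matrix with dimnames (e.g. [confusion_matrix()] or
#'   [cluster_overlap_fraction()] output).
#' @param value_name Legend title.
#' @return A ggplot.
#' @export
plot_label_matrix <- function(m, value_name = "fraction") {
  df <- tibble::as_tibble(as.table(m), .name_repair = "minimal")
  names(df) <- c("row", "col", "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = value_name, limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
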