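#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Jacobian summary into a one-row tibble
#'
#' @param x A `jacobian_summary`.
#' @param ... Unused.
#' @return Tibble with columns `label`, `u0`, `v0` and the six elements in
#'   the order `dx_du, dx_dv, dy_du, dy_dv, dz_du, dz_dv`.
#' @method tidy jacobian_summary
#' @export
tidy.jacobian_summary <- function(x, ...) {
  p <- attr(x, "point")
  dplyr::bind_cols(
    tibble::tibble(label = attr(x, "label"), u0 = p[[1]], v0 = p[[2]]),
    tibble::as_tibble(as.list(flatten_jacobian(x)))
  )
}

#' Tidy a morphospace
#'
#' @param x A [morphospace()].
#' @param matrix Which component to return: `"scores"` (default, one row per
#'   model), `"correlations"` (variable-PC correlations) or `"eigenvalues"`
#'   (with percent and cumulative variance).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy morphospace
#' @export
tidy.morphospace <- function(x, matrix = c("scores", "correlations", "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = dplyr::bind_cols(tibble::tibble(label = x$labels),
                              tibble::as_tibble(x$scores, .name_repair = "minimal")),
    correlations = dplyr::bind_cols(
      tibble::tibble(variable = rownames(x$correlations)),
      tibble::as_tibble(x$correlations, .name_repair = "minimal")
    ),
    eigenvalues = tibble::tibble(component = seq_along(x$eigenvalues),
                                 eigenvalue = x$eigenvalues,
                                 percent = x$percent,
                                 cumulative = x$cumulative)
  )
}

#' One-row summary of a morphospace
#'
#' @param x A [morphospace()].
#' @param ... Unused.
#' @return Tibble with model/variable counts and leading variance shares.
#' @method glance morphospace
#' @export
glance.morphospace <- function(x, ...) {
  tibble::tibble(
    n_models = nrow(x$scores),
    n_variables = length(x$eigenvalues),
    n_dropped = length(x$dropped),
    percent_pc1 = x$percent[1],
    cumulative_pc2 = if (length(x$cumulative) >= 2) x$cumulative[2] else x$cumulative[1]
  )
}

#' Plot morphospace scores
#'
#' @param object A [morphospace()].
#' @param pcs Length-2 integer vector: which PCs to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot morphospace
#' @export
autoplot.morphospace <- function(object, pcs = c(1, 2), ...) {
  sc <- tidy(object, "scores")
  xcol <- paste0("PC", pcs[1]); ycol <- paste0("PC", pcs[2])
  pct <- object$percent
  ggplot2::ggplot(sc, ggplot2::aes(.data[[xcol]], .data[[ycol]], label = .data$label)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 2.8) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", xcol, pct[pcs[1]]),
      y = sprintf("%s (%.1f%%)", ycol, pct[pcs[2]]),
      title = "Jacobian morphospace"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the orthogonal projections of a surface grid
#'
#' @param object A [surface_grid()].
#' @param ... Unused.
#' @return A ggplot with xy, xz and yz projections.
#' @method autoplot surface_grid
#' @export
autoplot.surface_grid <- function(object, ...) {
  d <- tibble::as_tibble(object)
  proj <- dplyr::bind_rows(
    dplyr::mutate(d, h = .data$x, w = .data$y, projection = "xy"),
    dplyr::mutate(d, h = .data$x, w = .data$z, projection = "xz"),
    dplyr::mutate(d, h = .data$y, w = .data$z, projection = "yz")
  )
  ggplot2::ggplot(proj, ggplot2::aes(.data$h, .data$w, group = .data$u)) +
    ggplot2::geom_path(linewidth = 0.2, alpha = 0.6) +
    ggplot2::facet_wrap(~projection, scales = "free") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = attr(object, "label") %||% "surface grid") +
    ggplot2::theme_minimal()
}

#' Plot an ontogenetic trajectory
#'
#' @param object A [trajectory()].
#' @param pcs Length-2 integer vector: which PCs to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot trajectory
#' @export
autoplot.trajectory <- function(object, pcs = c(1, 2), ...) {
  d <- tibble::as_tibble(object)
  xcol <- paste0("PC", pcs[1]); ycol <- paste0("PC", pcs[2])
  ggplot2::ggplot(d, ggplot2::aes(.data[[xcol]], .data[[ycol]], label = .data$stage)) +
    ggplot2::geom_path(arrow = grid::arrow(length = grid::unit(2, "mm"), type = "closed"),
                       colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.7, size = 2.8) +
    ggplot2::labs(title = sprintf("Ontogenetic trajectory (collinearity %.3f)",
                                  attr(object, "collinearity"))) +
    ggplot2::theme_minimal()
}
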