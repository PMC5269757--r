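#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Michaelis-Menten fit
#'
#' @param x An `mm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`vmax`, `km`).
#' @method tidy mm_fit
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble(term = c("vmax", "km"), estimate = c(x$vmax, x$km))
}

#' @rdname tidy.mm_fit
#' @return `glance()` returns a one-row fit summary.
#' @method glance mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  tibble(vmax = x$vmax, km = x$km, residual_norm = x$residual_norm,
         diverged = x$diverged, n_points = x$n_points)
}

#' Tidy a trained self-organizing map
#'
#' @param x A `som_grid`.
#' @param ... Unused.
#' @return One row per fragment: `fragment_id`, `bmu`, lattice `row`,
#'   `col`.
#' @method tidy som_grid
#' @export
tidy.som_grid <- function(x, ...) {
  tibble(
    fragment_id = x$fragment_id,
    bmu = x$bmu,
    row = (x$bmu - 1L) %/% x$som_cols,
    col = (x$bmu - 1L) %% x$som_cols
  )
}

#' @rdname tidy.som_grid
#' @method glance som_grid
#' @export
glance.som_grid <- function(x, ...) {
  tibble(som_rows = x$som_rows, som_cols = x$som_cols,
         n_fragments = length(x$bmu), epochs = length(x$qe),
         final_qe = tail(x$qe, 1))
}

#' U-matrix heat map of a trained map with fragment positions
#'
#' @param object A `som_grid`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot som_grid
#' @export
autoplot.som_grid <- function(object, ...) {
  n <- object$som_rows * object$som_cols
  um <- tibble(
    row = (seq_len(n) - 1L) %/% object$som_cols,
    col = (seq_len(n) - 1L) %% object$som_cols,
    u = object$umatrix
  )
  pts <- tidy.som_grid(object) |>
    group_by(.data$row, .data$col) |>
    summarise(n = dplyr::n(), .groups = "drop")
  ggplot2::ggplot(um, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$u)) +
    ggplot2::geom_point(data = pts, ggplot2::aes(size = .data$n),
                        colour = "white", alpha = 0.7) +
    ggplot2::scale_fill_viridis_c(name = "U-matrix") +
    ggplot2::scale_size_area(name = "fragments", max_size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Tetranucleotide SOM (toroidal)") +
    ggplot2::theme_minimal()
}

#' Saturation curve with optional Michaelis-Menten overlay
#'
#' @param object A `saturation_curve`.
#' @param fit Optional `mm_fit` to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot saturation_curve
#' @export
autoplot.saturation_curve <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "line", colour = "steelblue") +
    ggplot2::labs(x = "effort", y = "recovery") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    xs <- seq(0, max(object$x) * 1.2, length.out = 100)
    p <- p + ggplot2::geom_line(
      data = tibble(x = xs, y = fit$fitted(xs)),
      colour = "firebrick", linetype = 2) +
      ggplot2::geom_hline(yintercept = fit$vmax, linetype = 3)
  }
  p
}

#' Bar chart of the sharing spectrum
#'
#' @param object A `sharing_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sharing_spectrum
#' @export
autoplot.sharing_spectrum <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = factor(.data$k), y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "number of supporting cells",
                  y = "fraction of covered bases") +
    ggplot2::theme_minimal()
}
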