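#' ROI statistics of a parameter map
#'
#' Mean and sample standard deviation of the map over one or more masks;
#' masked-out and non-finite pixels are excluded.
#'
#' @param map Numeric matrix (e.g. `wt1_ms` of a [match_image()] map).
#' @param mask Logical matrix, or a (possibly named) list of logical
#'   matrices.
#' @param label Label(s) for the output rows.
#' @return Data frame with columns `label`, `n_pixels`, `mean`, `sd`.
#' @export
roi_stats <- function(map, mask, label = NULL) {
  if (!is.list(mask)) mask <- list(mask)
  if (is.null(label)) {
    label <- if (!is.null(names(mask))) names(mask) else
      paste0("roi_", seq_along(mask))
  }
  stopifnot(length(label) == length(mask))
  rows <- lapply(seq_along(mask), function(i) {
    m <- mask[[i]]
    stopifnot(all(dim(m) == dim(map)))
    v <- map[m]
    v <- v[is.finite(v)]
    if (length(v) == 0) stop("empty ROI: ", label[i])
    data.frame(label = label[i], n_pixels = length(v),
               mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0)
  })
  do.call(rbind, rows)
}

#' Circular ROI mask on the image grid
#'
#' @param matrix_size Matrix size (square grid).
#' @param fov_mm Field of view in mm.
#' @param center_mm Length-2 center (x, y) in mm, origin at the FOV center.
#' @param diameter_mm ROI diameter in mm.
#' @return Logical matrix.
#' @export
circular_roi <- function(matrix_size, fov_mm, center_mm, diameter_mm) {
  xy <- grid_coords_mm(matrix_size, fov_mm)
  X <- matrix(xy, matrix_size, matrix_size)
  Y <- matrix(xy, matrix_size, matrix_size, byrow = TRUE)
  (X - center_mm[1])^2 + (Y - center_mm[2])^2 <= (diameter_mm / 2)^2
}

#' Method-comparison linear regression
#'
#' Ordinary least squares of `y` on `x` with intercept; the coefficient of
#' determination is the squared Pearson correlation. This mirrors the usual
#' reporting of T1 method comparisons (`y = slope * x + intercept, R^2`).
#'
#' @param x_values,y_values Numeric vectors of equal length (>= 2).
#' @return An object of class `wt1_regression`: list with `slope`,
#'   `intercept`, `r_squared`, `n` and the underlying `lm` fit.
#' @export
compare_methods <- function(x_values, y_values) {
  stopifnot(length(x_values) == length(y_values), length(x_values) >= 2)
  if (stats::var(x_values) == 0) stop("zero variance in x")
  fit <- stats::lm(y_values ~ x_values)
  out <- list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = stats::cor(x_values, y_values)^2,
    n = length(x_values),
    fit = fit
  )
  class(out) <- "wt1_regression"
  out
}

#' @export
print.wt1_regression <- function(x, ...) {
  cat(sprintf("<wt1_regression> y = %.3f x %+.2f, R2 = %.3f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Extremes of a composite-T1 bias surface
#'
#' @param surface A [simulate_bias_grid()] result.
#' @return List with `min_pct`, `max_pct` and data-frame rows `argmin`,
#'   `argmax` giving their (wT1, PDFF, TE branch) coordinates.
#' @export
bias_report <- function(surface) {
  stopifnot(nrow(surface) >= 1)
  i_min <- which.min(surface$deviation_pct)
  i_max <- which.max(surface$deviation_pct)
  list(
    min_pct = surface$deviation_pct[i_min],
    max_pct = surface$deviation_pct[i_max],
    argmin = surface[i_min, c("wt1_ms", "pdff_percent", "te_branch")],
    argmax = surface[i_max, c("wt1_ms", "pdff_percent", "te_branch")]
  )
}

#' Plot a composite-T1 bias surface
#'
#' Percent deviation of composite T1 from the true water T1 as a raster over
#' the (wT1, PDFF) grid, one panel per TE branch.
#'
#' @param surface A [simulate_bias_grid()] result.
#' @return A ggplot object.
#' @export
plot_bias_surface <- function(surface) {
  ggplot2::ggplot(as.data.frame(surface),
                  ggplot2::aes(x = .data$wt1_ms, y = .data$pdff_percent,
                               fill = .data$deviation_pct)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~te_branch,
                        labeller = ggplot2::labeller(
                          te_branch = function(b) paste0("TE", b, " branch"))) +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "water T1 (ms)", y = "PDFF (%)",
                  fill = "T1comp deviation (%)") +
    ggplot2::theme_minimal()
}

#' Plot a wT1 map
#'
#' @param map A [match_image()] result.
#' @param limits Optional color limits in ms.
#' @return A ggplot object.
#' @export
plot_wt1_map <- function(map, limits = NULL) {
  d <- dim(map$wt1_ms)
  df <- data.frame(x = rep(seq_len(d[1]), d[2]),
                   y = rep(seq_len(d[2]), each = d[1]),
                   wt1 = as.vector(map$wt1_ms))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$wt1)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = limits, na.value = "grey20") +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "wT1 (ms)") +
    ggplot2::theme_void()
}
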