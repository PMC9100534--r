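#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a raster grid into a long tibble
#'
#' One row per valid cell with the cell-centre coordinates — the shape
#' `geom_raster()` wants.
#'
#' @param x An [env_grid()].
#' @param ... Unused.
#' @return A tibble with `lon`, `lat`, `value`.
#' @export
#' @method tidy env_grid
tidy.env_grid <- function(x, ...) {
  nr <- nrow(x$values); nc <- ncol(x$values)
  idx <- which(!is.na(x$values))
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  ctr <- cell_center(x, row, col)
  tibble::tibble(lon = ctr$lon, lat = ctr$lat, value = x$values[idx])
}

#' Map of a raster grid
#' @param object An [env_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot env_grid
autoplot.env_grid <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = "value")
}

#' Response curves for every variable of a fitted model
#'
#' @param model A [fit_maxent()] model with stored expansion.
#' @param background_values Background value table supplying the held-fixed
#'   means.
#' @param n_points Sweep resolution per variable.
#' @return A ggplot object faceted by variable.
#' @export
plot_response_curves <- function(model, background_values, n_points = 100) {
  exp_ <- model$expansion
  means <- vapply(as.data.frame(background_values)[exp_$variables], mean,
                  numeric(1))
  curves <- dplyr::bind_rows(lapply(
    exp_$variables, response_curve, model = model,
    background_means = means, n_points = n_points))
  ggplot2::ggplot(curves, ggplot2::aes(.data$value, .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_x") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Variable value", y = "Occurrence probability")
}

#' Scatter of the change regression against the identity line
#' @param object An [ols_fit()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot identity_ols
autoplot.identity_ols <- function(object, ...) {
  df <- object$fit$model
  ggplot2::ggplot(df, ggplot2::aes(.data$p_current, .data$p_future)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "blue") +
    ggplot2::geom_abline(slope = object$beta1, intercept = object$beta0,
                         colour = "red") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Current occurrence probability",
                  y = "Future occurrence probability")
}

#' Jackknife gain chart
#' @param jack Output of [jackknife_gains()].
#' @return A ggplot object.
#' @export
plot_jackknife <- function(jack) {
  full <- attr(jack, "full_gain")
  long <- tidyr::pivot_longer(jack, c("gain_only", "gain_without"),
                              names_to = "model", values_to = "gain")
  long$model <- ifelse(long$model == "gain_only", "only this variable",
                       "without this variable")
  ggplot2::ggplot(long, ggplot2::aes(.data$gain, .data$variable,
                                     fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_vline(xintercept = full, linetype = 2) +
    ggplot2::labs(x = "Training gain", y = NULL, fill = NULL)
}

#' @importFrom rlang .data
NULL
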