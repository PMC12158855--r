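# ggplot2 renderings of result objects.

#' @export
autoplot.thickness_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time / 1000, y = .data$thickness)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "time (ns)", y = "thickness (nm)",
                  title = "Per-frame membrane thickness")
}

#' @export
autoplot.surface_grid <- function(object, range_nm = 2.5, ...) {
  df <- tidy(object)
  lo <- min(df$thickness)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$thickness)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(lo, lo + range_nm),
                                  oob = scales_squish) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)", fill = "thickness (nm)",
                  title = "Thickness map")
}

# minimal squish so scales is not a hard dependency
scales_squish <- function(x, range = c(0, 1), ...) {
  pmin(pmax(x, range[1]), range[2])
}

#' @export
autoplot.curvature_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time / 1000, y = .data$max_abs_H)) +
    ggplot2::geom_line(color = "darkorange") +
    ggplot2::labs(x = "time (ns)", y = expression("max |H| (nm"^-1 * ")"),
                  title = "Per-frame maximum mean curvature")
}

#' @export
autoplot.order_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$bond_index),
                                       y = .data$p2, fill = .data$species)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "bond index (1 = closest to headgroup)",
                  y = expression(P[2]), title = "Tail order parameter")
}

#' @export
autoplot.msd_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t / 1000, y = .data$msd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag time (ns)", y = expression(MSD ~ (nm^2)),
                  title = sprintf("MSD (%dD)", attr(object, "dim")))
}

#' @export
autoplot.rdf_profile <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$g)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", color = "grey50") +
    ggplot2::labs(x = "r (nm)", y = "g(r)", title = "Radial distribution function")
  peaks <- attr(object, "peaks")
  if (!is.null(peaks) && nrow(peaks)) {
    p <- p + ggplot2::geom_point(data = peaks, color = "red")
  }
  p
}

#' @export
autoplot.contact_matrix <- function(object, ...) {
  df <- tidy(object)
  mid <- if (isTRUE(attr(object, "normalized"))) 1 else NA
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$species_a, y = .data$species_b,
                                        fill = .data$contacts)) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = if (is.na(mid)) "contacts" else "ratio",
                  title = if (is.na(mid)) "Contact matrix" else "Normalized contacts")
  if (!is.na(mid)) {
    p <- p + ggplot2::scale_fill_gradient2(midpoint = 1, low = "blue",
                                           mid = "white", high = "red")
  }
  p
}

#' @export
autoplot.comparison_table <- function(object, ...) {
  df <- dplyr::mutate(object, pair = paste(.data$group1, "vs", .data$group2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$pair,
                                   color = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf_low,
                                         xmax = .data$conf_high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "mean difference (95% CI)", y = NULL,
                  title = "Pairwise comparisons (Bonferroni-adjusted)")
}
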