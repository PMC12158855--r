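# broom-style tidiers for memphase result objects.

#' @export
glance.thickness_series <- function(x, ...) {
  q <- quantile(x$thickness, c(0.25, 0.5, 0.75))
  tibble(n_frames = nrow(x), mean = mean(x$thickness), sd = sd(x$thickness),
         q1 = q[[1]], median = q[[2]], q3 = q[[3]],
         iqr = q[[3]] - q[[1]])
}

#' @export
tidy.surface_grid <- function(x, ...) {
  g <- x$grid_n
  cx <- rep(x$cell_x, times = g)
  cy <- rep(x$cell_y, each = g)
  up <- as.vector(x$upper); lo <- as.vector(x$lower)
  th <- as.vector(x$thickness); obs <- as.vector(x$occupancy)
  tibble(x = cx, y = cy, upper = up, lower = lo, thickness = th,
         observed = obs)
}

#' @export
glance.surface_grid <- function(x, ...) {
  tibble(grid_n = x$grid_n, mean_thickness = mean(x$thickness),
         sd_thickness = sd(as.vector(x$thickness)),
         occupied_fraction = mean(x$occupancy))
}

#' @export
tidy.order_result <- function(x, ...) as_tibble(x)

#' @export
glance.order_result <- function(x, ...) {
  tibble(p2_mean = attr(x, "p2_mean"), abs_p2 = attr(x, "abs_p2"),
         window = attr(x, "window"))
}

#' @export
tidy.diffusion_result <- function(x, ...) {
  tibble(term = c("D", "slope"), estimate = c(x$D, x$slope),
         unit = c("nm^2/ns", "nm^2/ns"))
}

#' @export
glance.diffusion_result <- function(x, ...) {
  tibble(D = x$D, slope = x$slope, dim = x$dim,
         r_squared = x$r_squared, residual = x$residual,
         n_particles = x$n_particles)
}

#' @export
tidy.contact_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble(species_a = rep(rownames(m), times = ncol(m)),
         species_b = rep(colnames(m), each = nrow(m)),
         contacts = as.vector(m),
         normalized = isTRUE(attr(x, "normalized")))
}

#' @export
tidy.phase_label <- function(x, ...) {
  tibble(label = x$label, n_channels = x$n_channels, psi6 = x$psi6,
         axis = x$axis %||% NA_character_)
}

#' @export
glance.comparison_table <- function(x, ...) {
  tibble(n_comparisons = attr(x, "n_comparisons"),
         n_significant = sum(x$significant),
         alpha = attr(x, "alpha"),
         var_equal = attr(x, "var_equal"))
}
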