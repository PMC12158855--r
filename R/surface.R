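# Leaflet assignment, thickness distributions and maps, mean curvature.

circular_center <- function(z, L) {
  th <- 2 * pi * z / L
  atan2(mean(sin(th)), mean(cos(th))) %% (2 * pi) * L / (2 * pi)
}

#' Assign lipids to bilayer leaflets
#'
#' Unwraps headgroup heights in z (circular mean centering, so a bilayer
#' wrapped across the periodic boundary is handled), takes the median
#' headgroup height as the bilayer midplane, and labels lipids `upper` /
#' `lower` by the sign of their height relative to it. A frame whose
#' headgroup height distribution is not clearly bimodal (e.g. an inverted
#' hexagonal frame) raises a "not a bilayer" error.
#'
#' @param frame A [bead_frame()].
#' @param registry A `lipid_registry`.
#' @return Tibble `molecule_id`, `species`, `leaflet`, `z_rel` (height
#'   relative to the midplane, nm).
#' @export
assign_leaflets <- function(frame, registry = default_registry()) {
  heads <- headgroup_positions(frame, registry)
  if (!nrow(heads)) abort("no lipid headgroups in frame")
  L <- frame_box(frame)[3]
  zc <- circular_center(heads$z, L)
  zrel <- (heads$z - zc + L / 2) %% L
  mid <- median(zrel)
  zrel <- zrel - mid
  # bimodality guard: two tight bands well separated relative to their spread
  km <- suppressWarnings(stats::kmeans(
    zrel, centers = matrix(quantile(zrel, c(0.25, 0.75)), ncol = 1)))
  s <- sqrt(max(km$withinss / pmax(km$size, 1L)))
  sep <- abs(diff(km$centers[, 1]))
  if (!is.finite(sep) || (s > 0 && sep / s < 5)) {
    abort("not a bilayer: headgroup height distribution is not bimodal")
  }
  # split at the midpoint between the two bands (robust to slightly
  # unbalanced leaflet counts, where the median sits inside one band)
  boundary <- mean(km$centers[, 1])
  tibble(molecule_id = heads$molecule_id, species = heads$species,
         leaflet = ifelse(zrel > boundary, "upper", "lower"), z_rel = zrel)
}

#' Per-frame membrane thickness over a trailing window
#'
#' For each frame in the trailing `window` fraction of the trajectory,
#' thickness is the mean upper-leaflet headgroup height minus the mean
#' lower-leaflet headgroup height. Presenting per-frame values (rather than
#' a single time-averaged density profile) exposes thickness fluctuations.
#'
#' @param frames A `frame_sequence`.
#' @param window Trailing fraction of frames (default last half).
#' @param registry A `lipid_registry`.
#' @return A `thickness_series` tibble: `frame`, `time`, `thickness` (nm).
#' @export
thickness_series <- function(frames, window = 0.5, registry = default_registry()) {
  idx <- window_frames(frames, window)
  vals <- vapply(idx, function(i) {
    lf <- assign_leaflets(get_frame(frames, i), registry)
    mean(lf$z_rel[lf$leaflet == "upper"]) - mean(lf$z_rel[lf$leaflet == "lower"])
  }, numeric(1))
  structure(tibble(frame = idx, time = frames$time[idx], thickness = vals),
            class = c("thickness_series", class(tibble())),
            window = window)
}

# Periodic nearest-neighbour-ish fill of NA cells by iterative dilation.
fill_empty_cells <- function(m) {
  it <- 0L
  while (anyNA(m) && it < 4L * max(dim(m))) {
    nb <- array(c(m[c(2:nrow(m), 1), ], m[c(nrow(m), 1:(nrow(m) - 1)), ],
                  m[, c(2:ncol(m), 1)], m[, c(ncol(m), 1:(ncol(m) - 1))]),
                dim = c(nrow(m), ncol(m), 4))
    filled <- apply(nb, c(1, 2), function(v) {
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    })
    m[is.na(m)] <- filled[is.na(m)]
    it <- it + 1L
  }
  m
}

bin_leaflet_grid <- function(x, y, z, box, grid_n) {
  ix <- pmin(grid_n, floor(x / box[1] * grid_n) + 1L)
  iy <- pmin(grid_n, floor(y / box[2] * grid_n) + 1L)
  cell <- (iy - 1L) * grid_n + ix
  s <- tapply(z, factor(cell, levels = seq_len(grid_n^2)), sum)
  n <- tapply(rep(1, length(z)), factor(cell, levels = seq_len(grid_n^2)), sum)
  s[is.na(s)] <- 0; n[is.na(n)] <- 0
  list(sum = matrix(as.numeric(s), grid_n, grid_n),
       n = matrix(as.numeric(n), grid_n, grid_n))
}

#' Gridded thickness map of a bilayer
#'
#' Headgroups are binned on a `grid_n` x `grid_n` lateral grid per leaflet,
#' heights averaged over the trailing window, and the thickness field taken
#' as the upper minus the lower surface. Cells never visited by a headgroup
#' are filled from their occupied neighbours and flagged in the occupancy
#' mask. For rendering, the conventional color range spans 2.5 nm above the
#' map minimum.
#'
#' @param frames A `frame_sequence`.
#' @param grid_n Cells per side (default 100).
#' @param window Trailing fraction of frames.
#' @param registry A `lipid_registry`.
#' @return A `surface_grid`: list with `grid_n`, matrices `upper`, `lower`,
#'   `thickness`, `occupancy` (TRUE where both leaflets were observed),
#'   `cell_x`, `cell_y` (cell centers, nm), `box`, `window`.
#' @export
thickness_map <- function(frames, grid_n = 100, window = 0.5,
                          registry = default_registry()) {
  if (grid_n < 2) abort("grid_n must be >= 2")
  idx <- window_frames(frames, window)
  box <- frames$box[idx[1], ]
  acc <- list(upper = list(sum = 0, n = 0), lower = list(sum = 0, n = 0))
  for (i in idx) {
    fr <- get_frame(frames, i)
    lf <- assign_leaflets(fr, registry)
    heads <- headgroup_positions(fr, registry)
    for (side in c("upper", "lower")) {
      sel <- lf$leaflet == side
      g <- bin_leaflet_grid(heads$x[sel], heads$y[sel], lf$z_rel[sel],
                            box, grid_n)
      acc[[side]]$sum <- acc[[side]]$sum + g$sum
      acc[[side]]$n <- acc[[side]]$n + g$n
    }
  }
  mean_or_na <- function(a) {
    m <- a$sum / a$n
    m[a$n == 0] <- NA_real_
    m
  }
  upper <- mean_or_na(acc$upper); lower <- mean_or_na(acc$lower)
  occupancy <- !is.na(upper) & !is.na(lower)
  upper <- fill_empty_cells(upper); lower <- fill_empty_cells(lower)
  structure(list(grid_n = grid_n, upper = upper, lower = lower,
                 thickness = upper - lower, occupancy = occupancy,
                 cell_x = (seq_len(grid_n) - 0.5) * box[1] / grid_n,
                 cell_y = (seq_len(grid_n) - 0.5) * box[2] / grid_n,
                 box = box, window = window),
            class = "surface_grid")
}

#' @export
print.surface_grid <- function(x, ...) {
  cat(sprintf("<surface_grid> %dx%d cells, mean thickness %.3f nm (%.1f%% cells observed)\n",
              x$grid_n, x$grid_n, mean(x$thickness), 100 * mean(x$occupancy)))
  invisible(x)
}

roll <- function(m, k, margin) {
  n <- dim(m)[margin]
  idx <- ((seq_len(n) - 1 + k) %% n) + 1
  if (margin == 1) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
}

gaussian_smooth_periodic <- function(m, sigma) {
  if (sigma <= 0) return(m)
  n1 <- nrow(m); n2 <- ncol(m)
  d1 <- pmin(0:(n1 - 1), n1 - 0:(n1 - 1))
  d2 <- pmin(0:(n2 - 1), n2 - 0:(n2 - 1))
  k <- outer(exp(-0.5 * (d1 / sigma)^2), exp(-0.5 * (d2 / sigma)^2))
  k <- k / sum(k)
  Re(fft(fft(m) * fft(k), inverse = TRUE)) / (n1 * n2)
}

#' Mean curvature H of a gridded surface
#'
#' Central finite differences with periodic wrap;
#' `H = -0.5 * div(grad z / sqrt(1 + |grad z|^2))`, so a bulge toward +z has
#' positive H.
#'
#' @param z Surface height matrix (nm), periodic in both directions.
#' @param hx,hy Grid spacings (nm).
#' @return Matrix of H values (1/nm).
#' @export
mean_curvature <- function(z, hx, hy) {
  gx <- (roll(z, 1, 1) - roll(z, -1, 1)) / (2 * hx)
  gy <- (roll(z, 1, 2) - roll(z, -1, 2)) / (2 * hy)
  w <- sqrt(1 + gx^2 + gy^2)
  fx <- gx / w; fy <- gy / w
  div <- (roll(fx, 1, 1) - roll(fx, -1, 1)) / (2 * hx) +
         (roll(fy, 1, 2) - roll(fy, -1, 2)) / (2 * hy)
  -0.5 * div
}

#' Per-frame maximum mean curvature of the bilayer midplane
#'
#' For each frame in the window, the midplane surface (average of the two
#' leaflet surfaces on the grid) is Gaussian-smoothed (periodic, width
#' `smoothing` cells) and its mean curvature computed by central finite
#' differences; the maximum of |H| per frame is reported, along with the
#' signed extremum.
#'
#' @param frames A `frame_sequence`.
#' @param grid_n Cells per side.
#' @param smoothing Gaussian sigma in cells (default 1).
#' @param window Trailing fraction of frames.
#' @param registry A `lipid_registry`.
#' @return A `curvature_series` tibble: `frame`, `time`, `max_abs_H`,
#'   `max_H` (1/nm).
#' @export
curvature_series <- function(frames, grid_n = 100, smoothing = 1,
                             window = 0.5, registry = default_registry()) {
  idx <- window_frames(frames, window)
  box <- frames$box[idx[1], ]
  hx <- box[1] / grid_n; hy <- box[2] / grid_n
  res <- lapply(idx, function(i) {
    fr <- get_frame(frames, i)
    lf <- assign_leaflets(fr, registry)
    heads <- headgroup_positions(fr, registry)
    surf <- lapply(c(upper = "upper", lower = "lower"), function(side) {
      sel <- lf$leaflet == side
      g <- bin_leaflet_grid(heads$x[sel], heads$y[sel], lf$z_rel[sel], box, grid_n)
      m <- g$sum / g$n
      m[g$n == 0] <- NA_real_
      fill_empty_cells(m)
    })
    zmid <- gaussian_smooth_periodic((surf$upper + surf$lower) / 2, smoothing)
    H <- mean_curvature(zmid, hx, hy)
    c(max_abs_H = max(abs(H)), max_H = max(H))
  })
  m <- do.call(rbind, res)
  structure(tibble(frame = idx, time = frames$time[idx],
                   max_abs_H = m[, 1], max_H = m[, 2]),
            class = c("curvature_series", class(tibble())),
            grid_n = grid_n, smoothing = smoothing)
}
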