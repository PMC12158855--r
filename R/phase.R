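# Hemifusion onset detection and lamellar / inverted-hexagonal phase
# classification.

#' Bond-orientational hexagonal order parameter psi6
#'
#' `psi6 = |< exp(6 i phi) >|` over all nearest-neighbour bonds of a 2D
#' point set (optionally periodic). Neighbours are points within 1.35x the
#' median nearest-neighbour distance. 1 for a perfect triangular lattice;
#' small for random points.
#'
#' @param points Matrix (n x 2) of points.
#' @param plane Optional periodic extents (length 2); `NULL` for open
#'   boundaries.
#' @return Scalar in `[0, 1]`, or `NA` for fewer than 3 points.
#' @export
psi6 <- function(points, plane = NULL) {
  points <- matrix(points, ncol = 2)
  n <- nrow(points)
  if (n < 3L) return(NA_real_)
  dx <- outer(points[, 1], points[, 1], "-")
  dy <- outer(points[, 2], points[, 2], "-")
  if (!is.null(plane)) {
    dx <- dx - plane[1] * round(dx / plane[1])
    dy <- dy - plane[2] * round(dy / plane[2])
  }
  d <- sqrt(dx^2 + dy^2)
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  rc <- 1.35 * median(nn)
  ang <- c()
  for (i in seq_len(n)) {
    nb <- which(d[i, ] <= rc)
    if (length(nb)) ang <- c(ang, atan2(dy[nb, i], dx[nb, i]))
  }
  if (!length(ang)) return(NA_real_)
  Mod(mean(exp(6i * ang)))
}

tail_bead_rows <- function(topology, registry = default_registry()) {
  tails <- unique(unlist(registry$tail_beads))
  which(topology$name %in% tails &
          topology$species %in% registry$species[registry$is_lipid])
}

component_membership <- function(coords, box, cutoff, n_vertices) {
  pr <- cpp_pairs_within(coords, box, cutoff)
  g <- igraph::make_empty_graph(n = n_vertices, directed = FALSE)
  if (nrow(pr)) g <- igraph::add_edges(g, t(pr))
  igraph::components(g)$membership
}

#' Detect the hemifusion onset time in a stacked-bilayer trajectory
#'
#' The two bilayers are identified as the two (largest) connected components
#' of tail beads in the first frame (linkage cutoff `linkage_cutoff`).
#' Hemifusion is operationalized as a persistent stalk: the first frame at
#' which tail beads of the two bilayers come within `contact_cutoff` of each
#' other and stay bridged for at least `persistence` consecutive frames.
#'
#' @param frames A `frame_sequence` of a stacked pair.
#' @param contact_cutoff Tail-tail contact distance (nm, default the 0.5 nm
#'   contact cutoff).
#' @param persistence Minimum run of consecutive bridged frames (default 5;
#'   capped at the trajectory length).
#' @param linkage_cutoff Cutoff for the initial-frame connected components
#'   (nm).
#' @param registry A `lipid_registry`.
#' @return Onset time (ps), or `NA` if no persistent bridge forms.
#' @export
detect_hemifusion_time <- function(frames, contact_cutoff = 0.5,
                                   persistence = 5L, linkage_cutoff = 1.0,
                                   registry = default_registry()) {
  rows <- tail_bead_rows(frames$topology, registry)
  if (!length(rows)) abort("no tail beads in system")
  memb <- component_membership(seq_coords(frames, 1, rows),
                               frames$box[1, ], linkage_cutoff, length(rows))
  sizes <- sort(table(memb), decreasing = TRUE)
  if (length(sizes) < 2L || sizes[2] < 0.1 * length(rows)) {
    abort("not a stacked system: fewer than two substantial tail-bead components in frame 1")
  }
  top2 <- as.integer(names(sizes)[1:2])
  grp <- ifelse(memb == top2[1], 1L, ifelse(memb == top2[2], 2L, NA_integer_))
  persistence <- min(as.integer(persistence), length(frames))
  bridged <- vapply(seq_len(length(frames)), function(f) {
    pr <- cpp_pairs_within(seq_coords(frames, f, rows), frames$box[f, ],
                           contact_cutoff)
    if (!nrow(pr)) return(FALSE)
    ga <- grp[pr[, 1]]; gb <- grp[pr[, 2]]
    any(!is.na(ga) & !is.na(gb) & ga != gb)
  }, logical(1))
  r <- rle(bridged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= persistence)
  if (!length(hit)) return(NA_real_)
  frames$time[starts[hit[1]]]
}

# Does `vals` cover the full periodic length L? (bins of width `res`)
spans_axis <- function(vals, L, res = 0.7) {
  nb <- max(2L, floor(L / res))
  bins <- pmin(nb, floor(vals / L * nb) + 1L)
  length(unique(bins)) == nb
}

# Extent of a periodic 1D point set: L minus the largest empty gap.
periodic_extent <- function(vals, L) {
  s <- sort(vals %% L)
  gaps <- diff(c(s, s[1] + L))
  L - max(gaps)
}

circular_mean <- function(vals, L) {
  th <- 2 * pi * vals / L
  (atan2(mean(sin(th)), mean(cos(th))) %% (2 * pi)) * L / (2 * pi)
}

#' Classify a frame as lamellar, inverted hexagonal, or undefined
#'
#' Water beads are clustered into connected components under periodic
#' boundaries (`water_cutoff`). The frame is *inverted hexagonal* when at
#' least three components are quasi-cylindrical — spanning the box along a
#' single, common axis, with small comparable extents in the perpendicular
#' plane — and the hexagonal bond order psi6 of the channel centers reaches
#' `psi6_threshold`. It is *lamellar* when water forms slabs spanning both
#' lateral directions and the headgroup height distribution is bimodal.
#' Anything else is an *undefined non-bilayer*.
#'
#' @param frame A [bead_frame()] containing water and lipids.
#' @param water_cutoff Water clustering cutoff (nm; ~ the first-neighbour
#'   distance of coarse-grained water).
#' @param psi6_threshold Minimum psi6 for a hexagonal lattice call.
#' @param min_component Ignore water components smaller than this.
#' @param registry A `lipid_registry`.
#' @return A `phase_label` list: `label`, `n_channels`, `psi6`, `axis`,
#'   `channel_centers`.
#' @export
classify_phase <- function(frame, water_cutoff = 0.6, psi6_threshold = 0.7,
                           min_component = 10L, registry = default_registry()) {
  wrow <- which(frame$species == "W")
  if (!length(wrow)) abort("no water in frame")
  box <- frame_box(frame)
  wc <- coords_matrix(frame)[wrow, , drop = FALSE]
  memb <- component_membership(wc, box, water_cutoff, length(wrow))
  comp_ids <- as.integer(names(which(table(memb) >= min_component)))
  axes <- c("x", "y", "z")
  comp_info <- lapply(comp_ids, function(ci) {
    pts <- wc[memb == ci, , drop = FALSE]
    spans <- vapply(1:3, function(k) spans_axis(pts[, k], box[k]), logical(1))
    ext <- vapply(1:3, function(k) periodic_extent(pts[, k], box[k]), numeric(1))
    list(pts = pts, spans = spans, ext = ext, n = nrow(pts))
  })
  # quasi-cylindrical: spans exactly one axis; perpendicular extents small
  # and comparable
  cyl_axis <- vapply(comp_info, function(ci) {
    k <- which(ci$spans)
    if (length(k) != 1L) return(NA_integer_)
    perp <- setdiff(1:3, k)
    e <- ci$ext[perp]
    if (all(e < 0.35 * box[perp]) && max(e) / max(min(e), 1e-6) < 3) k else NA_integer_
  }, integer(1))
  cyl <- which(!is.na(cyl_axis))
  diag_list <- list(label = "undefined_nonbilayer", n_channels = 0L,
                    psi6 = NA_real_, axis = NA_character_,
                    channel_centers = NULL)
  if (length(cyl) >= 3L && length(unique(cyl_axis[cyl])) == 1L) {
    ax <- cyl_axis[cyl[1]]
    perp <- setdiff(1:3, ax)
    ctr <- t(vapply(comp_info[cyl], function(ci) {
      c(circular_mean(ci$pts[, perp[1]], box[perp[1]]),
        circular_mean(ci$pts[, perp[2]], box[perp[2]]))
    }, numeric(2)))
    p6 <- psi6(ctr, plane = box[perp])
    diag_list$n_channels <- length(cyl)
    diag_list$psi6 <- p6
    diag_list$axis <- axes[ax]
    diag_list$channel_centers <- ctr
    if (is.finite(p6) && p6 >= psi6_threshold) {
      diag_list$label <- "inverted_hexagonal"
      class(diag_list) <- "phase_label"
      return(diag_list)
    }
    class(diag_list) <- "phase_label"
    return(diag_list)
  }
  slab <- any(vapply(comp_info, function(ci) ci$spans[1] && ci$spans[2],
                     logical(1)))
  if (slab) {
    lamellar <- tryCatch({
      assign_leaflets(frame, registry); TRUE
    }, error = function(e) FALSE)
    if (lamellar) diag_list$label <- "lamellar"
  }
  class(diag_list) <- "phase_label"
  diag_list
}

#' @export
print.phase_label <- function(x, ...) {
  cat(sprintf("<phase_label> %s (channels: %d, psi6: %s, axis: %s)\n",
              x$label, x$n_channels,
              ifelse(is.na(x$psi6), "NA", sprintf("%.3f", x$psi6)),
              x$axis %||% "NA"))
  invisible(x)
}

#' Per-frame phase report of a trajectory
#'
#' @param frames A `frame_sequence`.
#' @param ... Passed to [classify_phase()].
#' @return A `phase_report` tibble: `frame`, `time`, `label`, `n_channels`,
#'   `psi6`.
#' @export
phase_report <- function(frames, ...) {
  rows <- lapply(seq_len(length(frames)), function(i) {
    pl <- classify_phase(get_frame(frames, i), ...)
    tibble(frame = i, time = frames$time[i], label = pl$label,
           n_channels = pl$n_channels, psi6 = pl$psi6)
  })
  structure(dplyr::bind_rows(rows),
            class = c("phase_report", class(tibble())))
}

#' First-appearance times of non-bilayer structures across conditions
#'
#' For each labeled run (MGDG percent, hydration, temperature), the
#' hemifusion onset time is detected; runs without an event are censored.
#' The table mirrors a first-appearance-time-versus-MGDG-content plot.
#'
#' @param runs A list of lists with elements `mgdg_percent`, `hydration`,
#'   `temperature`, `frames` (a `frame_sequence`).
#' @param classify_end Also classify the final frame of each run (slower).
#' @param ... Passed to [detect_hemifusion_time()].
#' @return Tibble `mgdg_percent`, `hydration`, `temperature_K`,
#'   `first_time_ps`, `censored`, `label_at_end`.
#' @export
first_appearance_curve <- function(runs, classify_end = FALSE, ...) {
  if (!length(runs)) {
    return(tibble(mgdg_percent = numeric(), hydration = numeric(),
                  temperature_K = numeric(), first_time_ps = numeric(),
                  censored = logical(), label_at_end = character()))
  }
  keys <- vapply(runs, function(r) {
    paste(r$mgdg_percent, r$hydration, r$temperature)
  }, character(1))
  if (anyDuplicated(keys)) abort("duplicate condition labels in run list")
  rows <- lapply(runs, function(r) {
    t_hemi <- detect_hemifusion_time(r$frames, ...)
    lab <- if (classify_end) {
      classify_phase(get_frame(r$frames, length(r$frames)))$label
    } else NA_character_
    tibble(mgdg_percent = r$mgdg_percent, hydration = r$hydration,
           temperature_K = r$temperature, first_time_ps = t_hemi,
           censored = is.na(t_hemi), label_at_end = lab)
  })
  dplyr::bind_rows(rows)
}
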