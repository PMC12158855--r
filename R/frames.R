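#' Bead frame: one configuration of a coarse-grained system
#'
#' A `bead_frame` is a tibble with one row per bead and columns `name`
#' (bead label, e.g. `"PO4"`), `molecule_id` (integer molecule index),
#' `species` (molecular species code), and coordinates `x`, `y`, `z` in nm.
#' The orthorhombic box edge lengths (nm) and the frame time (ps) are
#' carried as attributes.
#'
#' @param beads Data frame with columns `name`, `molecule_id`, `species`,
#'   `x`, `y`, `z`.
#' @param box Numeric length-3 vector of box edge lengths (nm), all > 0.
#' @param time Frame time in ps.
#' @param registry Registry used to validate species labels; `NULL` skips
#'   the species check.
#' @return A `bead_frame` tibble.
#' @export
bead_frame <- function(beads, box, time = 0, registry = default_registry()) {
  beads <- as_tibble(beads)[, c("name", "molecule_id", "species", "x", "y", "z")]
  beads$molecule_id <- as.integer(beads$molecule_id)
  stopifnot(length(box) == 3L)
  box <- as.numeric(box)
  if (any(!is.finite(box)) || any(box <= 0)) abort("box edges must be finite and > 0")
  if (nrow(beads) && any(!is.finite(as.matrix(beads[, c("x", "y", "z")])))) {
    abort("all coordinates must be finite")
  }
  if (nrow(beads)) {
    sp_per_mol <- tapply(beads$species, beads$molecule_id,
                         function(s) length(unique(s)))
    if (any(sp_per_mol != 1L)) abort("every bead must belong to exactly one molecule of one species")
    if (!is.null(registry)) registry_lookup(registry, unique(beads$species))
  }
  structure(beads,
            class = c("bead_frame", class(beads)),
            box = box, time = as.numeric(time))
}

#' @export
print.bead_frame <- function(x, ...) {
  cat(sprintf("<bead_frame> %d beads, %d molecules, box %.3f x %.3f x %.3f nm, t = %g ps\n",
              nrow(x), length(unique(x$molecule_id)),
              frame_box(x)[1], frame_box(x)[2], frame_box(x)[3], frame_time(x)))
  NextMethod()
}

#' Box and time accessors
#' @param frame A `bead_frame`.
#' @return `frame_box()`: numeric length-3 box (nm); `frame_time()`: time (ps).
#' @export
frame_box <- function(frame) attr(frame, "box")

#' @rdname frame_box
#' @export
frame_time <- function(frame) attr(frame, "time")

coords_matrix <- function(frame) {
  m <- cbind(frame$x, frame$y, frame$z)
  dimnames(m) <- NULL
  m
}

# Coordinates of frame i of a sequence as an n x 3 matrix (robust to n = 1).
seq_coords <- function(fs, i, rows = NULL) {
  m <- fs$coords[i, , , drop = FALSE]
  m <- matrix(m, ncol = 3)
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  m
}

#' Frame sequence: an ordered trajectory with fixed topology
#'
#' A `frame_sequence` stores a trajectory compactly: a single topology tibble
#' (`name`, `molecule_id`, `species`), a coordinate array of shape
#' `(n_frames, n_beads, 3)` in nm, per-frame boxes, and strictly increasing
#' times in ps. Individual frames are materialized with [get_frame()].
#'
#' @param frames Either a list of `bead_frame`s with identical topology, or
#'   `NULL` when `topology`/`coords` are given directly.
#' @param topology,coords,box,time Direct components: topology tibble,
#'   `(n_frames, n_beads, 3)` array, `n_frames x 3` box matrix, numeric times.
#' @return A `frame_sequence` object.
#' @export
frame_sequence <- function(frames = NULL, topology = NULL, coords = NULL,
                           box = NULL, time = NULL) {
  if (!is.null(frames)) {
    stopifnot(length(frames) > 0L)
    topo_of <- function(f) {
      tibble(name = f$name, molecule_id = f$molecule_id, species = f$species)
    }
    topology <- topo_of(frames[[1]])
    for (f in frames) {
      if (!identical(topo_of(f), topology)) {
        abort("all frames in a sequence must share an identical topology")
      }
    }
    nb <- nrow(topology)
    coords <- array(0, dim = c(length(frames), nb, 3L))
    for (i in seq_along(frames)) coords[i, , ] <- coords_matrix(frames[[i]])
    box <- do.call(rbind, lapply(frames, frame_box))
    time <- vapply(frames, frame_time, numeric(1))
  }
  if (is.null(dim(box))) box <- matrix(box, nrow = dim(coords)[1], ncol = 3L, byrow = TRUE)
  stopifnot(dim(coords)[1] == length(time), dim(coords)[2] == nrow(topology),
            dim(coords)[3] == 3L, nrow(box) == length(time))
  if (length(time) > 1L && any(diff(time) <= 0)) abort("frame times must be strictly increasing")
  structure(list(topology = as_tibble(topology), coords = coords,
                 box = box, time = as.numeric(time)),
            class = "frame_sequence")
}

#' @export
length.frame_sequence <- function(x) dim(x$coords)[1]

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %d frames, %d beads, t = [%g, %g] ps\n",
              length(x), nrow(x$topology), x$time[1], x$time[length(x)]))
  invisible(x)
}

#' Extract one frame from a sequence
#' @param fs A `frame_sequence`.
#' @param i Frame index (1-based).
#' @return A `bead_frame`.
#' @export
get_frame <- function(fs, i) {
  stopifnot(i >= 1L, i <= length(fs))
  beads <- fs$topology
  beads$x <- fs$coords[i, , 1]
  beads$y <- fs$coords[i, , 2]
  beads$z <- fs$coords[i, , 3]
  bead_frame(beads, box = fs$box[i, ], time = fs$time[i], registry = NULL)
}

#' Indices of the trailing analysis window
#'
#' Analysis defaults mirror common practice for equilibrated trajectories:
#' statistics are collected over the trailing fraction of frames (default the
#' last half).
#'
#' @param fs A `frame_sequence`.
#' @param window Trailing fraction of frames in (0, 1].
#' @return Integer frame indices.
#' @export
window_frames <- function(fs, window = 0.5) {
  n <- length(fs)
  if (!is.numeric(window) || window <= 0 || window > 1) {
    abort("window must be a fraction in (0, 1]")
  }
  k <- max(1L, ceiling(n * window))
  idx <- seq.int(n - k + 1L, n)
  if (length(idx) < 1L) abort("analysis window is empty")
  idx
}

#' Headgroup reference positions of all lipids in a frame
#'
#' Returns the position of the single headgroup reference bead of every lipid
#' molecule (the phosphate bead for PGs, the proximal or distal galactosyl
#' carbon for galactolipids and SQDG, per the registry). Water and ions are
#' excluded.
#'
#' @param frame A `bead_frame`.
#' @param registry A `lipid_registry`.
#' @return Tibble with columns `molecule_id`, `species`, `x`, `y`, `z` — one
#'   row per lipid molecule.
#' @export
headgroup_positions <- function(frame, registry = default_registry()) {
  idx <- registry_lookup(registry, unique(frame$species))
  hb <- registry$head_bead[registry_lookup(registry, frame$species)]
  keep <- !is.na(hb) & frame$name == hb
  out <- as_tibble(frame)[keep, c("molecule_id", "species", "x", "y", "z")]
  lip_species <- registry$species[registry$is_lipid]
  n_lip <- length(unique(frame$molecule_id[frame$species %in% lip_species]))
  if (nrow(out) != n_lip) {
    abort(sprintf("expected one headgroup reference bead per lipid (%d lipids, %d reference beads found)",
                  n_lip, nrow(out)))
  }
  out
}

#' Minimum-image displacement under orthorhombic periodic boundaries
#' @param d Matrix or vector of coordinate differences (nm).
#' @param box Box edge lengths (nm), recycled across columns.
#' @return Wrapped displacements.
#' @export
minimum_image <- function(d, box) {
  if (is.matrix(d)) {
    for (k in seq_len(ncol(d))) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    d
  } else {
    d - box * round(d / box)
  }
}

wrap_coords <- function(m, box) {
  for (k in 1:3) m[, k] <- m[, k] %% box[k]
  m
}
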