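# Radial distribution functions and contact-matrix clustering statistics.

#' Select bead rows of a topology or frame
#'
#' @param topology A topology tibble (or `bead_frame`).
#' @param species Optional species filter.
#' @param name Optional bead-name filter.
#' @return Integer row indices.
#' @export
select_beads <- function(topology, species = NULL, name = NULL) {
  keep <- rep(TRUE, nrow(topology))
  if (!is.null(species)) keep <- keep & topology$species %in% species
  if (!is.null(name)) keep <- keep & topology$name %in% name
  which(keep)
}

#' Radial distribution function g(r)
#'
#' Minimum-image pairwise distances between selections A (reference) and B
#' (distributed) are histogrammed up to `r_max` (half the shortest box
#' edge), shell-volume corrected (`4 pi r^2 dr`), and density-normalized.
#' `norm = "local"` divides by the density of B within `r_max` of the A
#' particles, averaged over A (so g -> 1 at large r for the sampled
#' neighbourhood); `norm = "box"` uses the global box density of B.
#'
#' @param frames A `frame_sequence`.
#' @param sel_A,sel_B Selections: lists with `species` and/or `name`
#'   components, passed to [select_beads()].
#' @param bin_width Histogram bin width (nm).
#' @param window Trailing fraction of frames (default all frames).
#' @param norm `"local"` or `"box"`.
#' @return An `rdf_profile` tibble: `r` (bin centers, nm), `g`, `count`
#'   (mean pair count per frame per bin); attributes `r_max`, `norm`,
#'   `n_A`, `n_B`.
#' @export
rdf <- function(frames, sel_A, sel_B, bin_width = 0.05, window = 1,
                norm = c("local", "box")) {
  norm <- match.arg(norm)
  if (bin_width <= 0) abort("bin_width must be > 0")
  idx <- window_frames(frames, window)
  topo <- frames$topology
  ia <- do.call(select_beads, c(list(topo), sel_A))
  ib <- do.call(select_beads, c(list(topo), sel_B))
  if (!length(ia) || !length(ib)) abort("empty selection for RDF")
  box <- frames$box[idx[1], ]
  r_max <- min(box) / 2
  if (bin_width > r_max) abort("bin_width exceeds r_max (half the shortest box edge)")
  nbins <- floor(r_max / bin_width)
  r_max_used <- nbins * bin_width
  h <- numeric(nbins)
  for (i in idx) {
    h <- h + cpp_cross_histogram(seq_coords(frames, i, ia),
                                 seq_coords(frames, i, ib),
                                 ia, ib, frames$box[i, ], r_max_used, nbins)
  }
  h <- h / length(idx)
  r_lo <- (seq_len(nbins) - 1) * bin_width
  shell <- 4 / 3 * pi * ((r_lo + bin_width)^3 - r_lo^3)
  n_A <- length(ia)
  rho <- if (norm == "local") {
    sum(h) / n_A / (4 / 3 * pi * r_max_used^3)
  } else {
    length(ib) / prod(box)
  }
  g <- h / (n_A * shell * rho)
  structure(tibble(r = r_lo + bin_width / 2, g = g, count = h),
            class = c("rdf_profile", class(tibble())),
            r_max = r_max_used, norm = norm, n_A = n_A, n_B = length(ib),
            bin_width = bin_width)
}

find_rdf_peaks <- function(profile, min_g = 1.2, min_sep_bins = 3L) {
  g <- profile$g
  n <- length(g)
  is_peak <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - min_sep_bins); hi <- min(n, i + min_sep_bins)
    g[i] >= min_g && g[i] == max(g[lo:hi]) && g[i] > min(g[lo:hi])
  }, logical(1))
  profile[is_peak, c("r", "g")]
}

#' Hydration RDF around a headgroup class
#'
#' g(r) of water beads around the headgroup reference beads of one headgroup
#' class — phosphatidylglycerol (`PG`), monogalactosyl (`MGAL`),
#' digalactosyl (`DGAL`) or sulfoquinovose (`SQ`). Detected g(r) maxima are
#' attached so hydration-layer structure (several sharp peaks vs one peak
#' and a broad bump) can be compared across classes.
#'
#' @param frames A `frame_sequence` containing water.
#' @param registry A `lipid_registry`.
#' @param headgroup_class `"PG"`, `"MGAL"`, `"DGAL"` or `"SQ"`.
#' @param bin_width,window,norm Passed to [rdf()].
#' @return An `rdf_profile` with a `peaks` attribute (tibble of `r`, `g`).
#' @export
hydration_rdf <- function(frames, registry = default_registry(),
                          headgroup_class = "PG", bin_width = 0.05,
                          window = 1, norm = "local") {
  species <- headgroup_class_species(headgroup_class)
  present <- intersect(species, unique(frames$topology$species))
  if (!length(present)) {
    abort(sprintf("headgroup class %s covers no lipids in this system", headgroup_class))
  }
  if (!"W" %in% frames$topology$species) abort("no water in system")
  heads <- registry$head_bead[registry_lookup(registry, present)]
  prof <- rdf(frames,
              sel_A = list(species = present, name = unique(heads)),
              sel_B = list(species = "W"),
              bin_width = bin_width, window = window, norm = norm)
  attr(prof, "peaks") <- find_rdf_peaks(prof)
  attr(prof, "headgroup_class") <- headgroup_class
  prof
}

species_pair_counts <- function(frame_coords, box, topo, rows, cutoff,
                                mode, brute = FALSE) {
  pr <- cpp_pairs_within(frame_coords[rows, , drop = FALSE], box, cutoff,
                         brute = brute)
  if (nrow(pr)) {
    i <- rows[pr[, 1]]; j <- rows[pr[, 2]]
    keep <- topo$molecule_id[i] != topo$molecule_id[j]
    i <- i[keep]; j <- j[keep]
  } else {
    i <- j <- integer(0)
  }
  if (mode == "molecule" && length(i)) {
    mp <- paste(pmin(topo$molecule_id[i], topo$molecule_id[j]),
                pmax(topo$molecule_id[i], topo$molecule_id[j]))
    first <- !duplicated(mp)
    i <- i[first]; j <- j[first]
  }
  sa <- topo$species[i]; sb <- topo$species[j]
  lo <- pmin(sa, sb); hi <- pmax(sa, sb)
  tibble(species_a = lo, species_b = hi) |>
    dplyr::count(.data$species_a, .data$species_b, name = "contacts")
}

#' Species-level contact matrix
#'
#' Two beads are in contact when their minimum-image distance is below
#' `cutoff` (default 0.5 nm). Per frame, contacts between beads of distinct
#' molecules are counted (all bead pairs by default; `mode = "molecule"`
#' collapses to molecule-pair presence), aggregated to species x species,
#' and averaged over the frames of the window.
#'
#' @param frames A `frame_sequence`.
#' @param cutoff Contact distance (nm).
#' @param window Trailing fraction of frames (default all).
#' @param species Species to include (default: lipid species present).
#' @param mode `"bead"` (count bead pairs) or `"molecule"` (count molecule
#'   pairs with any bead contact).
#' @param brute Force the all-pairs search path (oracle; used in tests).
#' @return A `contact_matrix`: symmetric numeric matrix with species
#'   dimnames and attributes `cutoff`, `mode`, `n_frames`, `normalized`.
#' @export
contact_matrix <- function(frames, cutoff = 0.5, window = 1, species = NULL,
                           mode = c("bead", "molecule"), brute = FALSE) {
  mode <- match.arg(mode)
  idx <- window_frames(frames, window)
  topo <- frames$topology
  if (is.null(species)) {
    reg <- default_registry()
    species <- intersect(unique(topo$species), reg$species[reg$is_lipid])
  }
  rows <- which(topo$species %in% species)
  if (!length(rows)) abort("no beads of the requested species")
  sp <- sort(unique(species))
  M <- matrix(0, length(sp), length(sp), dimnames = list(sp, sp))
  for (i in idx) {
    cnt <- species_pair_counts(seq_coords(frames, i), frames$box[i, ],
                               topo, rows, cutoff, mode, brute)
    for (k in seq_len(nrow(cnt))) {
      a <- cnt$species_a[k]; b <- cnt$species_b[k]
      M[a, b] <- M[a, b] + cnt$contacts[k]
      if (a != b) M[b, a] <- M[b, a] + cnt$contacts[k]
    }
  }
  M <- M / length(idx)
  structure(M, class = c("contact_matrix", "matrix"),
            cutoff = cutoff, mode = mode, n_frames = length(idx),
            normalized = FALSE)
}

#' Normalize a contact matrix by an initial-configuration matrix
#'
#' Element-wise ratio of a final-window contact matrix to the matrix of the
#' initial configuration. Because the initial configuration approximates a
#' random lateral distribution, a ratio above 1 reads as clustering of the
#' species pair and below 1 as separation. Cells with a zero initial count
#' are undefined (NaN) and flagged.
#'
#' @param final,initial `contact_matrix` objects over the same species set.
#' @return A normalized `contact_matrix` with attribute `undefined` (logical
#'   matrix marking zero-initial cells).
#' @export
normalized_contacts <- function(final, initial) {
  if (!identical(dimnames(final), dimnames(initial))) {
    abort("contact matrices must cover the same species sets")
  }
  ratio <- unclass(final) / unclass(initial)
  undef <- unclass(initial) == 0
  ratio[undef] <- NaN
  structure(ratio, class = c("contact_matrix", "matrix"),
            cutoff = attr(final, "cutoff"), mode = attr(final, "mode"),
            n_frames = attr(final, "n_frames"), normalized = TRUE,
            undefined = undef)
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix>%s cutoff %.2f nm, %s mode, %d frame(s)\n",
              if (isTRUE(attr(x, "normalized"))) " (normalized)" else "",
              attr(x, "cutoff"), attr(x, "mode"), attr(x, "n_frames")))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Mean of the unique entries of a (normalized) contact matrix
#'
#' Averages the upper triangle including the diagonal, skipping undefined
#' cells; the summary statistic used for clustering-null checks.
#'
#' @param m A `contact_matrix`.
#' @return Scalar mean.
#' @export
contact_matrix_mean <- function(m) {
  v <- unclass(m)[upper.tri(m, diag = TRUE)]
  mean(v[is.finite(v)])
}
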