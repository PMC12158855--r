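# Second-rank order parameter P2 and MSD-based diffusion.

#' Second-rank order parameter of bond vectors
#'
#' `P2 = <3 cos^2(theta) - 1> / 2`, where theta is the angle between each
#' bond vector and the bilayer normal. `P2 = 1` is perfect alignment with
#' the normal, `0` random orientation, `-0.5` anti-alignment (bonds
#' perpendicular to the normal).
#'
#' @param vectors Matrix (n x 3) of bond vectors (any length; normalized
#'   internally).
#' @param normal Bilayer normal (default the z axis).
#' @return Scalar P2.
#' @examples
#' p2_of_bonds(matrix(c(0, 0, 1), 1))        # 1
#' p2_of_bonds(matrix(c(1, 0, 0), 1))        # -0.5
#' @export
p2_of_bonds <- function(vectors, normal = c(0, 0, 1)) {
  vectors <- matrix(vectors, ncol = 3)
  normal <- normal / sqrt(sum(normal^2))
  ct <- (vectors %*% normal) / sqrt(rowSums(vectors^2))
  mean((3 * ct^2 - 1) / 2)
}

# Bond table: one row per (molecule, chain, bond index) with from/to bead
# row indices in the topology. Bond index i runs head->tail: with
# include_head_bond, bond 1 is headgroup -> first tail bead and bond i ends
# at tail bead i (indices 1..4); otherwise bonds are tail-internal (1..3).
bond_table <- function(topology, registry = default_registry(),
                       include_head_bond = TRUE) {
  key <- paste(topology$molecule_id, topology$name, sep = "\r")
  row_of <- function(mol, name) match(paste(mol, name, sep = "\r"), key)
  out <- list()
  for (sp in unique(topology$species)) {
    ri <- registry_lookup(registry, sp)
    chains <- registry$tail_beads[[ri]]
    if (is.null(chains)) next
    mols <- unique(topology$molecule_id[topology$species == sp])
    for (ci in seq_along(chains)) {
      beads <- chains[[ci]]
      if (length(beads) < 2L && !include_head_bond) {
        abort("chains must have at least 2 beads to define bonds")
      }
      from_names <- if (include_head_bond) {
        c(registry$head_bead[ri], beads[-length(beads)])
      } else beads[-length(beads)]
      to_names <- if (include_head_bond) beads else beads[-1]
      for (bi in seq_along(to_names)) {
        out[[length(out) + 1L]] <- tibble(
          species = sp, molecule_id = rep(mols, 1),
          chain = ci, bond_index = bi,
          from = row_of(mols, from_names[bi]),
          to = row_of(mols, to_names[bi]))
      }
    }
  }
  if (!length(out)) abort("no tail bonds found (head-only representation?)")
  bt <- dplyr::bind_rows(out)
  if (anyNA(bt$from) || anyNA(bt$to)) {
    abort("no tail bonds found: registry tail beads missing from topology (head-only representation?)")
  }
  bt
}

#' Tail order parameter P2 per bond index and species
#'
#' For every lipid chain, the P2 of each consecutive bond (indexed from the
#' headgroup end) against the bilayer normal is averaged over molecules,
#' chains and the trailing time window. The aggregate |P2| is the absolute
#' value of the grand mean over all bonds.
#'
#' @param frames A `frame_sequence`.
#' @param registry A `lipid_registry`.
#' @param window Trailing fraction of frames (default last half).
#' @param normal Bilayer normal, default the box z axis.
#' @param include_head_bond If `TRUE` (default) bond 1 is the
#'   headgroup-to-first-tail-bead bond and indices run 1..4 for 4-bead
#'   chains; if `FALSE`, only tail-internal bonds (1..3).
#' @return An `order_result` tibble: `species`, `bond_index`, `p2`,
#'   `n_bonds`; attributes `p2_mean` (grand mean) and `abs_p2`.
#' @export
p2_order <- function(frames, registry = default_registry(), window = 0.5,
                     normal = c(0, 0, 1), include_head_bond = TRUE) {
  idx <- window_frames(frames, window)
  bt <- bond_table(frames$topology, registry, include_head_bond)
  normal <- normal / sqrt(sum(normal^2))
  box <- frames$box[idx[1], ]
  grp <- paste(bt$species, bt$bond_index, sep = "\r")
  acc <- 0; nacc <- 0; grand <- 0; ngrand <- 0
  for (i in idx) {
    v <- frames$coords[i, bt$to, ] - frames$coords[i, bt$from, ]
    v <- minimum_image(v, frames$box[i, ])
    ct <- (v %*% normal) / sqrt(rowSums(v^2))
    p2 <- (3 * ct^2 - 1) / 2
    acc <- acc + rowsum(p2, grp)
    nacc <- nacc + rowsum(rep(1, length(p2)), grp)
    grand <- grand + sum(p2); ngrand <- ngrand + length(p2)
  }
  keys <- do.call(rbind, strsplit(rownames(acc), "\r"))
  res <- tibble(species = keys[, 1], bond_index = as.integer(keys[, 2]),
                p2 = as.numeric(acc / nacc), n_bonds = as.numeric(nacc))
  res <- dplyr::arrange(res, .data$species, .data$bond_index)
  structure(res, class = c("order_result", class(tibble())),
            p2_mean = grand / ngrand, abs_p2 = abs(grand / ngrand),
            window = window, normal = normal)
}

head_position_array <- function(frames, registry = default_registry(),
                                selection = NULL) {
  topo <- frames$topology
  reg_i <- registry_lookup(registry, topo$species)
  hb <- registry$head_bead[reg_i]
  sel <- !is.na(hb) & topo$name == hb
  if (!is.null(selection)) sel <- sel & topo$species %in% selection
  if (!any(sel)) abort("selection resolves to no lipid molecules")
  rows <- which(sel)
  list(coords = frames$coords[, rows, , drop = FALSE],
       species = topo$species[rows], molecule_id = topo$molecule_id[rows])
}

# Sliding-origin MSD via FFT (Kolafa / nMoldyn algorithm), vectorized over
# particles: msd(k) = SAB(k) - 2*S2(k).
msd_fft <- function(traj) {  # traj: (n_frames, n_particles, n_dims)
  n <- dim(traj)[1]; np <- dim(traj)[2]; nd <- dim(traj)[3]
  nfft <- 2^ceiling(log2(2 * n))
  S2 <- matrix(0, n, np)
  D <- matrix(0, n, np)
  for (d in seq_len(nd)) {
    x <- traj[, , d, drop = FALSE][, , 1]
    if (np == 1L) x <- matrix(x, ncol = 1)
    X <- stats::mvfft(rbind(x, matrix(0, nfft - n, np)))
    ac <- Re(stats::mvfft(X * Conj(X), inverse = TRUE))[seq_len(n), , drop = FALSE] / nfft
    S2 <- S2 + ac
    D <- D + x^2
  }
  # SAB(k) = sum_{t=0}^{n-k-1} D(t) + D(t+k); computed by running sums
  msd <- matrix(0, n, np)
  Dsum <- colSums(D)
  sse <- matrix(0, 1, np)
  for (k in seq_len(n) - 1L) {
    if (k > 0) sse <- sse + D[k, , drop = FALSE] + D[n - k + 1L, , drop = FALSE]
    sab <- 2 * rep(Dsum, each = 1) - sse
    msd[k + 1L, ] <- (sab - 2 * S2[k + 1L, ]) / (n - k)
  }
  rowMeans(msd)
}

#' Mean-squared displacement of lipid headgroups
#'
#' Headgroup reference bead positions are unwrapped through the periodic
#' boundaries (nearest-image steps), the center-of-mass drift of the
#' selected lipids is removed per frame, and the MSD is averaged over all
#' sliding time origins (FFT-based) and molecules. `dim = 2` restricts to
#' lateral (x, y) displacements (bilayers); `dim = 3` uses all coordinates
#' (inverted hexagonal structures).
#'
#' @param frames A `frame_sequence` (>= 2 frames).
#' @param selection Optional character vector of species to include.
#' @param dim 2 or 3.
#' @param registry A `lipid_registry`.
#' @param remove_com Remove per-frame center-of-mass drift (default TRUE).
#' @return An `msd_series` tibble: `lag`, `t` (ps), `msd` (nm^2).
#' @export
msd <- function(frames, selection = NULL, dim = 2,
                registry = default_registry(), remove_com = TRUE) {
  stopifnot(dim %in% c(2, 3), length(frames) >= 2L)
  hp <- head_position_array(frames, registry, selection)
  tr <- hp$coords
  n <- base::dim(tr)[1]; np <- base::dim(tr)[2]
  # unwrap: nearest-image per-step displacements, cumulatively summed
  for (k in 1:3) {
    x <- matrix(tr[, , k], n, np)
    steps <- x[-1, , drop = FALSE] - x[-n, , drop = FALSE]
    bm <- matrix(frames$box[-1, k], n - 1L, np)
    steps <- steps - bm * round(steps / bm)
    cums <- matrix(apply(steps, 2, cumsum), n - 1L, np)
    tr[, , k] <- rbind(matrix(0, 1L, np), cums) +
      matrix(x[1, ], n, np, byrow = TRUE)
  }
  dims_on <- seq_len(dim)
  tr <- tr[, , dims_on, drop = FALSE]
  if (remove_com && np > 1L) {
    for (k in seq_len(dim)) {
      com <- rowMeans(tr[, , k, drop = FALSE][, , 1, drop = FALSE])
      tr[, , k] <- tr[, , k] - com
    }
  }
  vals <- msd_fft(tr)
  vals[1] <- 0
  structure(tibble(lag = seq_len(n) - 1L,
                   t = frames$time - frames$time[1],
                   msd = vals),
            class = c("msd_series", class(tibble())),
            msd_dim = dim, n_particles = np,
            selection = selection %||% "all lipids")
}

#' Fit a diffusion coefficient to an MSD series
#'
#' Least-squares linear fit of MSD versus lag time over the fit window
#' (default lags between 10% and 50% of the trajectory length), with
#' `MSD = 4 D t` in two dimensions and `MSD = 6 D t` in three, so
#' `D = slope / (2 dim)`.
#'
#' @param msd_series An `msd_series` from [msd()].
#' @param fit_range Fraction range of lags used for the fit.
#' @return A `diffusion_result` list: `D` (nm^2/ns), `slope` (nm^2/ns),
#'   `dim`, `fit_window` (ps), `residual` (RMS, nm^2), `r_squared`.
#' @export
fit_diffusion <- function(msd_series, fit_range = c(0.1, 0.5)) {
  dim <- attr(msd_series, "msd_dim")
  if (is.null(dim)) abort("msd_series must carry its dimensionality")
  n <- nrow(msd_series)
  lo <- max(2L, floor(fit_range[1] * (n - 1L)) + 1L)
  hi <- max(lo + 1L, floor(fit_range[2] * (n - 1L)) + 1L)
  sub <- msd_series[lo:hi, ]
  fit <- lm(msd ~ t, data = sub)
  slope_ps <- coef(fit)[["t"]]
  slope_ns <- slope_ps * 1000
  D <- slope_ns / (2 * dim)
  if (D < 0) {
    warn("negative MSD slope; D clamped to 0")
    D <- 0
  }
  structure(list(D = D, slope = slope_ns, dim = dim,
                 fit_window = range(sub$t),
                 residual = sqrt(mean(stats::residuals(fit)^2)),
                 r_squared = summary(fit)$r.squared,
                 n_particles = attr(msd_series, "n_particles"),
                 selection = attr(msd_series, "selection")),
            class = "diffusion_result")
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat(sprintf("<diffusion_result> D = %.4g nm^2/ns (%dD, slope %.4g nm^2/ns, R^2 %.4f)\n",
              x$D, x$dim, x$slope, x$r_squared))
  invisible(x)
}

#' Per-species diffusion coefficients
#'
#' Convenience wrapper fitting one diffusion coefficient per lipid species
#' plus the pooled fit over all lipids.
#'
#' @inheritParams msd
#' @param fit_range Passed to [fit_diffusion()].
#' @return Tibble `species`, `D`, `slope`, `r_squared` (species `"all"` is
#'   the pooled fit).
#' @export
diffusion_by_species <- function(frames, dim = 2, registry = default_registry(),
                                 fit_range = c(0.1, 0.5)) {
  species <- intersect(unique(frames$topology$species),
                       registry$species[registry$is_lipid])
  rows <- lapply(c("all", species), function(sp) {
    sel <- if (sp == "all") NULL else sp
    dr <- fit_diffusion(msd(frames, selection = sel, dim = dim,
                            registry = registry), fit_range)
    tibble(species = sp, D = dr$D, slope = dr$slope, r_squared = dr$r_squared)
  })
  dplyr::bind_rows(rows)
}
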