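# Synthetic coarse-grained membrane generator. Every estimator in the
# package has a generator parameter it should recover; the generators are the
# ground-truth side of those closure checks.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Specification for the synthetic membrane generator
#'
#' Collects every knob of the synthetic system in one validated list. The
#' defaults emulate the coarse-grained thylakoid systems: the 40% MGDG
#' composition of ~1,344 lipids at 8 water beads per lipid, a 20 nm x 20 nm
#' lateral box, a 4 nm bilayer, and a moderately ordered tail region.
#'
#' @param composition A `system_composition` (see [build_composition()]).
#' @param box Orthorhombic box edges (nm).
#' @param thickness Base bilayer thickness (head-to-head, nm).
#' @param thickness_field `"constant"`, `"sinusoidal"` or `"gaussian_bump"`;
#'   modulation uses `thickness_amplitude` (nm) and `thickness_wavelength`
#'   (nm; for the bump, the Gaussian sigma).
#' @param thickness_amplitude,thickness_wavelength Modulation parameters (nm).
#' @param midplane_amplitude,midplane_wavelength Sinusoidal modulation of the
#'   midplane height along x (nm), for curvature ground truth.
#' @param tail_order Target P2 of tail bonds, in `[-0.5, 1]`.
#' @param lateral_layout `"random"` or `"clustered"`.
#' @param cluster_strength Fraction of lipids placed near same-species
#'   cluster centers (0 = indistinguishable from random).
#' @param cluster_sd Lateral spread of a cluster (nm).
#' @param dynamics `"static"` or `"brownian"`.
#' @param D Diffusion coefficient for Brownian dynamics (nm^2/ns).
#' @param dim Dimensionality of Brownian motion (2 = lateral, 3).
#' @param stacking `"single"` or `"pair"` (two stacked bilayers).
#' @param gap Water gap between stacked bilayers (nm).
#' @param hemifusion_time Time (ps) at which a tail-bead stalk bridges the
#'   stacked pair, or `NULL` for no event.
#' @param phase `"lamellar"` or `"inverted_hexagonal"`.
#' @param lattice_const Triangular-lattice constant of water channels (nm).
#' @param n_channels Number of water channels.
#' @param channel_jitter Random jitter of channel centers, as a fraction of
#'   the lattice constant (0 = perfect lattice).
#' @param representation `"full"` (head + 2x4 tail beads per lipid) or
#'   `"head"` (headgroup reference bead only; cheap frames for thickness,
#'   curvature and diffusion closures).
#' @param head_jitter Gaussian jitter of head bead heights (nm).
#' @param bond_length Tail bond length (nm).
#' @param seed Integer seed fixing the output bit-exactly.
#' @return A validated `generator_spec` list.
#' @export
generator_spec <- function(composition = build_composition(40, 1344, hydration = 8),
                           box = c(20, 20, 12),
                           thickness = 4.0,
                           thickness_field = c("constant", "sinusoidal", "gaussian_bump"),
                           thickness_amplitude = 0,
                           thickness_wavelength = 10,
                           midplane_amplitude = 0,
                           midplane_wavelength = 10,
                           tail_order = 0.5,
                           lateral_layout = c("random", "clustered"),
                           cluster_strength = 0,
                           cluster_sd = 1.5,
                           dynamics = c("static", "brownian"),
                           D = 0.01, dim = 2,
                           stacking = c("single", "pair"),
                           gap = 3, hemifusion_time = NULL,
                           phase = c("lamellar", "inverted_hexagonal"),
                           lattice_const = 6, n_channels = 4,
                           channel_jitter = 0,
                           representation = c("full", "head"),
                           head_jitter = 0,
                           bond_length = 0.47,
                           seed = 1L) {
  spec <- list(
    composition = composition, box = as.numeric(box),
    thickness = thickness, thickness_field = match.arg(thickness_field),
    thickness_amplitude = thickness_amplitude,
    thickness_wavelength = thickness_wavelength,
    midplane_amplitude = midplane_amplitude,
    midplane_wavelength = midplane_wavelength,
    tail_order = tail_order,
    lateral_layout = match.arg(lateral_layout),
    cluster_strength = cluster_strength, cluster_sd = cluster_sd,
    dynamics = match.arg(dynamics), D = D, dim = dim,
    stacking = match.arg(stacking), gap = gap,
    hemifusion_time = hemifusion_time,
    phase = match.arg(phase), lattice_const = lattice_const,
    n_channels = n_channels, channel_jitter = channel_jitter,
    representation = match.arg(representation),
    head_jitter = head_jitter, bond_length = bond_length,
    seed = as.integer(seed)
  )
  stopifnot(length(spec$box) == 3L, all(spec$box > 0), spec$thickness > 0,
            spec$gap > 0, spec$lattice_const > 0, spec$D >= 0,
            spec$dim %in% c(2, 3))
  if (spec$tail_order < -0.5 || spec$tail_order > 1) {
    abort("tail_order (target P2) must lie in [-0.5, 1]")
  }
  class(spec) <- "generator_spec"
  spec
}

thickness_at <- function(spec, x, y) {
  switch(spec$thickness_field,
    constant = rep(spec$thickness, length(x)),
    sinusoidal = spec$thickness + spec$thickness_amplitude *
      sin(2 * pi * x / spec$thickness_wavelength),
    gaussian_bump = {
      cx <- spec$box[1] / 2; cy <- spec$box[2] / 2
      s <- spec$thickness_wavelength
      spec$thickness + spec$thickness_amplitude *
        exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2))
    })
}

midplane_at <- function(spec, x) {
  if (spec$midplane_amplitude == 0) return(rep(0, length(x)))
  spec$midplane_amplitude * sin(2 * pi * x / spec$midplane_wavelength)
}

# Lateral (x, y) placement per lipid; clustered layouts draw a fraction of
# each species from same-species Gaussian cluster centers.
lateral_positions <- function(spec, species_vec) {
  n <- length(species_vec)
  lx <- spec$box[1]; ly <- spec$box[2]
  x <- stats::runif(n, 0, lx); y <- stats::runif(n, 0, ly)
  if (spec$lateral_layout == "clustered" && spec$cluster_strength > 0) {
    for (sp in unique(species_vec)) {
      i <- which(species_vec == sp)
      k <- max(1L, round(length(i) / 80))
      cx <- stats::runif(k, 0, lx); cy <- stats::runif(k, 0, ly)
      pick <- i[stats::runif(length(i)) < spec$cluster_strength]
      if (length(pick)) {
        ci <- sample.int(k, length(pick), replace = TRUE)
        x[pick] <- (cx[ci] + stats::rnorm(length(pick), 0, spec$cluster_sd)) %% lx
        y[pick] <- (cy[ci] + stats::rnorm(length(pick), 0, spec$cluster_sd)) %% ly
      }
    }
  }
  cbind(x, y)
}

# Unit bond directions achieving E[P2] = target: a mixture of perfectly
# aligned (P2 = 1) or perpendicular (P2 = -1/2) bonds with isotropic ones,
# with the mixing weight solved in closed form.
sample_bond_dirs <- function(n, target, inward_sign) {
  u <- stats::runif(n)
  if (target >= 0) {
    aligned <- u < target
  } else {
    aligned <- u < (-2 * target)  # weight on perpendicular component
  }
  dirs <- matrix(0, n, 3)
  n_iso <- sum(!aligned)
  if (n_iso) {
    z <- stats::runif(n_iso, -1, 1)
    phi <- stats::runif(n_iso, 0, 2 * pi)
    r <- sqrt(pmax(0, 1 - z^2))
    dirs[!aligned, ] <- cbind(r * cos(phi), r * sin(phi), z)
  }
  if (any(aligned)) {
    if (target >= 0) {
      dirs[aligned, 3] <- inward_sign[aligned]
    } else {
      phi <- stats::runif(sum(aligned), 0, 2 * pi)
      dirs[aligned, ] <- cbind(cos(phi), sin(phi), 0)
    }
  }
  dirs
}

water_bead_names <- function(n) rep("W", n)

# Assemble the lipid bead table for one bilayer (leaflets at
# z = z0 + midplane +/- thickness/2), plus water slab and ions.
build_bilayer_beads <- function(spec, z0) {
  counts <- composition_lipid_counts(spec$composition)
  counts <- counts[counts > 0]
  species_vec <- rep(names(counts), counts)
  n_lip <- length(species_vec)
  # equal leaflet occupancy per species (alternating within species)
  leaflet <- unlist(lapply(counts, function(k) rep_len(c(1, -1), k)), use.names = FALSE)
  xy <- lateral_positions(spec, species_vec)
  th <- thickness_at(spec, xy[, 1], xy[, 2])
  mid <- midplane_at(spec, xy[, 1])
  head_z <- z0 + mid + leaflet * th / 2
  if (spec$head_jitter > 0) head_z <- head_z + stats::rnorm(n_lip, 0, spec$head_jitter)
  reg <- default_registry()
  head_names <- reg$head_bead[registry_lookup(reg, species_vec)]

  if (spec$representation == "head") {
    lip <- tibble(
      name = head_names, molecule_id = seq_len(n_lip), species = species_vec,
      x = xy[, 1], y = xy[, 2], z = head_z
    )
  } else {
    # two chains of four beads; bonds run from the head toward the midplane
    n_chain <- 2L; n_bead <- 4L
    chain_id <- rep(seq_len(n_lip), each = n_chain)
    inward <- -leaflet[chain_id]  # chains descend toward the midplane
    pos <- array(0, dim = c(n_lip * n_chain, n_bead, 3))
    prev <- cbind(xy[chain_id, 1], xy[chain_id, 2], head_z[chain_id])
    for (k in seq_len(n_bead)) {
      dirs <- sample_bond_dirs(n_lip * n_chain, spec$tail_order, inward)
      prev <- prev + spec$bond_length * dirs
      pos[, k, ] <- prev
    }
    per_lip <- 1L + n_chain * n_bead
    mol <- rep(seq_len(n_lip), each = per_lip)
    nm <- c("HEAD", paste0("C", 1:4, "A"), paste0("C", 1:4, "B"))
    name <- rep(nm, n_lip)
    name[name == "HEAD"] <- head_names
    cx <- cy <- cz <- numeric(n_lip * per_lip)
    hsel <- seq(1, n_lip * per_lip, by = per_lip)
    cx[hsel] <- xy[, 1]; cy[hsel] <- xy[, 2]; cz[hsel] <- head_z
    for (c_i in 1:2) for (k in 1:4) {
      sel <- hsel + (c_i - 1L) * 4L + k
      row <- seq(c_i, n_lip * n_chain, by = n_chain)
      cx[sel] <- pos[row, k, 1]; cy[sel] <- pos[row, k, 2]; cz[sel] <- pos[row, k, 3]
    }
    lip <- tibble(name = name, molecule_id = mol, species = rep(species_vec, each = per_lip),
                  x = cx, y = cy, z = cz)
  }

  # water: two jittered-grid slabs at liquid CG density (one bead ~ 0.115
  # nm^3) adjacent to the two headgroup surfaces, so a hydrated system has
  # connected water slabs at the ~0.5 nm bead spacing of liquid CG water
  n_w <- spec$composition$count[spec$composition$species == "Water"]
  n_w <- if (length(n_w)) n_w else 0L
  half_mem <- max(th) / 2 + abs(spec$midplane_amplitude) + 0.3
  wat <- NULL
  slab_h <- 0
  if (n_w > 0) {
    n_top <- ceiling(n_w / 2); n_bot <- n_w - n_top
    nxy <- max(1L, round(spec$box[1] / 0.47)) * max(1L, round(spec$box[2] / 0.47))
    h_top <- ceiling(n_top / nxy) * 0.47
    h_bot <- ceiling(max(n_bot, 1) / nxy) * 0.47
    slab_h <- max(h_top, h_bot)
    if (2 * half_mem + h_top + h_bot > spec$box[3]) {
      abort("box z too small to hold the water at liquid density; increase box[3] or lower hydration")
    }
    gt <- jittered_grid(n_top, spec$box[1], spec$box[2], h_top, jitter = 0.15)
    gb <- jittered_grid(n_bot, spec$box[1], spec$box[2], h_bot, jitter = 0.15)
    wat <- tibble(name = "W", molecule_id = seq_len(n_w), species = "W",
                  x = c(gt[, 1], gb[, 1]), y = c(gt[, 2], gb[, 2]),
                  z = c(z0 + half_mem + gt[, 3],
                        z0 - half_mem - h_bot + gb[, 3]))
  }
  n_na <- spec$composition$count[spec$composition$species == "Sodium"]
  n_cl <- spec$composition$count[spec$composition$species == "Chloride"]
  n_na <- if (length(n_na) && !is.na(n_na)) n_na else 0L
  n_cl <- if (length(n_cl) && !is.na(n_cl)) n_cl else 0L
  ion <- NULL
  if (n_na + n_cl > 0) {
    n_i <- n_na + n_cl
    side <- stats::runif(n_i) < 0.5
    zi <- ifelse(side, z0 + half_mem + stats::runif(n_i, 0, max(slab_h, 0.4)),
                 z0 - half_mem - stats::runif(n_i, 0, max(slab_h, 0.4)))
    ion <- tibble(name = c(rep("NA", n_na), rep("CL", n_cl)),
                  molecule_id = seq_len(n_i), species = "ION",
                  x = stats::runif(n_i, 0, spec$box[1]),
                  y = stats::runif(n_i, 0, spec$box[2]), z = zi)
  }
  parts <- list(lip, wat, ion)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  off <- 0L
  for (i in seq_along(parts)) {
    parts[[i]]$molecule_id <- parts[[i]]$molecule_id + off
    off <- max(parts[[i]]$molecule_id)
  }
  beads <- dplyr::bind_rows(parts)
  beads$x <- beads$x %% spec$box[1]
  beads$y <- beads$y %% spec$box[2]
  beads$z <- beads$z %% spec$box[3]
  beads
}

# Jittered grid at (close to) liquid CG water spacing (~0.47 nm), filled
# layer by layer from z = 0 upward; the last layer may be partial.
jittered_grid <- function(n, lx, ly, lz, jitter = 0.15, spacing = 0.47) {
  nx <- max(1L, round(lx / spacing)); ny <- max(1L, round(ly / spacing))
  nz <- max(1L, ceiling(n / (nx * ny)))
  g <- expand.grid(x = (seq_len(nx) - 0.5) * lx / nx,
                   y = (seq_len(ny) - 0.5) * ly / ny,
                   z = (seq_len(nz) - 0.5) * spacing)
  # random subset so partial occupancy spreads over the whole slab
  g <- as.matrix(g[sample.int(nrow(g), n), , drop = FALSE])
  j <- jitter * spacing
  g + matrix(stats::runif(3 * n, -j, j), n, 3)
}

#' Generate a planar bilayer frame
#'
#' Builds a lamellar bilayer with headgroup beads at `z0 +/- thickness/2`
#' (optionally modulated thickness and midplane), tail chains whose bond
#' orientations achieve the target P2 in expectation, a jittered-grid water
#' slab at the composition's hydration, and randomly placed counterions.
#'
#' @param spec A [generator_spec()] with `phase = "lamellar"` and
#'   `stacking = "single"`.
#' @return A [bead_frame()] with a `ground_truth` attribute.
#' @export
make_bilayer <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (spec$phase != "lamellar" || spec$stacking != "single") {
    abort("make_bilayer requires phase = 'lamellar' and stacking = 'single'")
  }
  with_seed(spec$seed, {
    beads <- build_bilayer_beads(spec, z0 = spec$box[3] / 2)
    fr <- bead_frame(beads, box = spec$box, time = 0)
    attr(fr, "ground_truth") <- list(
      thickness = spec$thickness, tail_order = spec$tail_order,
      thickness_amplitude = spec$thickness_amplitude,
      thickness_wavelength = spec$thickness_wavelength,
      midplane_amplitude = spec$midplane_amplitude,
      midplane_wavelength = spec$midplane_wavelength)
    fr
  })
}

lipid_molecule_map <- function(topology, registry = default_registry()) {
  lip_species <- registry$species[registry$is_lipid]
  is_lip <- topology$species %in% lip_species
  mols <- unique(topology$molecule_id[is_lip])
  match(ifelse(is_lip, topology$molecule_id, NA_integer_), mols)
}

# Apply cumulative per-lipid rigid Brownian displacements to a base frame.
brownian_coords <- function(base_xyz, lipidx, n_frames, dt_ps, D, dim, box) {
  n_lip <- max(lipidx, na.rm = TRUE)
  sd_step <- sqrt(2 * D * dt_ps / 1000)  # D in nm^2/ns, dt in ps
  coords <- array(0, dim = c(n_frames, nrow(base_xyz), 3))
  disp <- matrix(0, n_lip, 3)
  dims_on <- seq_len(dim)  # 2D: x,y ; 3D: x,y,z
  for (f in seq_len(n_frames)) {
    if (f > 1 && sd_step > 0) {
      step <- matrix(0, n_lip, 3)
      step[, dims_on] <- stats::rnorm(n_lip * length(dims_on), 0, sd_step)
      disp <- disp + step
    }
    m <- base_xyz
    ok <- !is.na(lipidx)
    m[ok, ] <- m[ok, ] + disp[lipidx[ok], ]
    coords[f, , ] <- wrap_coords(m, box)
  }
  coords
}

#' Generate a trajectory of a bilayer with Brownian or static dynamics
#'
#' Starting from [make_bilayer()], each lipid is displaced rigidly (internal
#' geometry frozen) by independent Gaussian steps of variance `2 D dt` per
#' allowed dimension, so tail order and diffusion ground truths are
#' independent. Water and ions stay fixed.
#'
#' @param spec A [generator_spec()] with `dynamics` `"brownian"` or
#'   `"static"`.
#' @param n_frames Number of frames.
#' @param dt Frame interval (ps).
#' @return A `frame_sequence` with a `ground_truth` attribute.
#' @export
make_trajectory <- function(spec, n_frames, dt) {
  stopifnot(inherits(spec, "generator_spec"), n_frames >= 1, dt > 0)
  base <- make_bilayer(spec)
  with_seed(spec$seed + 1L, {
    topo <- as_tibble(base)[, c("name", "molecule_id", "species")]
    lipidx <- lipid_molecule_map(topo)
    xyz <- coords_matrix(base)
    D <- if (spec$dynamics == "brownian") spec$D else 0
    coords <- brownian_coords(xyz, lipidx, n_frames, dt, D, spec$dim, spec$box)
    fs <- frame_sequence(topology = topo, coords = coords, box = spec$box,
                         time = (seq_len(n_frames) - 1) * dt)
    attr(fs, "ground_truth") <- c(attr(base, "ground_truth"),
                                  list(D = D, dim = spec$dim, dt = dt))
    fs
  })
}

#' Generate a stacked bilayer pair, optionally with a hemifusion stalk
#'
#' Two bilayers separated by a water gap (the lower bilayer is replicated in
#' z, mirroring how stacked systems are built from a single membrane). If
#' `spec$hemifusion_time` is set, from that time onward a cylindrical stalk
#' of tail beads (radius >= 1 nm) bridges the inter-bilayer gap, displacing
#' the water inside the cylinder; before it, the gap holds only water and
#' ions.
#'
#' @inheritParams make_trajectory
#' @param spec A [generator_spec()] with `stacking = "pair"`.
#' @return A `frame_sequence`; ground truth records the stalk time and the
#'   bilayer membership of every molecule.
#' @export
make_stacked_pair <- function(spec, n_frames, dt) {
  stopifnot(inherits(spec, "generator_spec"), n_frames >= 1, dt > 0)
  if (spec$stacking != "pair") abort("make_stacked_pair requires stacking = 'pair'")
  if (spec$representation != "full") abort("stacked pairs need representation = 'full' (tail beads define the stalk)")
  T_hemi <- spec$hemifusion_time
  times <- (seq_len(n_frames) - 1) * dt
  if (!is.null(T_hemi) && T_hemi > times[n_frames]) {
    abort("hemifusion_time lies beyond the trajectory end")
  }
  half <- spec$box[3] / 2
  sub <- spec
  sub$box <- c(spec$box[1], spec$box[2], half)
  sub$stacking <- "single"
  with_seed(spec$seed, {
    b1 <- build_bilayer_beads(sub, z0 = half / 2)
    b2 <- b1
    b2$z <- b2$z + half
    b2$molecule_id <- b2$molecule_id + max(b1$molecule_id)
    beads <- dplyr::bind_rows(b1, b2)
    topo <- beads[, c("name", "molecule_id", "species")]
    lipidx <- lipid_molecule_map(topo)
    xyz <- cbind(beads$x, beads$y, beads$z)
    D <- if (spec$dynamics == "brownian") spec$D else 0
    coords <- brownian_coords(xyz, lipidx, n_frames, dt, D, spec$dim, spec$box)
    bilayer_of_mol <- c(rep(1L, max(b1$molecule_id)),
                        rep(2L, max(b1$molecule_id)))

    if (!is.null(T_hemi)) {
      # inner gap between the upper surface of bilayer 1 and the lower
      # surface of bilayer 2
      z_lo <- half / 2 + spec$thickness / 2
      z_hi <- half + half / 2 - spec$thickness / 2
      z_mid <- (z_lo + z_hi) / 2
      cx <- spec$box[1] / 2; cy <- spec$box[2] / 2
      r_stalk <- 1.2
      tail_names <- c("C3A", "C4A", "C3B", "C4B")
      is_tail <- beads$name %in% tail_names
      lat_d <- sqrt(minimum_image(beads$x - cx, spec$box[1])^2 +
                    minimum_image(beads$y - cy, spec$box[2])^2)
      pick_from <- function(bl, n_take) {
        cand <- which(is_tail & bilayer_of_mol[beads$molecule_id] == bl)
        cand[order(lat_d[cand])][seq_len(min(n_take, length(cand)))]
      }
      n_each <- 60L
      s1 <- pick_from(1L, n_each); s2 <- pick_from(2L, n_each)
      stalk_pos <- function(n, zmin, zmax) {
        r <- r_stalk * sqrt(stats::runif(n)); a <- stats::runif(n, 0, 2 * pi)
        cbind((cx + r * cos(a)) %% spec$box[1],
              (cy + r * sin(a)) %% spec$box[2],
              stats::runif(n, zmin, zmax))
      }
      p1 <- stalk_pos(length(s1), z_lo - 0.2, z_mid + 0.25)
      p2 <- stalk_pos(length(s2), z_mid - 0.25, z_hi + 0.2)
      # water inside the stalk cylinder is pushed outside it
      in_cyl <- beads$species == "W" & lat_d < (r_stalk + 0.4) &
        beads$z > z_lo & beads$z < z_hi
      n_wmove <- sum(in_cyl)
      if (n_wmove) {
        r <- r_stalk + 0.8 + stats::runif(n_wmove, 0, 2)
        a <- stats::runif(n_wmove, 0, 2 * pi)
        wpos <- cbind((cx + r * cos(a)) %% spec$box[1],
                      (cy + r * sin(a)) %% spec$box[2],
                      stats::runif(n_wmove, z_lo, z_hi))
      }
      after <- which(times >= T_hemi)
      for (f in after) {
        coords[f, s1, ] <- p1
        coords[f, s2, ] <- p2
        if (n_wmove) coords[f, in_cyl, ] <- wpos
      }
    }
    fs <- frame_sequence(topology = topo, coords = coords, box = spec$box,
                         time = times)
    attr(fs, "ground_truth") <- list(
      hemifusion_time = T_hemi, gap = spec$gap,
      bilayer_of_molecule = bilayer_of_mol, D = D, dt = dt)
    fs
  })
}

#' Triangular-lattice channel centers
#'
#' Centers of `n_channels` water channels in the plane perpendicular to the
#' channel axis, on a triangular lattice of the given constant, optionally
#' jittered. Errors if the lattice patch does not fit the plane.
#'
#' @param n_channels Number of channels (>= 1).
#' @param lattice_const Lattice constant (nm).
#' @param plane Extents of the perpendicular plane (length-2, nm).
#' @param jitter Jitter as a fraction of the lattice constant.
#' @return Matrix `n_channels x 2` of centers.
#' @export
lattice_centers <- function(n_channels, lattice_const, plane, jitter = 0) {
  a <- lattice_const
  n1 <- ceiling(sqrt(n_channels))
  n2 <- ceiling(n_channels / n1)
  ij <- expand.grid(i = seq_len(n1) - 1, j = seq_len(n2) - 1)[seq_len(n_channels), ]
  px <- ij$i * a + (ij$j %% 2) * a / 2 + a / 2
  py <- ij$j * a * sqrt(3) / 2 + a / 2
  if (max(px) + a / 2 > plane[1] || max(py) + a / 2 > plane[2]) {
    abort(sprintf("channel lattice (%d channels, a = %g nm) does not fit the %g x %g nm plane",
                  n_channels, a, plane[1], plane[2]))
  }
  ctr <- cbind(px, py)
  if (jitter > 0) {
    ctr <- ctr + matrix(stats::rnorm(2 * n_channels, 0, jitter * a),
                        n_channels, 2)
  }
  ctr
}

#' Generate an inverted hexagonal (HII) frame
#'
#' Water beads fill cylinders along the y axis whose centers sit on a
#' triangular lattice in the (x, z) plane; headgroup beads coat the cylinder
#' surfaces and tail beads fill the interstitial matrix. With
#' `n_channels = 0` the generator degenerates to [make_bilayer()].
#'
#' @param spec A [generator_spec()] with `phase = "inverted_hexagonal"`.
#' @return A [bead_frame()] with channel centers in its `ground_truth`.
#' @export
make_inverted_hexagonal <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (spec$n_channels == 0) {
    sub <- spec; sub$phase <- "lamellar"
    return(make_bilayer(sub))
  }
  with_seed(spec$seed, {
    lx <- spec$box[1]; ly <- spec$box[2]; lz <- spec$box[3]
    ctr <- lattice_centers(spec$n_channels, spec$lattice_const,
                           plane = c(lx, lz), jitter = spec$channel_jitter)
    r_w <- 0.25 * spec$lattice_const
    # water: regular grid filling each cylinder, dense enough to connect
    sp <- 0.42
    xs <- seq(-r_w, r_w, by = sp); ys <- seq(sp / 2, ly, by = sp)
    disc <- expand.grid(dx = xs, dz = xs)
    disc <- disc[disc$dx^2 + disc$dz^2 <= r_w^2, ]
    wat_list <- lapply(seq_len(nrow(ctr)), function(c_i) {
      g <- expand.grid(y = ys, k = seq_len(nrow(disc)))
      tibble(name = "W", molecule_id = 0L, species = "W",
             x = (ctr[c_i, 1] + disc$dx[g$k]) %% lx,
             y = g$y %% ly,
             z = (ctr[c_i, 2] + disc$dz[g$k]) %% lz)
    })
    wat <- dplyr::bind_rows(wat_list)
    wat <- wat[!duplicated(round(cbind(wat$x, wat$y, wat$z), 4)), ]
    jit <- matrix(stats::runif(3 * nrow(wat), -0.06, 0.06), ncol = 3)
    wat$x <- (wat$x + jit[, 1]) %% lx
    wat$y <- (wat$y + jit[, 2]) %% ly
    wat$z <- (wat$z + jit[, 3]) %% lz
    wat$molecule_id <- seq_len(nrow(wat))

    counts <- composition_lipid_counts(spec$composition)
    counts <- counts[counts > 0]
    species_vec <- rep(names(counts), counts)
    n_lip <- length(species_vec)
    ch <- rep_len(seq_len(nrow(ctr)), n_lip)
    phi <- stats::runif(n_lip, 0, 2 * pi)
    yy <- stats::runif(n_lip, 0, ly)
    R <- r_w + 0.3
    hx <- (ctr[ch, 1] + R * cos(phi)) %% lx
    hz <- (ctr[ch, 2] + R * sin(phi)) %% lz
    reg <- default_registry()
    head_names <- reg$head_bead[registry_lookup(reg, species_vec)]
    per_lip <- if (spec$representation == "full") 9L else 1L
    mol <- rep(seq_len(n_lip), each = per_lip)
    if (per_lip == 1L) {
      lip <- tibble(name = head_names, molecule_id = mol, species = species_vec,
                    x = hx, y = yy, z = hz)
    } else {
      nm <- c("HEAD", paste0("C", 1:4, "A"), paste0("C", 1:4, "B"))
      name <- rep(nm, n_lip)
      name[name == "HEAD"] <- head_names
      k_out <- rep(c(0, 1:4 * 0.3, 1:4 * 0.3), n_lip)  # radial extent per bead
      side <- rep(c(0, rep(-0.1, 4), rep(0.1, 4)), n_lip)
      li <- rep(seq_len(n_lip), each = per_lip)
      lipx <- (ctr[ch[li], 1] + (R + k_out) * cos(phi[li])) %% lx
      lipz <- (ctr[ch[li], 2] + (R + k_out) * sin(phi[li])) %% lz
      lipy <- (yy[li] + side) %% ly
      lip <- tibble(name = name, molecule_id = li, species = species_vec[li],
                    x = lipx, y = lipy, z = lipz)
    }
    lip$molecule_id <- lip$molecule_id + max(wat$molecule_id)
    fr <- bead_frame(dplyr::bind_rows(wat, lip), box = spec$box, time = 0)
    attr(fr, "ground_truth") <- list(
      channel_centers = ctr, lattice_const = spec$lattice_const,
      n_channels = spec$n_channels, axis = "y", water_radius = r_w)
    fr
  })
}
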