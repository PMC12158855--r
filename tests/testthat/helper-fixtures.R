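# In-code fixtures shared across test files.

small_comp <- function(n = 300, mgdg = 40, hydration = 0) {
  build_composition(mgdg, n, hydration = hydration)
}

flat_spec <- function(n = 300, mgdg = 40, hydration = 0, seed = 1, ...) {
  generator_spec(composition = small_comp(n, mgdg, hydration = hydration),
                 box = c(12, 12, 10), thickness = 4, seed = seed, ...)
}

one_frame_seq <- function(frame) frame_sequence(list(frame))

# uniform ideal-gas frame of single-bead molecules
ideal_gas_frame <- function(n, box = c(8, 8, 8), seed = 1, species = "W",
                            name = "W") {
  withr::with_seed(seed, {
    bead_frame(tibble::tibble(
      name = name, molecule_id = seq_len(n), species = species,
      x = stats::runif(n, 0, box[1]), y = stats::runif(n, 0, box[2]),
      z = stats::runif(n, 0, box[3])), box = box)
  })
}

# independent all-pairs R oracle for contact counting under minimum image
brute_pairs_r <- function(coords, box, cutoff) {
  n <- nrow(coords)
  out <- matrix(integer(0), ncol = 2)
  if (n < 2) return(out)
  res <- list()
  for (i in seq_len(n - 1)) {
    d <- sweep(coords[(i + 1):n, , drop = FALSE], 2, coords[i, ])
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    j <- which(rowSums(d^2) < cutoff^2)
    if (length(j)) res[[length(res) + 1]] <- cbind(i, i + j)
  }
  if (!length(res)) return(out)
  do.call(rbind, res)
}

# uniform directions on the unit sphere
random_unit_vectors <- function(n, seed = 1) {
  withr::with_seed(seed, {
    z <- stats::runif(n, -1, 1)
    phi <- stats::runif(n, 0, 2 * pi)
    r <- sqrt(pmax(0, 1 - z^2))
    cbind(r * cos(phi), r * sin(phi), z)
  })
}
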