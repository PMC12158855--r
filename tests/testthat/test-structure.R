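test_that("the cell-list pair search equals the all-pairs oracle bit-exactly", {
  fr <- ideal_gas_frame(450, box = c(6, 6, 6), seed = 4)
  co <- as.matrix(fr[, c("x", "y", "z")])
  for (cutoff in c(0.3, 0.5, 0.9)) {
    fast <- memphase:::cpp_pairs_within(co, frame_box(fr), cutoff, brute = FALSE)
    slow <- memphase:::cpp_pairs_within(co, frame_box(fr), cutoff, brute = TRUE)
    r_oracle <- brute_pairs_r(co, frame_box(fr), cutoff)
    key <- function(m) sort(paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2])))
    expect_identical(key(fast), key(slow))
    expect_identical(key(fast), key(r_oracle))
  }
})

test_that("contact matrices from the optimized and brute-force paths agree bit-exactly", {
  fs <- one_frame_seq(make_bilayer(flat_spec(n = 50, seed = 40)))
  fast <- contact_matrix(fs, brute = FALSE)
  slow <- contact_matrix(fs, brute = TRUE)
  expect_identical(unclass(fast), unclass(slow))
})

test_that("RDF of an ideal gas is 1 at all distances beyond the first bins", {
  fs <- one_frame_seq(ideal_gas_frame(3000, box = c(8, 8, 8), seed = 5))
  for (nrm in c("local", "box")) {
    pr <- rdf(fs, sel_A = list(species = "W"), sel_B = list(species = "W"),
              bin_width = 0.1, norm = nrm)
    expect_true(all(abs(pr$g[pr$r > 1] - 1) < 0.05))
  }
})

test_that("RDF histograms match a direct R pair count on a small frame", {
  fr <- ideal_gas_frame(80, box = c(5, 5, 5), seed = 6)
  fs <- one_frame_seq(fr)
  pr <- rdf(fs, sel_A = list(species = "W"), sel_B = list(species = "W"),
            bin_width = 0.25)
  co <- as.matrix(fr[, c("x", "y", "z")])
  pairs <- brute_pairs_r(co, frame_box(fr), attr(pr, "r_max"))
  d <- sqrt(rowSums((memphase::minimum_image(
    co[pairs[, 1], , drop = FALSE] - co[pairs[, 2], , drop = FALSE],
    frame_box(fr)))^2))
  h <- hist(d, breaks = seq(0, attr(pr, "r_max"), by = 0.25), plot = FALSE)$counts
  expect_equal(pr$count, 2 * h)  # both directions of each unordered pair
})

test_that("two particles at distance d populate exactly one bin", {
  fr <- bead_frame(tibble::tibble(name = "W", molecule_id = 1:2, species = "W",
                                  x = c(1, 2.2), y = c(1, 1), z = c(1, 1)),
                   box = c(8, 8, 8))
  pr <- rdf(one_frame_seq(fr), sel_A = list(species = "W"),
            sel_B = list(species = "W"), bin_width = 0.1)
  expect_equal(sum(pr$count > 0), 1L)
  expect_equal(pr$r[pr$count > 0], 1.25)  # bin center containing 1.2
})

test_that("a hard-core exclusion zone gives g = 0 inside it", {
  # reference particles on a wide grid; distributed particles rejected
  # within 0.3 nm of any reference
  ctr <- as.matrix(expand.grid(x = c(2, 6), y = c(2, 6), z = c(2, 6)))
  withr::with_seed(7, {
    b <- matrix(stats::runif(3 * 3000, 0, 8), ncol = 3)
  })
  mind <- apply(b, 1, function(p) {
    d <- sweep(ctr, 2, p)
    for (k in 1:3) d[, k] <- d[, k] - 8 * round(d[, k] / 8)
    sqrt(min(rowSums(d^2)))
  })
  b <- b[mind >= 0.3, , drop = FALSE]
  fr <- bead_frame(tibble::tibble(
    name = c(rep("NA", nrow(ctr)), rep("W", nrow(b))),
    molecule_id = seq_len(nrow(ctr) + nrow(b)),
    species = c(rep("ION", nrow(ctr)), rep("W", nrow(b))),
    x = c(ctr[, 1], b[, 1]), y = c(ctr[, 2], b[, 2]),
    z = c(ctr[, 3], b[, 3])), box = c(8, 8, 8))
  pr <- rdf(one_frame_seq(fr), sel_A = list(species = "ION"),
            sel_B = list(species = "W"), bin_width = 0.05)
  expect_true(all(pr$g[pr$r < 0.28] == 0))
  expect_gt(mean(pr$g[pr$r > 1]), 0.9)
})

test_that("RDF rejects empty selections and oversized bins", {
  fs <- one_frame_seq(ideal_gas_frame(10))
  expect_error(rdf(fs, list(species = "ION"), list(species = "W")), "empty")
  expect_error(rdf(fs, list(species = "W"), list(species = "W"),
                   bin_width = 10), "bin_width")
})

test_that("the contact definition honors the 0.5 nm cutoff", {
  mk <- function(dx) bead_frame(
    tibble::tibble(name = c("C1A", "C1A"), molecule_id = 1:2,
                   species = c("JPPG", "JPPG"),
                   x = c(1, 1 + dx), y = 1, z = 1), box = c(10, 10, 10))
  m_in <- contact_matrix(one_frame_seq(mk(0.4)))
  m_out <- contact_matrix(one_frame_seq(mk(0.6)))
  expect_equal(unname(unclass(m_in)["JPPG", "JPPG"]), 1)
  expect_equal(unname(unclass(m_out)["JPPG", "JPPG"]), 0)
})

test_that("a lone molecule has an all-zero contact matrix", {
  fr <- bead_frame(tibble::tibble(
    name = c("PO4", "C1A", "C2A"), molecule_id = 1L, species = "JPPG",
    x = c(1, 1.1, 1.2), y = 1, z = 1), box = c(10, 10, 10))
  m <- contact_matrix(one_frame_seq(fr))
  expect_true(all(unclass(m) == 0))
})

test_that("duplicating a frame in the window leaves the averaged matrix unchanged", {
  fr <- make_bilayer(flat_spec(n = 80, seed = 42))
  one <- contact_matrix(one_frame_seq(fr))
  two <- contact_matrix(frame_sequence(
    topology = tibble::tibble(name = fr$name, molecule_id = fr$molecule_id,
                              species = fr$species),
    coords = array(rep(as.matrix(fr[, c("x", "y", "z")]), each = 2),
                   dim = c(2, nrow(fr), 3)),
    box = rbind(frame_box(fr), frame_box(fr)), time = c(0, 1)))
  expect_equal(tidy(two)$contacts, tidy(one)$contacts)
})

test_that("molecule-pair mode never exceeds bead-pair counts", {
  fs <- one_frame_seq(make_bilayer(flat_spec(n = 120, seed = 43)))
  mb <- contact_matrix(fs, mode = "bead")
  mm <- contact_matrix(fs, mode = "molecule")
  expect_true(all(unclass(mm) <= unclass(mb) + 1e-12))
})

test_that("normalizing a matrix by itself gives exactly 1, and mismatches error", {
  fs <- one_frame_seq(make_bilayer(flat_spec(n = 100, seed = 44)))
  m <- contact_matrix(fs)
  r <- normalized_contacts(m, m)
  vals <- unclass(r)[unclass(m) > 0]
  expect_true(all(vals == 1))
  m2 <- unclass(m)[1:3, 1:3]
  class(m2) <- c("contact_matrix", "matrix")
  expect_error(normalized_contacts(m, m2), "same species")
})

test_that("planted clustering raises same-species normalized contacts above 1.2", {
  comp <- small_comp(1000)
  ref <- contact_matrix(one_frame_seq(make_bilayer(
    generator_spec(composition = comp, box = c(18, 18, 10), seed = 45))))
  clu <- contact_matrix(one_frame_seq(make_bilayer(
    generator_spec(composition = comp, box = c(18, 18, 10),
                   lateral_layout = "clustered", cluster_strength = 0.8,
                   cluster_sd = 1.0, seed = 46))))
  r <- unclass(normalized_contacts(clu, ref))
  expect_gt(min(diag(r)), 1.2)
})

test_that("hydration RDF finds planted water shells and validates its inputs", {
  withr::with_seed(8, {
    nh <- 60
    hb <- tibble::tibble(name = "PO4", molecule_id = seq_len(nh),
                         species = "JPPG",
                         x = stats::runif(nh, 0, 8), y = stats::runif(nh, 0, 8),
                         z = stats::runif(nh, 0, 8))
    shell <- function(r0, k, off) {
      d <- random_unit_vectors(nh * k, seed = 80 + off)
      m <- hb[rep(seq_len(nh), k), ]
      tibble::tibble(name = "W", molecule_id = seq_len(nh * k) + off,
                     species = "W",
                     x = (m$x + r0 * d[, 1]) %% 8, y = (m$y + r0 * d[, 2]) %% 8,
                     z = (m$z + r0 * d[, 3]) %% 8)
    }
    wat <- dplyr::bind_rows(shell(0.5, 10, 1000), shell(0.9, 10, 2000))
  })
  fr <- bead_frame(dplyr::bind_rows(hb, wat), box = c(8, 8, 8))
  fs <- one_frame_seq(fr)
  pr <- hydration_rdf(fs, headgroup_class = "PG", bin_width = 0.05)
  peaks <- attr(pr, "peaks")
  top2 <- peaks[order(-peaks$g), ][1:2, ]
  expect_equal(sort(top2$r), c(0.5, 0.9), tolerance = 0.051)
  expect_error(hydration_rdf(fs, headgroup_class = "MGAL"), "covers no lipids")
  fs_dry <- one_frame_seq(bead_frame(hb, box = c(8, 8, 8)))
  expect_error(hydration_rdf(fs_dry, headgroup_class = "PG"), "no water")
  expect_error(headgroup_class_species("XX"), "unknown headgroup class")
})

test_that("a frame lacking a headgroup class errors by class coverage", {
  fr <- make_bilayer(flat_spec(n = 100, mgdg = 0, hydration = 4, seed = 47))
  expect_error(hydration_rdf(one_frame_seq(fr), headgroup_class = "MGAL"),
               "covers no lipids")
})
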