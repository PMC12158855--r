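test_that("the P2 estimator reproduces its analytic limits", {
  expect_equal(p2_of_bonds(matrix(c(0, 0, 1), 1)), 1)
  expect_equal(p2_of_bonds(matrix(c(0, 0, -2.5), 1)), 1)   # anti-parallel
  expect_equal(p2_of_bonds(matrix(c(1, 0, 0), 1)), -0.5)
  expect_equal(p2_of_bonds(matrix(c(0, 3, 0), 1)), -0.5)
  v <- random_unit_vectors(1e5, seed = 123)
  expect_lt(abs(p2_of_bonds(v)), 0.01)
})

test_that("P2 stays in [-0.5, 1] and is invariant under rotation about the normal", {
  v <- random_unit_vectors(2000, seed = 3)
  p <- p2_of_bonds(v)
  expect_gte(p, -0.5); expect_lte(p, 1)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_equal(p2_of_bonds(v %*% R), p, tolerance = 1e-12)
})

test_that("generated bilayers recover their target tail order", {
  for (target in c(0.2, 0.5, 0.8)) {
    fr <- make_bilayer(flat_spec(n = 800, seed = 30 + target * 10,
                                 tail_order = target))
    o <- p2_order(one_frame_seq(fr), window = 1)
    expect_lt(abs(attr(o, "p2_mean") - target), 0.05)
  }
})

test_that("|P2| falls monotonically as the generator order decreases", {
  vals <- vapply(c(0.8, 0.5, 0.2, 0.0), function(target) {
    fr <- make_bilayer(flat_spec(n = 600, seed = 77, tail_order = target))
    attr(p2_order(one_frame_seq(fr), window = 1), "abs_p2")
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("P2 of static order is invariant under frame decimation", {
  fs <- make_trajectory(flat_spec(n = 200, seed = 31, tail_order = 0.6,
                                  dynamics = "static"),
                        n_frames = 8, dt = 100)
  o_all <- p2_order(fs, window = 1)
  thin <- frame_sequence(topology = fs$topology,
                         coords = fs$coords[c(2, 4, 6, 8), , , drop = FALSE],
                         box = fs$box[c(2, 4, 6, 8), ],
                         time = fs$time[c(2, 4, 6, 8)])
  o_thin <- p2_order(thin, window = 1)
  expect_equal(o_thin$p2, o_all$p2, tolerance = 1e-12)
})

test_that("head-only systems cannot define tail bonds", {
  fs <- one_frame_seq(make_bilayer(flat_spec(n = 50, representation = "head")))
  expect_error(p2_order(fs), "no tail bonds")
})

test_that("a ballistic walker has the closed-form MSD", {
  n <- 20
  frames <- lapply(seq_len(n), function(i) {
    bead_frame(tibble::tibble(name = "PO4", molecule_id = 1L, species = "JPPG",
                              x = (0.1 * (i - 1)) %% 50, y = 1, z = 1),
               box = c(50, 50, 50), time = (i - 1) * 1.0)
  })
  m <- msd(frame_sequence(frames), dim = 2, remove_com = FALSE)
  expect_equal(m$msd, (0.1 * m$lag)^2, tolerance = 1e-10)
})

test_that("MSD unwraps periodic crossings", {
  # walker stepping +0.4 nm per frame in a 2 nm box crosses many times
  n <- 30
  frames <- lapply(seq_len(n), function(i) {
    bead_frame(tibble::tibble(name = "PO4", molecule_id = 1L, species = "JPPG",
                              x = (0.4 * (i - 1)) %% 2, y = 0.5, z = 0.5),
               box = c(2, 2, 2), time = (i - 1) * 1.0)
  })
  m <- msd(frame_sequence(frames), dim = 2, remove_com = FALSE)
  expect_equal(m$msd, (0.4 * m$lag)^2, tolerance = 1e-10)
})

test_that("exact linear MSD inputs return the defining diffusion laws", {
  t_ps <- 0:100
  for (d in c(2, 3)) {
    D0 <- 0.01  # nm^2/ns
    series <- structure(
      tibble::tibble(lag = t_ps, t = t_ps, msd = 2 * d * D0 * t_ps / 1000),
      class = c("msd_series", class(tibble::tibble())),
      msd_dim = d, n_particles = 1L, selection = "synthetic")
    fit <- suppressWarnings(fit_diffusion(series))  # perfect-fit lm note
    expect_equal(fit$D, D0, tolerance = 1e-10)
    expect_equal(fit$slope / D0, 2 * d, tolerance = 1e-10)
  }
})

test_that("Brownian ensembles recover their diffusion coefficient within 10%", {
  fs2 <- make_trajectory(flat_spec(n = 500, seed = 32, dynamics = "brownian",
                                   D = 0.01, dim = 2, representation = "head"),
                         n_frames = 500, dt = 100)
  D2 <- fit_diffusion(msd(fs2, dim = 2))$D
  expect_lt(abs(D2 - 0.01) / 0.01, 0.10)

  fs3 <- make_trajectory(flat_spec(n = 500, seed = 33, dynamics = "brownian",
                                   D = 0.02, dim = 3, representation = "head"),
                         n_frames = 500, dt = 100)
  D3 <- fit_diffusion(msd(fs3, dim = 3))$D
  expect_lt(abs(D3 - 0.02) / 0.02, 0.10)
})

test_that("the Brownian D estimate is unbiased across seeds", {
  Ds <- vapply(1:20, function(s) {
    fs <- make_trajectory(flat_spec(n = 60, seed = 100 + s,
                                    dynamics = "brownian", D = 0.01,
                                    dim = 2, representation = "head"),
                          n_frames = 120, dt = 100)
    fit_diffusion(msd(fs, dim = 2))$D
  }, numeric(1))
  se <- sd(Ds) / sqrt(length(Ds))
  expect_lt(abs(mean(Ds) - 0.01), 3 * se + 0.0005)
})

test_that("per-species diffusion includes the pooled fit", {
  fs <- make_trajectory(flat_spec(n = 100, seed = 34, dynamics = "brownian",
                                  D = 0.01, representation = "head"),
                        n_frames = 80, dt = 100)
  tbl <- diffusion_by_species(fs)
  expect_true("all" %in% tbl$species)
  expect_true(all(tbl$D >= 0))
})
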