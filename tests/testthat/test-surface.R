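test_that("leaflet assignment splits an even bilayer in half and survives z-wrapping", {
  fr <- make_bilayer(flat_spec(n = 200, seed = 2))
  lf <- assign_leaflets(fr)
  expect_equal(sum(lf$leaflet == "upper"), sum(lf$leaflet == "lower"))
  # translate by half a box in z so the bilayer wraps the periodic boundary
  fr2 <- fr
  fr2$z <- (fr2$z + frame_box(fr)[3] / 2) %% frame_box(fr)[3]
  lf2 <- assign_leaflets(fr2)
  expect_equal(lf2$leaflet, lf$leaflet)
})

test_that("non-lamellar frames raise a 'not a bilayer' error", {
  sp <- generator_spec(composition = small_comp(300),
                       box = c(14, 8, 14), phase = "inverted_hexagonal",
                       lattice_const = 5, n_channels = 4,
                       representation = "head", seed = 5)
  fr <- make_inverted_hexagonal(sp)
  expect_error(assign_leaflets(fr), "not a bilayer")
})

test_that("thickness series recovers a constant generator thickness", {
  fs <- make_trajectory(flat_spec(n = 300, seed = 7, dynamics = "brownian",
                                  D = 0.01, representation = "head"),
                        n_frames = 20, dt = 100)
  ts <- thickness_series(fs, window = 0.5)
  expect_equal(nrow(ts), 10L)
  expect_true(all(abs(ts$thickness - 4.0) < 0.05))
})

test_that("a sinusoidal thickness field leaves the per-frame mean at the base value", {
  sp <- flat_spec(n = 2000, seed = 8, thickness_field = "sinusoidal",
                  thickness_amplitude = 0.75, thickness_wavelength = 6,
                  representation = "head")
  ts <- thickness_series(one_frame_seq(make_bilayer(sp)), window = 1)
  expect_equal(ts$thickness, 4.0, tolerance = 0.02)
})

test_that("thickness maps are flat for constant fields and recover planted modulation", {
  fs_flat <- one_frame_seq(make_bilayer(flat_spec(n = 3000, seed = 9,
                                                  representation = "head")))
  mp <- thickness_map(fs_flat, grid_n = 24, window = 1)
  expect_lt(sd(as.vector(mp$thickness)), 0.1)
  expect_equal(mean(mp$thickness), 4.0, tolerance = 0.02)

  sp <- flat_spec(n = 3000, seed = 10, thickness_field = "sinusoidal",
                  thickness_amplitude = 0.75, thickness_wavelength = 6,
                  representation = "head")
  mp2 <- thickness_map(one_frame_seq(make_bilayer(sp)), grid_n = 24, window = 1)
  prof <- rowMeans(mp2$thickness)
  co <- stats::fft(prof)
  k <- which.max(Mod(co[2:(length(prof) / 2)]))  # dominant nonzero mode
  expect_equal(k, 2L)                            # 2 cycles over the 12 nm box
  wavelength <- 12 / k
  expect_lt(abs(wavelength - 6), 12 / 24 + 1e-9) # within one cell
  amp <- 2 * Mod(co[k + 1]) / length(prof)
  expect_lt(abs(amp - 0.75) / 0.75, 0.15)
})

test_that("thickness maps and series agree for static frames", {
  fs <- one_frame_seq(make_bilayer(flat_spec(n = 2000, seed = 11,
                                             representation = "head")))
  ts <- thickness_series(fs, window = 1)
  mp <- thickness_map(fs, grid_n = 16, window = 1)
  expect_lt(abs(mean(mp$thickness) - mean(ts$thickness)) / mean(ts$thickness),
            0.02)
})

test_that("thickness maps reject degenerate grids and empty windows", {
  fs <- one_frame_seq(make_bilayer(flat_spec(n = 100, seed = 1)))
  expect_error(thickness_map(fs, grid_n = 1), "grid_n")
  expect_error(window_frames(fs, 0), "fraction")
})

test_that("surface metrics are invariant under lateral rigid translation with wrap", {
  sp <- flat_spec(n = 2000, seed = 12, thickness_field = "sinusoidal",
                  thickness_amplitude = 0.5, thickness_wavelength = 6,
                  representation = "head")
  fr <- make_bilayer(sp)
  ts1 <- thickness_series(one_frame_seq(fr), window = 1)
  fr2 <- fr
  fr2$x <- (fr2$x + 3.7) %% frame_box(fr)[1]
  fr2$z <- (fr2$z + 2.2) %% frame_box(fr)[3]
  ts2 <- thickness_series(one_frame_seq(fr2), window = 1)
  expect_equal(ts2$thickness, ts1$thickness, tolerance = 1e-6)
})

test_that("a flat bilayer has (numerically) zero maximum mean curvature", {
  fs <- one_frame_seq(make_bilayer(flat_spec(n = 3000, seed = 13,
                                             representation = "head")))
  cs <- curvature_series(fs, grid_n = 20, smoothing = 1, window = 1)
  expect_lt(cs$max_abs_H, 0.02)
})

test_that("curvature of a sinusoidal midplane matches the closed form within 10%", {
  sp <- flat_spec(n = 6000, seed = 14, midplane_amplitude = 0.5,
                  midplane_wavelength = 6, representation = "head")
  cs <- curvature_series(one_frame_seq(make_bilayer(sp)), grid_n = 40,
                         smoothing = 1, window = 1)
  expected <- 0.5 * (2 * pi / 6)^2 / 2
  expect_lt(abs(cs$max_abs_H - expected) / expected, 0.10)
  expect_gt(cs$max_H, 0)  # bulge toward +z counts positive
})

test_that("stronger smoothing never increases the maximum curvature", {
  sp <- flat_spec(n = 3000, seed = 15, midplane_amplitude = 0.5,
                  midplane_wavelength = 6, representation = "head")
  fs <- one_frame_seq(make_bilayer(sp))
  vals <- vapply(c(0.5, 1, 2, 4), function(s) {
    curvature_series(fs, grid_n = 30, smoothing = s, window = 1)$max_abs_H
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-9))
})

test_that("thickness box-plot summaries are reproducible for a fixed window", {
  fs <- make_trajectory(flat_spec(n = 200, seed = 16, dynamics = "brownian",
                                  representation = "head"),
                        n_frames = 12, dt = 100)
  g1 <- glance(thickness_series(fs, window = 0.5))
  g2 <- glance(thickness_series(fs, window = 0.5))
  expect_identical(g1, g2)
  expect_true(all(c("q1", "median", "q3", "iqr") %in% names(g1)))
})
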