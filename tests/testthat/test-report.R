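test_that("reports carry one section per result and are byte-stable", {
  fs <- make_trajectory(flat_spec(n = 100, seed = 50, dynamics = "brownian",
                                  representation = "head"),
                        n_frames = 10, dt = 100)
  ts <- thickness_series(fs)
  r1 <- build_report(list(`Membrane thickness` = ts))
  expect_true(any(grepl("^## Membrane thickness$", r1)))
  full <- build_report(list(
    thickness = ts,
    diffusion = fit_diffusion(msd(fs, dim = 2)),
    comparison = pairwise_compare(list(a = rnorm(10, 4), b = rnorm(10, 4)))))
  expect_equal(sum(grepl("^## ", full)), 3L)
  expect_identical(build_report(list(`Membrane thickness` = ts)), r1)
  expect_error(build_report(list()), "at least one")
  expect_error(build_report(list(ts)), "named")
})

test_that("autoplot methods return ggplot objects for every result type", {
  fs <- make_trajectory(flat_spec(n = 200, seed = 51, dynamics = "brownian",
                                  representation = "head"),
                        n_frames = 8, dt = 100)
  ts <- thickness_series(fs)
  mp <- thickness_map(fs, grid_n = 8)
  m <- msd(fs, dim = 2)
  fr <- make_bilayer(flat_spec(n = 150, seed = 52))
  cm <- contact_matrix(one_frame_seq(fr))
  o <- p2_order(one_frame_seq(fr), window = 1)
  gas <- one_frame_seq(ideal_gas_frame(500))
  pr <- rdf(gas, list(species = "W"), list(species = "W"), bin_width = 0.2)
  ct <- pairwise_compare(list(a = rnorm(10, 4, .1), b = rnorm(10, 4, .1)))
  for (obj in list(ts, mp, m, cm, o, pr, ct)) {
    expect_s3_class(ggplot2::autoplot(obj), "ggplot")
  }
})

test_that("the pipeline validates configs before work and is deterministic", {
  td <- withr::local_tempdir()
  fsd <- file.path(td, "traj")
  fs <- make_trajectory(flat_spec(n = 120, hydration = 4, seed = 53,
                                  dynamics = "brownian"),
                        n_frames = 6, dt = 100)
  write_gro_sequence(fs, fsd)
  cfg <- list(trajectories = list(list(path = fsd, label = "demo",
                                       mgdg_percent = 40, hydration = 4,
                                       temperature = 300)),
              analyses = c("thickness", "order", "contacts", "phase"),
              parameters = list(window = 1), seed = 7,
              outdir = file.path(td, "out"))
  bad <- cfg; bad$analyses <- c("thickness", "nope")
  expect_error(run_pipeline(bad), "unknown analysis")
  bad2 <- cfg; bad2$trajectories[[1]]$path <- file.path(td, "missing")
  expect_error(run_pipeline(bad2), "does not exist")

  res <- run_pipeline(cfg)
  expect_length(res$errors, 0L)
  expect_true(file.exists(file.path(td, "out", "demo_report.md")))
  expect_true(file.exists(file.path(td, "out", "demo_thickness.csv")))
  rep1 <- readLines(file.path(td, "out", "demo_report.md"))
  cfg2 <- cfg; cfg2$outdir <- file.path(td, "out2")
  run_pipeline(cfg2)
  expect_identical(readLines(file.path(td, "out2", "demo_report.md")), rep1)
})

test_that("pipeline stage failures are recorded and do not stop other stages", {
  td <- withr::local_tempdir()
  fsd <- file.path(td, "traj")
  # dry system: the rdf stage must fail, thickness must still run
  fs <- make_trajectory(flat_spec(n = 80, hydration = 0, seed = 54),
                        n_frames = 3, dt = 100)
  write_gro_sequence(fs, fsd)
  cfg <- list(trajectories = list(list(path = fsd, label = "dry")),
              analyses = c("thickness", "rdf"),
              parameters = list(window = 1), outdir = file.path(td, "out"))
  expect_warning(res <- run_pipeline(cfg), "stage 'rdf' failed")
  expect_length(res$errors, 1L)
  expect_true(file.exists(file.path(td, "out", "dry_thickness.csv")))
  cfg$fail_fast <- TRUE
  expect_error(run_pipeline(cfg), "stage 'rdf' failed")
})

test_that("the fixture set is deterministic and its sidecar truths are recovered", {
  td1 <- withr::local_tempdir()
  td2 <- withr::local_tempdir()
  man1 <- make_fixtures(td1, seed = 1)
  man2 <- make_fixtures(td2, seed = 1)
  expect_identical(unname(unlist(man1)), unname(unlist(man2)))
  expect_setequal(
    setdiff(list.dirs(td1, recursive = FALSE, full.names = FALSE), ""),
    c("flat_bilayer", "modulated_bilayer", "brownian2d", "brownian3d",
      "clustered", "stacked_pair", "hii_perfect", "hii_jittered"))

  truth <- jsonlite::read_json(file.path(td1, "flat_bilayer", "truth.json"))
  fr <- read_gro(file.path(td1, "flat_bilayer", "frame_000001.gro"))
  ts <- thickness_series(one_frame_seq(fr), window = 1)
  expect_equal(ts$thickness, truth$thickness, tolerance = 0.05)

  truth_h <- jsonlite::read_json(file.path(td1, "stacked_pair", "truth.json"))
  fs <- read_gro_sequence(file.path(td1, "stacked_pair"))
  expect_equal(detect_hemifusion_time(fs), truth_h$hemifusion_time)

  hii <- read_gro(file.path(td1, "hii_perfect", "frame_000001.gro"))
  expect_equal(classify_phase(hii)$label, "inverted_hexagonal")
  jit <- read_gro(file.path(td1, "hii_jittered", "frame_000001.gro"))
  expect_equal(classify_phase(jit)$label, "undefined_nonbilayer")
})

test_that("tidy and glance methods return well-formed tibbles", {
  fs <- make_trajectory(flat_spec(n = 100, seed = 55, dynamics = "brownian",
                                  representation = "head"),
                        n_frames = 8, dt = 100)
  expect_s3_class(glance(thickness_series(fs)), "tbl_df")
  d <- fit_diffusion(msd(fs, dim = 2))
  expect_equal(nrow(tidy(d)), 2L)
  expect_equal(glance(d)$dim, 2)
  fr <- make_bilayer(flat_spec(n = 100, seed = 56))
  td <- tidy(contact_matrix(one_frame_seq(fr)))
  expect_true(all(c("species_a", "species_b", "contacts") %in% names(td)))
  mp <- thickness_map(fs, grid_n = 8)
  expect_equal(nrow(tidy(mp)), 64L)
})
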