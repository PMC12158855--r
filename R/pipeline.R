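# Configuration-driven orchestration and the canonical fixture set.

pipeline_analyses <- c("thickness", "map", "curvature", "order", "msd",
                       "rdf", "contacts", "phase", "hemifusion")

#' Run a configured analysis pipeline
#'
#' Executes any subset of analyses over one or more trajectories. The
#' configuration is a list (or path to a YAML file) with fields:
#' `trajectories` (list of entries with `path` — a GRO frame directory —
#' plus condition labels `mgdg_percent`, `hydration`, `temperature`),
#' `analyses` (subset of thickness, map, curvature, order, msd, rdf,
#' contacts, phase, hemifusion),
#' `parameters` (e.g. `grid_n`, `window`, `dim`, `cutoff`, `bin_width`),
#' `outdir`, `seed`, and `fail_fast`. Unknown analysis names fail validation
#' before any work. Tables are written as CSV, a markdown report and a JSON
#' metadata file per trajectory; stage errors are logged and remaining
#' stages continue unless `fail_fast`.
#'
#' @param config List or YAML file path.
#' @return Invisibly, a list with per-trajectory `results` and `errors`;
#'   re-running with the same config and seed reproduces outputs.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  analyses <- config$analyses %||% c("thickness", "order", "msd")
  bad <- setdiff(analyses, pipeline_analyses)
  if (length(bad)) {
    abort(paste0("unknown analysis name(s): ", paste(bad, collapse = ", "),
                 "; known: ", paste(pipeline_analyses, collapse = ", ")))
  }
  trajs <- config$trajectories
  if (!length(trajs)) abort("config lists no trajectories")
  for (tr in trajs) {
    if (is.null(tr$path) || !dir.exists(tr$path)) {
      abort(paste0("trajectory path does not exist: ", tr$path %||% "<missing>"))
    }
  }
  p <- config$parameters %||% list()
  grid_n <- p$grid_n %||% 100
  window <- p$window %||% 0.5
  dim <- p$dim %||% 2
  cutoff <- p$cutoff %||% 0.5
  bin_width <- p$bin_width %||% 0.05
  outdir <- config$outdir %||% "memphase_out"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$seed)) set.seed(config$seed)
  all_out <- list()
  errors <- character(0)
  for (ti in seq_along(trajs)) {
    tr <- trajs[[ti]]
    label <- tr$label %||% sprintf("trajectory_%d", ti)
    fs <- read_gro_sequence(tr$path)
    results <- list()
    for (an in analyses) {
      res <- tryCatch(switch(an,
        thickness = thickness_series(fs, window = window),
        map = thickness_map(fs, grid_n = grid_n, window = window),
        curvature = curvature_series(fs, grid_n = grid_n, window = window),
        order = p2_order(fs, window = window),
        msd = fit_diffusion(msd(fs, dim = dim)),
        rdf = hydration_rdf(fs, headgroup_class = p$headgroup_class %||% "PG",
                            bin_width = bin_width),
        contacts = contact_matrix(fs, cutoff = cutoff, window = window),
        phase = classify_phase(get_frame(fs, length(fs))),
        hemifusion = detect_hemifusion_time(fs, contact_cutoff = cutoff)
      ), error = function(e) e)
      if (inherits(res, "error")) {
        msg <- sprintf("[%s] stage '%s' failed: %s", label, an, conditionMessage(res))
        if (isTRUE(config$fail_fast)) abort(msg)
        errors <- c(errors, msg)
      } else {
        results[[an]] <- res
        csv <- file.path(outdir, sprintf("%s_%s.csv", label, an))
        df <- tryCatch(switch(an,
          map = tidy(res), contacts = tidy(res),
          msd = glance(res), phase = tidy(res),
          hemifusion = tibble(first_time_ps = res, censored = is.na(res)),
          as_tibble(res)), error = function(e) NULL)
        if (!is.null(df)) utils::write.csv(df, csv, row.names = FALSE)
      }
    }
    if (length(results)) {
      meta <- list(label = label, mgdg_percent = tr$mgdg_percent,
                   hydration = tr$hydration, temperature = tr$temperature,
                   analyses = analyses,
                   parameters = list(grid_n = grid_n, window = window,
                                     dim = dim, cutoff = cutoff,
                                     bin_width = bin_width),
                   seed = config$seed,
                   memphase_version = as.character(utils::packageVersion("memphase")))
      build_report(results, path = file.path(outdir, paste0(label, "_report.md")),
                   metadata = meta[!vapply(meta, is.null, logical(1))])
      jsonlite::write_json(meta, file.path(outdir, paste0(label, "_meta.json")),
                           auto_unbox = TRUE, null = "null", digits = NA)
    }
    all_out[[label]] <- results
  }
  if (length(errors)) {
    warn(paste(c("pipeline completed with stage errors:", errors), collapse = "\n"))
  }
  invisible(list(results = all_out, errors = errors, outdir = outdir))
}

#' Generate the canonical synthetic fixture set
#'
#' Writes the fixture set the test suite and demos use — flat and
#' thickness-modulated bilayers, 2D/3D Brownian trajectories, a clustered
#' layout, a stacked pair with a stalk at a known time, and perfect and
#' jittered inverted hexagonal frames — each as a GRO file or frame
#' directory with a sidecar `truth.json` of its ground-truth parameters,
#' plus a checksum manifest. Deterministic in `seed`.
#'
#' @param out_dir Writable output directory.
#' @param seed Integer seed.
#' @return Invisibly, the manifest as a named list of md5 checksums.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  if (dir.exists(out_dir)) {
    if (file.access(out_dir, 2) != 0) abort(paste0("out_dir not writable: ", out_dir))
  } else {
    ok <- tryCatch({dir.create(out_dir, recursive = TRUE)},
                   warning = function(w) FALSE)
    if (!isTRUE(ok)) abort(paste0("cannot create out_dir: ", out_dir))
  }
  seed <- as.integer(seed)
  put <- function(name, truth) {
    d <- file.path(out_dir, name)
    dir.create(d, showWarnings = FALSE)
    jsonlite::write_json(truth, file.path(d, "truth.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
    d
  }
  comp_small <- build_composition(40, 400, hydration = 4)

  d <- put("flat_bilayer", list(thickness = 4.0, tail_order = 0.6))
  sp <- generator_spec(composition = comp_small, box = c(12, 12, 10),
                       thickness = 4.0, tail_order = 0.6, seed = seed)
  write_gro(make_bilayer(sp), file.path(d, "frame_000001.gro"))

  d <- put("modulated_bilayer",
           list(thickness = 4.0, amplitude = 0.75, wavelength = 6.0))
  sp <- generator_spec(composition = build_composition(40, 3000, hydration = 0),
                       box = c(12, 12, 10), thickness = 4.0,
                       thickness_field = "sinusoidal",
                       thickness_amplitude = 0.75, thickness_wavelength = 6,
                       representation = "head", seed = seed + 1L)
  write_gro(make_bilayer(sp), file.path(d, "frame_000001.gro"))

  for (dd in c(2, 3)) {
    d <- put(sprintf("brownian%dd", dd),
             list(D = 0.01, dim = dd, dt_ps = 100, n_frames = 300))
    sp <- generator_spec(composition = build_composition(40, 150, hydration = 0),
                         box = c(12, 12, 10), dynamics = "brownian",
                         D = 0.01, dim = dd, representation = "head",
                         seed = seed + 1L + dd)
    write_gro_sequence(make_trajectory(sp, n_frames = 300, dt = 100), d)
  }

  d <- put("clustered", list(cluster_strength = 0.8, cluster_sd = 1.0))
  sp <- generator_spec(composition = build_composition(40, 800, hydration = 0),
                       box = c(16, 16, 10), lateral_layout = "clustered",
                       cluster_strength = 0.8, cluster_sd = 1.0,
                       seed = seed + 5L)
  write_gro(make_bilayer(sp), file.path(d, "frame_000001.gro"))

  d <- put("stacked_pair", list(hemifusion_time = 1000, n_frames = 24, dt_ps = 100))
  sp <- generator_spec(composition = build_composition(40, 300, hydration = 6),
                       box = c(12, 12, 16), stacking = "pair",
                       hemifusion_time = 1000, seed = seed + 6L)
  write_gro_sequence(make_stacked_pair(sp, n_frames = 24, dt = 100), d)

  for (jit in c(0, 0.3)) {
    nm <- if (jit == 0) "hii_perfect" else "hii_jittered"
    d <- put(nm, list(lattice_const = 4, n_channels = 9, channel_jitter = jit))
    sp <- generator_spec(composition = build_composition(40, 600, hydration = 0),
                         box = c(16, 8, 16), phase = "inverted_hexagonal",
                         lattice_const = 4, n_channels = 9,
                         channel_jitter = jit, representation = "head",
                         seed = seed + 7L)
    write_gro(make_inverted_hexagonal(sp), file.path(d, "frame_000001.gro"))
  }

  files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  man <- as.list(tools::md5sum(files))
  names(man) <- substring(names(man), nchar(out_dir) + 2L)
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(man)
}
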