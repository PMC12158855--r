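# Report assembly: one structured markdown document per run, deterministic
# given the same inputs, suitable for diffing.

report_section <- function(x, name) UseMethod("report_section")

#' @export
report_section.default <- function(x, name) {
  c(paste0("## ", name), "", utils::capture.output(print(x)), "")
}

fmt_tbl <- function(df, digits = 4) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  hdr <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  rows <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
  c(hdr, sep, rows)
}

#' @export
report_section.thickness_series <- function(x, name) {
  g <- glance(x)
  c(paste0("## ", name), "",
    sprintf("Per-frame thickness over %d frames: mean %.3f nm, median %.3f nm, IQR %.3f nm.",
            g$n_frames, g$mean, g$median, g$iqr), "")
}

#' @export
report_section.surface_grid <- function(x, name) {
  g <- glance(x)
  c(paste0("## ", name), "",
    sprintf("%dx%d thickness map: mean %.3f nm, sd %.3f nm, %.1f%% of cells observed.",
            g$grid_n, g$grid_n, g$mean_thickness, g$sd_thickness,
            100 * g$occupied_fraction), "")
}

#' @export
report_section.curvature_series <- function(x, name) {
  c(paste0("## ", name), "",
    sprintf("Maximum mean curvature per frame over %d frames: median %.4f 1/nm, max %.4f 1/nm.",
            nrow(x), median(x$max_abs_H), max(x$max_abs_H)), "")
}

#' @export
report_section.order_result <- function(x, name) {
  c(paste0("## ", name), "",
    sprintf("Aggregate |P2| = %.4f (grand mean P2 = %.4f).",
            attr(x, "abs_p2"), attr(x, "p2_mean")), "",
    fmt_tbl(x), "")
}

#' @export
report_section.diffusion_result <- function(x, name) {
  c(paste0("## ", name), "",
    sprintf("D = %.4g nm^2/ns (%dD fit, slope %.4g nm^2/ns, R^2 %.4f).",
            x$D, x$dim, x$slope, x$r_squared), "")
}

#' @export
report_section.rdf_profile <- function(x, name) {
  peaks <- attr(x, "peaks")
  lines <- c(paste0("## ", name), "",
             sprintf("g(r) to r_max = %.3f nm (%s normalization).",
                     attr(x, "r_max"), attr(x, "norm")))
  if (!is.null(peaks) && nrow(peaks)) {
    lines <- c(lines, sprintf("Detected %d maxima at r = %s nm.", nrow(peaks),
                              paste(sprintf("%.2f", peaks$r), collapse = ", ")))
  }
  c(lines, "")
}

#' @export
report_section.contact_matrix <- function(x, name) {
  df <- tidy(x)
  c(paste0("## ", name), "",
    sprintf("%s contact matrix (cutoff %.2f nm, %s mode).",
            if (isTRUE(attr(x, "normalized"))) "Normalized" else "Raw",
            attr(x, "cutoff"), attr(x, "mode")), "",
    fmt_tbl(df[, c("species_a", "species_b", "contacts")]), "")
}

#' @export
report_section.phase_report <- function(x, name) {
  c(paste0("## ", name), "", fmt_tbl(x), "")
}

#' @export
report_section.comparison_table <- function(x, name) {
  c(paste0("## ", name), "",
    sprintf("%d pairwise comparisons, Bonferroni-adjusted; %d significant at alpha = %g.",
            attr(x, "n_comparisons"), sum(x$significant), attr(x, "alpha")), "",
    fmt_tbl(x), "")
}

#' Assemble a structured analysis report
#'
#' Formats a named list of analysis results (thickness series and maps,
#' order, diffusion, RDF, contacts, phase labels, comparisons) into a single
#' markdown document with one section per result, plus run metadata.
#' Deterministic inputs give a byte-identical report body.
#'
#' @param results Named list of memphase result objects.
#' @param path Optional file to write.
#' @param metadata Optional named list recorded in the header (condition
#'   labels, parameters, seed).
#' @return Character vector of markdown lines, invisibly if `path` given.
#' @export
build_report <- function(results, path = NULL, metadata = list()) {
  if (!length(results)) abort("at least one analysis result is required")
  if (is.null(names(results)) || any(names(results) == "")) {
    abort("results must be a named list")
  }
  lines <- c("# memphase analysis report", "")
  if (length(metadata)) {
    lines <- c(lines, "## Run metadata", "",
               vapply(names(metadata), function(k) {
                 sprintf("- %s: %s", k, paste(format(metadata[[k]]), collapse = " "))
               }, character(1)), "")
  }
  for (nm in names(results)) {
    lines <- c(lines, report_section(results[[nm]], nm))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
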