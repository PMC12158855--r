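#' Read a GRO configuration file
#'
#' Parses the fixed-column GRO format (resid 1-5, resname 6-10, atom name
#' 11-15, atom number 16-20, then x/y/z in 8.3f columns, nm) with a final
#' orthorhombic box line. Molecules are grouped by runs of identical residue
#' numbers; residue names must resolve to registry species.
#'
#' @param path Path to a `.gro` file.
#' @param registry Registry mapping residue names to species; unknown residue
#'   names are an error.
#' @return A [bead_frame()].
#' @export
read_gro <- function(path, registry = default_registry()) {
  lines <- readLines(path)
  if (length(lines) < 3L) abort("GRO file too short: need title, count, and box lines")
  title <- lines[1]
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || n < 0) abort("GRO line 2 must be the bead count")
  if (length(lines) < 3L + n) abort("GRO file truncated: fewer atom lines than declared")
  atom_lines <- if (n > 0) lines[3:(2 + n)] else character(0)
  bad <- which(nchar(atom_lines) < 44L)
  if (length(bad)) {
    abort(sprintf("malformed GRO atom line %d: expected at least 44 columns", bad[1] + 2L))
  }
  num <- function(s, from, to) {
    v <- suppressWarnings(as.numeric(substr(s, from, to)))
    v
  }
  resid <- suppressWarnings(as.integer(substr(atom_lines, 1, 5)))
  resname <- trimws(substr(atom_lines, 6, 10))
  name <- trimws(substr(atom_lines, 11, 15))
  x <- num(atom_lines, 21, 28); y <- num(atom_lines, 29, 36); z <- num(atom_lines, 37, 44)
  if (n > 0 && (anyNA(resid) || anyNA(x) || anyNA(y) || anyNA(z))) {
    bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))[1]
    abort(sprintf("malformed GRO atom line %d: could not parse fixed columns", bad + 2L))
  }
  box_fields <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]]))
  if (length(box_fields) < 3L || anyNA(box_fields[1:3])) abort("malformed GRO box line")
  # residue-number runs define molecules (resid may wrap at 99999)
  if (n > 0) {
    new_mol <- c(TRUE, resid[-1] != resid[-n] | resname[-1] != resname[-n])
    molecule_id <- cumsum(new_mol)
  } else {
    molecule_id <- integer(0)
  }
  t_ps <- 0
  tm <- regmatches(title, regexec("t=\\s*([-0-9.eE+]+)", title))[[1]]
  if (length(tm) == 2L) t_ps <- as.numeric(tm[2])
  bead_frame(tibble(name = name, molecule_id = molecule_id,
                    species = resname, x = x, y = y, z = z),
             box = box_fields[1:3], time = t_ps, registry = registry)
}

#' Write a GRO configuration file
#'
#' Fixed-column GRO output at the format's native 3-decimal (nm) precision.
#'
#' @param frame A [bead_frame()].
#' @param path Output path.
#' @param title Title line; the frame time is appended as `t= <ps>`.
#' @return `path`, invisibly.
#' @export
write_gro <- function(frame, path, title = "memphase configuration") {
  n <- nrow(frame)
  xyz <- coords_matrix(frame)
  if (n > 0 && any(abs(xyz) >= 10000)) {
    abort("coordinate exceeds GRO column width (|x| >= 10000 nm)")
  }
  header <- sprintf("%s, t= %.3f", title, frame_time(frame))
  body <- character(0)
  if (n > 0) {
    resid <- ((frame$molecule_id - 1L) %% 99999L) + 1L
    body <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                    resid, substr(frame$species, 1, 5),
                    substr(frame$name, 1, 5),
                    ((seq_len(n) - 1L) %% 99999L) + 1L,
                    xyz[, 1], xyz[, 2], xyz[, 3])
  }
  box <- frame_box(frame)
  writeLines(c(header, sprintf("%5d", n), body,
               sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3])), path)
  invisible(path)
}

#' Read or write a frame sequence as a directory of GRO files
#'
#' Frames are stored as `frame_000001.gro`, ... in `dir`; times come from the
#' title lines. Reading sorts files lexicographically.
#'
#' @param fs A `frame_sequence` (for writing).
#' @param dir Directory path.
#' @param registry Registry for reading.
#' @return `write_gro_sequence()`: `dir` invisibly; `read_gro_sequence()`: a
#'   `frame_sequence`.
#' @export
write_gro_sequence <- function(fs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(length(fs))) {
    write_gro(get_frame(fs, i), file.path(dir, sprintf("frame_%06d.gro", i)))
  }
  invisible(dir)
}

#' @rdname write_gro_sequence
#' @export
read_gro_sequence <- function(dir, registry = default_registry()) {
  files <- sort(list.files(dir, pattern = "\\.gro$", full.names = TRUE))
  if (!length(files)) abort(paste0("no .gro files found in ", dir))
  frame_sequence(lapply(files, read_gro, registry = registry))
}
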