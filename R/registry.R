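#' Lipid registry for coarse-grained thylakoid species
#'
#' A lipid registry maps each molecular species to its headgroup reference
#' bead, its ordered tail beads (two chains of four beads for the
#' coarse-grained thylakoid lipids), and its net charge. The default registry
#' covers the seven thylakoid lipid species — two phosphatidylglycerols
#' (JFPG, JPPG), two MGDGs (DFMG, FPMG), two DGDGs (DFGG, FPGG) and the SQDG
#' (FPSG) — plus water (`W`) and monovalent ions (`ION`).
#'
#' Headgroup reference beads follow the conventions used for these lipids:
#' the phosphate bead `PO4` for the PGs, the proximal galactosyl carbon `C1`
#' for the MGDGs and the SQDG, and the distal galactosyl carbon `GA2` for the
#' DGDGs. PG and SQDG species carry one negative charge; galactolipids are
#' neutral.
#'
#' @param species Optional character vector restricting the registry to a
#'   subset of species (water and ions are always retained).
#' @return A tibble of class `lipid_registry` with columns `species`,
#'   `head_bead`, `tail_beads` (list of character vectors, chain beads in
#'   order 1..4 for chain A then chain B), `n_chains`, `charge`, and
#'   `is_lipid`.
#' @examples
#' default_registry()
#' @export
default_registry <- function(species = NULL) {
  tails <- list(c("C1A", "C2A", "C3A", "C4A"), c("C1B", "C2B", "C3B", "C4B"))
  reg <- tibble::tibble(
    species   = c("JFPG", "JPPG", "DFMG", "FPMG", "DFGG", "FPGG", "FPSG", "W", "ION"),
    head_bead = c("PO4", "PO4", "C1", "C1", "GA2", "GA2", "C1", NA, NA),
    tail_beads = c(rep(list(tails), 7L), list(NULL), list(NULL)),
    n_chains  = c(rep(2L, 7L), 0L, 0L),
    charge    = c(-1L, -1L, 0L, 0L, 0L, 0L, -1L, 0L, 0L),
    is_lipid  = c(rep(TRUE, 7L), FALSE, FALSE)
  )
  if (!is.null(species)) {
    keep <- reg$species %in% c(species, "W", "ION")
    reg <- reg[keep, , drop = FALSE]
  }
  class(reg) <- c("lipid_registry", class(reg))
  reg
}

#' Classes of lipid headgroups
#'
#' Maps a headgroup class — phosphatidylglycerol (`PG`), monogalactosyl
#' (`MGAL`), digalactosyl (`DGAL`) or sulfoquinovose (`SQ`) — to the species
#' carrying it, for hydration radial distribution functions.
#'
#' @param class One of `"PG"`, `"MGAL"`, `"DGAL"`, `"SQ"`.
#' @return Character vector of species codes.
#' @export
headgroup_class_species <- function(class) {
  cls <- list(
    PG   = c("JFPG", "JPPG"),
    MGAL = c("DFMG", "FPMG"),
    DGAL = c("DFGG", "FPGG"),
    SQ   = "FPSG"
  )
  if (!class %in% names(cls)) {
    abort(paste0("unknown headgroup class '", class,
                 "'; expected one of PG, MGAL, DGAL, SQ"))
  }
  cls[[class]]
}

registry_lookup <- function(registry, species) {
  i <- match(species, registry$species)
  if (anyNA(i)) {
    abort(paste0("species not in registry: ",
                 paste(unique(species[is.na(i)]), collapse = ", ")))
  }
  i
}

#' Anionic lipid species in a registry
#' @param registry A `lipid_registry`.
#' @return Character vector of species with net charge -1.
#' @export
anionic_species <- function(registry = default_registry()) {
  registry$species[registry$is_lipid & registry$charge < 0]
}
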