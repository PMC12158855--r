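#' Reference coarse-grained system compositions
#'
#' The printed compositions of the coarse-grained thylakoid-lipid systems at
#' the six MGDG contents (0, 5, 10, 20, 30, 40 mol%) and two hydration
#' levels (8 and 12 water beads per lipid). These are fixtures: the counts
#' are reproduced verbatim, including their water counts.
#'
#' @param hydration 8 or 12 (water beads per lipid).
#' @return Tibble with columns `species`, then one column per MGDG content
#'   (`mgdg_0` ... `mgdg_40`), rows for the seven lipid species plus
#'   `Water` and `Sodium`.
#' @export
reference_compositions <- function(hydration = 8) {
  if (hydration == 8) {
    counts <- rbind(
      JFPG  = c(226, 214, 202, 182, 156, 134),
      JPPG  = c(112, 106, 100,  90,  78,  66),
      DFMG  = c(  0,  58, 118, 220, 354, 472),
      FPMG  = c(  0,   8,  16,  34,  50,  66),
      DFGG  = c(562, 534, 506, 456, 394, 338),
      FPGG  = c(112, 106, 100,  90,  78,  66),
      FPSG  = c(338, 320, 304, 274, 236, 202),
      Water = c(9959, 10087, 10170, 10327, 10312, 10276),
      Sodium = c(676, 640, 606, 546, 470, 402)
    )
  } else if (hydration == 12) {
    counts <- rbind(
      JFPG  = c(226, 214, 202, 180, 156, 134),
      JPPG  = c(112, 106, 100,  90,  78,  66),
      DFMG  = c(  0,  58, 118, 236, 354, 472),
      FPMG  = c(  0,   8,  16,  32,  50,  66),
      DFGG  = c(562, 534, 506, 450, 394, 338),
      FPGG  = c(112, 106, 100,  90,  78,  66),
      FPSG  = c(338, 320, 304, 270, 236, 202),
      Water = c(16117, 14791, 15456, 15785, 15737, 15650),
      Sodium = c(676, 640, 606, 540, 470, 402)
    )
  } else {
    abort("hydration must be 8 or 12 for the reference compositions")
  }
  out <- as_tibble(counts, .name_repair = "minimal")
  names(out) <- paste0("mgdg_", c(0, 5, 10, 20, 30, 40))
  dplyr::bind_cols(tibble(species = rownames(counts)), out)
}

# Largest-remainder apportionment of `total` into integer counts with
# the given (non-negative) weights. Guarantees sum == total.
apportion <- function(total, weights) {
  if (total == 0 || sum(weights) == 0) return(rep(0L, length(weights)))
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  rem <- quota - base
  short <- total - sum(base)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Build a thylakoid-lipid system composition
#'
#' Constructs integer molecule counts for a target MGDG mole percent at a
#' given total lipid count and hydration level. Non-MGDG species keep the
#' fixed mutual ratios of the MGDG-free reference system
#' (JFPG:JPPG:DFGG:FPGG:FPSG = 226:112:562:112:338); the MGDG pool is split
#' between the di-18:3 (DFMG) and 18:3/16:0 (FPMG) forms in the 472:66 ratio
#' of the thylakoid reference. Integer rounding uses largest-remainder
#' apportionment within the MGDG and non-MGDG pools, so totals are exact and
#' the achieved MGDG fraction stays within 0.5 percentage points of the
#' target. Sodium is recomputed from the rounded counts of the anionic
#' species (PGs and SQDG), so the composition is exactly charge-neutral.
#'
#' @param mgdg_percent Target MGDG mole percent in `[0, 100)`.
#' @param total_lipids Total lipid count (> 0).
#' @param hydration Water beads per lipid (CG) or water molecules per lipid
#'   (AA, after the 4:1 mapping).
#' @param resolution `"CG"` (bead counts) or `"AA"` (the water count is
#'   converted with [cg_to_aa_water()]).
#' @return A `system_composition` tibble: columns `species`, `count`, with
#'   attributes `mgdg_percent` (achieved), `hydration`, `resolution`.
#' @examples
#' build_composition(40, 1344, hydration = 8)
#' @export
build_composition <- function(mgdg_percent, total_lipids, hydration = 8,
                              resolution = c("CG", "AA")) {
  resolution <- match.arg(resolution)
  if (mgdg_percent < 0 || mgdg_percent >= 100) abort("mgdg_percent must be in [0, 100)")
  if (total_lipids <= 0) abort("total_lipids must be > 0")
  n_mgdg <- round(total_lipids * mgdg_percent / 100)
  achieved <- 100 * n_mgdg / total_lipids
  if (abs(achieved - mgdg_percent) > 0.5) {
    step <- 100 / total_lipids
    abort(sprintf(paste0("total_lipids = %d cannot realize %.2f%% MGDG within 0.5 ",
                         "percentage points; achievable grid spacing is %.2f%%"),
                  total_lipids, mgdg_percent, step))
  }
  mgdg_counts <- apportion(n_mgdg, c(DFMG = 472, FPMG = 66))
  rest_counts <- apportion(total_lipids - n_mgdg,
                           c(JFPG = 226, JPPG = 112, DFGG = 562,
                             FPGG = 112, FPSG = 338))
  counts <- c(JFPG = rest_counts[1], JPPG = rest_counts[2],
              DFMG = mgdg_counts[1], FPMG = mgdg_counts[2],
              DFGG = rest_counts[3], FPGG = rest_counts[4],
              FPSG = rest_counts[5])
  water <- hydration * total_lipids
  if (resolution == "AA") water <- cg_to_aa_water(water)
  comp <- tibble(
    species = c(names(counts), "Water", "Sodium", "Chloride"),
    count = c(unname(counts), water, NA_integer_, 0L)
  )
  comp$count[comp$species == "Sodium"] <- counterion_count(comp)
  structure(comp,
            class = c("system_composition", class(comp)),
            mgdg_percent = achieved, hydration = hydration,
            resolution = resolution)
}

#' Sodium counterions needed to neutralize a composition
#'
#' The PG species (JFPG, JPPG) and the SQDG (FPSG) each carry one negative
#' charge; one sodium ion per anionic lipid neutralizes the system.
#'
#' @param composition A `system_composition` or any tibble with `species` and
#'   `count` columns.
#' @param registry Registry defining per-species charges.
#' @return Integer sodium count.
#' @examples
#' comp <- build_composition(40, 1344)
#' counterion_count(comp)
#' @export
counterion_count <- function(composition, registry = default_registry()) {
  an <- anionic_species(registry)
  idx <- composition$species %in% an
  as.integer(sum(composition$count[idx]))
}

#' Convert coarse-grained water beads to all-atom water molecules
#'
#' One Martini water bead maps to four all-atom water molecules (so 8 and 12
#' beads per lipid correspond to 32 and 48 molecules per lipid).
#'
#' @param beads Non-negative water bead count.
#' @return `4 * beads`.
#' @export
cg_to_aa_water <- function(beads) {
  if (any(beads < 0)) abort("water bead count must be >= 0")
  4 * beads
}

#' Achieved MGDG mole percent of a composition
#' @param composition A `system_composition` (or species/count tibble).
#' @return MGDG mole percent among lipids.
#' @export
mgdg_percent <- function(composition) {
  lip <- composition$species %in% default_registry()$species[default_registry()$is_lipid]
  mg <- composition$species %in% c("DFMG", "FPMG")
  100 * sum(composition$count[mg]) / sum(composition$count[lip])
}

composition_lipid_counts <- function(composition) {
  reg <- default_registry()
  lip <- composition$species %in% reg$species[reg$is_lipid]
  setNames(composition$count[lip], composition$species[lip])
}
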