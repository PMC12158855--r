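---
title: "Analyzing thylakoid lipid membranes and their non-bilayer phases with memphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing thylakoid lipid membranes and their non-bilayer phases with memphase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Plant thylakoid membranes are dominated by monogalactosyl diacylglycerol
(MGDG), a conically shaped lipid that on its own prefers the inverted
hexagonal (HII) phase — water channels on a triangular lattice wrapped by
headgroups with tails filling the interstices — rather than a flat bilayer.
Characterizing when mixtures of the seven thylakoid lipid species (two
phosphatidylglycerols, two MGDG forms, two DGDG forms, and one SQDG)
abandon the lamellar state requires a set of trajectory observables:
membrane thickness and its lateral map, midplane curvature, tail order,
lateral diffusion, headgroup hydration structure, species-level contact
statistics, and detectors for hemifusion and the HII phase.

memphase implements this analysis chain for coarse-grained (Martini-style)
bead configurations, and pairs every estimator with a synthetic-membrane
generator whose ground truth that estimator must recover. The generators
stand in for molecular-dynamics output: a closure test (generate with known
parameters, analyze, compare) validates the estimator without requiring
microsecond simulations.

## Data model

A configuration (`bead_frame`) is a tibble of beads — name, molecule,
species, x/y/z in nm — with an orthorhombic box (nm) and a time (ps).
Trajectories (`frame_sequence`) store one topology plus a
`(frames x beads x 3)` coordinate array. All distances use the minimum-image
convention in orthorhombic boxes; GRO files are read and written at the
format's native 3-decimal precision. The lipid registry records per species
the headgroup reference bead (the phosphate bead `PO4` for the PGs, the
proximal galactosyl carbon `C1` for the MGDGs and SQDG, the distal `GA2` for
the DGDGs), the tail beads of the two four-bead chains, and the net charge
(PGs and SQDG carry −1).

## Compositions

`build_composition()` constructs integer molecule counts for a target MGDG
mole percent. The non-MGDG species keep the mutual ratios of the MGDG-free
reference mixture (JFPG : JPPG : DFGG : FPGG : FPSG = 226 : 112 : 562 :
112 : 338) and the MGDG pool is split 472 : 66 between its di-18:3 and
18:3/16:0 forms. Rounding uses largest-remainder apportionment inside the
MGDG and non-MGDG pools, which keeps the total exact and the achieved MGDG
fraction within 0.5 percentage points of the target; sodium is then
recomputed from the rounded counts of the anionic species, so neutrality is
exact by construction rather than by rounding luck. Water is `hydration`
beads per lipid (one CG bead ≙ 4 all-atom waters, so 8 and 12 beads/lipid
correspond to 32 and 48 molecules/lipid). `reference_compositions()` ships
the six printed reference columns per hydration level as fixtures; their
sodium rows (676, 640, 606, 546, 470, 402 at 8 beads/lipid) double as an
exact cross-check of the counterion rule. Note that the reference columns
were not generated by this constructor: the nominal "20%" column, for
instance, actually contains 18.9% MGDG, so the constructor reproduces the
construction *rule*, not each printed integer.

## The synthetic generator

`generator_spec()` collects every knob; defaults emulate the thylakoid
system (40% MGDG, ~1,344 lipids, 20 nm lateral box, 8 waters/lipid).
Design choices that matter:

- **Tail order.** Bonds are drawn from a two-component mixture — perfectly
  aligned (P2 = 1) or isotropic (P2 = 0), with the weight equal to the
  target P2 (for negative targets, perpendicular bonds with weight
  −2·target) — so the expected P2 equals the target exactly, in closed
  form, without any dynamics.
- **Dynamics.** Brownian steps of variance 2·D·dt per allowed dimension are
  applied rigidly to whole lipids, so diffusion and order ground truths are
  independent.
- **Water.** Beads sit on a jittered grid at liquid CG water spacing
  (~0.47 nm, one bead per 0.115 nm³), in two slabs hugging the leaflet
  surfaces. This reproduces connectivity and large-r RDF normalization, but
  it is *not* a liquid structure: hydration-shell peak positions of real
  water are outside what the generator emulates (planted shells are used to
  test peak detection instead).
- **Stacked pairs.** One bilayer is built in half the box and replicated in
  z. A hemifusion event at time T relocates the distal tail beads of lipids
  near the box center into a trans-gap cylinder (radius 1.2 nm) and pushes
  the water out of it, so tail beads of the two bilayers form a persistent
  bridging contact from T onward.
- **HII frames.** Water cylinders along y with centers on a triangular
  lattice (optionally jittered by a fraction of the lattice constant),
  headgroups on the cylinder surfaces, tails radially outward.

Because the generator is geometric rather than physical, passing closure
tests demonstrates that the estimators are correct, not that real membranes
behave this way; energies, equilibration, and realistic bead packing are
out of scope.

## Estimators and numerical choices

**Thickness.** Leaflets are assigned from headgroup heights after circular
(periodic) centering; the midplane is the median headgroup height, and the
upper/lower split uses the midpoint of the two k-means band centers, which
is robust to slightly unbalanced leaflets. A frame whose headgroup heights
are not clearly bimodal (band separation < 5 within-band standard
deviations) raises a "not a bilayer" error — the guard that keeps surface
metrics off HII frames. Per-frame thickness is the difference of leaflet
mean heights over the trailing window (default the last half of frames,
expressed as a fraction so scaled-down tests behave identically). Maps bin
headgroups on a grid (default 100 × 100) and average over the window;
never-occupied cells are filled by iterative neighbour dilation and flagged
in an occupancy mask. Rendered maps span 2.5 nm above the map minimum.

**Curvature.** The midplane surface (mean of the two leaflet surfaces) is
Gaussian-smoothed periodically (default σ = 1 cell) and
H = −½∇·(∇z/√(1+|∇z|²)) is evaluated with periodic central differences; a
bulge toward +z has H > 0, and the per-frame maximum of |H| is reported.
Smoothing and finite differences attenuate a mode of wavelength λ by
roughly exp(−(kσ)²/2)·sinc²(kh/2) (k = 2π/λ, h the cell size); the closure
test against the small-slope closed form a·k²/2 for a sinusoidal midplane
therefore uses a grid fine enough (h ≈ λ/20) that the combined attenuation
stays inside the 10% check.

**Tail order.** P2 = ⟨3cos²θ − 1⟩/2 of consecutive-bond vectors against the
bilayer normal (the box z axis by default; a user normal overrides). Bond
index 1 is the headgroup-to-first-tail-bead bond and index i ends at tail
bead i, so indices run 1..4 for the four-bead chains; `include_head_bond =
FALSE` switches to tail-internal bonds only. Results are per species and
bond index with the aggregate |P2| as the absolute grand mean.

**Diffusion.** Headgroup positions are unwrapped by nearest-image steps,
the per-frame center of mass of the selection is removed (the whole-phase
drift is not signal), and the MSD uses all sliding time origins via the
FFT autocorrelation algorithm. The fit is least squares over lags between
10% and 50% of the trajectory, and D = slope/(2·dim): MSD = 4Dt in two
dimensions (bilayers), 6Dt in three (HII). A negative slope clamps D to 0
with a warning. Per-species and pooled fits are both available since either
may be wanted when comparing mobilities.

**RDF.** Pair distances are histogrammed to r_max = half the shortest box
edge and normalized by shell volume and density. The "local" normalization
divides by the density of B within r_max of the A particles (count in the
r_max sphere averaged over A); a "box" switch uses the global density
instead — both give g → 1 for homogeneous systems, and the choice is
exposed because the normalization wording is genuinely ambiguous in common
usage. Hydration RDFs take the headgroup class (PG, MGAL, DGAL, SQ) as the
reference selection and report detected maxima (g ≥ 1.2 local maxima) so
the "several sharp hydration layers vs one peak and a broad bump" contrast
is quantitative.

**Contacts.** Two beads of distinct molecules are in contact below 0.5 nm
(minimum image). Counts aggregate to species × species, averaged over the
window; `mode = "molecule"` collapses to molecule-pair presence since
bead-pair vs molecule-pair counting is a genuine convention choice. The
neighbour search uses cell lists above 200 beads with a brute-force
all-pairs path below (and on demand) that the tests hold bit-equal.
`normalized_contacts()` divides a final matrix by an initial-configuration
matrix; ratios above 1 read as clustering, below 1 as separation, and
zero-initial cells are flagged undefined rather than silently dropped.

**Hemifusion.** The two bilayers are the two largest connected components
of tail beads in the first frame (linkage cutoff 1.0 nm; an error is raised
unless two components each hold ≥ 10% of tail beads). The onset time is the
first frame whose inter-component tail–tail contact (0.5 nm) persists for
≥ 5 consecutive frames; both cutoff and persistence are configurable and
reported. Runs without an event are censored ("none"), never reported as
the trajectory length.

**Phase labels.** Water beads are clustered at 0.6 nm (≈ the first-neighbor
distance of liquid CG water). A frame is HII when ≥ 3 water components each
span the box along one common axis with small, comparable perpendicular
extents, and the bond-orientational order ψ6 = |⟨e^{6iφ}⟩| of the channel
centers (neighbors within 1.35× the median nearest-neighbor distance,
periodic) reaches 0.7. A perfect lattice gives ψ6 = 1 and random centers
≈ 0.2–0.4, so 0.7 separates them cleanly; it is a package default, not a
literature value. Lamellar requires a water slab spanning both lateral
axes plus a bimodal headgroup height distribution; everything else is an
undefined non-bilayer. With few channels ψ6 is a high-variance statistic,
so jitter-sensitivity checks use 9 channels.

**Statistics.** `pairwise_compare()` runs two-sample Student t-tests
(pooled variance by default, Welch optional) on every condition pair with
Bonferroni adjustment and 95% confidence intervals. Per-frame values from
one trajectory are autocorrelated; the default replicates the plain
frame-wise test deliberately, and an optional thinning stride (`block`) is
provided, off by default and recorded in the output. Degenerate pairs (two
zero-variance groups with equal means) report p = 1 and are flagged.

## Problem sizes used in the checks

The bundled checks run at desk scale by design: closure fixtures use
300–6,000 lipids in 12–20 nm boxes and tens of frames; diffusion-law
recovery uses 500–1,000 walkers for 500–2,000 frames; the contact-statistic
null uses a 4×-scaled thylakoid mixture (5,376 lipids, 40 nm box) over 20
seed pairs — the rarest species pair needs on the order of a hundred
contacts per layout before the ratio statistic concentrates tightly enough
around 1, which sets that size. The full test suite completes in well under
a minute.

## A worked closure example

```{r, eval = FALSE}
library(memphase)

spec <- generator_spec(
  composition = build_composition(40, 1344, hydration = 8),
  box = c(20, 20, 12), thickness = 4.0, tail_order = 0.5,
  dynamics = "brownian", D = 0.01, seed = 1)
traj <- make_trajectory(spec, n_frames = 200, dt = 100)

glance(thickness_series(traj))          # mean ~ 4.0 nm
glance(p2_order(traj))                  # |P2| ~ 0.5
fit_diffusion(msd(traj, dim = 2))       # D ~ 0.01 nm^2/ns
autoplot(thickness_map(traj, grid_n = 50))
```

## Known limitations

- Orthorhombic boxes only; triclinic cells are not supported.
- The generator's water is a jittered grid: RDF shapes below ~0.5 nm and
  true hydration-shell positions are not emulated.
- Phase classification assumes channel axes aligned with a box axis (the
  generator's convention); arbitrarily tilted channels would need a
  PCA-based axis estimate.
- The frame-wise t-test inherits the autocorrelation of trajectory data;
  the thinning option is a palliative, not an effective-sample-size model.
- All-atom systems are supported through the same types with a custom
  registry (atoms as beads), but the coarse-grained path is the tested
  surface; the all-atom headgroup reference atom (which galactose ring
  oxygen) is left configurable rather than fixed.
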