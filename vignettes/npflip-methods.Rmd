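---
title: "Methods: ligand-flipping energetics of amphiphilic nanoparticles in bilayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ligand-flipping energetics of amphiphilic nanoparticles in bilayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npflip)
```

## The system and the question

Amphiphilic monolayer-protected gold nanoparticles — a 2 nm core grafted
with a 1:1 mixture of anionic 11-mercaptoundecanesulfonate (MUS) and
hydrophobic octanethiol (OT) ligands — can embed into phospholipid bilayers
without forming pores. Starting from a particle lodged in the upper leaflet
with all 29 charged sulfonate end groups on the solution side (the
`29+/0-` distribution), the particle reaches a membrane-spanning
configuration through a sequence of single-ligand *flips*: one charged end
group at a time translocates across the bilayer, analogous to lipid
flip-flop. `npflip` implements the computational side of that picture as a
reusable pipeline:

1. **geometry builders** for the particle monolayer and a simplified bead
   bilayer, with the composition rules (grafting density, charge
   neutrality, salt counts) enforced;
2. a **synthetic configuration generator** that emulates the statistical
   structure of equilibrated particle–bilayer systems at any ligand
   distribution, so every analysis can be exercised end-to-end without a
   molecular-dynamics engine;
3. the **flip state machine**: per-ligand `d_z`, distribution
   classification, next-flip selection, harmonic bias schedules, and the
   14-step iteration from `29+/0-` to `15+/14-`;
4. **surface-area machinery**: Shrake–Rupley quadrature restricted to the
   nonpolar ligand backbones, and hydrophobic free-energy scoring
   `dG_phob = gamma * dSASA`;
5. **pair-structure statistics**: radial distribution functions with
   first-minimum threshold extraction, sulfonate–choline contacts,
   end-group coordination numbers, cylindrical density maps, linear
   core-depth trends, and block-averaging error estimates;
6. the **six-state insertion landscape** assembled from its component
   estimates.

## The flip workflow

For a MUS ligand, `d_z` is the z-distance between the mass-weighted centre
of its sulfonate end group (one S, three O) and the bilayer midplane. The
midplane is taken as the midpoint between the mean phosphate heights of the
two leaflets; this estimator is deliberately simple and documented so a
user can substitute, e.g., a tail-bead-based one. The distribution label
`N+/M-` counts MUS ligands with positive/negative mean `d_z`; an exactly
zero mean is treated as an ambiguous classification and raised as an error
rather than silently assigned to a side.

Each iteration selects the ligand with the *smallest positive* mean `d_z`
(closest to the flipping transition state) and emits a bias schedule for
it: a harmonic restraint of 3000 kJ/mol/nm² on the sulfonate group moved to
the mirror height `-d_z` over 1.5 ns, followed by 20 ns of unbiased
equilibration. The spring constant is stored in kJ/mol/nm², the unit pull
codes print; `kj_to_kcal()` converts where kcal are needed (1 kcal =
4.184 kJ). Ties in `d_z` are broken by the smallest ligand id — the
selection rule does not specify a tie-break, so we chose a deterministic
one and log it. Fourteen iterations transform `29+/0-` into `15+/14-`,
decrementing `n_plus` by exactly one per step.

## The synthetic generator

The generator stands in for equilibrated trajectories. It encodes the
features the analyses rely on and nothing more:

* **Depth law.** The core centre sits at
  `depth_max * (14 - n_minus) / 14` above the midplane, i.e. the core
  descends linearly to the midplane as ligands flip. Linearity is imposed
  by design, motivated by the observed near-linear descent; `depth_max`
  defaults to 1.0 nm as an order-of-magnitude choice, since no tabulated
  value is available.
* **End-group placement.** The `n_plus` sulfonates sit above the midplane
  with target heights evenly spread between `0.35 * head_z` and the
  head-group plane `head_z` (default 1.9 nm); the `n_minus` are mirrored
  below. Within each side, end groups ordered by height are laid out at
  golden-angle azimuths with the axis distance cycling through 1.6, 2.2
  and 2.8 nm. That layout keeps every pair of sulfonate sulfurs at least
  ~1.3 nm apart, so a hydration shell built within 0.56 nm of one sulfur
  can never be counted (cutoff 0.7 nm) around another — which is what lets
  the coordination analysis recover the generator's hydration law cleanly.
* **Hydration law.** Each end group carries
  `round(hydration_floor + hydration_slope * |d_z|)` water oxygens placed
  on a sphere of radius `0.8 * coord_threshold` around its sulfur: end
  groups farther from the midplane are more hydrated. Only the counts
  matter to the analyses; the shell geometry is arbitrary. Defaults
  (floor 2, slope 3 per nm) give coordination numbers in the 3–8 range.
* **Composition.** 334 four-bead lipids (choline N, phosphate P, two tail
  beads) on a lattice at 0.65 nm² per lipid, lipids overlapping the
  particle removed; a nominal 21,418 waters enter the salt arithmetic,
  giving 89 Na⁺ and 60 Cl⁻ for the −29 e particle with the chloride count
  pinned at 60 (see below).
* **Noise.** Gaussian jitter (default sd 0.05 nm, clipped at 3 sigma) is
  applied to every placed atom after deterministic placement; each frame
  draws from a stream derived from `(seed, frame_index)`, so trajectories
  are bit-reproducible and zero-noise trajectories are constant.

What the generator does **not** emulate: lipid conformational sampling,
bilayer curvature and undulations, bulk water structure, realistic ligand
conformations, or any dynamics. Consequently, tests passing on generated
data validate the *analysis machinery* (counting, binning, averaging,
geometry) and the workflow logic — they do not validate force fields or
sampling, and quantities such as absolute SASA values or contact counts on
synthetic frames are not predictions for the real system.

## Surface areas and hydrophobic scoring

The solvent-accessible surface area uses Shrake–Rupley sphere quadrature:
for each atom, points on its probe-expanded sphere (`r + 0.14 nm` by
default) are tested for burial inside any neighbour's expanded sphere. We
implement the quadrature method rather than an exact analytic surface: the
observable is the same, and the quadrature error is controlled and
testable (an isolated sphere and the analytic two-sphere overlap agree to
<1% at the default 960 points; quadrature at 4x the points shifts the
monolayer total by <0.5%). Quadrature points come from a deterministic
golden-section spiral — no random numbers enter the SASA path. Totals are
exactly translation invariant; rotation invariance holds to the quadrature
resolution (about 0.3% at 960 points, 0.04% at 3840), so the invariance
test runs at the denser setting.

Candidate occluders are pruned with the exact cutoff
`r_i + r_j + 2 * probe` from a vectorised all-pairs distance matrix, which
is guaranteed identical to an unpruned scan; at this package's frame sizes
(a few thousand atoms) this is simpler and fast enough that a cell-list
structure is unnecessary. Water and ions never occlude (solvent defines
the probe); all other frame atoms do, including atoms outside the
requested subset. The rigid hollow core is represented as a single
pseudo-atom whose van der Waals radius equals the core radius.

The hydrophobic observable is the SASA of the ligand backbone carbons only
(29x11 + 29x8 = 551 atoms), excluding sulfonate, thiol sulfurs and gold.
Changes are taken relative to the `29+/0-` configuration and scored as
`dG_phob = gamma * dSASA` with `gamma = 4.7` kcal/mol/nm² (water-to-alkane
transfer). The scoring is exactly linear, so per-flip drives sum exactly
to the total.

## Pair structure and errors

Radial distribution functions are minimum-image pair histograms normalised
by the ideal-gas expectation at the partner species' number density; the
contact and coordination cutoffs are first minima of such profiles,
located after a centred moving-average smoothing (default window 3 bins; a
monotone profile has no minimum and errors). Sulfonate–choline contacts
count S–N pairs under 0.7 nm. Coordination numbers count polar-group
central atoms (water O, choline N, phosphate P, other ligands' sulfonate
S, Na⁺) within per-role thresholds of an end-group sulfur. The
species-resolved threshold values are not tabulated in the available text,
so all roles default to the sulfonate–choline value of 0.7 nm and every
threshold is a configuration key — users with better-resolved pair
structure should override them.

Periodicity convention: raw pair distances (RDF, contacts, coordination)
are minimum-image in all three directions; quantities referenced to the
bilayer normal (`d_z`, density maps) treat z as non-periodic, matching the
physical setup of a bilayer normal to z.

Cylindrical density maps bin counts by distance from the vertical axis
through the core and height above the midplane, normalised by
`2 * pi * r_mid * dr * dz` and the frame count; only `r >= 0` is computed
(mirrored negative-r presentations are cosmetic).

Statistical errors of time averages use the blocking transform: the series
is pairwise coarse-grained and the naive standard error tracked across
levels; the estimate is read at the first plateau (change <5% over two
successive levels) and falls back to the largest-level estimate — a
conservative choice — when no plateau is reached. For white noise this
reproduces `sigma/sqrt(N)`; for correlated series it exceeds the naive
estimate, as it must.

## The six-state landscape

The landscape is reported as a table of labelled states and transitions,
not a drawn curve (the pathway sketch it represents is schematic). States:
(1) particle adsorbed at the surface, the zero of energy; (2) lipid-tail
protrusion contact, a barrier peak at +6.0 kcal/mol; (3) particle inserted
in the upper leaflet, `29+/0-`; (4) the single-flip transition state,
+11.2 kcal/mol above state 3; (5) the first flipped local minimum; (6) the
membrane-spanning configuration. Minima-to-minima components accumulate
from state 1: single-leaflet insertion (−102.6 ± 2.8 kcal/mol) and the
iterative-flipping total (−52.1 ± 2.9 kcal/mol), giving −154.7 kcal/mol
between states 1 and 6; barriers attach to transitions, never to the
cumulative sum.

Prior-work constants (protrusion +6.0, flip barrier 11.2 ± 0.2, the
two-state −232.1 ± 5.6 for a 130-ligand particle and its per-leaflet
−115.05 ± 2.8) are configuration inputs tagged `PRIOR_WORK_CONSTANT` and
never recomputed — they are cited estimates, not derivable here. The
single-leaflet component is obtained by linear ligand-count scaling of the
per-leaflet reference (65 → 58 ligands). Note an inconsistency in the
inputs: half of −232.1 is −116.05, not the −115.05 the per-leaflet value
states; the assembler honours the stated per-leaflet value (which is the
one the scaling arithmetic reproduces: −115.05 × 58/65 = −102.66 ≈ −102.6)
and flags the discrepancy in the report notes. The purely hydrophobic
reference for a 4 nm sphere uses the *bare* sphere area
(−gamma * pi * d² ≈ −236 kcal/mol), since that is the convention the
printed value matches; using the probe-inflated area would be a user
override.

Component uncertainties propagate in quadrature across sums. That is a
simplification — the components are partly estimates with unstated
correlations — and is documented as such.

## Numerical choices and degenerate inputs

* Graft points: deterministic Fibonacci lattice (nearest-neighbour spacing
  varies by ~12% across 58 points); MUS/OT identities by seeded shuffle.
  The grafting pattern is otherwise unconstrained.
* Ion counts: chloride from the mole-fraction formula
  `round(conc * n_water / 55.5 M)`; for the study composition this yields
  58, while the stated count is 60 — whether a box-volume formula was used
  is unknown, so the builder accepts an explicit chloride override
  (default 60) and always restores electroneutrality through the sodium
  count. Positive particle charges are rejected explicitly rather than
  silently swapping the ion roles.
* Classification uses the strict sign of the mean `d_z`; zero raises.
* A frame whose phosphates do not form two separated planes (gap
  >= 1 nm) has no defined midplane and errors.
* `select_next` with no positive ligand raises a typed terminal-state
  condition that the sequence runner propagates.
* Degenerate bins (`dr` or `dz` = 0), empty role selections, `r_max`
  beyond half the box, and series shorter than 4 points are rejected with
  explicit errors.

## Problem sizes

The bundled tests and the acceptance script run at desk scale by design:
synthetic frames of ~2,500 atoms (334 lipids, 726 particle atoms,
hydration shells, 149 ions), trajectories of 4–50 frames, 960–3,840
quadrature points, block-averaging series of 4,096 points, and the full
14-step flip sequence with 6 equilibrium frames per step. These sizes keep
every statistical recovery target (classification for all 15
distributions, hydration slope within 15%, blocking error within 20%)
comfortably resolvable while the whole suite completes in a few minutes on
one CPU.

## Limitations

The package analyses configurations; it does not generate physical ones.
No free-energy barriers are computed (the flip barrier is an input), no
umbrella sampling or PMFs are implemented, and the implicit-solvent model
behind the insertion reference is used only through its printed scaling
arithmetic. Real-trajectory observables (absolute SASA changes, contact
counts, coordination values) require real trajectories; the synthetic
generator's defaults are order-of-magnitude emulations chosen once, not
fits.
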