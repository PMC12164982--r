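---
title: "Methods: handshake trajectory analysis and the synthetic system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: handshake trajectory analysis and the synthetic system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piezotraj)
```

# Scope and model

`piezotraj` analyses trajectories of trimeric mechanosensitive channels of
the PIEZO family: three identical subunits, each contributing a curved
transmembrane blade of nine transmembrane helical units (THU1 peripheral,
THU9 proximal) around a central pore. Two membrane-parallel helices — the
short helix (SH) of one blade and the long helix (LH) of the clockwise
neighbour — form a transient *handshake* whose presence or absence
modulates channel compactness, the membrane dome, pore geometry, and
ultimately mechanosensitivity. The package computes the descriptors of
this mechanism from coordinates, and fits the electrophysiological
response curves with which the mechanism is probed experimentally.

All coordinates are stored in nanometres; PDB input is converted from
ångström on read. Boxes are orthorhombic; triclinic input is rejected
explicitly. Distances between groups use unweighted centres of geometry
without re-wrapping the group across the periodic boundary: selections are
assumed whole, which the synthetic generator guarantees and which real
input should satisfy after centring. Bead indices are 0-free (1-based) in
R; file formats keep their native numbering at the boundary.

## Handshake detection

For each of the three ordered pairs (SH tip, residue 176 of chain *k*; LH
tip, residue 1912 of the clockwise successor of *k*) the minimum-image
distance between the tip-residue centres of geometry is computed per
frame. A separation **≤ 1.5 nm (inclusive)** defines the bound state; the
per-frame handshake count is the number of bound pairs (0–3).
"Clockwise" is defined viewing the channel from the extracellular side
(+z) using the topology's chain order; the generator constructs geometry
consistent with this convention. Tip distance uses the single tip residue
(one bead at coarse-grained resolution) rather than a whole-helix minimum,
because the state definition names single residues.

## Mode taxonomy

Single-pair distance series are segmented with hysteresis: a pair binds at
≤ `bind_cutoff` (1.5 nm) and unbinds only above `unbind_cutoff` (2.0 nm),
which prevents boundary jitter from fragmenting episodes. Episodes are
labelled

* **stable** — a bound dwell of at least `stable_min_dwell` (200 frames);
* **unstable** — runs bordered by a cluster of at least
  `unstable_min_transitions` (3) state changes within `unstable_window`
  (500 frames);
* **release** — a terminal unbound run of at least `release_min_unbound`
  (500 frames) that follows a bound episode.

The hysteresis width and the dwell windows are exposed defaults, chosen as
round numbers on the frame scale of microsecond coarse-grained runs; the
modes themselves are qualitative categories, so the thresholds are design
choices rather than measured constants. Each episode is annotated with its
mean PIP₂ pool. `pool_mode_contrast()` compares the pool during stable
episodes against the frames immediately preceding each release *event*
(bound→unbound transition of the hysteretic state); using the event rather
than the terminal-episode label makes the contrast well-defined even in
runs that end bound.

## Blade, projected-area and membrane descriptors

* **Blade distance** — 3D minimum-image distance between the THU1 centre
  of geometry and the centre of geometry of the inner-pore selection
  (residues 2433–2462 over all chains).
* **Blade angle** — the angle at the THU6 vertex between the xy-projected
  arms THU1−THU6 and THU9−THU6. The projection reflects that the angle
  measures curvature in the membrane plane; a straight blade reads 180°,
  consistent with the reported 85–130° working range. A vertical arm
  (zero projected length) is flagged and skipped rather than silently
  folded into the statistics.
* **Compact/extended** — compact if distance < 13 nm *and* angle < 100°;
  extended if distance > 13 nm; otherwise intermediate.
* **Conditional histograms** — 2D (distance, angle) histograms over frames
  with a given handshake count, normalised by frame count and bin area
  (defaults Δd = 0.25 nm, Δθ = 2°, unstated in the source analyses and
  exposed as parameters). With shared bin ranges the frequency-weighted
  conditional histograms reproduce the unconditional histogram exactly
  (law of total probability), which the tests assert.
* **Projected area** — from the three pairwise L71 distances:
  `r_b = d̄/√3` (the circumradius of the equilateral triangle with the
  mean side) and `area = π r_b²`. Whether the upstream convention uses one
  pairwise distance or the mean of three is not documented; the mean is
  used because it is symmetric in the chains and reduces to the single
  distance for an equilateral triangle.
* **Height maps and dome depth** — per-bin mean z of phosphate headgroup
  beads of one leaflet (default bin 0.5 nm); empty bins are
  nearest-neighbour filled but masked. Dome depth is the mean height over
  the outer 10% radial band minus the minimum observed height.

## Lipid contacts and pools

Contacts use the minimum-image *minimum* bead distance between a residue
and a lipid headgroup with a 0.6 nm cutoff — the conventional
protein–lipid contact distance for coarse-grained headgroup beads, exposed
in the configuration. Counts are normalised by frames and by the number of
lipids of the species, averaged over the three chains, and averaged across
replicate trajectories after per-trajectory normalisation. The PIP₂ pool
is the number of distinct PIP₂ lipids whose headgroup lies within
2.5 nm (inclusive) of any SH bead. The 2.5 nm default follows the value
used when the pool was related to handshake stability; a 2.0 nm preset is
kept available because both values appear in the source methods, and the
package does not guess which produced specific published panels. Headgroup
beads are `PO4` for phospholipids, `ROH` for cholesterol and the
inositol-phosphate bead (`P1`) for PIP₂; the map is configurable.

## Pore geometry

Triangle sides are pairwise minimum-image distances between the marker
residues Y2444 (top), V2450 (middle) and F2454 (bottom) of the three
chains; the area follows Heron's formula with a small negative radicand
(rounding) clamped to zero. Residue overrides implement the mutant
convention of substituting L2449 for V2450 on a rotated chain. Cavity
volumes voxelise the inner-pore selection at 1.4 Å spacing; a voxel is
occupied if its centre lies within the bead van der Waals radius (2.6 Å
for regular coarse-grained beads, configurable); an empty voxel's *degree
of buriedness* is the number of the six axis directions along which an
occupied voxel occurs, cavity voxels need degree ≥ 3, and the 6-connected
component containing the seed (the selection centre by default) is
retained. Volume is the voxel count times spacing³.

## Response fits

All three fits use damped (Levenberg–Marquardt) least squares with
data-driven starting values (`Imin`/`Imax` from the pressure extremes,
`p50` at the half-range response, `dp = −range(p)/6`; `EC50` at the
geometric median dose with `HC = 1`; `τ` from the 1/e crossing time).
Non-convergence is flagged in the result object, never silent. The Hill
function is implemented in its standard bounded-sigmoid form with the
denominator parenthesised, `R = Rmin + (Rmax−Rmin)·d^HC/(EC50^HC+d^HC)`;
a typographically ambiguous rendering of this formula exists in print, but
only the parenthesised form is a bounded sigmoid. `dp` may legitimately
fit negative for inward currents that grow with pressure; report |dp|
alongside the signed value. Boltzmann fits leave `Imin` free (constraining
it to zero is not documented anywhere authoritative). Rows lost to patch
rupture are handled upstream by fitting on the ≥ 5 remaining points.
Surface tension is `γ = Lz(pN − pL)` with `pL = (pxx+pyy)/2`; with `Lz` in
nm and pressures in bar, 1 nm·bar = 0.1 mN/m.

# The synthetic system

The generator exists so every analysis stage can be validated against
known ground truth without molecular-dynamics data. It emulates the
*statistical structure* the analyses assume, not the physics:

* **Membrane** — headgroup beads only, one per lipid, apportioned per
  leaflet by largest remainder from the endothelial composition (lower
  leaflet POPC/POPE/POPS/CHOL/PIP₂ = 50/20/5/20/5, upper
  POPC/POPE/DPSM/CHOL = 55/20/5/20; the 0% PIP₂ variant moves the 5% to
  POPS). Default 600 lipids in a 44 × 44 nm box — a deliberate headgroup
  subsample of the ~5900-lipid systems the composition comes from, chosen
  so that full test suites and the acceptance script run on a single CPU
  in minutes; all composition arithmetic is exact at any count.
* **Handshake kinetics** — a two-state Markov chain per pair with
  formation rate `k_on` and release rate `k_off(n) = k_off0·e^{−βn}`,
  where `n` is the anchored-PIP₂ pool, itself a birth–death chain over the
  pair's walkers with binding-state-dependent anchoring. The per-frame
  update uses the exact two-state discretisation
  `P(bound at t+dt) = π_b + (s_t − π_b)e^{−(k_on+k_off)dt}`, so the
  stationary occupancy is exactly `k_on/(k_on+k_off)` at any frame
  interval — this is what makes the binomial-mixture oracle for the 0–3
  count frequencies analytic. A frame interval so coarse that the
  per-step switching probability exceeds 0.5 is rejected.
* **Tip distances** — bound: 1.0 nm plus Gaussian jitter (sd 0.1 nm);
  unbound: an exact-discretisation Ornstein–Uhlenbeck process around
  4.0 nm. On release the distance restarts at 2.2 nm (outside the bound
  band): once the anionic screen is lost the like-charged helices separate
  quickly, and this choice keeps the emitted coordinates consistent with
  the 1.5 nm state rule (the residual inconsistent-frame fraction is
  reported in the ground truth).
* **Blades** — tip-to-pore distance and vertex angle follow OU processes
  whose means interpolate between bound (12 nm, 95°) and unbound (15 nm,
  115°) values with the chain's handshake involvement, relaxation 50
  frames, stationary sds 0.8 nm and 5°. The blade is embedded so that the
  emitted THU positions reproduce the target 3D distance and angle
  exactly (a small fixed-point solve places THU1 on the dome surface).
* **Dome** — phosphate z follows
  `h(x,y) = −D·e^{−r²/(2σ²)}(1 + a·cos 3θ)` (defaults D = 5 nm, σ = 7 nm,
  a = 0.2), lower leaflet offset −2 nm, upper +2 nm; the trilobate term
  gives the three-fold footprint the height-map analysis should resolve.
* **PIP₂** — each pair owns an equal share of the PIP₂ walkers; anchored
  walkers are placed within 1.5 nm of the SH tip, unanchored walkers in a
  far annulus more than 2.5 nm from every SH bead. The measured pool
  therefore equals the latent pool exactly, which turns pool-series tests
  into exact comparisons.
* **Pore** — marker triangles are equilateral with OU side series per
  level (defaults 2.2/1.6/1.9 nm top/middle/bottom); L2449 sits 0.15 nm
  tangentially from V2450 so the substitution rule is exercisable.

What the generator does **not** emulate: forces, solvent, lipid tails and
chemistry, elastic-network constraints, realistic diffusion constants, or
the true kinetics of handshake formation and release — no quantitative
rates are published, so `k_on`, `k_off0` and β are free parameters of the
test harness and are never claimed to match a real channel. Passing the
recovery suites therefore demonstrates that the *analysis code* measures
what it claims to measure on data with the assumed structure; it says
nothing about the biology of any particular trajectory.

# Numerical choices

* Minimum image: each displacement component is wrapped into (−L/2, L/2];
  correctness is asserted against a 27-image brute force.
* Superposition: Kabsch SVD with the determinant correction; a
  (near-)collinear fit set is an explicit error.
* Heron radicand clamped at zero for degenerate triples.
* Statistical tests on autocorrelated series use analytically corrected
  standard errors: variance inflation `(1+λ)/(1−λ)` with
  `λ = e^{−(k_on+k_off)dt}` for two-state occupancy, and `2σ²τ/T` for OU
  means. The 3-standard-error bands in the tests are computed from these
  exact factors rather than naive i.i.d. errors.
* Problem sizes in tests: 600-frame/200-lipid cached run for most
  recoveries, one 3000-frame/600-lipid run for state-agreement checks,
  500 replicates for the Boltzmann bias suite, 60 for the Hill
  confidence-width contrast — sizes chosen so that the statistical
  tolerances above are decisive while the whole suite completes in a few
  minutes on one CPU.
* Degenerate inputs: empty selections, missing species, zero-area
  triangles, non-decaying exponentials, all-empty height maps and
  seedless cavities are all explicit, classed conditions (config, data or
  numeric), which the command-line wrapper maps to exit codes 2/3/4.

# Limitations

* The helix charge profile can verify arginine/lysine counts for any
  user-supplied sequence span, but the package ships no reference
  sequences; the documented hPIEZO1 values (6R/0K and 9R/0K on the two
  handshake helices) require the user to supply the UniProt Q92508
  sequence and span bounds.
* `r_b` assumes the equilateral circumradius of the mean L71 side; for
  strongly scalene configurations this is a summary, not an exact
  circumradius. Estimating a spherical radius of curvature from the dome
  is out of scope.
* Leaflet assignment relies on topology labels; for real input without
  labels, assign leaflets by the sign of z relative to the phosphate
  median plane before building the topology CSV.
* The cavity tool reproduces the published degree-of-buriedness
  definition (6 axis rays, no diagonals); internal van der Waals radii of
  the original implementation are not public, so the bead radii are
  documented defaults.
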