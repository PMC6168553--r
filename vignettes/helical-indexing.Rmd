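---
title: "Helical symmetry from filament power spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Helical symmetry from filament power spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helifil)
```

# Scope

helifil reimplements, as reusable and testable code, the desk-scale
computational steps behind the structure determination of a death-domain
(CARD) protein filament: helical-parameter arithmetic, layer-line indexing
of filament power spectra, helical-diffraction simulation with
amplitude-correlation grid refinement, filament assembly generation with
interface typing, chemical-shift perturbation mapping between the solution
and filament states, and immuno-gold polarity statistics. Everything runs
on seeded synthetic data; nothing requires a download.

# The helical model

A 1-start helical filament is fully described by the *twist* (rotation per
subunit about the filament axis, degrees; negative = left-handed under the
+z right-hand convention used throughout) and the *rise* (axial translation
per subunit, Å). Two equivalent parameterisations are interconverted
exactly:

* pitch `P = rise × upt` (axial distance of one 360° turn) and units per
  turn `upt = 360 / |twist|`;
* the rational repeat `u/t`: the filament repeats exactly after `u`
  subunits in `t` turns, over a repeat distance `c = u × rise`.

`rational_units_per_turn()` finds the best coprime `u/t` with `t` bounded,
via the bounded-denominator continued-fraction (Stern–Brocot) walk. The
walk is exact, including semiconvergents; ties in approximation error break
toward the smaller `t` for parsimony. For 3.56 units per turn with `t ≤ 10`
this gives `u = 32, t = 9`.

Layer line `l` of the power spectrum sits at axial frequency `l/c` and
carries only the Bessel orders `n` allowed by the selection rule
`l = t·n + u·m`. Two lines anchor the indexing: the first meridional line
(`n = 0`, hence `l = u`) measures the rise (`height = 1/rise`), and the
strong near-meridian `n = 1` line at `l = t` measures the pitch
(`height = 1/P`).

# Synthetic data

`make_filament()` expands point scatterers given in cylindrical coordinates
by the symmetry; `project_filament()` renders each scatterer as an
isotropic Gaussian (default σ = 2 px; the acceptance analyses use 1 px to
retain more high-resolution signal) after projection along the viewing
axis, with the filament axis vertical. Consecutive stack images view the
filament advanced by one segment step (default 70 Å), which rotates the
azimuth by `(step/rise)·twist` — emulating segments excised along one
filament. Noise is additive white Gaussian applied last, seeded.

What the generator deliberately does **not** model: the contrast transfer
function, ice or support background, atomic form factors and B-factors,
out-of-plane tilt, and bending/flexibility. Passing tests therefore
demonstrate the correctness of the indexing and refinement chain under an
idealised image formation model, not robustness to every pathology of real
micrographs; CTF handling and segment alignment live upstream in
conventional processing packages.

Default image geometry follows the study conditions: 1.21 Å/px sampling;
the test analyses use 256 px boxes with 280 Å filaments so that the
per-axis frequency sampling (1/309.8 Å⁻¹) resolves the ~1/155 Å⁻¹
layer-line spacing while keeping the suite fast. A single scatterer at
radius 25 Å is used for spectra — the mid-wall radius between the reported
~12.5 Å channel radius and ~37.5 Å outer radius — matching the
single-radius diffraction model below.

# Indexing chain

`average_power_spectrum()` averages squared Fourier magnitudes over the
stack (origin centred at pixel `N/2 + 1`; rows are axial frequency Z,
columns radial frequency R). `detect_layer_lines()` integrates power per
row, subtracts a running-median background — which tracks the smooth
reciprocal-space envelope so that weak high-frequency lines are not
swamped by strong low-frequency ones — and keeps local maxima exceeding
`min_snr` MADs of the residual; Friedel mates are merged. The peak
criterion is this package's documented choice; robust (median/MAD)
statistics were preferred because half the rows of a filament spectrum
legitimately contain signal.

`fit_repeat()` indexes heights as `l_i = round(h_i·c)` for each candidate
lowest index, refines `1/c` by least squares, and applies a two-phase
rule: an indexing with machine-zero residual wins immediately (smallest
such repeat first), otherwise the smallest repeat within `rel_tol` is
taken. The exact-first phase is what lets two noiseless anchor lines
(9/155.8 and 32/155.8) index as `l = 9, 32` rather than as a smaller
approximate repeat; the parsimony phase is what prevents overfitting of
jittered heights by absurdly large repeats.

`assign_bessel_order()` uses the single-radius first-maximum heuristic: on
layer line `l` the radial intensity follows `J_n(2πRr)²`, so the radial
position of the first maximum encodes `|n|` (0 for meridional). The first
maxima of `J_n` are located numerically and cached. A full Fourier–Bessel
decomposition is deliberately out of scope. When the observed maximum lies
beyond the prediction for `n_max` the result is capped and flagged
low-confidence.

Handedness cannot be read from a single projection power spectrum — both
hands give identical intensities — so it is an explicit input, defaulting
to left as established for CARD-family filaments.

# Grid refinement

`simulate_spectrum()` implements the single-radius Cochran–Crick–Vand
model: on line `l`, amplitude `Σ_n J_n(2πRr)` over the allowed orders,
squared; finite length broadens each line axially with a
`sinc²((Z − l/c)·L)` profile. Units per turn is rationalised (denominator
bound 50) before applying the selection rule, which makes the simulated
intensity invariant under equivalent `(u, t)` descriptions of the same
twist/rise. An optional Gaussian envelope (`blob_sigma_ang`) matches the
generator's known point spread — the analogue of the envelope implicit in
reprojection-based refinement.

`amplitude_correlation()` is the Pearson correlation of square-root
amplitudes over a mask. The default mask removes the equator row and a
3-px origin disc (both dominated by low-frequency background); the
refinement analyses additionally limit the axial range to
|Z| ≤ 0.22 Å⁻¹, just above the meridional rise line, because the region
beyond carries no layer-line signal under the rendering envelope. The
correlation *value* is not the tested contract — the mask and weighting
are documented defaults — parameter recovery is.

`grid_refine()` evaluates every node of an inclusive grid
(`round((max−min)/step)+1` nodes per axis, reproducing 11 × 11 from
17.2–17.4 Å / 3.4–3.6 at step 0.02) and returns the argmax with ties
broken toward the grid centre. Under the test conditions (SNR 1, 24
segments) the generating node (17.26 Å, 3.56) is recovered exactly without
noise and within one grid step in ≥ 95 of 100 noise realisations.

# Assemblies, interfaces, RMSD

`build_filament()` places monomer copies at `Rz(k·twist)·X + k·rise·ẑ`,
one chain per subunit (A…Z, a…z, 0–9, then two-character ids; PDB output
refuses more than 62 chains). Symmetry exactness — subunit k mapped by
(twist, rise) reproduces subunit k+1 to ≤ 1e-9 Å — is a tested invariant.

`subunit_contacts()` enumerates heavy-atom pairs between subunit 0 and
subunit k within a cutoff (default 4.0 Å), grouped by offset k. Which
offsets realise the death-domain type I/II/III interfaces is *not*
hard-coded: `classify_offsets()` matches the contacting residue sets
against a curated annotation (shipped as JSON, transcribed from the
published interface descriptions, residues 433–518) by mean Jaccard
overlap of the two surfaces, trying both orientations. The offset→type
mapping is thus a result, not an assumption. Salt-bridge candidates are
charged-group N/O pairs within 4 Å; hydrogens are ignored throughout.

`superpose_rmsd()` is the closed-form Kabsch solution via SVD with the
determinant correction that enforces a proper rotation; collinear point
sets are rejected. Tests cross-check it against a rotation-grid numerical
minimiser and an independent reference implementation. Published
crystal-vs-filament RMSD values were produced with secondary-structure
matching, which trims pairs; a plain Kabsch over the stated residue range
may differ at the second decimal, so those comparisons are integration
checks against deposited models, not unit tests.

# Chemical shifts

`secondary_shifts()` subtracts random-coil Cα/Cβ values per residue type;
the sign convention is `observed − random coil` (positive Cα deviation ⇒
helical propensity), configurable, since the opposite convention appears
in figure legends and only the sign, never the magnitude, differs. A
standard DSS-referenced random-coil table ships as data; analyses may
substitute their own.

`state_perturbation()` sums `|ΔCα| + |ΔCβ|` per residue between two
states. A missing atom omits its term (rather than dropping the residue),
and residues absent from either table are reported unassessed — both
choices keep partial assignments informative and are flagged in the
output. The default threshold is 1.2 ppm applied to the absolute sum;
whether the published threshold was absolute or a deviation from the mean
is ambiguous, so both modes are implemented (`mode = "from_mean"`), with
absolute as default. Flags are monotone in the threshold, and the
perturbation equals the difference of the two secondary-shift profiles
(random-coil terms cancel) — both tested.

# Gold polarity

`gold_summary()` computes the fraction of particles on filaments and, of
those, the fraction at an end. Because annotations do not record *which*
end, the both-ends count is reported as the number of filaments carrying
two or more end particles — an upper bound. `end_preference_test()` is the
exact upper-tail binomial probability; the null end fraction `rho0` (e.g.
2 × end-window length / filament length) must be supplied by the caller,
because no end-window convention exists to default to. The test is
one-sided by design: the hypothesis (nucleation from one end) is
directional.

# Numerical conventions

* Coordinates Å, angles degrees at interfaces (radians internally);
  subunit indices 0-based; origin of even-box spectra at pixel `N/2 + 1`.
* Segment bookkeeping: each refinement segment contributes
  `floor(step/rise)` unique subunits, so 9661 segments at a 70 Å step and
  4.848 Å rise give 135,254 asymmetric units. The formula is inferred from
  that arithmetic (`floor(70/4.848) = 14`); refinement software does not
  publish its exact counting rule.
* The printed 3.56 units/turn is treated as a continuous grid coordinate
  in refinement and as the value to rationalise (32/9 ≈ 3.5556 or the
  exact 89/25) elsewhere; both readings are carried, and grid refinement
  does not assume either.
* `asymmetric_units()` warns rather than errors when step < rise (the
  segment then contributes no unique subunit).
* Report JSON never contains timestamps, so identical config + seed give
  byte-identical reports.

# Problem sizes

The shipped analyses and tests use 256 px boxes, 280 Å filaments, 24
segments per stack, 121-node grids, 100-trial recovery runs, ≤ 2000-atom
toy assemblies, and 72-residue shift tables — sizes chosen so the whole
chain runs in well under a minute per analysis on one CPU while every
frequency-domain quantity of interest stays resolvable.

# Known limitations

No CTF or 3D reconstruction; no segment alignment or classification; no
multi-start helices beyond the selection-rule generalisation; no
solvent-accessible surface or energetics for interfaces; no peak picking
or assignment for NMR; no image analysis for gold particles (annotations
are inputs). Deposited-model comparisons (crystal-vs-filament RMSD,
75/25 Å diameters, the real offset→type lattice mapping) require accession
downloads and are integration checks outside the test suite.
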