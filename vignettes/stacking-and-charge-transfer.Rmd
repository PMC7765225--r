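---
title: "Stacking poses and charge-transfer state analysis with stackCT"
author: "stackCT authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacking poses and charge-transfer state analysis with stackCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stackCT)
```

## The scientific problem

Planar aromatic photosensitizers such as anthraquinone (AQ) intercalate
between consecutive DNA base pairs, and their photochemistry — in
particular photoinduced electron transfer from a flanking guanine to the
excited chromophore — depends strongly on how the two rings stack. A
typical simulation campaign produces (i) a long classical trajectory of the
intercalated complex and (ii) a large set of vertical excited states
computed on selected snapshots, each state annotated with a
fragment-partitioned transition-density (Omega) matrix. stackCT implements
the post-processing that turns those raw outputs into interpretable
quantities: stacking-pose descriptors, representative-snapshot selection,
per-state electronic descriptors with a four-way classification, and
class-resolved densities of states and absorption spectra. It deliberately
does *not* run molecular dynamics or electronic-structure calculations; it
consumes their outputs, or synthetic stand-ins generated by its own
generator module.

## Stacking-pose geometry

Three descriptors characterize a pose of the intercalator relative to the
stacked guanine:

* **Twist angle** — the angle between the directed intercalator long axis
  (center of mass of outer ring R1 to that of outer ring R2) and the
  directed base-pair axis (first to second C1' sugar atom). Both axes are
  used as genuine 3-D vectors; no projection is applied. The angle lives in
  [0, 180] degrees and supplementary angles are *different* poses, which is
  why the axes must be directed: the ordering of R1/R2 and of the C1' pair
  in the fragment configuration fixes the sign convention (swapping R1 and
  R2 maps an angle to 180 minus itself, and a test pins this down).
* **Shift (N1) and slide (N2)** — in-plane components of the separation
  between each outer intercalator ring center and the guanine
  six-membered-ring centroid. "In-plane" means the total least-squares
  plane of the six ring atoms: the distance definitions only invoke that
  ring, so we use the smallest atom set consistent with them. N1 points
  from the ring centroid to the midpoint of the C–C bond opposite the
  pyrrole ring (named explicitly in the fragment configuration as two atom
  indices — ring-perception code would be more fragile than an explicit
  label); N2 points toward the carbonyl group and is Gram–Schmidt
  orthogonalized against N1 inside the plane. The separation vector is
  projected into the plane *first* and its N1/N2 components taken second
  (the two orders differ only off-plane, and projecting first keeps both
  components consistently in-plane). Shift and slide are reported as
  absolute values, matching their use as nonnegative distances.

Degenerate inputs — collinear ring atoms, a zero-length axis, a carbonyl
direction parallel to N1 — raise descriptive errors; `analyze_trajectory()`
converts them into flagged rows (`status` column) rather than dropping
frames. The plane normal's sign is tied to the guanine-to-intercalator
direction so that all descriptors are invariant under rigid motions of the
whole frame to better than 1e-8, a property the test suite checks against
random rotations and translations.

## Configuration windows and Metropolis snapshot selection

The twist-angle distribution of an intercalated chromophore concentrates in
four regions: two strongly stacked "symmetric" windows, (0, 30) and
(150, 180) degrees, and two partially unstacked "rotated" windows, (30, 60)
and (120, 150). `assign_window()` uses half-open intervals [lo, hi), with
180 included in the last window, so every angle maps to exactly one window
or to the (60, 120) gap.

For excited-state calculations one selects a fixed number of snapshots per
window whose twist angles are representative of the equilibrium ensemble.
Since the trajectory itself is already Boltzmann-weighted, the natural
target is the *empirical* in-window twist distribution (no potential-energy
function is needed). `metropolis_select()` runs a Metropolis chain over the
bins of a 2-degree histogram of the in-window twists: a bin is proposed
uniformly and accepted with probability `min(1, mass_prop/mass_cur)`, so
the stationary law over bins is the empirical histogram. After a burn-in of
`max(1000, 50 * n_bins)` proposals the current bin is recorded every 5th
step (a rejected proposal leaves the chain in place) and a pool frame is
drawn uniformly from the recorded bin — without replacement whenever the
pool is large enough, with replacement (and a flag) otherwise. Recording at
fixed steps rather than at acceptance events matters: sampling the chain
only when a move is accepted distorts the recorded distribution away from
the stationary law. The default bin width of 2 degrees matches the
resolution at which such twist distributions are usually inspected; burn-in
and thinning are package choices (the chain state space has at most ~90
bins, so a few thousand proposals decorrelate it thoroughly). Selections
are deterministic given the seed, and a two-sample Kolmogorov–Smirnov
check against the pool is part of the test suite.

## Transition-density descriptors and state classification

Each excited state carries a nonnegative fragment Omega matrix whose
element (A, B) is the transition-density weight with the hole on fragment A
and the excited electron on fragment B (here fragment 1 is the
photosensitizer, fragment 2 the guanine). The matrix is always normalized
to unit element sum — descriptors are weight *fractions* — and the
pre-normalization sum is retained as `raw_norm` for bookkeeping. (Whether
an upstream wavefunction-analysis tool normalizes by the element sum or by
the squared transition-density norm varies; normalizing here makes the
descriptors independent of that choice.)

From the normalized matrix:

* hole and electron populations are the row and column sums;
* the participation ratio `PR = 1 / sum(p^2)` counts the effective number
  of fragments a carrier is spread over;
* `DL_av` is the mean of the hole and electron participation ratios
  (1 for a pure monomer state, 2 for a pure two-fragment exciton);
* `CTN` is the off-diagonal weight sum (0 for pure Frenkel excitons,
  1 for pure charge transfer);
* `POS_i`/`POS_f` are the population-weighted fragment indices of hole and
  electron.

Classification uses the standard thresholds `DL_av = 1.25` and
`CTN = 0.2 / 0.8`: CTN above 0.8 is charge transfer (this rule takes
precedence), CTN below 0.2 splits into monomer (DL_av strictly below 1.25)
and exciton, and everything with intermediate CTN — inclusive at both 0.2
and 0.8 — is an excimer. Two corner conventions deserve a note because the
threshold rules alone do not cover them: DL_av exactly 1.25 at low CTN is
labeled exciton (the monomer inequality is strict), and the region of low
DL_av with intermediate CTN is labeled excimer, consistent with the
excimer band spanning all delocalization lengths at intermediate CTN in
CTN/DL_av maps. With these choices the truth table is total: every
in-range (DL_av, CTN) pair receives exactly one label, which a grid test
asserts.

The implementation generalizes to N ≥ 2 fragments (populations, PR, POS
and CTN extend verbatim); the two-fragment behavior is pinned by the
tests, and all descriptors are cross-checked against an independent
brute-force implementation to 1e-12 on random matrices.

## Ensemble decomposition

`class_fractions()` reports the percentage of states per class — the
class-resolved density of states (DOS) — while `intensity_fractions()`
weights each state by its oscillator strength, the class-resolved
absorption spectrum. `broadened_decomposition()` turns both into curves on
an energy grid by giving each state a Gaussian of configurable FWHM
(default 0.3 eV, an ordinary choice for condensed-phase ensemble spectra;
nothing in the analysis depends on it beyond visual smoothness) with unit
area (DOS) or oscillator-strength area (spectrum). Class curves sum
pointwise to the total by construction, and the DOS total integrates to
the number of states on a covering grid.

The central physical contrast the decomposition exposes: charge-transfer
states carry very small transition dipoles because the hole and electron
sit on different, spatially separated fragments, so their share of the
absorption spectrum is far below their share of the DOS. The synthetic
generator reproduces this "dark CT" structure (below) and the test suite
asserts the strict inequality.

Auxiliary views: `ctn_dlav_map()` builds the 2-D CTN/DL_av histogram
(0.05-wide bins by default; with bin edges on the thresholds its quadrant
masses reproduce the class fractions — except for states sitting exactly on
the CTN = 0.8 edge, which classify as excimer but fall in the CT quadrant;
a measure-zero caveat of half-open binning); `pos_distributions()` gives
unit-mass POS_i/POS_f histograms per class; `nearest_ion_distance()` plus
`binned_trend()` (1-Angstrom bins over 0–20 Angstrom by default) support
counter-ion distance trends; `compare_models()` aligns class fractions
across embedding models (e.g. full solvated system vs. strand-embedded vs.
vacuum).

## The synthetic-data generator

The generator exists so that every stage of the chain can be validated
against known ground truth without MD or quantum chemistry.

*Geometry.* `make_stacked_dimer()` builds idealized planar templates — a
guanine-like unit with a labeled six-membered ring, carbonyl arm,
pyrrole-opposite C–C bond and C1' anchors, and a tricyclic
intercalator-like unit with labeled outer rings — and places the
intercalator at a prescribed (twist, shift, slide, rise). The templates are
regular polygons, not chemically accurate molecules: the descriptors
depend only on labeled centers of mass, the ring plane and anchor atoms,
so idealized templates make the construction an *exact* oracle — the
geometry module recovers the construction parameters to 1e-6, and
round-trip plus rigid-motion tests run over hundreds of random poses. The
default rise of 3.4 Angstrom is a typical aromatic stacking separation;
optional per-atom Gaussian jitter emulates thermal noise.

*Pose ensembles.* `make_pose_trajectory()` draws twists from truncated
Gaussians centered in each window (sd 8 degrees — wide enough to fill a
30-degree window while keeping distinct within-window structure; the
empirical shapes of real twist distributions are not tabulated anywhere,
so no attempt is made to match them numerically) with mixture weights over
the four windows, and records ground-truth labels.

*Excited-state ensembles.* `sample_omega()` perturbs the four archetype
matrices (monomer localized on fragment 1; exciton `diag(0.5, 0.5)`;
charge transfer with all weight on one off-diagonal element; excimer an
equal monomer/CT mixture) with a blended random nonnegative matrix and
renormalizes; by default a rejection loop guarantees the draw still
classifies as the requested label (without the guarantee, classification
accuracy decays with the mixing noise, which is itself a tested property).
`make_ensemble()` assembles frames-by-states records with multinomial
class labels, uniform energies on 2.5–6.5 eV (the near-UV window typical
of such chromophores), and log-normal oscillator strengths in which the
charge-transfer mean is suppressed 100-fold — a deliberately simple
"dark CT" model chosen because the darkness of CT states is a robust
qualitative feature while its precise magnitude varies by system; both the
suppression factor and the direction bias (90% of CT states transfer the
electron from guanine to the photosensitizer, mirroring the dominant flow
in such systems) are configurable. Default class fractions
(42% monomer, 3% exciton, 25% excimer, 30% charge transfer) represent a
realistic DOS composition for a stacked photosensitizer/guanine dimer.

What passing tests on synthetic data do and do not show: they verify the
*analysis* — descriptor algebra, classification logic, distributional
bookkeeping, selection machinery — exactly, because the generator's truth
is known. They do not validate force fields, electronic-structure methods
or the physical realism of the archetype mixtures; real Omega matrices
have correlated structure (e.g. energy-dependent class composition) the
generator does not attempt to emulate.

## Problem sizes and numerical choices

The shipped tests run ensembles of 4 windows x 100 frames x 10 states
(4000 states, the scale of a realistic QM/MM campaign), 10,000-frame pools
with 2000-frame selections for the Metropolis check, 10,000 random Omega
matrices for bound/conservation properties and 100 random dimer poses for
geometric round-trips — sizes chosen so the full suite completes in well
under a minute while keeping binomial error bars tight enough for 3-sigma
recovery checks. Tolerances: exact algebraic identities at 1e-12,
geometric round-trips at 1e-6 (plane fits involve an SVD), rigid-motion
invariance at 1e-8, statistical recoveries at 3 binomial standard errors,
and the Kolmogorov–Smirnov distance below 0.05 at n = 2000.

## Known limitations

* The Omega matrices are consumed, never computed: constructing them from
  quantum-chemistry output (natural transition orbitals, Lowdin/Mulliken
  fragment partitioning) is out of scope.
* Only the three stacking descriptors are provided; full helicoidal
  parameter sets (rise, roll, tilt, ...) are not.
* The Metropolis target is the empirical twist distribution; no
  energy-based reweighting (e.g. at a different temperature) is attempted.
* Classification thresholds are sharp; states near a threshold flip class
  under small perturbations of the Omega matrix, which is inherent to any
  threshold scheme and why the 2-D maps are provided alongside the
  fractions.
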