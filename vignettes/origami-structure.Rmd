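---
title: "Quantifying DNA origami structure with origametry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA origami structure with origametry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(origametry)
```

## The problem

DNA origami folds a long scaffold strand into a designed shape by
hybridizing hundreds of short staple strands. The resulting object is a
raft or bundle of parallel double helices joined at four-way (Holliday)
junctions wherever a strand crosses between helices. Three structural
signatures dominate such objects:

* the **weave**: adjacent helices splay apart between junctions, so the
  inter-helix distance oscillates with the junction spacing;
* the **corrugation**: junctions prefer a twist angle slightly away from
  perfectly anti-parallel, which rotates inter-helix vectors out of the
  sheet plane in a small, systematic wave;
* in 3D bundles, helix centrelines trace a weak **helical path** whose
  period matches the junction spacing.

`origametry` measures these signatures from coarse-grained nucleotide
configurations (oxDNA-style text files: one position plus two orientation
versors per nucleotide), imports caDNAno designs to build starting
configurations, and characterizes isolated junctions through windowed
sampling and WHAM. A seeded synthetic generator produces duplexes,
junction ensembles, weave/corrugation tiles and bundles with recorded
ground truth, so the entire analysis chain is validated by round trip at
desk scale — no molecular-dynamics engine is involved or required.

## Junction angles

A stacked four-way junction is described by four arms, grouped into two
coaxially stacked duplexes, two *continuing* strands that run straight
along their duplex and two *exchanging* strands that cross at the centre.
We quantify its geometry with two angles:

* **phi** (twist): each arm's axis is fit by least squares through its
  base-pair midpoints, skipping the 2 pairs nearest the junction and using
  the next 8 (arms in the reference constructs are 16 bp). `phi1` and
  `phi2` are the signed dihedrals, about the inter-duplex axis, between
  corresponding arms of the two duplexes; `phi` is their circular mean
  mapped to [0, 360). The anchors are definitional: an ideal parallel
  junction gives 0, an ideal anti-parallel junction 180, and values below
  180 are left-handed. All phi arithmetic is circular; theta is linear.
* **theta** (splay): the junction plane passes through the exchanging
  strands' midpoint nucleotides with its normal along the inter-duplex
  direction (oriented toward the duplex of the first continuing strand).
  Each arm's theta is the angle between its axis and that plane, positive
  when the arm bends away from the partner duplex; `theta` averages the
  four arms.

A deliberate consequence of these definitions: theta is *achiral*. Arms
that splay apart still splay apart in any mirror image, so theta is
invariant under reflection, while phi maps to 360 − phi. The tests pin
both behaviours.

Isomer classification follows the arm axes directly: the labelled
stacking (arms 1+2, 3+4) must be anti-aligned beyond a dot product of
−0.8 for isomer I, either cross pairing for isomer II, and anything else
is called open. The −0.8 threshold tolerates splay up to about 18
degrees, well beyond the few degrees seen in stacked ensembles.

## Windowed sampling and WHAM

Free junctions are sampled under harmonic phi biases
`U_w(phi) = 0.5 k (phi − c_w)^2` (kT per squared degree, circular
difference). `wham()` combines windows on a fixed (phi, theta) grid —
2 × 1 degree bins by default — by standard self-consistent reweighting,
iterating the per-window offsets to 1e-7 and reporting `F = −ln P`
shifted to minimum 0, with unoccupied bins `NA` (never 0) and the
normalizing shift stored so `exp(−(F + log_norm))` sums to one. The
temperature (default 296.15 K) only labels the kT unit. Windows whose
sampled phi ranges fail to chain trigger a disconnected-landscape flag:
the relative offsets of disconnected groups are then arbitrary.

Binned free energies are Poisson-noisy (roughly `1/sqrt(count)` kT per
bin), so the landscape minimum is located by a counts-weighted quadratic
fit over the basin (bins within 2 kT of the raw argmin by default) rather
than by the raw argmin, which wanders under noise in flat wells. The
validation in the test suite draws 5e4 samples from a stated Gaussian
density through 12 windows and checks the recovered surface on a 4 × 2
degree grid over bins holding at least 150 effective samples, where the
per-bin noise is safely below the 0.3 kT acceptance band; those sizes are
the package's validation choices, stated here so they can be reproduced.

Junctions whose midpoint base pairs come apart (branch migration or
melting) are detectable with `check_branch_migration()` and should be
excluded before accumulating a landscape; the synthetic sequences are
generated without immediate base repeats precisely to make the designed
register unambiguous.

## Weave and corrugation

Helix axes are the midpoints of paired bases, taken per base-pair index
from the design registration; positions whose design pair is missing
(fraying, melted staples) are masked and propagate as gaps through every
profile. `weave_profile()` reports, per adjacent helix pair and index,
the mean and standard deviation over frames of the inter-axis distance.
`weave_waveform_stats()` smooths with a 3-point moving average (enough to
suppress single-frame jitter without moving extrema), takes
`amplitude = mean(maxima) − mean(minima)`, and reads the dominant period
from the circular autocorrelation peak; a profile with no interior
extrema is flagged aperiodic.

The triangular-wave model ties the weave to the junction splay: if
helices leave each junction straight at angle theta and meet the next
extremum half a period later,
`theta = atan((amplitude/2) / (half_period × rise))`. With the typical
1.5 nm amplitude, 16 bp half-period and 0.34 nm rise this gives 7.85
degrees — the worked example in the test suite, and the `t1` quantity of
`scripts/acceptance.R`.

Corrugation follows the orientation of inter-helix vectors around each
junction: at every offset, the local inter-helix vector and the
frame-averaged vector at the junction are projected onto the plane
perpendicular to the junction's average helix axis (a central difference
over ±2 bp on both helices) and the angle between projections is signed
by their scalar triple product with the axis. The profile is
antisymmetric about the junction, passes through zero at the midpoints
between same-pair junctions (where the neighbouring group's junctions
sit), and reaches its extremes — half the full junction twist — a quarter
period out, which is why the analyses default to `max_offset` of a
quarter spacing. Junction averaging uses only *canonical* junctions:
edge junctions (outermost pairs, or within half a spacing of the helix
ends) and seam or seam-adjacent junctions are excluded via explicit
flags that the generator and the caDNAno importer both provide.

## Mean structures, RMSD and helicity

`superpose()` is the closed-form Kabsch solution restricted to proper
rotations; reflections are never returned because molecular chirality
must survive alignment, and the test suite cross-checks the minimum
against an independent nested rotation-grid search. `mean_structure()`
aligns every frame to the running mean (initialized from frame 1),
averages positions and versors, re-orthonormalizes versors (a3
normalized first, a1 projected perpendicular — adequate for the small
angular fluctuations of structural ensembles, and much simpler than
quaternion averaging), and stops when the mean moves less than 1e-4 nm
or after 20 passes. `rmsd_to_reference()` superposes helix-axis points
(or any mapped point set) onto a reference and reports the RMSD with
per-point displacement vectors.

`helix_path_helicity()` subtracts a running-mean local axis (window 15
bp by default) from the centreline, accumulates the winding of the
residual about the path direction, and converts the winding slope to a
period; residual amplitudes below the 0.05 nm noise floor report no
helicity. Handedness flips exactly under mirror imaging.

## The synthetic generator

Every generator is seeded, deterministic (byte-identical reruns), leaves
the caller's RNG stream untouched, and returns its construction
parameters as ground truth. Geometry defaults are the untwisted-origami
conventions: 0.34 nm rise, 10.5 bp/turn pitch, 2.5 nm lattice spacing,
backbone sites at 0.6 nm radius.

* `make_duplex()` builds an ideal B-form duplex (the base-pair map is
  exact by construction).
* `make_junction_frame()` / `make_junction_ensemble()` construct stacked
  junctions realizing requested (phi, theta) exactly — four ideal 16 bp
  arms posed by the forward geometry — with angles drawn from a stated
  density: delta, Gaussian (sampled exactly, including the harmonic
  window bias via the product-of-Gaussians identity), or an arbitrary
  density function via inverse transform on a 0.5 degree grid.
* `make_tile()` lays parallel helices whose gaps follow a triangular
  wave (minima exactly at crossovers, the two pair groups offset by half
  a spacing), adds corrugation as an out-of-plane triangular wave of
  inter-helix-vector angles, and can open a seam by removing one group's
  crossover. Thermal noise is iid Gaussian applied per *base pair* (both
  nucleotides of a pair move together), so axis points carry the noise
  sigma directly and the inter-helix distance fluctuates with standard
  deviation sqrt(2) × sigma — the propagation oracle used by the tests.
* `make_bundle()` places helices on a square lattice with circular
  centreline residuals of one turn per junction spacing; the stagger
  sign sets the handedness.

What the generator does **not** emulate: any force field or
thermodynamics, sequence-dependent structure, correlated (bending-mode)
fluctuations, fraying kinetics, or electrostatics. Passing round-trip
tests therefore demonstrates that the *measurement* chain is correct and
unbiased at realistic signal sizes — not that real origami behaves like
the generator. Analyses of real trajectories ingest the same file
formats through `read_oxdna_topology()` / `read_oxdna_trajectory()`.

## caDNAno import and relaxation

`parse_cadnano()` handles v2 JSON ("vstrands") and refuses v3 files
explicitly. Lattices are inferred by the parity heuristic
(`num %% 2 == (row + col) %% 2` for every helix means honeycomb) because
designs do not declare them; an explicit argument always wins.
`build_initial()` walks the scaffold and staple linked lists (linear
paths first, then remaining cycles), omits skips, inserts loops at
fractional axial positions, applies a given or seeded scaffold sequence
with staples complementing their slot, and places everything on ideal
helices at the lattice coordinates. The nucleotide count is exactly
`occupied slots − skips + loop insertions`.

Such structures can hold stretched backbones or overlaps, so
`relax_config()` runs capped-displacement steepest descent (cap 0.05 nm)
on a surrogate energy — harmonic backbone springs at 0.64 nm rest length
plus a soft quadratic repulsion below 0.6 nm — halving the step whenever
the energy would increase, which makes the reported energy trace
monotone by construction. This surrogate is a declared design choice of
this package: it removes pathological geometry cheaply and
rigid-motion-covariantly, and makes no claim to physical dynamics.

## Pipeline

`run_pipeline()` executes configured stages in order (convert, synth,
weave, corrugation, mean-structure, rmsd, helicity, junction), writes
every artifact with an md5 manifest, and serializes the configuration
into the output directory; identical configs and seeds rerun
bit-identically. The `origametry` script under `inst/exec/` wraps the
same functions for shell use. Plots are optional ggplot2 helpers and
never required by any analysis.

## Known limitations

* Base-pair detection is a geometric proxy (site distance, anti-aligned
  stacking versors, facing base versors, complementarity, greedy
  nearest-first assignment), not an energy model; heavily distorted
  duplexes can re-pair diagonally.
* The inter-helix registration assumes the design's base-pair indexing;
  trajectories without design metadata need an externally supplied
  registration.
* WHAM assumes the bias depends on phi only, matching the windowing
  strategy implemented here.
* The caDNAno importer aims at structurally faithful topology and
  starting geometry, not at reproducing any particular published
  relaxation protocol.
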