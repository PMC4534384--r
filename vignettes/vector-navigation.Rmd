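---
title: "Vector navigation with modular grid codes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vector navigation with modular grid codes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridnav)
```

## The representation

A grid system is an ordered set of modules, largest spatial scale first.
Module `i` represents location only through a pair of spatial phases
`(p_x, p_y)` in `[0, 2π)` along two non-collinear principal axes of its
firing lattice. With the default separation of 60° the scale is equal
along both axes and the phase space is the twisted torus of the rhombic
unit tile. We fix the phase origin of every module at the world origin;
nothing downstream depends on this choice because every decoder consumes
only phase *differences*, which are invariant to joint translation of the
two locations.

Along an axis with effective scale `s` (ellipticity multiplies the axis-2
scale), the phase of a coordinate `u` is `2π (u mod s) / s`. The joint
code across modules is a residue number system: it repeats only after the
system period `C`, the smallest displacement at which every module phase
returns to its start. For rationally related scales `C` is the least
common multiple (300 cm for scales {50, 30, 20}; 60 cm for {30, 20});
`system_period()` computes it by continued-fraction rationalisation
(denominator cap 10^6) and, as an independent route, by a numeric
coincidence scan. Irrational scale ratios make the system effectively
aperiodic; the scan then reports `Inf`, and the array-based decoders
refuse to build, since their cell counts are bounded by `C`.

## The algorithmic decoder

A wrapped phase difference `Δp_i` stands for the unwrapped family
`Δp_i + 2πn_i`, i.e. candidate displacements `s_i (Δp_i/2π + n_i)`. A
displacement `d` is consistent with all modules exactly when some integer
set `{n_i}` puts every unwrapped phase on the line through the origin
with gradient `2πd` in unwrapped-phase versus inverse-scale coordinates —
the Fourier shift theorem applied to the grid's spatial harmonics. The
decoder therefore:

1. enumerates coherent integer sets, anchored on module 1
   (`d_hyp = s_1 (Δp_1/2π + n_1)` for `n_1` covering `[−C/2, C/2]`) with
   the other `n_i` snapped to the nearest integer — `O(C/s_1 · M)` rather
   than the exhaustive product over modules;
2. least-squares fits the through-origin line per candidate (slope/2π is
   the displacement; modules weighted equally);
3. returns the candidate with minimal rms phase misfit whose displacement
   lies in the signed range `[−C/2, C/2)`.

We report displacements in the symmetric signed range because navigation
is bidirectional; the representation itself fixes no branch. Noise-free
input yields residuals at machine precision, so the default success
threshold is 10^-6 rad rms; for noisy phases the threshold is
configurable and the best-effort vector is always reported.

In 2D with shared module axes the problem separates into two independent
1D fits, one per principal axis, assembled through the axis basis. When
modules differ in orientation or ellipticity a single plane through the
origin is fit instead; the axis coordinates of a cartesian displacement
come from the *dual* basis (rows of the inverted basis matrix), not from
projection onto the axis unit vectors, which differ when the basis is
non-orthogonal. Both paths agree on shared-axis systems, which the tests
verify. A third redundant axis would add no independent information
(the three hexagonal axis phases sum to zero), so only under noise would
pooling help; we keep two axes.

`brute_force_oracle()` scores every displacement on a grid over
`[−C/2, C/2)²` by summed squared circular distance between predicted and
observed phase differences. It is the independent cross-check for the
line/plane fit; for shared axes the score is separable per axis, keeping
the full scan cheap enough to run hundreds of times in the test suite.

## The four network readouts

All rate-based models receive grid input as phase-binned population
vectors per axis: one bin per phase `φ_k = 2πk/m` (`m` =
`cells_per_axis`), pooling every cell in the module that shares that
phase on the axis. The bin's tuning is the hexagonal three-cosine rate
map marginalised over the orthogonal axis, `(cos(p − φ) + 1.5) / 4.5` —
the exact marginal, since the two oblique cosine components average out.

**Distance cells.** One cell per preferred location on `[0, C)` at
spacing δ, with weights equal to each grid bin's rate at that location
(row-normalised). Winner-take-all yields the encoded position; ties break
to the smallest preferred location for determinism. Current- and
goal-position arrays project to "move up"/"move down" readout neurons
with linear weights of opposite slope (`ℓ/C` and `(C−ℓ)/C`), so
`up − down = 2(goal − current)/C`; the affine relation is inverted with
the known construction (the readout calibration is constructed, not
learned — developmental learning of these weights is out of scope) and
wrapped to `[−C/2, C/2)`.

**Rate-coded vector cells.** One cell per displacement bin, receiving
multiplicative input from every (current-bin, goal-bin) pair in every
module whose wrapped phase difference matches its displacement; each
module contributes `m` pairs per cell. The summed product over pairs is,
per module, proportional to `cos` of the circular mismatch between the
cell's displacement and the true one, so the winner-take-all picks the
bin nearest the true displacement — the same criterion the brute-force
oracle minimises. Multiplication is implemented as the elementwise
product of presynaptic rates; we implement the computational contract,
not a dendritic mechanism. An optional variable-resolution mode coarsens
bin spacing in proportion to `|d|/s_1`, trading far-goal precision for
array size; precision recovers by re-decoding as the goal nears.

**Phase-coded vector cells.** Idealised axis-aligned theta phase
precession: spanning the full cycle linearly over one grid tile, with
current-location cells firing at the theta trough (0 rad) and goals less
than half a scale ahead firing at later (positive) phases. The theta
firing phase of a goal-coding cell is then just its spatial phase
difference re-expressed on `(−π, π]`. Spikes are abstract
(module, phase) events carrying an explicit goal tag — the model's
content is the phase mapping, not spike generation, and biological
demultiplexing of several goals within one cycle is not modelled.
Decoding matches each goal's phase vector against per-displacement
templates by summed squared circular distance. The template bank spans
`(−C/2, C/2]`: at the boundary, where `±C/2` are genuinely
indistinguishable, the forward (positive) displacement is reported, and
near-ties are flagged ambiguous with the smaller magnitude returned.

**Linear look-ahead.** The phase code is advanced from the start at a
constant simulated speed along one axis (`2π · step/s_i` per step, faster
for smaller scales), leaving the other axis' phases untouched (the
swept population is a phase "band"). Coincidence with the target code —
all modules simultaneously within tolerance — stops the sweep; steps to
coincidence encode distance. The default tolerance is half the per-step
phase advance of the smallest-scale module (`π · step/s_M`): that is the
smallest value guaranteeing detection at the step nearest an arbitrary
real-valued displacement, and it reduces to half the phase-bin width
when the step equals the phase-bin spacing. Aliased coincidences lie a
full period away, beyond the `C/2` sweep range, so the first hit is the
true displacement. Both directions are swept and the nearer hit fixes
the sign; latency is the summed steps of the winning sweeps.

## Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `axis_separation` | π/3 | rad | axes of symmetry of a hexagonal grid; equal scale on both |
| `ellipticity` | 1 | — | circularly symmetric fields; multiplies the axis-2 scale |
| `cells_per_axis` | 32 | cells | phase resolution of the network models (0.625 cm at s = 20); our choice, typical of sheet models |
| array resolution δ | s_M/4 | cm | cell counts bounded by capacity; quarter of the finest scale balances array size against quantisation |
| look-ahead step | s_M/8 | cm | no module phase advances more than π/4 per step |
| residual threshold | 1e-6 | rad rms | machine-precision fits on noise-free input |
| phase-equality tolerance | 1e-9 | rad | wrap/round-trip comparisons |

## The synthetic benchmark

`random_scenarios()` draws start locations uniformly over a square work
area (side `C`) in axis coordinates and displacements uniformly within
`(−C/2, C/2)` per axis — the unambiguous range, so every scenario is
decodable in principle. Noise is optional independent von Mises jitter
per phase (`perturb_code()`; sampler after Best & Fisher 1979), applied
at decode time with per-scenario derived seeds; a single user seed makes
the whole run, including its CSV output, byte-reproducible. Gaussian
rate noise is not separately modelled: every decoder consumes phases, so
phase jitter is the common currency of input noise here.

`run_benchmark()` scores each decoder per axis, circularly: the code is
periodic in `C`, so an estimate of `+C/2` against a truth just below
`−C/2` is a near-zero error, not `C`. A decode succeeds when each axis
component is within `max(model resolution, s_M/4)` of the truth — the
per-axis bound is the one the array constructions actually guarantee
(each location/displacement quantises independently per axis), whereas a
Euclidean criterion would conflate the two axes through the oblique
basis. The Euclidean length of the wrapped error vector is still
reported as `error_cm`.

What the generator emulates: arbitrary start/goal geometry over ranges
exceeding the largest scale, and circular phase noise. What it does not:
spiking variability and temporal dynamics, grid distortions near
boundaries, module-specific noise correlations, and anchoring/drift of
the grid representation itself. Passing the noise-free consensus test
therefore shows the five readouts compute the same function of the phase
code, not that any of them is robust to everything real circuits face.

Problem sizes used by the shipped test-suite runs: 500 random scenarios
for the five-decoder consensus property, 100 cases for oracle
equivalence (1 cm scan), 500 trials for noisy candidate agreement
(σ = 0.2 rad), 50 cases for the latency-linearity fit. These sizes give
the comparisons sub-centimetre resolution while keeping a full suite run
in a few minutes on a laptop.

## Numerical conventions and degenerate inputs

* Phases wrap to `[0, 2π)` half-open, with values within 10^-12 of 2π
  snapped to 0; theta phases live on `(−π, π]` with the boundary kept at
  +π (field entry).
* Floating-point `mod` uses the non-negative wrapped remainder.
* Winner-take-all ties break deterministically: smallest preferred
  location (distance cells), smallest `|d|` (vector cells, templates;
  positive preferred on exact magnitude ties).
* Collinear axes (separation 0 or π) are a configuration error; an
  infinite period makes the array decoders refuse with an explicit
  message; a look-ahead tolerance loose enough to fire at step 0 for
  clearly distinct codes triggers a warning.
* Enumeration bounds guarantee every displacement in `[−C/2, C/2]` has a
  candidate; the fitted, not hypothesised, displacement is range-checked.

## Known limitations

* The brute-force oracle and the array decoders require shared module
  axes; only the plane-fit path handles per-module orientations and
  ellipticities.
* Readout rates are unbounded and linear; biological saturation is not
  modelled.
* Within-axis winner-take-all only — competition across axis arrays is
  not modelled.
* Phase precession is the idealised axis-aligned, full-cycle version;
  mechanistic precession models and trajectory-dependent 2D precession
  are out of scope, as are Hebbian development of any weight matrix,
  place-cell/boundary anchoring, and spiking attractor dynamics.
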