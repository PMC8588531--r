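---
title: "Reconstructing hyperspectral vegetation spectra from few-band measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing hyperspectral vegetation spectra from few-band measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsrecon)
library(dplyr)
```

## The problem

A network of cheap multispectral sensor nodes measures reflectance in only
M bands (typically fewer than ten), while the downstream analyses —
vegetation indices, red-edge inflection, species classification — want the
full N-band hyperspectral spectrum. hsrecon estimates the full spectrum
from the few measured bands. Three methods are implemented, differing in
what side information they assume:

* **K-SVD dictionary reconstruction** (the package's core): a dictionary
  of K unit-norm spectral atoms is learned from a hyperspectral training
  set; a measured pixel `y = Φx` is completed by finding a sparse code α
  of `ΦD` with the smoothed-ℓ0 (SL0) solver and synthesising `x̂ = Dα`.
  All nodes may share one band set (homogeneous networks): the
  information about unmeasured bands lives in the dictionary.
* **JSM-1 joint reconstruction (DCS)**: groups of nodes with *different*
  band sets are solved jointly as one sparse common signal plus per-node
  sparse innovations, both sparse under the first-difference transform
  (reflectance spectra are smooth, so their derivative is concentrated at
  a few transitions such as the red edge). Group-median aggregation
  (DCS-GM) reconstructs each pixel under L independent groupings and
  takes the per-band median.
* **UPDM unmixing**: each pixel is modelled as a linear mix of water,
  vegetation and soil base spectra; fractions are estimated from the
  measured bands by least squares and the full-resolution bases are
  recombined.

Band-set quality matters for the single-band-set methods, so both K-SVD
and UPDM come with best-band-set selection by rejection ("-BBS"): a
handful of random candidate band sets is scored on a held-out split and
only the few lowest-median-RMSE sets are kept. The point is rejecting the
rare catastrophic sets (e.g. all bands crowded into the blue-green
window), not finding an optimum — rankings inside the low-RMSE plateau
transfer only weakly between datasets.

## Data model

Spectra travel as long tibbles (`id`, `wavelength` in nm, `reflectance`,
optional `class`, `row`, `col`) sharing one strictly increasing
wavelength grid. The default working grid is 40 evenly spaced bands over
406–1100 nm, the range where visible/NIR field spectrometers and airborne
imagers overlap; both the range and N are configurable
(`default_grid()`). Cross-sensor band matching is nearest-band
*selection*, never interpolation (`resample_spectra()`), with ties broken
to the lower wavelength and a 10 nm default coverage limit.

## The synthetic scene generator

The methods are exercised on synthetic scenes (`scene_config()`,
`make_scene()`, `make_splits()`) because suitable paired
field/airborne campaigns are rarely public. The generator emulates the
statistical features the methods rely on, with these per-class models:

* *vegetation*: low visible level (0.05) + Gaussian green peak (0.03 at
  550 nm) + logistic red-edge transition centred at 715 nm (10–90 % width
  30 nm) up to a NIR plateau of 0.5 — five parameters reproduce the red
  edge that dominates trained atoms;
* *soil*: smooth linear increase 0.15 → 0.40 across the grid;
* *water*: low exponential decay from 0.08 (the decay keeps the three
  bases linearly independent on any band subset — exactly affine water
  and soil curves would make the 3×3 unmixing system singular whenever
  the drawn bands avoid the red edge);
* *built-up anomalies*: a broadband level with low-frequency cosine
  ripples, deliberately outside the water/vegetation/soil span.

Scenes are rectangular patches of land use (default 70 % vegetation,
20 % soil, 10 % water), per-pixel multiplicative parameter jitter
(sd 5 %, red-edge position ±1 nm·jitter·20), additive Gaussian sensor
noise (sd 0.005 reflectance — small enough that exact-recovery tests stay
meaningful, large enough to be non-trivial), and an optional anomaly
fraction. Everything is seeded: identical configurations give bitwise
identical scenes. `make_splits()` renders the evaluation split through a
4× denser "second sensor" grid and band-matches it back, so training and
evaluation never share a sensor. What passing tests on these scenes do
**not** show: robustness to atmospheric effects, radiometric
miscalibration, mixed pixels at patch borders, or non-Gaussian sensor
noise — none of which the generator emulates.

## Numerical choices

**SL0.** The solver is the noiseless equality-constrained variant:
initialise at the minimum-ℓ2-norm solution `A⁺y`, then for a geometric
sigma schedule take 3 gradient steps on `Σ exp(−x²/2σ²)` per level,
projecting onto `{x: Ax = y}` after each step. Defaults: σ₀ = 2·max|A⁺y|,
decay 0.8, μ = 2, σ_min = 1e−6. The decay and floor were validated
against an exhaustive ℓ0 oracle on small random instances: a 0.5 decay
anneals too fast (support recovery drops several points), and σ_min must
sit below the 1e−6 relative threshold used to report supports, because
off-support entries settle at O(σ_min). When `A` is square the ℓ2
initialisation is already the unique consistent point and the projection
undoes every gradient step — SL0 degenerates to the plain ℓ2 solution.
This is why a dictionary whose size equals the number of measured bands
reconstructs poorly; `reconstruct_ksvd()` warns when K = M.

**OMP.** Textbook greedy selection (max |correlation| with the residual,
normalised by column norms) with a least-squares refit on the support
each step and a 1e−12 residual early stop. On hard coherent instances
(M = 8, K = 16, 2-sparse) greedy selection fails in a few percent of
cases; this is a property of the algorithm, not the implementation —
scikit-learn's OMP picks the identical wrong atoms on the same instances.

**K-SVD.** Initialisation is a seeded farthest-point selection of
training spectra (first spectrum drawn by seed, each next one the
spectrum least coherent with the atoms so far) — random-sample
initialisation can seed two atoms in the same direction and stall in a
local minimum when the sparsity target is 1. Atom updates use the exact
rank-one SVD of the restricted residual; unused atoms are replaced by the
worst-represented training spectrum; atom signs are flipped so the
largest-magnitude entry is positive, making dictionaries comparable
across runs. The sparse-coding step carries a per-spectrum guard: the
previous iteration's code is kept wherever fresh OMP coding would
increase that spectrum's residual. Plain alternation does not guarantee a
monotone objective across the re-coding step; the guard makes the
training error provably non-increasing while leaving the algorithm
otherwise standard. Default 20 iterations with an early stop at relative
improvement < 1e−5. The sparsity target defaults to the 10 % rule
`T = min(K, max(1, round(0.1 N)))` — 4 on the default 40-band grid.

**JSM-1.** The first-difference transform kills constant offsets, so
signals are synthesised as `x = S·θ` with `S = [1 | L]`, an explicit
constant column next to the lower-triangular cumulative sum; the
non-constant part of θ is exactly the discrete derivative. The stacked
system for a group of J nodes has (J+1)·N unknowns and ΣM_j rows and is
never formed densely: matvecs route through S once for all nodes, and the
Gram matrix of the stack is the stacked `B B'` with doubled diagonal
blocks, factorised once per group by Cholesky (SVD pseudo-inverse
fallback with a warning when the stack is rank-deficient, e.g. fully
homogeneous band sets). The operator path is algebraically identical to
running `sl0()` on the dense stack and is tested to agree to machine
precision. Common and innovation coefficients are weighted equally in the
objective. The default group size is 64 — large enough that the common
part is well constrained, small enough that the per-group factorisation
stays cheap.

**UPDM.** Fractions are unconstrained least squares by default — the
simplest reading of fraction estimation; a nonnegative mode (exact
enumeration of the 8 sign patterns of the 3-variable problem) is
available behind `nonneg = TRUE`, since sum-to-one and nonnegativity
conventions vary between deployments. Base spectra default to class
means of the labelled pixels (deterministic, noise-robust);
`single_pixel = TRUE` picks single labelled pixels instead. A singular
3×3 normal matrix (collinear bases on the drawn bands) is a hard error,
not a silent pseudo-inverse.

## Evaluation protocol

`rmse()` is the per-pixel root-mean-square error over all N bands
(measured bands included; a diagnostics flag restricting to unmeasured
bands was considered and rejected to keep one headline number).
`evaluate_method()` repeats reconstruction over R = 20 replications that
redraw the band set, records the median per-pixel RMSE per replication,
and reports the **median of the R medians** — robust to the occasional
catastrophic band set. BBS variants evaluate the kept sets (default 3)
instead of random draws. For DCS the 20 replications are structured as 4
band-set assignments × 5 groupings; DCS-GM takes, per band-set
assignment, the per-band median over the 5 groupings' estimates, yielding
4 median spectra per pixel. Box statistics follow the Tukey convention;
plots suppress outliers (the data keep them). `rmse_map()` gives the
per-pixel spatial error map; `illustrative_spectra()` picks the
lowest/median/highest-RMSE pixels for qualitative display.

## Design choices that were genuinely open

* **Band indices are 1-based** throughout the R API (serialized JSON band
  sets are written 0-based for cross-language portability).
* **The constant-offset atom in JSM-1** (the `[1 | L]` synthesis) is the
  package's resolution of the rank deficiency of the difference
  transform; alternatives (mean-centring per node, pinning the first
  sample) couple nodes or bands asymmetrically.
* **BBS scores each candidate in a single pass** over the selection
  split rather than its own 20-seed median-of-medians: the ranking logic
  is identical and the rejection of bad sets — the only thing BBS is
  relied on for — is unchanged.
* **The small-vs-large dictionary comparison** (K = 4 vs K = 100 at
  T = 4) is run at M = 8 measured bands so that the separate K = M
  square-dictionary pathology does not confound it.
* **Benchmark problem sizes** used by the tests and the acceptance
  script: mixed scenes of 48–56 px squared with 500 training, 300
  selection and 1000–2000 evaluation pixels; the vegetation design-target
  benchmark uses 500 evaluation pixels. These sizes give stable medians
  (the median-of-medians moves by well under 10 % when the evaluation
  split is halved) while keeping a full run in minutes on one core.
  End-to-end determinism is asserted on a deliberately small
  configuration — determinism does not depend on problem size.

## Known limitations

* The generator's land-use layout is rectangular patches without mixed
  pixels; real scenes have gradients and boundary mixing that raise UPDM
  and dictionary error floors.
* Measurements are noiseless point samples of bands: filter transmission
  curves (band integration) are not modelled.
* SL0 support recovery degrades near the compressed-sensing phase
  transition; with very few bands (M = 4) and K = M dictionaries the
  documented ℓ2 degeneration applies.
* The exhaustive ℓ0 oracle is exponential in the support size and is
  deliberately capped (K ≤ 20, support ≤ 3 by default budget); it is a
  test instrument, not a solver.
* `read_envi_cube()` covers BSQ/BIL float32/float64/uint16-with-scale
  dialects only — enough for common exporter output, not a full ENVI
  driver.
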