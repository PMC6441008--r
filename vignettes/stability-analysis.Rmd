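---
title: "Ranking GPCR fusion constructs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking GPCR fusion constructs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrstab)
```

## The scientific setting

Thermostabilized GPCR constructs — typically a receptor with T4 lysozyme
(T4L) fused into intracellular loop 3 and one or more point mutations — are
screened before crystallization trials.  Two independent read-outs rank
candidate constructs:

1. **Conformational fluctuation** of a structure ensemble (snapshots from
   molecular dynamics): a stable construct deviates less from its average
   structure and concentrates in fewer conformational substates.
2. **Thermal denaturation** by circular dichroism: the 222 nm ellipticity
   tracks helical content; its sigmoidal loss with temperature gives a
   melting midpoint Tm.

`gpcrstab` implements both read-outs behind one segment-map abstraction
(named residue ranges for TM1..TM7, the fusion domain, and any linkers) so
the same analyses apply to any seven-helix receptor-fusion complex.

## RMSD observables

All superpositions use the Kabsch algorithm: SVD of the covariance matrix
of two centered, matched coordinate sets, with the determinant-corrected
composition so only *proper* rotations are returned — a reflection can
spuriously halve the RMSD of near-planar selections, so it is excluded by
construction.  Degenerate inputs (fewer than 3 atoms, collinear sets,
detected via the second singular value of the centered coordinates at a
relative tolerance of 1e-9) are refused rather than silently fitted.

Per frame, against a reference structure:

* `rmsd_all`, `rmsd_tm`, `rmsd_t4l` — Kabsch RMSD over the heavy atoms of
  the whole complex, the pooled TM segments, and the fusion domain.
* `rmsd_t4l_prime` — the *transform-transfer* observable: the rigid
  transform fitted on the TM heavy atoms is applied to the fusion domain
  and the raw (no-refit) RMSD is taken there.  It measures how much the
  fusion domain moves *relative to* the receptor; internal rigidity of
  T4L keeps `rmsd_t4l` small while a hinge motion inflates
  `rmsd_t4l_prime`.  Kabsch optimality on the fusion atom set guarantees
  `rmsd_t4l_prime >= rmsd_t4l`, which the test suite asserts on every
  generated frame.

Atom-class choices: the three refit observables use heavy (non-hydrogen)
atoms; whether the TM observable should instead use backbone atoms is a
genuinely open convention, so the atom class is an argument of
`select_atoms()` and heavy atoms are the default for consistency across
the four observables.  "Backbone" means N, CA, C: the carbonyl O is
excluded, the common trajectory-analysis convention; this is configurable
nowhere because mixing conventions inside one analysis is a mistake we do
not want to enable.

### The reference structure

The reference is the iterative ensemble average: align every frame on the
current mean (heavy atoms of the `"ALL"` selection), re-average
coordinates, repeat until the mean moves < 1e-6 Å RMSD or 100 iterations
(non-convergence returns the last mean with a warning and a `converged`
attribute, rather than failing an otherwise useful run).  The iteration is
needed because a plain coordinate mean of unaligned frames smears rigid
drift into apparent internal motion.

### The 7×7 per-helix matrix

Entry (i, j) is the raw RMSD of helix j's backbone after applying the
transform fitted on helix i's backbone.  Diagonals are Kabsch-minimal and
report deformation *within* each helix; off-diagonals report relative
displacement, i.e. bundle packing.  Rows are the alignment helix — the
convention is fixed and recorded in the output dimnames because the matrix
is not symmetric.  The test suite checks the full matrix against an
independent quaternion-superposition implementation to 1e-9, and checks
that diagonals are direction-symmetric.

## Ensemble clustering

Pairwise Kabsch RMSD on the pooled TM heavy atoms (upper triangle computed
once, symmetry exact by construction) feeds Jarvis–Patrick clustering:

* neighbor list of a frame = its up-to-`M` nearest frames **within** the
  RMSD `cutoff` (defaults M = 10, cutoff = 1.5 Å);
* two frames link when their neighbor lists share at least `P = 3` frames;
* clusters are connected components of the link graph.

The published phrasing of the neighbor criterion ("the M most similar
structures or all structures within the cutoff") does not say whether the
two conditions intersect or unite.  We default to the intersection: in a
dense ensemble every frame has M neighbors inside the cutoff, so under the
union reading the cutoff would never do anything.  Both readings are
available (`neighbor_rule = "intersect" | "union"`), as are both cluster
constructions (`variant = "components" | "accretion"`); neither is claimed
to be byte-compatible with any particular MD package's implementation.
Determinism: ties at neighbor rank M break toward the lower frame index,
and cluster ids are assigned in decreasing size order (ties by lowest
member index).

Cumulative top-k occupancy (k = 5 by default) summarizes how concentrated
the ensemble is; large values indicate few, deep conformational substates.

## Contacts, box statistics, ranking

Side-chain centers are unweighted geometric means of the residue's heavy
side-chain atoms (excluding N, CA, C, O, OXT); glycine maps to its CA.
Mass weighting is deliberately not used — the published protocol does not
specify it, and the unweighted center is the simpler convention to state.

Box statistics fix the quartile rule to linear interpolation at rank
1 + p(n−1) (`stats::quantile` type 7) and the 1.5·IQR fence rule;
whiskers clamp to the most extreme data inside the fences.

`rank_constructs()` orders constructs by ascending median RMSD^TM (smaller
median = more stable) and merges adjacent constructs into "~" tie groups
when their medians differ by at most `tie_tol` (default 0.15 Å, merging
transitively along the sorted chain).  The tie tolerance is our
parameterization — the qualitative "~" pairs in published rankings come
with no stated threshold — and it is exposed as an argument.

## Melting-curve fitting

Raw curves (temperature °C, ellipticity) are normalized to the denatured
fraction Δf_D = (θ − θ_min)/(θ_max − θ_min) over the sampled range, which
is affine-invariant in θ.  Fits run on the normalized curve with baselines
fixed at 0 and 1 (a free-baseline mode exists but is off by default, since
normalization already set the plateaus).  Two midpoint-parameterized
sigmoids are available:

* Hill (default): Δf_D(T) = T^n/(Tm^n + T^n), evaluated internally as
  1/(1 + exp(n(log Tm − log T))) so exponents up to several hundred stay
  finite;
* logistic: Δf_D(T) = 1/(1 + exp((Tm − T)/s)), s in °C.

Both place Δf_D = 0.5 at T = Tm, so the reported midpoint is comparable
across models.  Fitting is Levenberg–Marquardt (`minpack.lm::nls.lm`) with
multi-start: Tm from the sampled temperature nearest Δf_D = 0.5 and the
curve midrange; steepness from {5, 20, 60} (Hill) or {1, 3, 10} °C
(logistic); box bounds Tm ∈ [min T − 20, max T + 20]; best residual sum of
squares wins, ties to the first start; an L-BFGS-B minimization of the RSS
is the fallback if a start fails structurally.  A fitted midpoint outside
the sampled range is reported but flagged (`converged = FALSE`) with an
extrapolation warning — a midpoint you never bracketed is an
extrapolation, not a measurement.  One known ambiguity: "calculated by
difference of ellipticity values" could describe a derivative-based
midpoint; we fit the normalized curve directly, which is the standard Hill
protocol, and note the alternative here rather than implementing a second
estimator of unclear provenance.

## The synthetic-data generators

The generators stand in for inputs the analyses were designed for and give
every test a known ground truth:

* `make_bundle()` builds an idealized complex: seven ideal α-helices
  (rise 1.5 Å/residue, 100°/residue twist, backbone N/CA/C plus one CB per
  residue) on a 12 Å circle with alternating direction, and a
  pseudo-globular fusion domain below the bundle built as a self-avoiding
  random cluster (minimum CA–CA distance 2.5 Å).  Consecutive CA–CA
  distances land near the canonical 3.8 Å.  Geometric realism is *not* a
  goal: the construction exists to make selections, transforms and
  segment bookkeeping testable.
* `make_ensemble()` perturbs the reference per frame: optional planted
  cluster (drawn by occupancy; fixed per-domain offset transforms), then
  per-domain rigid jitter (rotation axis uniform on the sphere, angle
  ~ Normal(0, σ°), Rodrigues composition; translation Normal per axis),
  then global rigid jitter, then isotropic atom noise.  The full ground
  truth (cluster label, global transform, the spec itself) is attached to
  the ensemble, and every generator is a pure function of its seed.
* `make_melting_curve()` maps Hill denatured fractions to a synthetic
  ellipticity scale (defaults −20 to −2, a plausible 222 nm millidegree
  span for a helical protein) sampled 25–90 °C in 5 °C steps, plus
  Gaussian θ noise.

What the generators do **not** emulate: force-field physics, lipid/water
environment, correlated (non-rigid) internal motions, instrument drift or
buffer artifacts in CD signals.  Passing tests therefore demonstrate that
the *analysis machinery* recovers planted truth under realistic noise
magnitudes — not that the pipeline would reach the same biological
conclusions on real trajectories.

### Study-condition presets

`preset_fluctuation_specs()` fixes per-construct jitter scales so the six
emulated constructs (WT and five mutants) realize median RMSD^TM values
inside the 2–3 Å band with the ordering
L126W < G294A < WT ~ A240D < L81A ~ K154A (ties planted 0.05 Å apart,
distinct groups ≥ 0.25 Å apart).  The per-helix translation jitter σ was
calibrated once against the resulting median (the relation is linear,
median ≈ 1.385 σ + 0.18 Å over the working range) and frozen; rotation
jitter (2°/helix), atom noise (0.25 Å) and fusion-domain jitter (12°, 3 Å
baseline, 6 Å for the three constructs with pronounced fusion motion) are
held fixed.  `preset_cluster_specs()` plants five major substates holding
each construct's target top-5 occupancy (0.80 for the most stable
construct down to 0.38) plus twelve minor centers; cluster centers are
per-helix displacements drawn once at Normal(0, 4 Å) per axis, far above
the 1.5 Å neighbor cutoff, with 0.15 Å within-cluster atom noise.

**Problem sizes.**  Ranking recovery is estimated from 1,500 frames per
construct in the acceptance script — the per-construct snapshot count of
the emulated study — because the median of a distribution with ~0.5 Å
spread has a standard error of roughly 1.25·σ/√n, and the planted 0.05 Å
tie gaps (against the 0.15 Å tie tolerance) need that error well below
~0.02 Å to resolve deterministically.  Unit tests use 60–200 frames at
fixed seeds where determinism makes smaller sizes sufficient.  Occupancy
is averaged over three replicate 200-frame ensembles, mirroring the three
independent trajectories such protocols pool.

## Numerical and degenerate-input policy

* Transforms are validated (orthogonality and det = +1 within 1e-9).
* Distance matrices must be exactly symmetric with a zero diagonal;
  `pairwise_rmsd()` guarantees this by computing i < j only.
* Empty selections, unknown domains/residues, constant melting curves,
  sub-4-point curves, and coordinate magnitudes ≥ 10,000 Å (unwritable in
  fixed PDB columns) raise classed errors, not NA results.
* PDB parsing keeps the first alternate location per atom (warning),
  retains hydrogens flagged by element, and demands identical atom lists
  across models — trajectory semantics, where frame i atom k must be the
  same physical atom everywhere.

## Known limitations

* Selections match residues by (chain, resseq, icode) identity; there is
  no sequence alignment, so cross-protein comparisons (e.g. two different
  receptors) require segment maps that already select matched atom counts
  per helix — `compare_tm_bundles()` documents this contract.
* The Jarvis–Patrick neighbor rule and accretion order of the original
  MD-package implementation are not uniquely documented; both variants
  here are principled readings, neither claims bit-compatibility.
* Melting fits assume a single two-state transition; multi-phasic curves
  will fit poorly (visible in `rss`) rather than being detected.
* mmCIF, binary trajectory formats, per-residue RMSF, DSSP assignment and
  free-energy interpretation of cluster sizes are out of scope.
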