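---
title: "Connectivity hyperalignment: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity hyperalignment: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Category-selective visual topographies are consistent across people at a
coarse scale but idiosyncratic in their fine conformation, so they are
usually mapped per subject with a functional localizer. `chalign`
implements the alternative route: movie-viewing fMRI plus localizers in a
normative sample, movie-viewing alone in a new participant, and functional
alignment to carry the normative localizer data into the new participant's
cortical anatomy. Because the alignment is driven by each vertex's
*connectivity profile* rather than by stimulus-locked responses, the
normative sample and the new participant may have watched different
movies.

## The model

**Geometry.** All subjects share one template sphere per hemisphere: a
subdivided icosahedron (order $k$ has $10\cdot4^k+2$ vertices) with a
cortex mask for the medial wall. Vertices are ordered coarse-first, so an
order-$g$ grid is an index prefix of any finer mesh, and all distances are
exact great-circle arcs on the nominal sphere (radius 100 mm). We chose
the closed-form spherical metric over graph shortest paths because the
meshes are spheres by construction; real template spheres are rescaled to
the nominal radius on import so millimetre radii keep their meaning.
Vertex indices are 1-based throughout, following R convention. Hemispheres
are disjoint meshes: searchlights never span the midline, while
connectivity targets concatenate both hemispheres (left first).

**Connectivity profiles.** Each run of a time series is z-scored per
vertex (population variance); targets are either coarse-grid vertices
carrying the mean time series of an averaging searchlight, or, in `full`
mode, the vertices themselves. The profile entry for seed $s$ and target
$t$ is the Pearson correlation over the concatenated runs, and each seed
row is then normalized to zero mean and unit variance. Degenerate
(constant) seeds or targets produce correlation 0 with a warning rather
than `NaN`, keeping the downstream linear algebra total.

**Alignment.** For each 15 mm searchlight, the orthogonal Procrustes
problem $\min_R \lVert RA - B\rVert_F$ is solved by the SVD of $BA^\top$;
reflections are allowed and no isotropic scaling is fitted, because
transformed data are re-z-scored anyway. Searchlight rotations are summed
into a sparse hemisphere-wide matrix without count normalization: the
resulting per-vertex scale cancels in the z-scoring step, which makes
self-alignment exactly correlation-preserving. Transforms are pairwise
and directional (source brain into target brain); no common model space
is ever constructed.

**Iterative refinement.** Dense connectivity targets on anatomically
aligned data produce poor correspondence, so alignment starts coarse and
sharpens: the canonical six-step schedule uses order-3 grids with 13 mm
averaging searchlights for steps 1–3, order-4 grids with 7 mm for steps
4–5, and vertex-wise targets for step 6, with 15 mm alignment
searchlights at every step. After each step the source movie (working
copy) is transformed and re-z-scored; the target subject's own movie is
never transformed, and its profiles are recomputed per step only because
the grid changes. Whether data should be re-z-scored between steps is not
dictated by the algorithm; we do, so every step sees unit-variance input.
For cross-movie alignment the identical loop runs with the target profile
computed from the target subject's different movie; no within-dataset
pre-alignment precedes the cross-movie pair fit.

**Response hyperalignment (RHA).** The time-locked baseline replaces
profile rows by movie response patterns (vertices × timepoints). It is
only defined when both subjects watched the same movie; mismatched run
lengths raise an error stating that restriction.

**Prediction and evaluation.** Own topographies are means across localizer
runs of unthresholded per-run GLM t maps (ordinary least squares,
HRF-convolved category boxcars, intercept plus Legendre drifts up to
order 2, contrast $+1$ on the target category and $-1/(C-1)$ on each other
category). Predicted topographies average t maps over all source subjects
and runs with equal weight, after projecting either the run time series
(canonical) or the pre-computed t maps (maps are mean-centered over cortex
before each sparse multiplication, with no z-scoring between steps)
through the chains. Identity chains give the anatomical-alignment (AA)
baseline. Evaluation uses whole-map and 15 mm searchlight Pearson
correlations, Cronbach's alpha across runs (runs as items, vertices as
observations, population variances) as the noise ceiling, searchlight
correlation of vectorized profile blocks for connectome similarity, and
paired two-sided t-tests on Fisher-z transformed correlations with
Bonferroni adjustment for method comparisons. The paired t-test is our
choice; the comparison machinery only assumes paired z values.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| nominal sphere radius | 100 | mm | scale of a template cortical sphere, so mm radii behave as on cortex |
| alignment searchlight radius | 15 | mm | canonical local-alignment scale; fixed across iterative steps |
| averaging radius at grid order $g$ | $13\cdot2^{3-g}$ | mm | matches the grid spacing (13 mm at order 3, ~7 mm at order 4) |
| GLM drift order | 2 | – | quadratic run drift |
| HRF | double gamma (6/16/1/1/6, 32 s) | s | canonical shape, peak normalized to 1 |
| contrast weights | $+1$, $-1/(C-1)$ | – | zero-sum "target vs all others"; control categories included in the baseline unless the design marks them excluded |

## The synthetic cohort

The generator plants everything the pipeline must recover, at desk scale.

* **Template**: order-3 meshes, 30° polar-cap medial wall, 20 latent
  components with smooth loading maps and 5 category tuning maps, each a
  sum of 10 spherical Gaussian bumps of 20 mm width.
* **Movies**: latent time courses are AR(1) series (coefficient 0.3,
  unit marginal variance) drawn once per movie and shared by all subjects;
  movies A and B have independent time courses but identical spatial
  loadings — the premise that different movies engage the same fine-scale
  connectivity structure, implemented minimally. 300 timepoints in 3 runs.
* **Localizers**: 4 runs of the 5-category block design (10 blocks of
  18 s per run, two per category, randomized order, TR 2 s).
* **Misalignment**: cortical vertices are partitioned into patches by
  nearest order-2 grid center, and each patch receives an independent
  random orthogonal block — exactly hyperalignment's hypothesis class, so
  ground-truth recovery is well-posed. The blocks are rotations of bounded
  plane angle (matrix exponential of a scaled skew-symmetric matrix,
  largest angle 60° by default) rather than Haar-uniform draws: a
  uniformly random orthogonal block has zero expected overlap with the
  identity, which would scramble all coarse structure, leave
  searchlight-averaged targets with no cross-subject correspondence, and
  make connectivity-based alignment uninformative by construction
  (`max_rotation_deg = Inf` reproduces that regime as a negative
  control). The 60° default is the strongest bound that keeps the planted
  misalignment recoverable by a single full-target CHA step at zero noise
  (the tested recovery property, mean vertex-wise $r \ge 0.95$).
* **Noise**: Gaussian, SD equal to 1.0 × the mean cortical signal SD for
  both movies and localizers (an SNR near 1, typical of vertex-level
  fMRI).
* **Seeding**: every array derives from the master seed through stable
  child seeds hashed from (seed, subject, condition, run), recorded in the
  manifest; regenerating from the manifest is bitwise reproducible.

What passing tests on this cohort do **not** show about real data: the
simulator is favorable-case by design. Real misalignment is not exactly
block-orthogonal or patch-aligned; real noise is temporally autocorrelated
and spatially structured; hemodynamics, motion, and session effects are
absent; and the AA baseline here is weaker than on real brains, where
anatomical alignment already captures much coarse structure. The
qualitative ordering (CHA ≈ RHA > AA, cross-movie ≈ within-movie) is the
claim under test, not the absolute correlation values.

## Numerical choices and degenerate inputs

* Population (divisor $n$) variance everywhere; scale cancels in
  correlations and alpha.
* Closed-ball searchlight membership (ties at exactly the radius are in);
  a vertex's self-distance is forced to exact zero so vanishing radii
  yield singletons.
* SVD sign/tie handling: any valid singular decomposition is accepted for
  rank-deficient Procrustes problems; tests assert optimality and
  orthogonality, never entrywise uniqueness.
* Zero residual variance in the GLM (perfect fit, detected relative to
  the data's scale) produces a signed sentinel t of $\pm10^{10}$ with a
  warning; masked vertices carry `NA`, never 0.
* Whole-map zero variance in `map_pearson()` is an error (a pipeline
  bug), while degenerate searchlight centers yield `NA` (expected local
  degeneracy, excluded from histograms).
* `compare_methods()` on identical paired samples returns statistic 0 and
  $p = 1$; on exactly shifted samples, $p = 0$; $|r| = 1$ is clipped
  before `atanh`.
* Chains compose by sequential application with interleaved z-scoring;
  `collapse_chain()` provides the raw matrix product for inspection only
  and is documented as approximate.

## Problem sizes used by the test suite

Unit tests run on order-1/2 meshes and a 3-subject cohort with shortened
movies. The acceptance-level property tests use the default study
conditions — 10 subjects on order-3 meshes (1284 vertices, 1210 cortical)
with full-length movies — plus a 2-subject noise-free cohort for
planted-rotation recovery and a 5-subject cohort for the 3-step iterative
schedule (orders 2, 3, then vertex-wise). These sizes keep the full suite
within a few minutes on one CPU while leaving every claim at the scale the
generator defines.

## Interfaces

Cohorts (data, ground truth, fitted transforms as sparse triplets per
pair/hemisphere/step, predicted maps, manifest) round-trip bitwise through
a single-file serialized container with a validated schema. GIFTI
import/export (surfaces, masks, per-vertex maps, multi-run data series;
ASCII, Base64Binary and GZipBase64Binary encodings) handles interop with
real surface-based datasets; masks may also be one-column text. Reports
are tibbles with `tidy()`/`glance()` methods, TSV/JSON export, and
`autoplot()` figures. The `chalign` executable chains
simulate/align/predict/evaluate/report from a shell with `key = value`
configs and deterministic seeding.

## Known limitations

* No nuisance regression, prewhitening, or AR noise models in the GLM —
  inputs are assumed preprocessed.
* No common-model-space (two-step) hyperalignment, ridge-regularized or
  non-orthogonal alignment.
* Great-circle distances assume spherical meshes; no support for
  subject-specific folded geometry.
* The synthetic generator's favorable-case assumptions, listed above.
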