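---
title: "Measuring needle-placement accuracy against a nerve target"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring needle-placement accuracy against a nerve target}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

Pulsed radiofrequency (PRF) neuromodulation of the pudendal nerve is only
expected to work when the needle's 5.00 mm active tip ends up within about
5 mm of the nerve. Phantom validation studies of guidance systems therefore
repeat a placement many times, scan each result, segment nerve and needle as
STL surfaces, and quantify the placement error. `needleplace` is that
analysis as a tested, reusable pipeline, plus a synthetic phantom generator
that makes every stage verifiable against known ground truth.

The per-trial model is purely geometric. After rigid registration of the
trial's nerve onto a common reference nerve (and propagation of the same
transform to the needle), the needle shaft is assumed straight and its axis
is fitted by total least squares (the principal axis of the centered cloud).
With axial coordinate $s$ along the unit direction $\hat d$ (hub to tip) and
$s_\max$ at the deepest point, the three accuracy quantities are:

* **Euclidean** $e = \min_{t \in \mathrm{tip},\, n \in \mathrm{nerve}} \lVert t - n \rVert$,
  where the tip is every needle point with $s \ge s_\max - 5.00$ mm;
* **lateral** $l$: the minimal perpendicular distance from nerve points to
  the *infinite* line through the axis (so an undershooting needle still has
  a lateral offset). Its sign is the sign of the dot product of
  (nerve closest point $-$ foot point) with a configured reference vector,
  with positive mapped to "subject's right";
* **depth** $d = s_\mathrm{foot} - s_\max$, where $s_\mathrm{foot}$ is the
  axial coordinate of the orthogonal projection of the nerve's closest point
  onto the axis. Negative depth means the tip went deeper than the target;
  positive means it stopped short.

For a locally straight nerve and a point tip, $e^2 = l^2 + d^2$; the test
suite asserts this identity on noiseless synthetic trials.

## Registration chain

Two alignment layers mirror how such studies are run: a closed-form rigid
Procrustes fit on six named pelvic landmarks (left/right ischial tuberosity,
left/right midpoint of the lateral sacral border, left/right greater
trochanter) and plain point-to-point ICP between dense nerve surface
samples. When per-trial landmarks exist, the Procrustes fit initializes ICP;
otherwise ICP starts from the identity. Reflections are rejected everywhere
(determinant $+1$ enforced): anatomy cannot mirror. The reference frame is
configurable — for synthetic cohorts the unposed generator model, for
measured data a `reference_nerve.stl` or, failing that, the first trial.

A practical limitation surfaced by the synthetic world and worth knowing
about: the nerve surrogate is a smooth circular tube, and point-to-point ICP
on such a surface has a sliding local optimum (translation along / rotation
about the tube axis are nearly free). From an identity initialization, a
5-degree + few-mm perturbation can stall about 0.1 deg / 0.25 mm away from
the true pose; from the landmark initialization the same perturbations are
recovered to machine precision, which is why the landmark layer is the
pipeline default whenever landmarks are available. Real segmented nerves are
irregular and suffer much less from this, but the tests document the
behaviour rather than hide it (no trimming or robust weighting is added: the
method is deliberately plain ICP).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `spacing_mm` | 0.01 | mm | maximum nearest-sample spacing of the deterministic surface sampling; the analysis convention for "consecutive coordinates". Coarser values (0.05–0.2) are used in tests for speed; metric error scales with spacing. |
| `tip_length_mm` | 5.00 | mm | active-tip length of common PRF needles; the tip set is all points in the outermost 5.00 mm (closed interval). |
| `threshold_mm` | 5.00 | mm | PRF effective range; `within_range` uses strict `<` (the boundary is a measure-zero event; inclusivity is a documented convention, not observable in practice). |
| `nerve_reference` | `"surface"` | — | distances to the segmented nerve surface (what an STL measures) or to the centerline (the point-to-line oracle used by the recovery identity). |
| `tip_mode` | `"all"` | — | minimal distance over all tip points (the quoted definition) or the single deepest point (`"extreme"`), kept as a flag because the source definition is ambiguous. |
| `icp_max_iter`, `icp_tol_mm` | 100, 1e-6 | —, mm | plain ICP stopping rule on RMS improvement; the matched-pair RMS is non-increasing by construction and asserted per iteration. |
| `icp_subsample_max` | 50000 | points | deterministic (evenly strided) cap on source points used for correspondences, so registration stays tractable at 0.01 mm sampling. Distances are always computed on full clouds. |
| `quantile_rule` | `"pn1"` | — | quartiles at plotting position $p(n+1)$ (R type 6), the SPSS default, so published (Q1, Q3) pairs are reproducible; `"linear"` (R type 7) selectable. |
| `alpha` | 0.05 | — | normality gate: Wilcoxon if the Shapiro–Wilk p is strictly below `alpha`, one-sample t otherwise. |

## The synthetic world

`synth_config()` states the emulated phantom: a nerve tube 75 mm long and
2 mm in diameter (the copper-wire surrogate used in pelvic phantoms) bent
along a circular arc with a 5 mm default chord deflection (a gently bent
wire; 0 gives a straight one); a 100 mm x 1 mm needle whose axis is placed
along the common perpendicular through the nerve midpoint so the configured
lateral/depth offsets are *exact* by construction; per-trial rigid pose
jitter (default 5 deg / 10 mm, standing in for the per-scan frame); optional
Gaussian surface noise along vertex normals (standing in for
threshold-segmentation boundary error; 0.1 mm is realistic for 0.3 mm
voxels, 0 is the default because the generator's first job is exact
oracles); and six landmarks on an ~190 mm frame. One integer seed fully
determines all randomness, bitwise.

Two modelling choices deserve explanation:

* **Conical needle point.** A flat end cap would make the "deepest needle
  point" a whole disc and the point-tip recovery identity unattainable; a
  short cone (default 2 mm, like a bevel) gives a unique apex vertex which
  the generator reports exactly.
* **Two ground-truth references.** The configured offsets are
  centerline-referenced point-to-line statements ($e = \sqrt{l^2+d^2}$
  exactly, asserted to 1e-9). An STL analysis, however, measures to the
  nerve *surface*, about one tube radius closer. The ground truth therefore
  carries both: the exact centerline values and numeric surface-referenced
  values computed by brute force on the noiseless clouds at
  `truth_spacing_mm`. Acceptance-grade recovery checks use
  `nerve_reference = "centerline"` with `tip_mode = "extreme"`; the default
  surface pipeline is checked against the surface oracle.

What a green synthetic test does **not** establish: anything about CBCT
physics, segmentation thresholds, tracking or display error of a real
guidance system, needle bending, or the distribution of human placements —
the generator's offset distributions are user-set, not calibrated to any
study.

## Numerical and procedural choices

* Surface sampling is a deterministic barycentric grid per triangle
  (subdivision count from the longest edge), so repeated runs are bitwise
  identical and every surface point is provably within the requested
  spacing of a sample; zero-area triangles are skipped with a warning.
* STL is read in both dialects with byte-offset error reporting; binary
  writing stores float32, so round trips are exact only to ~1e-7 relative.
  Units are taken as millimetres verbatim (the CBCT/segmentation
  convention); exact duplicate corner vertices are welded.
* The axis fit refuses clouds whose top two spread eigenvalues are within
  10% (no dominant axis). Which shaft end is the tip is decided by nerve
  proximity of the two extreme points — the only automatic rule consistent
  with an inserted needle whose segmentation may include hub geometry.
* One-sample Wilcoxon: zeros dropped, mid-ranks for ties, exact signed-rank
  distribution when $n \le 15$ without ties, otherwise a normal
  approximation with tie and continuity corrections (the behaviour of the
  mainstream packages these tables come from); the test-suite oracle is an
  independent $2^n$ enumeration. An all-zero sample warns and returns
  $p = 1$ by convention.
* Printed percentages round half up (33/40 becomes 83, not R's
  round-half-even 82); exact fractions are kept in machine output.
* Per-trial failures in a cohort run (malformed STL, ambiguous axis) are
  logged and skipped; the run fails only if no trial succeeds.

## Known limitations

Plain ICP's tube-sliding optimum from uninitialized starts (above); no
deformable registration; the needle is assumed straight; no PRF field or
lesion modelling; no between-subject modelling in the cohort layer (all
trials are pooled, as in the validation design this implements); reproducing
any specific published table additionally requires that study's own STL or
raw-distance data, which this package does not ship.
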