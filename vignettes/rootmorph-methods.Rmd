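---
title: "Quantifying conical root morphology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying conical root morphology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Conical roots — roots that taper sharply from the cervix to the apex —
are a clinically relevant anomaly of the maxillary premolars: a conical
root carries less periodontal ligament, bears occlusal load worse, and is
an adverse prognostic factor in periodontitis. Clinical screening has
historically relied on a subjective reading of 2D periapical radiographs.
`rootmorph` implements the quantitative alternative: measure root length
(RL), root surface area (RSA) and root volume (RV) on 3D surface models
segmented from cone-beam CT, normalise by length (RSA/RL, RV/RL), and use
ROC analysis to turn those indices into an explicit diagnostic rule.

Because the clinical image data behind such studies cannot be
redistributed, the package is organised around a synthetic-data module
that generates tooth meshes and scalar cohorts with known ground truth.
Every downstream stage — morphometry, 2D root-width measurement,
diagnostics, shape atlas — is exercised against analytic or quadrature
oracles rather than against inaccessible patient scans.

## Geometry model

A synthetic tooth is a solid of "elliptical revolution" about the tooth
axis $z$ (apex at $z=-L$, cemento-enamel junction — CEJ — at $z=0$,
mesiodistal $=x$, buccolingual $=y$, all units mm). The cross-section at
height $z$ is an ellipse with semi-axes $a\,g(z)$ and $b\,g(z)$, where

$$g(z) = (1 + z/L)^p, \qquad -L \le z \le 0 .$$

* **Normal roots** use $p = 0.5$: convex, near-parallel-walled cervically.
* **Conical roots** use $p = 1$: a straight taper.

With equal cervical dimensions the conical profile is strictly narrower
at every interior height, which is the defining geometric contrast
between the two classes. The literature describes the conical root only
qualitatively ("narrowed from the cervix to the apex"), so these two
exponents are surrogates chosen to reproduce that qualitative contrast;
no claim is made that real premolar profiles follow a power law.

Two optional features complete the solid: an ellipsoidal **apex cap** of
axial depth `apex_radius` (default 0.3 mm) that rounds the tip and avoids
degenerate triangles, and a half-ellipsoid **crown** of height
`crown_height` (default 6 mm) above the CEJ. Setting both to zero yields
exact cones/paraboloids for closed-form oracle tests.

Default cervical halfwidths (normal 3.6 × 4.8 mm, conical 3.75 × 5.0 mm)
were fixed once so that the quadrature ground truth of a default normal
tooth lands on the reported premolar scale (RV ≈ 315 mm³, RSA ≈ 214 mm²,
RL 11.62 mm); the conical default then gives RV ≈ 27% lower. The real
cohort effect sizes (−12.29% RSA, −19.33% RV) are emulated exactly only
by the *scalar* cohort generator, which draws each parameter from the
published group means and SDs directly; the mesh generator is judged
against its own quadrature ground truth, not against the cohort table.

**Ground truth.** For every profile the package computes the root's
lateral surface area by adaptive 1D quadrature of the parametric surface
integral (the periodic circumferential integral is evaluated by a
720-point trapezoid rule, which is spectrally accurate) and the volume by
quadrature of $\pi a b g(z)^2$. Tests verify the generated mesh converges
to these values (≤ 0.5% at a 200 × 200 resolution) and that both agree
with an independent midpoint-Riemann oracle implemented in the test
helpers with numerical derivatives.

## Morphometry

* **RL** is the Euclidean distance from the apex landmark to the midpoint
  of the buccal–lingual CEJ chord.
* **CEJ plane**: total-least-squares plane through the four CEJ
  landmarks — a deterministic surrogate for manual slice-by-slice
  segmentation.
* **Crown/root split**: `split_by_plane()` subdivides crossing
  triangles, chains the intersection into closed curves, and caps each
  half with a planar fan from the curve centroid. Intersection points are
  computed once per mesh edge, so the conservation identities
  $A_{crown}+A_{root}=A_{tooth}+2\,S_{S1}$ and
  $V_{crown}+V_{root}=V_{tooth}$ hold to floating-point exactness; the
  tests assert 1e−6 relative. Vertices lying exactly on the plane (the
  generated CEJ ring is the common case) are assigned to the positive
  side; the degenerate sub-triangles this creates are dropped after the
  split, which preserves closedness. Planes that touch the surface
  without separating interior volume are rejected as tangent.
* **RSA** uses the closed-object bookkeeping
  $RSA = (S_{MT} + S_{MR} - S_{MC})/2$, which algebraically isolates the
  root's outer surface (the root object's area minus the truncation cap
  $S_{S1}$); the identity is asserted on every split.
* **RV** is the divergence-theorem volume of the closed root object.
  `enclosed_volume()` refuses open or inconsistently oriented meshes
  (naming the open-edge count) rather than returning an undefined number;
  a trivial repair (vertex merge at 1e−6 mm, duplicate-face removal) is
  attempted first by `compute_metrics()`.

Reporting precision is 2 decimals (`format_metrics()`); all internal
computation is double precision.

## The 2D root-width parameter (PRW)

On a periapical silhouette with apex $G$ and mesial/distal CEJ points
$F, E$: $B$ and $C$ are the midpoints of $GF$ and $GE$; the line through
$B$ and $C$ is extended until it crosses the mesial margin at $A$ and the
distal margin at $D$; $PRW = (|AD| - |BC|)/2$. A perfectly straight-sided
(conical) silhouette gives $PRW = 0$ exactly; the parabolic-profile tooth
of width $W$ gives the closed form $(\sqrt{1/2}-1/2)\,W/2$, both of which
are test oracles. If the line crosses a margin more than once the
crossing nearest $B$ (respectively $C$) is taken — real mid-root outlines
are near-convex, so the nearest crossing is the anatomical margin.
Concave margins can produce a small negative PRW; it is reported as
computed rather than clamped, since the construction itself is silent on
that case.

`project_to_radiograph()` produces the silhouette as the convex hull of
the orthographically projected mesh vertices. For every tooth the
generator can produce (power taper $p \le 1$ plus ellipsoidal cap and
crown) the silhouette region is convex, so the hull *is* the silhouette;
for arbitrary non-convex meshes it is only an outer bound — a documented
limitation, acceptable because the operation exists to feed the PRW
construction with generated anatomy.

## Diagnostics

CRT (conical) is the positive class, indicated by *lower* metric values;
the classification rule is strictly `value < cutoff => CRT`, with
boundary values classified NRT.

* **ROC/AUC**: the empirical AUC is computed from ranks as the
  Mann–Whitney probability $P(X_{CRT} < X_{NRT}) + \tfrac12 P(=)$, and
  the trapezoidal area under the returned step curve reproduces it to
  1e−12. Brute-force pairwise enumeration is the test oracle for all
  small groups.
* **Youden cut-off**: exhaustive maximisation of $YI = Se + Sp - 1$ over
  midpoints between adjacent distinct pooled values plus $\pm\infty$;
  ties resolve to the smallest qualifying cut-off (favouring sensitivity
  under the `<` rule). Candidate midpoints make the result independent of
  sample ordering.
* **2×2 metrics**: standard definitions; any metric with a zero
  denominator is `NA` (flagged missing), never silently 0.
* **Sample size**: $n_1 = \lceil \frac{k+1}{k}
  ((z_{\alpha/2}+z_\beta)\sigma/\delta)^2 \rceil$, $n_2 = \lceil k n_1
  \rceil$, floored at 2 per group; with $k = 0.75$ the published 54/41
  pairing is reproduced.
* **ICC**: ICC(2,1), two-way random effects, absolute agreement, single
  measure. The reliability literature behind the workflow does not name
  its ICC model; ICC(2,1) is the conservative conventional choice for
  test–retest agreement of a single rater, and is recorded here as a
  design decision.
* **Group comparison**: classical equal-variance t-test (the named
  "group t-test") with Welch behind a flag, plus the Mann–Whitney
  rank-sum test. These two are delegated to `stats`; the ROC/Youden layer
  is implemented in the package and oracle-tested.

A deliberate caveat: on synthetic binormal cohorts the *expected*
Youden cut-off is the equal-density crossing of the two normals
(≈ 19.3 for RSA/RL), not the empirically published 19.61, which is a
property of the original sample. Tests therefore check cut-off recovery
against the enumeration oracle and AUC recovery against the binormal
expectation, never against the empirical cut-offs.

## Shape atlas

Registration is landmark-based orthogonal Procrustes (Kabsch) without
scaling or reflection — absolute millimetre differences are the result of
interest, so scale must be preserved. Dense ICP was considered and left
out: with six anatomically corresponding landmarks the closed-form fit is
deterministic, and the tests show residual RMS within 3× the landmark
noise. The mean model matches each template vertex to its closest surface
point on every mesh (an Rcpp kernel) and averages; this makes averaging
copies of a mesh exactly idempotent and the result order-invariant.

The colour map assigns each reference vertex the distance to the model
surface, signed along the reference's angle-weighted outward vertex
pseudo-normals (positive = model outside the reference). Colours follow a
piecewise-linear blue–green–red ramp clamped at ±1.145 mm — the
standardised display bound used in the source imaging workflow; its
provenance is not documented there, so it is treated as a fixed display
constant, adjustable via the `bound` argument.

## What a green test establishes — and what it does not

The synthetic world states: two power-law taper classes; independent
per-parameter normal cohorts at the published means/SDs with n = 54/41;
landmark noise at 0.05 mm where noise is modelled. It does **not**
emulate CBCT voxelisation, beam hardening, manual contouring error at
0.3 mm slice spacing, cross-parameter correlation (available but off by
default), or multi-root anatomy. Green tests therefore establish that
the *computational pipeline* is correct against its stated geometry and
statistics, not that the published empirical cut-offs would reproduce on
new clinical material.

## Numerical choices

* Plane-side classification tolerance: 1e−9 × coordinate scale; on-plane
  vertices go to the positive side.
* Quadrature: `stats::integrate` at rel.tol 1e−9 per smooth profile
  region (apex cap / root / crown are integrated separately to keep the
  integrand smooth).
* Procrustes degeneracy: collinear landmarks are rejected when the
  second singular value falls below 1e−9 of the first.
* Youden ties: smallest cut-off; boundary classification: NRT.
* RNG: single seed per run; per-tooth child seeds are derived
  deterministically and kept below 2^31.

## Known limitations

* Silhouettes are convex hulls (see above).
* The cap fan assumes near-convex intersection curves; strongly
  non-convex cuts of pathological meshes would make the fan self-overlap
  (the area bookkeeping remains exact for the convex single-root case the
  pipeline targets).
* Closest-point queries are brute force O(points × faces); adequate for
  the mesh sizes used here, no spatial index.
* No DICOM/voxel input: meshes arrive as STL, matching the scope of the
  surface-based analysis.
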