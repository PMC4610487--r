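---
title: "Depth-camera fall detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-camera fall detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`depthfall` detects falls of a single person from sequences of depth images:
per-pixel range maps in millimetres, with 0 as the "no return" sentinel, as
produced by Kinect-class structured-light sensors. This vignette explains the
statistical models in the pipeline, the parameters that matter, what the
synthetic-scene generator does and does not emulate, and the design decisions
taken where the method left genuine freedom.

## 1. The pipeline

A monitored scene passes through five stages:

1. a **single-Gaussian background model** per pixel, fitted on subject-free
   frames and updated adaptively;
2. **silhouette extraction** by a 2.5σ deviation test, followed by
   morphological cleaning;
3. **head localization** in the first subject frame by a three-ellipse
   foreground coefficient;
4. **dense spatio-temporal context (STC) tracking** of the head through all
   later frames;
5. a **floor-plane height decision**: the tracked head's height above a
   least-squares floor plane is compared against an adaptive threshold, with
   the body-centroid height as a lazily evaluated second judgment.

The stages are exposed individually (`fit_background()`,
`extract_silhouette()`, `locate_head()`, `track_step()`, `fit_plane()`,
`fall_step()`, ...) and orchestrated by `run_pipeline()`.

## 2. Background model and silhouette

Each pixel is modelled as `N(μ, σ²)` over `n_fit` background frames
(default 40). Invalid (zero) observations are excluded per pixel; a pixel
with no valid observation is permanently invalid and never classified
foreground — depth holes would otherwise become phantom subjects. σ is the
square root of the mean squared deviation, floored at `sigma_min` (default
10 mm, roughly the sensor's depth quantization at 2 m) so the silhouette
threshold cannot collapse to zero on noiseless input.

A valid pixel is foreground iff `|F − μ| > 2.5 σ`. For a Gaussian background
pixel the retention probability is

```{r}
pnorm(2.5) - pnorm(-2.5)   # 0.9875807, i.e. 98.76%
```

so roughly 1.24% of background pixels flicker foreground each frame; the
morphological opening and largest-component rule in `clean_mask()` remove
them. Equality `|F − μ| = 2.5σ` classifies background (both branches of the
rule are strict inequalities, so a tie-break is needed; background is the
conservative choice). After classification, background pixels are blended
(`μ ← (1−α)μ + αF`, variance updated recursively with rate β against the new
mean, defaults α = β = 0.05) and foreground pixels are frozen so the subject
never melts into the model.

`clean_mask()` (3×3 opening, 3×3 closing, keep the largest 8-connected
component if its area ≥ `min_area_px`, default 200 px at 320×240) is
plumbing around the model: a person at indoor range occupies thousands of
pixels, so the rule only discards noise and fragments.

## 3. Head localization

The head is found once, in the first frame with a non-empty cleaned
silhouette, by maximizing the foreground coefficient of three concentric
ellipses (central `a, b`; inner 3/4 scale; outer 5/4 scale). Forty normal
segments run from the inner to the outer ellipse; for each, `D` is half the
segment length (= a quarter of the local central-ellipse radius) and `d` the
distance from the central point to the silhouette boundary crossing, clamped
to `D` when the segment sees no crossing. The score is
`C = mean((D − d)/D) ∈ [0, 1]`, maximal when the boundary lies on the
central ellipse everywhere.

The search enumerates centres on a stride-2 grid over foreground pixels in
the top of the silhouette — the top 40% of its bounding box, but never a
shallower band than the largest candidate radius, so an isolated head-sized
blob keeps its own centre inside the band. Semi-axis `a` steps through
`radius_min_px..radius_max_px` (defaults 5–14, covering heads at 2–5 m with
the default intrinsics) with aspect ratios `b/a ∈ {1.0, 1.2, 1.3}` and
orientation fixed at 0: silhouette heads are near-vertical ellipses in every
pre-fall frame, which is the only place the locator runs.

**Acceptance threshold.** Two unavoidable effects cap the score of a
*correct* fit on real silhouettes: pixel rasterization puts the observed
boundary up to half a pixel from the true ellipse, costing about `D/8` per
normal (with `D ≈ 2` px for a 8-px head this is ~0.12), and the lower arc of
a real head merges into the shoulders, so its normals see no crossing and
contribute 0. A perfect head-and-shoulders fit therefore scores ≈ 0.5–0.55
(an isolated disk ≈ 0.85), while headless convex blobs stay below ≈ 0.3.
The default `min_score` is 0.4: comfortably above the headless regime,
tolerant of sensor noise around the head-and-shoulders optimum.

## 4. STC tracking

The tracker learns, in the frequency domain, a spatial-context filter
relating the head to the depth values of its surrounding window:

* **context prior** `P = I · ω_σ`: window depth normalized to zero mean/unit
  deviation over valid pixels (raw depth has arbitrary offset; normalization
  conditions the spectral division), times a Gaussian distance weight with
  scale `sigma_w` normalized to sum 1;
* **confidence target** `c(x) = exp(−(|x − x*|/α_c)^β_c)`, defaults
  `α_c = 2.25`, `β_c = 1` — sharply peaked at the target with a
  heavier-than-Gaussian tail;
* **learning** solves `c = h ⊛ P` by conjugate-regularized spectral division
  `H = F(c)·Conj(F(P)) / (|F(P)|² + λ)`, default `λ = 1e-3`. The plain form
  `F(c)/(F(P)+λ)` is identical as `λ → 0` but unstable in practice: smooth
  depth windows have near-zero high-frequency content, and dividing by it
  amplifies the phase mismatch of a shifted target until the argmax lands on
  window corners. The conjugate form keeps the denominator real and
  positive and degrades to a matched filter where the context spectrum
  vanishes;
* **tracking**: the confidence map over the window around the previous
  centre is `IFFT(H · F(P_new))`; its argmax (ties: smallest row, then
  column; integer grid, no sub-pixel refinement — downstream heights are
  histogram-based and insensitive to sub-pixel shifts) is the new centre,
  after which the filter is relearned and blended with rate `ρ = 0.075`.

The window side is `context_scale` (default 4) times the head bounding box,
odd-rounded; `sigma_w` defaults to half the head semi-axis. The tracking
scale is frozen at initialization.

**Known limitation — scale change.** When the subject falls *toward* the
camera (anterior), the head's pixel radius grows (≈ 7 → 13 px in the
benchmark) while its depth contrast against the nearby floor collapses; in
the last few, fastest frames the frozen-scale filter prefers the static
feet/legs pattern inside the window and the centre sticks there. Larger
weight scales and faster temporal rates do not fix this (verified up to
`sigma_w_scale = 3` and `ρ = 1`): it is a scale problem, not a lag problem.
Falls in that orientation are still *detected* — by then the head height is
already far below the threshold — but tracked-centre accuracy guarantees
hold only under the tracker's operating assumptions: per-frame motion below
a quarter of the context window *and* near-constant target scale. The
tracking-accuracy checks in the test suite condition on exactly those
assumptions (walk plus left/right/posterior falls); scale-adaptive tracking
is out of scope.

## 5. Floor plane and heights

Back-projection uses the pinhole model (`X = (u−cx)d/fx`, `Y = (v−cy)d/fy`,
`Z = d`; camera at the origin, Y down, millimetres). Intrinsics are
configuration, not constants — depth cameras vary; the defaults
(`fx = fy = 285.6`, principal point at the image centre of 320×240) are
Kinect-v1 depth intrinsics halved, and the synthetic scenes use the same
values so tests are self-consistent.

The floor is `AX + BY + CZ = 1`, least-squares fitted (normal equations) to
the back-projected valid pixels of a *user-designated* polygon on the
background mean-depth map. The "= 1" form excludes planes through the
camera origin, which cannot be a visible floor. The residual
`|AX + BY + CZ − 1|` is dimensionless (A, B, C carry 1/mm), so the inlier
bound 0.05 transfers unchanged across unit choices. The ROI *defines* the
reference surface: a region placed on a wall yields heights measured from
that wall — intended behaviour, documented rather than guarded. Fitting is
a single pass; no robust refitting (plain least squares over thousands of
ROI pixels is the method's robustness argument against 3-point plane
solutions).

Heights use `H = |AX + BY + CZ − 1|/√(A² + B² + C²)`. The depth entering a
height is not a single pixel read but `representative_depth()`: a histogram
of the region's valid depths at 10 mm bins, a Gaussian fitted around the
modal bin (±200 mm window), one 2σ-trim re-estimation pass, and the fitted
mean — robust to background leakage into the head box and to dropout noise.
Bin width, window and trim count are implementation choices: 10 mm matches
sensor quantization at range, ±200 mm spans a head while excluding
background at typical contrasts, and one trim pass is enough for the ≤ 10%
contamination seen in the box regions.

## 6. The fall decision

`threshold = 0.25 × H_head¹`, a quarter of the *first* computed head height,
fixed for the rest of the sequence; it adapts the decision to subjects of
different statures. The head height is compared every frame; only when it is
below the threshold is the centroid height computed (the `fall_step()`
contract takes a deferred provider and the pipeline counts its invocations,
so this laziness is testable), and both must be below the *same* threshold
simultaneously — no second threshold is ever defined. The centroid is the
binary first moment of the cleaned silhouette, back-projected at the
representative depth of the whole silhouette. `debounce` (default 1)
requires that many consecutive qualifying frames; the single-frame default
implements "both below at the same time", and noisy deployments can raise
it. A declared fall is absorbing within a sequence; re-entry and
re-initialization are out of scope.

## 7. The synthetic scene generator

`render_background()` / `render_activity()` z-buffer render a camera at
1.2 m height with a 12.5° downward tilt viewing a floor and a back wall at
6 m, and a humanoid of two primitives — an ellipsoid head (semi-axes
90/90/110 mm, centre at 1600 mm standing) overlapping a box torso/legs
(400 × 250 × 1520 mm) — standing ~3.6 m from the camera. The primitives give
exact analytic ground truth (head centre, body centroid, heights, floor
mask) every frame. Falls rotate the body rigidly about a pivot at the feet
toward one of four orientations (anterior = toward the camera, posterior,
left, right) with an accelerating `θ(s) = θ_end s²` profile (gravity), over
40 frames ≈ 1.3 s at 30 fps; the completion frame (rest angle, head resting
at its own radius) is the ground-truth fall frame. Walking translates the
subject laterally 1.2 m across the sequence; sitting lowers the body to
66% of standing height with the same easing.

Sensor emulation is first-order: additive Gaussian depth noise (default
σ = 10 mm), i.i.d. invalid dropouts (default 1%), integer quantization to
1 mm, and a 10 m range cutoff. Real sensors additionally show
depth-dependent noise, correlated speckle, edge dropout around silhouettes
and motion blur; none of these are modelled. Passing tests on these scenes
therefore validates the *algorithmic* pipeline — geometry, statistics,
decision logic — not robustness to every sensor artefact. Geometry defaults
were chosen once so that all scripted poses stay inside the frustum (the
renderer errors on "subject leaves frame"): the standing head needs the top
of the field of view, the fallen anterior head the bottom.

Benchmark sequences are 150 frames (40-frame pre-fitted background block,
~1.3 s fall starting at frame 40), six sequences per seed: four fall
orientations plus walk and sit controls. These sizes keep a full benchmark
run around two minutes in a single process while matching the scale of the
original experiments; all are arguments.

## 8. Numerical choices and degenerate inputs

* Equality at the silhouette threshold → background; equality at the floor
  inlier bound → outlier (both rules are strict).
* `fit_plane()` rejects rank-deficient designs (`rcond < 1e-14`): collinear
  points or planes through the origin.
* `foreground_coefficient()` samples each normal at ≈ 0.25 px steps and
  places crossings at sample midpoints; no-crossing normals contribute 0
  (clamped `d = D`), keeping `C ∈ [0, 1]`.
* Frequency-domain and spatial-domain tracker pathways agree to ~1e-15;
  argmax ties break to the smallest row, then column, for determinism.
* Empty silhouettes after subject entry are recorded as gaps; the tracker
  still steps (its context window needs no mask). Head boxes without enough
  valid depth skip the frame's decision with a warning.
* All randomness in the generator flows from explicit seeds; identical
  seeds reproduce frames bit-for-bit, and the caller's RNG state is
  restored.

## 9. Limitations

Single subject, single episode, fixed tracking scale (see §4), first-order
noise model (see §7), no re-detection after tracking loss, no posture
classification, and heights are only as good as the designated floor ROI.
The 16-bit PNG frame format and the raw stack format are the only
interchange formats; RGB streams are ignored by design — the method is
depth-only.
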