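---
title: "Cortical thickness mapping and morphometry for focal cortical dysplasia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortical thickness mapping and morphometry for focal cortical dysplasia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(fcdmap)
```

`fcdmap` detects circumscribed cortical thinning — the morphometric
signature of focal cortical dysplasia — in traced 2D histological sections,
and characterizes flagged tissue by neuronal morphometry. This vignette is
the package's methods account: the models, their assumptions, the numerical
choices, and what the synthetic validation does and does not establish.

## 1. Laplacian cortical thickness

### Model

The cortical ribbon of a 2D section is the region between two manually
traced curves: the pial boundary (outer) and the grey/white boundary
(inner). Thickness defined by nearest-point distance is ambiguous in curved,
folded cortex. The electrostatic definition removes the ambiguity: solve

$$\nabla^2 \varphi = 0 \quad \text{in the ribbon}, \qquad
\varphi = +1 \text{ (inner)}, \quad \varphi = -1 \text{ (outer)},$$

and define field lines as curves everywhere parallel to $\nabla\varphi$.
Each interior point lies on exactly one field line running from one boundary
to the other; field lines never cross; the thickness $t$ at a point is the
length of its field line. $t$ and the signed curvature $\kappa$ are sampled
on the mid-cortical equipotential $\varphi = 0$, the natural "medial
surface" of the ribbon. The $\pm 1$ "volt" boundary values are dimensionless
potentials; all geometric outputs are in micrometres via the pixel size,
which is always an explicit input.

### Discretization and numerics

* **Rasterization** (`rasterize_ribbon()`): pixels between the contours are
  labelled grey; rim pixels lying on a contour become Dirichlet boundary
  pixels assigned to the nearer contour. Rim pixels far from both contours —
  the open cut ends of a gyral band — stay grey and receive a zero-flux
  condition, i.e. the cut edge is treated as insulating.
* **Solve** (`solve_laplace()`): 5-point stencil, sparse direct solve of the
  interior system (sections are 2D, so direct solves are cheap and exactly
  reproducible); the residual of the discrete Laplacian is verified against
  the tolerance (default 1e-6). Because boundary pixel *centres* are up to
  about a pixel away from the true contour, nodal $\pm 1$ values incur an
  $O(h)$ error (about 0.035 in $\varphi$ on the annulus benchmark). The
  default `boundary = "subpixel"` therefore runs a second pass that moves
  each boundary value from $\pm 1$ to $\pm(1 - d\,\lvert\nabla\varphi\rvert)$,
  where $d$ is the pixel-centre-to-contour distance — the value the harmonic
  solution itself takes at the pixel centre. This restores near-$O(h^2)$
  accuracy (the same benchmark drops to ~0.015) while the $\pm 1$ levels are
  attained on the traced contour, where they belong. `boundary = "nodal"`
  gives the plain scheme.
* **Field lines** (`trace_field_line()`): 4th-order Runge–Kutta on the
  bilinearly interpolated, normalized gradient, fixed step 0.25 px. A trace
  terminates when its estimated remaining distance to the target level set,
  $(1 - |\varphi|)/\lvert\nabla\varphi\rvert$, falls below one grid unit, or
  when a step makes almost no potential progress (the signature of entering
  a degenerate rim cell where interpolation plateaus). The final segment is
  then the *exact* distance from the stopping point to the traced contour
  polyline — the tracer finishes on the geometry the anatomist drew, not on
  an extrapolation. On the annulus benchmark every midline thickness sample
  is within 0.1% of the analytic value; the acceptance tolerance is 2%.
* **Midline** (`midline_profile()`): marching squares on $\varphi = 0$ with
  linear interpolation (`grDevices::contourLines`), pieces ordered by
  connectivity and oriented deterministically (ascending x), resampled at a
  regular arc step. Open pieces can be end-trimmed (`trim_um`): within
  roughly one cortical width of a cut edge, field lines run into the
  insulating end face and thickness is not meaningful there.
* **Curvature** (`curvature()`): algebraic (Kasa) circle fit over a sliding
  window of fixed arc length, default 2 mm — window smoothing suppresses
  rasterization noise; the estimator is exact on circles (verified to 5%
  down to the benchmark radius). The sign is anatomical: positive where the
  midline is convex toward the pial side (gyral crest), negative in sulcal
  fundi, derived from $-\nabla\varphi$ as the outward direction. This
  estimator is a documented package choice; nothing deeper than "circular
  arc over a fixed window" is assumed anywhere downstream.

## 2. Stereotaxic positioning and matching

Slides are placed on a normalized anterior–posterior axis anchored at three
landmarks: frontal pole $y = +73$ mm, anterior commissure $y = 0$, occipital
pole $y = -106$ mm. Intermediate slides interpolate **linearly in slide
index** between landmarks — only landmark anchors are available, so
index-linear interpolation is the choice here, with the nominal 1.2 mm
physical spacing used as a consistency warning (deviation > 25%). Case
slides pair with the nearest-$y$ control slide; pairs farther than `max_dy`
(default 1.2 mm, one inter-slide spacing) are dropped; nearest ties break
toward the more anterior slide so output is deterministic.

## 3. Fence-based screening

### The adjusted boxplot

Thickness samples within a slide are not symmetric, so Tukey's 1.5 IQR rule
misflags skewed samples. The screening uses medcouple-adjusted fences: with
MC the medcouple and IQR $= q_3 - q_1$,

$$\text{MC} \ge 0: \quad [\,q_1 - 1.5\,e^{-4\text{MC}}\,\text{IQR},\;
q_3 + 1.5\,e^{3\text{MC}}\,\text{IQR}\,]$$
$$\text{MC} < 0: \quad [\,q_1 - 1.5\,e^{-3\text{MC}}\,\text{IQR},\;
q_3 + 1.5\,e^{4\text{MC}}\,\text{IQR}\,]$$

At MC $= 0$ this is exactly Tukey's rule. The medcouple is computed by the
full $O(n^2)$ kernel (midline samples number in the hundreds to thousands;
fast $O(n\log n)$ algorithms buy nothing here), with the standard
$-1/0/+1$ tie rule at the median. Quantiles are type-7 (linear
interpolation) — stated because fence values depend on the quantile
definition. Plain Tukey fences remain available (`variant = "tukey"`) for
sensitivity analysis.

Fences are estimated **per matched control slide**, never pooled per brain:
the sampling distribution of $t$ in *that* control section defines "too
thin" for *that* case section. Runs of case midline samples below the lower
fence become candidate regions; runs shorter than `min_len_um` (default
1 mm, the field-line reporting interval) are discarded as noise. How
below-fence samples merge into regions is an explicit knob, not a
reconstruction of any particular convention.

### What the phantom calibration shows — and its limits

The screening stage is validated on twin ribbon phantoms
(`make_phantom_pair()`): a randomized sinusoidal gyral ribbon (2.5 mm
baseline thickness; smooth ±0.1 mm within-slide variation composed of two
incommensurate short-wavelength sinusoids; 100 µm/px) and an identical twin
with one implanted focus (default: multiplier 0.7 over 4 mm, with 0.5 mm
cosine tapers). Recovery is scored by interval Jaccard overlap against the
full support of the perturbation (focus plus tapers — the tapered shoulders
are genuinely thinned tissue). Under these conditions the fence rule detects
the focus at Jaccard ≥ 0.8 in well over 90% of seeded phantoms, and flags
under 5% (empirically ≤ 3%) of arc length on null twins differing only
by 20 µm i.i.d. measurement noise — flagged arc counted by the screening
rule's own 1 mm region-length floor, so isolated single-sample noise dips
do not count as flagged regions.

Two design notes, both deliberate:

* The ±0.1 mm variation is the regime this phantom probes. A fence rule is
  a *distributional* screen: if genuine within-slide spread approaches the
  contrast of the lesion itself (a 0.7× focus removes ~0.75 mm), no fence
  threshold can separate them. Real sections carry larger physiological
  variation — which case and control share; the phantom isolates the rule's
  sensitivity floor rather than claiming field performance.
* The variation uses several spatial periods per slide. On long-wavelength
  (trending or U-shaped) thickness samples the medcouple is unstable — MC
  can swing to ±0.4 and the exponential fence factor then moves the lower
  fence by a factor of 3. That instability is a property of the adjusted
  boxplot on bimodal samples worth knowing about when interpreting real
  slides, and it is why the phantom's variation is chosen unimodal.

Cohort summaries reproduce the two standard displays: mean $t$ per slide
against stereotaxic position, and the case-minus-control thickness
difference binned on a position × curvature grid (bins below a minimum
per-group count are masked).

## 4. Neuron segmentation

Three deterministic steps (`segment_neurons()`):

1. **GGMRF relaxation** (`ggmrf_relax()`): MAP estimate of a generalized
   Gauss–Markov random field — minimize
   $\sum_i (x_i - y_i)^2/2\sigma^2 + \beta\sum_{(i,j)\in N_8} |x_i - x_j|^p$
   by checkerboard coordinate descent with damped Newton updates (the
   energy is convex for $p > 1$; iterations that fail to decrease it are
   step-halved, so the "never hard failure" contract holds). Defaults:
   $p = 1.5$, $\beta = 1$, $\sigma$ from a robust MAD of the
   Laplacian-filtered image. $p$ near 1 preserves step edges dramatically
   better than $p = 2$ (the benchmark ratio of preserved edge gradients is
   about 10:1); all parameters are exposed because no canonical values
   exist for this material.
2. **Marker-controlled watershed** (`watershed_initial()`): markers are
   regional minima of the Gaussian-smoothed relief surviving an h-minima
   filter (grayscale reconstruction-by-erosion, depth 10 on an 8-bit
   scale); markers closer than `min_sep_px` merge; background is everything
   above the global intermeans threshold. Foreground pixels are assigned to
   markers by seeded growing on the intensity relief (EBImage `propagate`
   with small regularization), so touching cells split along the saddle
   ridge between their minima.
3. **Per-object refinement** (`refine_object()`): within the object's
   dilated bounding window, scan 256 threshold levels, locate the
   intermeans fixed points (threshold = midpoint of the induced
   foreground/background means) and keep the fixed point with the largest
   mean separation $|\mu_{fg} - \mu_{bg}|$. A literal unconstrained
   maximization of the mean gap degenerates on noisy unimodal windows (the
   gap is maximized by splitting off a handful of extreme pixels), which is
   why the search is over intermeans fixed points — the refinement the gap
   criterion is meant to express. Windows without an interior fixed point
   fall back to the initial region with a warning. Refinement is idempotent
   to within 1% of object pixels.

Polarity is dark-on-light (gallocyanine/Nissl); an `invert` flag flips it.
Objects below `min_area_um2` (default 10 µm², well under any soma at
0.74 µm/px) are removed. On simulated fields of 50 disjoint noisy cells the
pipeline recovers 50 ± 2 objects with mean Dice ≥ 0.85 (empirically ~0.97)
across seeds.

## 5. Boolean germ-grain model and granulometry

### Method of densities

A stationary, isotropic Boolean model with convex grains is characterized
by germ intensity $\lambda$, mean grain area $\bar A$ and mean grain
perimeter $\bar U$, linked to the observable densities by

$$A_A = 1 - e^{-\lambda\bar A},\qquad
L_A = \lambda\bar U\,e^{-\lambda\bar A},\qquad
\chi_A = e^{-\lambda\bar A}\!\left(\lambda - \frac{\lambda^2\bar U^2}{4\pi}\right).$$

These close in sequence:
$\lambda = \chi_A/(1-A_A) + \left(L_A/(1-A_A)\right)^2/4\pi$, then $\bar U$,
then $\bar A$ — no root finding is required. A strongly negative Euler
density can drive $\lambda$ non-positive; that is reported as an infeasible
fit (with sparse-limit diagnostics) rather than silently clipped.

### Measurement conventions (they matter)

* **Boundary length** — sub-pixel marching-squares contour length, not
  pixel-edge counting (which overestimates by up to $4/\pi$). The contour
  is taken on the raw binary mask: Gaussian pre-smoothing removes the
  residual ~10% staircase bias on isolated discs but erases real boundary
  where grains fuse, a worse trade at the densities of interest.
* **Euler characteristic** — bit-quad counts, **4-connected foreground** by
  default. In rasterized unions of smooth convex grains, diagonal-only
  pixel contacts are nearly always grains that do *not* touch in the
  continuum; the 8-connected count consequently runs ~40% low on dense disc
  fields and propagates directly into $\lambda$. The 4-connected count
  compensates exactly that artifact; `connectivity = 8` is available.
* **Edge effects** — germs are simulated on a window dilated by the maximal
  grain radius (minus-sampling-compatible edge correction), and
  `edge_margin` optionally erodes the measurement window.

With these conventions, all three parameters are recovered within 10%
(empirically within ~6%) of simulation truth at $\lambda = 0.005$/px²,
radius-6 discs, 1000² windows, averaged over 10 seeds.

### Granulometry

The pattern spectrum sieves the mask through disc openings of increasing
radius (default 0.74 µm steps — one pixel at the high-resolution scale — up
to 30 µm) and records the area each size band removes. The opening at
radius $r$ is computed as the union of inscribed discs via the Euclidean
distance transform, with a half-pixel tolerance on the inscribed-disc
criterion. The tolerance matters: rasterized discs of similar radii are not
nested, so erosion-based openings shave a ring of boundary pixels at
*every* size — on a 5 µm disc at 0.74 µm/px, over 20% of the area leaks
into small bins that way, while the tolerant inscribed-disc openings keep
it whole and remove it exactly one size step past its radius. Two exactness
guarantees remain: openings are forced monotone (each intersected with its
predecessor), so the sieving axiom holds; and the final band collects
everything the largest element leaves, so the spectrum sums *exactly* to
the foreground area. The same disc rasterization is used for stamping
simulated grains and for the structuring elements, so monodisperse fixtures
land in exactly the expected band. The spectrum's modal size is the summary used for group contrasts: a
downward modal shift indicates smaller stained objects, and simulated
radius-6 vs radius-5 fields reproduce it.

Per-lamina analysis takes explicit lamina bands as transverse row
intervals. How laminae are delineated is out of scope; equipotential-depth
quantile bands can serve as a clearly labelled surrogate when no annotation
exists.

## 6. Inter-rater agreement

Gwet's AC1 with pixels as items and {grey, not-grey} as categories:
$AC_1 = (P_a - P_e)/(1 - P_e)$ with
$P_e = \tfrac{1}{K-1}\sum_k q_k(1-q_k)$, $q_k$ the mean marginal proportion
of category $k$. Unlike Cohen's κ, AC1 does not collapse under the extreme
prevalence imbalance of cortical masks (background dominates). The unit of
agreement (pixels vs boundary points) is a package choice, recorded here.
Only the pairwise coefficient is implemented; multi-rater sets report every
pairwise AC1 and their mean, labelled as such, because pooling conventions
differ and an explicit table is unambiguous.

## 7. Synthetic data: what passing does and does not show

The phantoms carry their ground truth alongside the rendered geometry; no
analysis stage reads the truth. They are emitted in the same contour-CSV /
TIFF formats the pipeline reads, so tests exercise the I/O layer too. All
randomness flows through a single seeded generator per call; the same seed
reproduces any phantom bit for bit.

What the phantoms deliberately do **not** emulate: Nissl texture, laminar
cytoarchitecture, blood vessels, tissue artifacts (tears, folds), tracing
error beyond i.i.d. pixel flips, or 3D effects (the method is strictly
per-2D-section). Passing the validation therefore establishes correctness
of the *computation* — the PDE solve, the integrators, the estimators, the
robust statistics — under controlled conditions, not field performance on
stained tissue.

## 8. Problem sizes and defaults

The validation experiments run at: annulus 40/70 px (≈150² grid, ~10k
interior unknowns); 50 phantom pairs of ~700 px ribbons for focus recovery
and 50 null twins; 10 Boolean simulations at 1000²; 10 cell fields at 400²
with 50 cells. Together these complete in a few minutes on one core —
sizes chosen so the full suite runs routinely, while each remains large
enough that the measured quantities are statistically stable.

Key defaults, with units: grid spacing 1 px; solver tolerance 1e-6;
RK step 0.25 px; midline sample step 1 mm (250 µm in the recovery
experiment, where interval Jaccard needs resolution well below the 4 mm
focus); curvature window 2 mm; fence floor n ≥ 8; minimum region 1 mm;
matching radius 1.2 mm; GGMRF p 1.5, β 1; h-minima depth 10 (8-bit scale);
minimum object area 10 µm²; SE radii 0–30 µm in 0.74 µm steps.

## 9. Known limitations

* Thickness near open cut edges of a traced ribbon is ill-defined
  (insulating-boundary artifact); end-trimming is available and used in the
  validation experiments.
* The medcouple destabilizes on strongly bimodal thickness samples (§3);
  inspect MC when a slide's fences look extreme.
* The Boolean inversion assumes stationarity, isotropy and convex grains;
  heavy anisotropy or clustering of somata violates it. The sparse-limit
  diagnostic and the infeasible-fit error are the guard rails.
* The $O(n^2)$ medcouple holds ~10⁸ kernel values at n = 10⁴ midline
  samples; subsample first if profiles grow beyond that.
* Lamina bands must be supplied; the package does not segment laminae.
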