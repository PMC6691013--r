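---
title: "Quantification methods for stromal remodeling and biosensor imaging assays"
author: "stromaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods for stromal remodeling and biosensor imaging assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromaquant)
```

# Scope

Studies of cancer-associated fibroblasts (CAFs) in pancreatic cancer lean on
a recurring set of quantification stages: FLIM-FRET biosensor readouts of
drug response, texture and coverage statistics of the remodeled collagen
matrix, chromogen optical density in stained sections, scoring of 3D
organotypic invasion, contact-mechanics fits of matrix stiffness, and a thin
layer of planning and multiple-comparison statistics. `stromaquant`
implements each stage as a small, testable function, and pairs every stage
with a seeded synthetic-data generator that carries its ground truth, so the
whole pipeline can be validated end to end without raw microscopy or
instrument files. The `analysis/` scripts in the repository run each stage
over generated study conditions and write their tables under `results/`.

# FLIM-FRET lifetime fitting and the CDK1 classifier

## Model

Time-correlated single-photon counting yields, per pixel, a histogram of
photon arrival times. We model it as a single-exponential decay over a
constant offset,
$$\mu_i = A\,e^{-t_i/\tau} + B,$$
and estimate $(A, \tau, B)$ by maximizing the Poisson likelihood of the
binned counts. At the acquisition budget this pipeline targets (500
photons/pixel) least squares is noticeably miscalibrated for low-count tail
bins, while the Poisson MLE is not; a log-linear regression on the positive
bins supplies the starting point. The default time axis is 64 bins over a
12.5 ns window, the period of an 80 MHz pulsed source.

Numerical choices:

* **Fit window.** Fitting starts at the bin after the count peak
  (`fit_start = "auto"`). No instrument response function is modeled or
  deconvolved; the tail of a mono-exponential convolved with a narrow IRF is
  itself mono-exponential to good approximation, and inventing an IRF the
  acquisition does not document would add an unverifiable component.
* **Background term.** $B \ge 0$ is fitted, but retained only when a
  likelihood-ratio test against the $B = 0$ model exceeds the 5% critical
  value of the boundary-corrected $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$
  mixture. A freely fitted non-negative background sits at its zero boundary
  in roughly half of background-free realizations, which biases $\hat\tau$
  downward by 2–3% at 500 photons; the gate removes that bias while keeping
  the model for data with genuine offsets. The flip side, stated plainly: a
  true background too weak to reach the critical value is absorbed into
  $\hat\tau$.
* **Bounds and failure.** $\tau$ is constrained to (0.1, 10) ns — generous
  around mCerulean's range — and a fit that converges onto a bound, or a
  histogram whose photons sit outside the fitted tail (e.g. a single-bin
  spike), returns `converged = FALSE` rather than a silently wrong value.

Under these choices the estimator's empirical SD at 500 photons is about
1.3× the ideal $\tau/\sqrt{N}$ bound, and the bias is below 1% (the test
suite checks 2% over 500 Monte-Carlo replicates, and the $1/\sqrt{N}$
scaling at $N \in \{200, 500, 2000\}$).

## Lifetime maps and classification

`fit_lifetime_map()` marks a pixel valid only when its total photon count
exceeds the mean background pixel intensity (a scalar, or measured over a
supplied background region), optionally pools decays over $k \times k$
blocks, and fits each valid block. Invalid pixels carry no lifetime and
render black; `render_lifetime_map()` maps valid lifetimes onto a rainbow
LUT clamped to 1.9–2.8 ns, the mCerulean display range.

The biosensor classifier is deliberately simple, mirroring how such
thresholds are set in practice: `midpoint_threshold()` places the cut at the
midpoint of the untreated and treated population mean lifetimes (flagging
mean separations under a resolvability floor, default 0.05 ns), and
`classify_cdk1()` calls a cell CDK1-high when its donor lifetime falls
strictly below the threshold — FRET shortens the donor lifetime — with ties
going to CDK1-low, the conservative direction of "no drug response". For two
Gaussian populations the expected misclassification rate has the closed form
$\tfrac12\Phi\!\left(\frac{thr-\mu_u}{\sigma}\right) +
\tfrac12\left[1-\Phi\!\left(\frac{thr-\mu_t}{\sigma}\right)\right]$, which
the suite verifies empirically at $n = 500$ per group.

# Collagen texture and streaming

## GLCM correlation decay

`compute_glcm()` quantizes an image by uniform min–max binning (default 64
levels — standard Haralick practice; the level count is configurable because
no single convention dominates) and tabulates the joint distribution of
levels at a pixel offset. The Haralick correlation of that matrix, averaged
over the four protocol directions (0°, 90°, 180°, 270°; 0° and 180° are
computed as distinct transposed matrices even though their correlation
coincides, for fidelity to the four-direction protocol), is traced against
the offset ("neighbor index") by `correlation_decay()`. A slower decay
indicates a more organized fiber network; the trapezoidal area under the
mean curve is exposed as a scalar summary. Normalization divides each curve
by its distance-1 value so curves compare as decay shapes — this convention
is a documented choice, not an inferred fact, since published analyses do
not pin down the normalization. The implementation is held to a brute-force
pair-enumeration oracle to $10^{-10}$ on small images.

## Gradient-tensor anisotropy

Coordinated cell streaming (and fibril alignment) is quantified
FibrilTool-style: after Gaussian pre-smoothing (default $\sigma = 1$ px,
needed for stable centered-difference derivatives), the $2\times2$ nematic
tensor of averaged gradient products is assembled over the ROI and the
anisotropy is $(\lambda_1-\lambda_2)/(\lambda_1+\lambda_2)$ — 0 for
isotropic texture, 1 when all gradient energy lies on one axis. The
statistic is invariant to intensity scaling and to 90° rotation (checked to
$10^{-6}$), and a flat ROI (gradient energy at floating-point noise level
relative to the intensity scale) raises an error rather than returning
noise.

## Coverage and contraction area

Birefringence-style coverage is the percentage of included pixels at or
above a threshold (fixed, or Otsu); contraction-assay area Otsu-thresholds
the brightfield image, keeps the largest connected component, and converts
to cm². Both are checked against constructions with known answers (drawn
fiber masks, analytic disk areas), and monotonicity in the threshold is
asserted as a property.

# Color-deconvolution DAB optical density

Transmitted-light intensities follow Beer–Lambert:
$I_c = i_{0,c}\,10^{-\sum_s c_s V_{sc}}$ with unit stain vectors $V$.
`unmix()` converts channels to optical density with an intensity floor of
one quantum before the log (bounding the OD of saturated-black pixels),
solves the $3\times3$ linear system, clips negative concentrations to zero
and reports the clipped-pixel fraction. The default vectors are the standard
published hematoxylin/DAB pair completed with an orthogonal residual
channel. Whether "average DAB intensity per cell" means mean OD or mean raw
DAB-channel intensity is ambiguous in common usage; mean OD is the default
and a raw-intensity mode sits behind `measure = "raw"`. Cell segmentation is
an input (a labeled mask) — detector and classifier training belong to the
imaging platform, not this pipeline.

# Organotypic invasion scoring

The invasive index is $100 \times n_{\text{invading}} / n_{\text{total}}$.
Clusters follow the ">4 cancer cells in close proximity" rule:
single-linkage components of invading cells under a pairwise distance
threshold, a component counting as a cluster only at size ≥ 5. Each invading
fl-genotype cell is then assigned one mode: member of an all-fl cluster, of
a mosaic cluster containing mt cells, or single. Two conventions required a
decision because the cluster definition leaves them open: the proximity
radius (default 30 µm, about two cell diameters; a mandatory, reported
parameter rather than a hidden constant) and components of size 2–4, which
are scored as "single" for each member since only ≥5-cell groups meet the
cluster definition. Clustering is held to a brute-force union-find oracle,
and mode counts are asserted to partition the invading fl cells exactly.

Doubling time uses $DT = T\,\ln 2 / \ln(X_e/X_b)$ (48 h co-culture in the
assay this emulates); declining populations return a negative DT with a
`decline` flag instead of an error, since the quantity is still
interpretable. Ordinal local-invasion scores aggregate as per-mouse maximum,
then group mean of maxima.

# Mechanics

AFM force curves are fitted with the Hertz spherical model
$F = \tfrac43\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2}$, as a piecewise
least-squares problem over (modulus, contact point, baseline): flat before
contact, Hertzian beyond. The contact point is fitted jointly by default —
the suite demonstrates that a contact fixed 20 nm off truth biases the
modulus while joint fitting removes the bias. Two parameters the instrument
description leaves open are declared, logged defaults: Poisson ratio
$\nu = 0.5$ (incompressible gel) and probe radius $R = 0.5$ µm, reading "1
µm spherical colloidal probe" as a diameter. The 0.06 N/m spring constant is
carried as metadata; indentation-axis data are the fitting input.

Rheometer strain sweeps (0.2–2.0% oscillation strain, log-spaced) reduce to
the storage modulus over the linear viscoelastic range: the maximal leading
run staying within a relative tolerance (default 5%) of the median of the
first `min_points` samples, averaged. Points just past the plateau onset
that remain inside the tolerance band are, by construction, averaged in;
clearly decayed points are excluded, and appending post-plateau points does
not move the result.

# Statistics

`holm_sidak()` implements the step-down Šidák familywise adjustment:
ascending $p_{(j)} \mapsto 1-(1-p_{(j)})^{m-j+1}$, running maximum, cap at
1. (Reports sometimes label this method "step-up"; the named procedure is
canonically step-down, and that is what is computed — the suite checks it
against direct enumeration on all family sizes up to 6.) Two-sample power
uses the noncentral $t$ with $df = 2n-2$ and noncentrality
$(\delta/\sigma)\sqrt{n/2}$; `sample_size()` increments $n$ until the target
power is reached. The power model is the two-sample $t$ on percentage
incidences — with means 75 and 25, SD 20, $\alpha = 0.05$ and power 0.80 it
yields 4 per group, consistent with cohort sizes planned from those figures,
which a proportions-test model would not reproduce. `compare_groups()` is
reporting glue over `wilcox.test`/`kruskal.test` with Holm-Šidák adjustment
across the pairwise family and the conventional star thresholds
(0.05/0.01/0.001/0.0001).

# The synthetic-data generators

Every generator is a pure function of its parameters and a seed (per-call
streams are derived from the seed and the operation name, so call order
cannot leak randomness between stages), and attaches a `truth` record
sufficient to score the downstream stage without re-deriving parameters.

What they emulate, and deliberately do not:

* **Decays/stacks** (`gen_decay`, `gen_flim_stack`): independent Poisson
  bin counts around a truncated mono-exponential plus uniform background,
  evaluated at bin centers; 500 photons/pixel and a 64-bin/12.5 ns axis by
  default. No IRF, no detector afterpulsing, no vendor file formats.
* **Fiber images** (`gen_fiber_image`): anti-aliased line segments with
  axial von Mises orientations (Best–Fisher sampler; $\kappa = 0$ isotropic,
  $\kappa = \infty$ parallel), Gaussian-blurred with $\sigma$ = width/2 so
  the images are continuous-valued as GLCM quantization requires, plus
  Gaussian noise at a default peak SNR of 20 reflecting line-averaged SHG
  acquisition. No fiber curvature, branching, or 3D volumes.
* **Histology RGB** (`gen_histology_rgb`): exact Beer–Lambert forward model
  with additive sensor noise and clipping — the matched inverse of
  `unmix()`. No scanner color profiles or tissue autofluorescence.
* **Invasion scenes** (`gen_invasion_scene`): clusters laid down as chains
  with spacing 0.4–0.7× the radius, distinct invading entities separated by
  at least twice the radius, singles rejection-sampled; placement failures
  error after bounded retries rather than degrading silently. The geometry
  guarantees the scorer can reproduce truth exactly — which is the point:
  the oracle tests exactness of the scoring logic, not robustness to
  ambiguous geometry.
* **Force curves / strain sweeps**: exact forward models plus additive
  Gaussian noise.

Because the generators match the fitted models exactly (up to noise),
passing tests demonstrate correctness of the estimators and scoring logic
under the stated noise models — not robustness to the mismatches real data
carry (IRF tails, multi-exponential decays from mixed FRET states, fiber
curvature, stain cross-talk beyond the linear model, tilted AFM baselines).
That boundary is intentional and worth restating wherever results are
interpreted.

# Problem sizes and reproducibility

The default validation sizes — 40×80-pixel two-population FLIM stacks, 500
Monte-Carlo decay replicates, 100 force-curve replicates per stiffness,
50 random invasion scenes, 256²–512² texture images — were chosen so the
statistical tolerances quoted above are comfortably resolvable while the
whole suite stays quick to iterate on. `scripts/acceptance.R` re-runs the
pipeline's headline quantities from scratch under a caller-supplied seed and
writes them as JSON; see the README for how to run it.

# Known limitations

* Single-exponential decays only; mixed FRET states within a pixel need
  multi-exponential or phasor treatment that is out of scope here.
* Cell ROIs on lifetime maps, and cell segmentations on IHC, are inputs;
  no detector is provided.
* The GLCM normalization convention and the invasion proximity radius are
  documented choices; results quoted against other implementations should
  state both.
* The LVE detector assumes the sweep starts inside the plateau; sweeps
  already decaying at the first point will (correctly) error.
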