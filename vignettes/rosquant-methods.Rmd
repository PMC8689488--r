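---
title: "Quantifying whole-organism oxidative stress from confocal z-stacks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying whole-organism oxidative stress from confocal z-stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rosquant)
```

## The measurement problem

Translucent juvenile bivalves (mussel spat up to roughly 4–5 mm shell
length) can be stained in vivo with a fixable ROS-sensitive fluorogenic
probe and imaged whole on a confocal microscope at low magnification. Three
channels are acquired per individual:

* **CH1** (~410/20 nm, "shell"): shell autofluorescence. It outlines the
  animal and, crucially, bleeds into the green channel.
* **CH2** (~510/20 nm, "ros"): the ROS-activated stain, plus the
  bleed-through copy of the shell signal.
* **CH3** (~660/20 nm, "gut"): autofluorescence of digestive organs and
  ingested algae. Informative for condition, never quantified here.

The per-individual readout is an **area fraction**:

$$\mathrm{ROS\%} \;=\; 100 \times
  \frac{|\,\text{ROS-positive pixels inside the shell footprint}\,|}
       {|\,\text{projected shell footprint}\,|}.$$

Normalising by the projected shell area makes the readout unit-free and
comparable across individuals of different sizes, which is why missing
physical pixel size is tolerated throughout: areas are reported in pixels
and percent, physical units only when the pixel size is known.

## The image chain

For a z-stack $I_c(z, x, y)$ the pipeline computes, per channel, the
maximum-intensity projection $P_c(x,y) = \max_z I_c(z,x,y)$, then:

1. **Shell footprint** from CH1: Otsu threshold → binary closing (disc,
   radius 2 px) → hole filling → largest connected component. The mask is
   the *filled* whole-animal footprint, not the shell outline ring, because
   the normalising quantity is the projected area of the individual.
2. **Gain** $g$: the acquisition protocol balances the detectors so the
   shell reads equally in CH1 and CH2; by default $g = 1$. Opt-in
   estimation computes $g = \mathrm{med}(P_2)/\mathrm{med}(P_1)$ over
   *fluorescing* shell pixels (footprint pixels with CH1 above Otsu within
   the footprint). Using the whole footprint would be wrong — its interior
   carries no CH1 signal, so both medians would be dominated by zeros.
3. **Subtraction**: $S = \max(0,\; P_2 - g\,P_1)$, in floating point,
   clipped at zero. With a balanced acquisition and no stain this is
   exactly the zero image.
4. **ROS-positive area**: threshold of $S$ computed from pixels *inside the
   footprint only* (a global threshold would be dragged down by the empty
   background around the animal), by Otsu with two guards (below), or by a
   fixed value. The ROS mask is by construction a subset of the footprint.

### Why Otsu needs guards here

Otsu's method always returns a split, even when there is nothing to split.
Two ROS-free situations occur by design and must quantify to (near) zero:

* **Only clipped noise** inside the footprint (stain-free, tissue-free
  scene). Any threshold through a unimodal distribution yields a Fisher
  class separation — class mean gap over pooled within-class SD — of about
  2.5–4 (≈2.65 for a Gaussian, ≈4 for zero-clipped noise), whereas a
  genuine stain-vs-tissue split at SNR ≥ 10 scores well above 10, even at a
  2% ROS fraction. The default `min_separation = 6` sits between the
  regimes; we deliberately do **not** use Otsu's own separability
  $\eta$, which collapses toward the noise value under strong class
  imbalance (at a 2% true fraction $\eta \approx 0.75$ vs $\approx 0.72$
  for pure noise — unusable).
* **Dim tissue autofluorescence with no stain.** Tissue at ~10% of the
  shell level against the ring-subtracted zeros is a perfectly bimodal,
  well-separated split — the separation statistic cannot reject it. What
  distinguishes it from real stain is *contrast relative to the
  acquisition's dynamic range*: the default `min_contrast = 0.25` requires
  the class mean gap to exceed 25% of the CH2 projection maximum. Both
  guards are ratios, so quantification is invariant to rescaling all
  intensities (and Otsu's threshold is computed on 256 bins spanning the
  data range for the same reason).

Both cutoffs were validated on the two regimes they must separate (margins
of 3× or better on either side), not tuned to any test outcome; both are
exposed in `seg_params()` alongside fixed-threshold overrides that bypass
the guards entirely.

Remaining segmentation defaults: closing radius 2 px and minimum component
size 100 px suppress noise speckle at 4×-objective scale; equal-area
component ties are broken by total CH1 intensity, then scan order, for
determinism.

## The statistical chain

Individuals are raised in replicate containers nested within treatments, so
individual readouts are not independent samples of the treatment effect.
The chain is:

1. transform proportions $p = \mathrm{ROS\%}/100$ by
   $y = \arcsin\sqrt{p}$ (variance stabilisation);
2. check normality (Shapiro–Wilk on residuals about container means) and
   homoscedasticity (Brown–Forsythe: Levene's test on absolute deviations
   from treatment *medians*);
3. nested one-way ANOVA with container as a **random** factor nested in
   treatment. The sums of squares decompose as between-treatment, among
   containers within treatments, and among individuals within containers.
   Because container is random, the expected-mean-squares rules dictate
   $F = MS_\text{treatment}/MS_\text{container}$ on
   $(a-1,\; \sum_i(b_i-1))$ degrees of freedom — *not* the residual mean
   square. This is the single most consequential choice in the module: with
   3 containers per treatment the error df is 12, not 160-odd, and claimed
   significance is correspondingly harder to reach.
4. Tukey HSD on treatment means using the same error term
   ($MS_\text{container}$, container df) for consistency of inference
   level, Tukey–Kramer style under imbalance;
5. group means are computed on the transformed scale and back-transformed
   ($\sin^2$) only for reporting.

Unbalanced designs reuse the same decomposition with per-cell counts and
emit a warning that SS additivity is then only approximate. Degenerate
inputs are handled explicitly: a zero container mean square under a nonzero
treatment effect reports $F = \infty$, $p = 0$ with a `degenerate` flag;
all-identical observations are an error, as is a design without replicate
containers (use a one-way ANOVA instead). A pooled-variance two-sample
t-test (`two_sample_t()`) covers side-by-side control comparisons such as
an anaesthetic check.

## What the phantom generator emulates — and what it does not

`render_phantom()` draws a minimal-sufficient scene: an elliptical shell
ring (bright in CH1 and, scaled by the bleed-through ratio, in CH2), a dim
tissue interior, circular ROS foci in CH2 only, an optional CH3 gut blob,
and i.i.d. Gaussian sensor noise per voxel (a Poisson option exists but is
not the default — at the SNRs tested the distinction does not move an area
threshold). Scene signal is spread across z so that the per-pixel maximum
over slices reconstructs the scene exactly; noise is added per slice, so
projection noise behaves like a maximum of Gaussians, as in real MIPs.

ROS foci are placed inside the footprint and rescaled until the *rendered*
truth-mask area is within 2% (relative) of the requested fraction — the
pixel-counted truth mask, not disc algebra, is the contract the pipeline is
tested against. Requested fractions that cannot be tiled with the given
focus count produce an error after bounded retries.

What a green test on phantoms does establish: the area arithmetic,
thresholding behaviour, subtraction identity, scale invariance, and the
statistical chain's operating characteristics, end to end. What it cannot
establish: robustness to real tissue texture, uneven staining, shell
pigmentation and curvature artefacts, optical sectioning effects, or
touching individuals — real-data concerns that no geometric phantom
exercises.

## The simulated experiment and its parameters

`default_design()` mirrors the six-treatment emersion study the method was
developed against: an immersed control, a freeze-killed reference, and the
four combinations of emersion duration (1 h, 20 h) × relative humidity
(high ≈85%, moderate ≈60%), each with 3 replicate containers × 10 imaged
individuals. True mean ROS fractions are 0.05 (control), 0.16–0.38
(stressed, with the 20 h/moderate-RH group lowest at 0.16) and 0.30 for the
dead reference, which sits inside the stressed range.

Per-individual true fractions are drawn hierarchically: treatment mean →
Gaussian container offset (SD 0.02) → Gaussian individual offset
(SD 0.03), truncated to [0, 0.99] with truncation messaged. The two SDs
deserve a note:

* the **within-container SD of 0.03** is calibrated to the printed
  variability of the source assay (±1.07 s.d. at a mean of 2.69% ROS in
  unstressed animals, which scales to roughly 3 percentage points at
  stressed means under the variance-stabilisation premise);
* the **between-container SD of 0.02** is stated nowhere and was chosen
  once as a plausible level of drift between replicate 750 ml containers
  under a shared treatment.

## Numerical and interface choices

* Intensities are stored as unsigned integers at native bit depth (8 or
  16); all arithmetic after reading is floating point, so clipping happens
  only where the method defines it.
* TIFF support is a deliberately narrow, dependency-free subset:
  uncompressed grayscale multi-page baseline TIFF, 8/16-bit, both byte
  orders on read, with OME-XML (sizes, channel names, physical pixel size)
  in the first page's `ImageDescription`. OME metadata overrides a declared
  channel order; plain multi-page files are interpreted channel-fastest
  with roles taken from the declaration. Masks are written as 0/255 8-bit
  TIFF.
* All randomness flows from single integer seeds consumed in a documented
  order; identical configuration + seed reproduces every output byte for
  byte, and the run manifest materialises every default so no silent
  defaults exist.
* Coordinates are row-major with masks pixel-aligned to projections;
  connected components use 8-connectivity for foreground and
  4-connectivity for background (hole filling).

## Known limitations

Signal-intensity quantification (as opposed to area), 3-D volumetric
readouts, tissue-type attribution of the signal, proprietary microscope
formats, stitching and illumination correction are out of scope. The
nested-ANOVA module reports its own degrees of freedom honestly and should
not be expected to reproduce published F-statistics whose df are
inconsistent with the stated design. Multi-individual frames are split by
connected components only — touching animals are not separated.

## A worked example

```{r example, eval = FALSE}
library(rosquant)

# one phantom, known truth
ph <- render_phantom(phantom_spec(ros_fraction = 0.25, seed = 42))
quantify_individual(ph$stack)

# a full simulated experiment
res <- run_all(list(seed = 1, out_dir = tempfile("demo_")))
print(res$analysis$anova)
head(res$analysis$posthoc)
```
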