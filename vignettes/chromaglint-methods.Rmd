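---
title: "Models and methods behind chromaglint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chromaglint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromaglint)
```

# The perceptual question

Specular highlights dilute and brighten the retinal image of a colored
surface. If the visual system could perfectly separate specular from diffuse
shading, judgments of surface saturation and lightness would be unaffected by
gloss; in practice they are not. The working model in this package treats the
residual bias as a weighted combination of two perceptual cues measured by
paired comparison — perceived gloss and perceived specular coverage:

$$P' = W \, P_{\mathrm{coverage}} + (1 - W)\,(1 - P_{\mathrm{gloss}})$$

Both the saturation percept (matched $C^*/L^*$) and the lightness percept
(matched $L^*$) use this same functional form with independent weights. The
complement $1 - P_{\mathrm{gloss}}$ encodes the assumption that image
structure *not* attributed to gloss is misread as diffuse shading and biases
the color estimate.

`W` is estimated by a grid sweep from $-1$ to $1$ in steps of $0.01$ (201
points), maximizing the squared Pearson correlation between model output and
percepts across conditions. Because the model output is affine in `W` for
fixed cues, the $r^2$ profile has a closed-form continuous optimum; the test
suite checks the grid winner against that analytic solution. The signed $r$
is reported (its sign depends on how percepts scale with the model output),
ties on the grid break toward smaller $|W|$ for determinism, and $p$ values
use the standard $t$ transform with $n - 2$ degrees of freedom. Weights at
which the model output is constant carry no information and are excluded
with a warning. Whether one correlates the raw model output or an affine
least-squares fit of it is immaterial: Pearson $r$ is affine-invariant, so
plain correlation is used.

# Colorimetry conventions

Conversions run LCH → Lab → XYZ → linear RGB → companded sRGB. Two Lab
reference-white conventions are implemented behind the `white` argument:

* **D65** (default): Lab referred to the display's native white.
* **D50**: Lab referred to D50 with Bradford adaptation to D65 before the
  sRGB matrix.

The default was selected because it reproduces the published sRGB triplets
of the stimulus coordinates $(L^*, C^*) = (60, 60)$ at hue angles 39.999°,
136.016° and 306.285° to two decimals, which the D50 route does not; the
convention used is recorded in the conversion output. The RGB↔XYZ matrix is
derived at load time from the sRGB primary chromaticities so that RGB
$(1,1,1)$ maps *exactly* to the D65 white — with the usual 7-digit published
matrix, grays come out very slightly chromatic, which breaks round-trip and
achromatic invariants at the $10^{-5}$ level.

Out-of-gamut conversion is an error by default, carrying the unclipped
channel values; an opt-in clip mode records the clipping magnitude. Zero
chroma leaves the hue undefined; the convention is $H = 0$ plus an
`achromatic` flag.

The maximum displayable chroma at fixed $(L^*, H^*)$ is found by bisection
(the in-gamut chroma set is an interval), refined to 0.25 chroma units by
default — comfortably below a just-noticeable difference. The per-hue gamut
boundary tabulates this maximum and the implied maximum saturation
$C^*_{\max}/L^*$ for $L^* = 0 \dots 100$.

A consequence worth stating plainly: the nominal 22 × 22 matching grid
($L^*$ 18.75–97.5, $C^*$ 22.5–101.25) extends well beyond the sRGB gamut
boundary at all three stimulus hues — high-chroma cells at low or high
lightness are not displayable. `build_matching_grid()` therefore errors by
default and offers `"flag"` and `"clip"` modes; the analysis pipeline uses
flagged nominal values, since for simulation and aggregation the nominal LCH
coordinates are what matter.

# The simplified renderer

The renderer is deliberately minimal: its job is to expose the geometry
of highlight formation (which facets bisect the view and light directions),
not to reproduce a path-traced image.

* **Height fields** are smoothstep-interpolated value noise (default one
  octave, 8 lattice cells per side, two 3 × 3 smoothing passes), min-max
  normalized and scaled so the peak-to-peak amplitude equals the
  displacement scale exactly, in tile-width units.
* **Shading** is direct illumination from a rectangular overhead emitter
  (default 2.5 m × 1.0 m at 1.2 m), stratified-sampled with each sample
  weighted by the area-light measure (emitter cosine over squared distance).
  Diffuse is Lambertian; specular is the Beckmann normal distribution
  $D(\theta_m) = \exp(-\tan^2\theta_m/\alpha^2)/(\pi\alpha^2\cos^4\theta_m)$
  evaluated at the half-vector angle with cosine foreshortening and a scalar
  amplitude (default 0.2). Fresnel and shadow-masking are omitted: the
  stimulus model specifies a scalar specular amplitude, not an index of
  refraction. The camera is orthographic; the tile is rotated about the
  horizontal axis so that at 45° slant the mean normal bisects the viewing
  and lighting directions. Interreflection and room walls are out of scope.
* **Physical specular coverage** is the fraction of pixels whose specular
  component reaches a threshold fraction (default 0.1) of the image's own
  specular maximum.

The relative-to-max coverage statistic has a known failure mode, visible in
the test suite: at frontal slants with high roughness the specular image of
a low-relief tile is a nearly uniform dim haze, so almost every pixel sits
within a factor of ten of the maximum and coverage saturates. Under those
conditions the statistic no longer tracks the area of distinct highlights,
and the relief ordering of mean coverage at 15° inverts. At sharp-to-moderate
roughness the expected geometry-driven behaviour holds: more relief adds
highlight area at frontal slants and disperses the mirrored emitter at
oblique slants. An absolute reference (e.g. specular relative to local
diffuse luminance) behaves better in the haze regime but is not the
documented statistic, so it was not adopted.

# Psychophysical aggregation

Matching responses are averaged per observer and condition. Saturation uses
mean-of-ratios by default (each trial's $C/L$ first, then the mean), with
ratio-of-means available; the two differ whenever matched lightness varies
across trials. Choice probabilities are wins over presentations, with
presentations counted from the trial list so never-chosen conditions are 0
rather than missing; blocks (hue × slant) are never pooled at estimation
time.

The repeated-measures ANOVA implements the classical balanced
within-subjects partitioning: sums of squares by inclusion-exclusion on
marginal totals, each effect tested against its own effect-by-subject
interaction, no sphericity correction. Replicates within subject × cell are
averaged; missing cells raise an error rather than being imputed. The
implementation is hand-rolled precisely so that `stats::aov` with
`Error(subject/...)` strata can serve as an independent oracle in the tests
(agreement to $10^{-8}$), rather than being both implementation and check.

# Synthetic observers

The generator exists to give every downstream stage a ground truth. Its
default condition set mirrors the paired-comparison design (4 relief × 4
roughness per hue × slant, 3 slants, 3 hues, 4 observers), so recovery tests
exercise exactly the pooling the model stage uses.

**Cue surfaces.** Latent gloss falls linearly with normalized roughness
(strongly) and log-relief (weakly); an optional flag reproduces the reported
inversion where the flattest tiles look glossier as roughness grows. Latent
coverage has a roughness slope proportional to $(1 - 2s)$ in normalized
slant — positive at 15°, zero at 30°, negative at 45° — and a relief slope
proportional to $(0.5 - 1.5s)$, which reverses sign between 15° and 45°
while staying nonzero at 30°, where a relief effect on coverage persists in
the data the templates emulate. Both surfaces are clamped to $[0, 1]$. The
middle-slant relief term matters for identifiability: if coverage were flat
at 30°, the model weight would be undefined in those blocks.

**Choices** follow a Thurstonian rule: first wins iff
$\Delta\mathrm{cue} + \mathcal{N}(0, \sigma_c) > 0$, with
$\sigma_c = 0.1$ by default against cue ranges of roughly 0.6 — chosen so
that simulated probability estimates span most of $[0,1]$ with some
saturation at the extremes, as empirical paired-comparison data do. The
expected round-robin probability has the closed form
$\bar p_i = \mathrm{mean}_j\,\Phi((c_i - c_j)/(\sqrt2\sigma_c))$, which the
simulated estimates converge to.

**Matching settings** are generated from the model itself:
$P'$ computed with the true weights is mapped affinely into matched
lightness ($L = 35 + 45 P'$) and saturation ($S = 0.65 + 0.55 P'$), with
$C = S \cdot L$; the gains were chosen once so that the implied settings
stay inside the default grid for model outputs anywhere in $[0,1]$ (the
generator warns if a configuration pushes more than 10% of condition means
outside). Gaussian setting noise (default 3.75, one grid step, in LCH
units) is added to $L$ and $C$, then settings snap to the nearest grid
level, with exact midpoints breaking to the lower index and out-of-range
values clipping to the edges.

**Cue scale.** By default the cues entering the matching generator are the
expected round-robin choice probabilities, not the raw latent surfaces.
This is a deliberate design choice: the analysis estimates weights on the
probability scale, and the Thurstonian transform from latent cues to
probabilities is nonlinear (saturating), so a ground truth defined on the
latent scale would not be recoverable even from noiseless data — the
recovered weight would be biased by the scale distortion rather than by any
defect in the pipeline. Defining truth on the scale the analysis measures
makes end-to-end recovery a meaningful test; the `"latent"` option remains
for studying the distortion itself.

**Randomness** fans out from a single top-level seed through labelled
substream seeds (one per observer × stage × block), so adding draws in one
stage never perturbs another and datasets are bit-reproducible.

# What the synthetic data do and do not show

The generator reproduces the statistical *structure* the analysis assumes:
monotone cue templates with the published slope signs, Thurstonian choices,
grid-quantized matching noise, and percepts that truly follow the weighted
model. Passing recovery tests therefore demonstrates that the pipeline is
consistent and unbiased under its own assumptions. They do not show that
human percepts follow the model, that the cue templates match any real
observer's internal scales, or that hue differences arise — hue enters the
generator only through optional offsets on the weights. Empirical
F statistics, correlations, and fitted weights from the original human data
cannot be reproduced without those data.

# Numerical and design choices, briefly

* Gamut membership tolerates $10^{-9}$ on the channel bounds; the chroma
  boundary is bisected to 0.25 units.
* The weight sweep is inclusive of both endpoints; `seq(-1, 1, 0.01)` is
  exactly 201 points.
* Model fits use the 4 × 4 relief × roughness blocks shared by the matching
  and paired-comparison designs (the fifth roughness level of the matching
  design is dropped), 16 points per block.
* Test and validation problem sizes were chosen to keep the default suite
  fast while leaving no statistical ambiguity: renders at 64–128 px with 32
  light samples, 100-seed recovery batches at the model level, 25-seed
  batches end-to-end, $n = 10{,}000$ for the discretized-Gaussian check.
* The pipeline's `run_pipeline()` is the orchestration surface; module
  functions are the public API, and tables are written as plain CSV/JSON so
  a run is reproducible byte-for-byte from its config and seed.

# Known limitations

* The renderer omits shadowing, masking, interreflection and perspective;
  its images are statistical stand-ins, not replicas of path-traced stimuli.
* The coverage statistic's haze regime (above) limits comparisons across
  relief at frontal slants and high roughness.
* The nominal matching grid exceeds the sRGB gamut at its far corners; any
  use of the grid for actual display must clip or flag those cells.
* The ANOVA assumes a balanced, fully crossed design and reports no
  sphericity correction, matching the analysis it mirrors.
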