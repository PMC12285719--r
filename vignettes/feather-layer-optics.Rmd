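---
title: "Modelling how hidden achromatic feather layers shape plumage color"
author: "plumoptics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling how hidden achromatic feather layers shape plumage color}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plumoptics)
```

## The problem

Body (contour) feathers are layered structures: a colorful pennaceous tip
sits over a hidden achromatic (white or black) region, which in turn covers
the downy base. When feathers overlap on a bird, light that passes through
the colorful tips interacts with these hidden layers before returning to the
eye, so the whiteness or blackness of a layer the observer never sees
directly can modulate the brightness and saturation of the visible patch.
`plumoptics` implements a computational treatment of this mechanism: a
three-layer optical model of the feather stack, spectral colorimetry,
tetrachromat (avian) visual modelling with receptor-noise discriminability,
and the image-side color extraction used alongside spectroscopy, plus seeded
synthetic-data generators that stand in for museum-specimen measurements.

## The three-layer optical model

Each layer is described by wavelength-resolved reflectance, transmission and
absorption fractions with $R(\lambda)+T(\lambda)+A(\lambda)=1$ enforced at
construction (class validity, tolerance $10^{-12}$). Total patch reflectance
sums the three single-bounce light paths through the stack:

$$R_{tot}(\lambda) = R_c + T_c^2\,R_a + T_c^2\,T_a^2\,R_d,$$

where subscripts $c$, $a$, $d$ denote the colorful, achromatic and downy
layers; each transmission appears squared because the path crosses the layer
once downward and once upward. Higher-order interreflections are omitted —
with realistic layer reflectances below 0.6 the first neglected term is a
few percent of the smallest retained one — and the result is clamped to
$[0,1]$ to guard pathological parameter sets. The downy layer is terminal
($T \equiv 0$): the body behind it is not modelled.

### Colorful layers

*Carotenoid-pigmented barbs.* Pigmentary color needs backscatter: the
pigment only absorbs, and the returning light comes from the surrounding
keratin and deeper layers. We model a wavelength-flat keratin backscatter
fraction $s_c$ and a Beer–Lambert pigment pass,
$t(\lambda) = 10^{-D\,\hat g(\lambda)}$, giving $R_c = s_c\,t$,
$T_c = (1-s_c)\,t$. $D$ is the pigment optical density; backscattered light
is charged one full density $D$ (down and up through half depth each), the
simplest convention that keeps $D$ interpretable as the single-pass density
of the whole layer. The absorbance template $\hat g$ is a generic
lutein-like long-pass shape: a unit-peak sum of Gaussians at 430 and 460 nm
($\sigma = 30$ nm), zero above 550 nm. Every directional result in the
package (brightness and luminance gains on white, hue invariance) is robust
to the template's fine structure; a measured template can be passed via the
`template` argument.

*Structurally colored barbs.* Noniridescent structural color from the
spongy keratin–air nanostructure is modelled phenomenologically as a
Gaussian reflectance peak over an incoherent baseline,
$R(\lambda) = s_b + H_{pk} \exp\!\big(-4\ln 2\,(\lambda-\lambda_0)^2/w^2\big)$,
parameterized by peak position $\lambda_0$, height $H_{pk}$ and full width
at half maximum $w$ (narrow peak = saturated color). A flat internal
absorptance $a_s$ acts on the non-reflected light. No wave-optics
(Fourier/FDTD) treatment is attempted, and iridescent barbule colors are out
of scope.

*Achromatic and downy layers.* Spectrally flat, with presets anchored to
measured exposed achromatic regions: white $R = 0.55$, black $R = 0.05$
(gray $R = 0.30$ is the midpoint convention). Transmission is
$T = \tau (1-R)$ with $\tau$ defaulting to 0.40 / 0.10 / 0.05 for
white/gray/black — white achromatic regions are loose and translucent,
black ones are melanized and strongly absorbing; published transmission
values are not available, so these defaults are package choices, flat in
wavelength and overridable. The downy layer is an opaque gray reflector
($R = 0.30$).

### What the model predicts

With the defaults, the qualitative pattern the model is built to express
follows directly: a white achromatic layer raises the brightness of
carotenoid-pigmented patches (the $T_c^2 R_a$ path adds light at all
wavelengths the pigment transmits) without touching hue; a black achromatic
layer raises the saturation and lowers the brightness of structurally
colored patches (the background path fills in the off-peak valleys of the
Gaussian peak on white, flattening the spectrum). `runBackgroundSwap()`,
`runParameterSweep()` and `runVisualSweep()` regenerate these patterns as
tidy tables.

One scale subtlety matters when sweeping the structural peak height
$H_{pk}$ with the baseline fixed: the *absolute* saturation enhancement
$S8_{black}-S8_{white}$ necessarily vanishes as $H_{pk} \to 0$ (a colorless
layer has no saturation to enhance) and grows with $H_{pk}$, while the
*proportional* enhancement $(S8_{black}-S8_{white})/S8_{black}$ is largest
precisely where the nanostructure reflects weakly and decreases
monotonically in $H_{pk}$. The proportional form is the meaningful measure
of "how much the achromatic layer changes the color", so sweep tables
report both (`dS8` and `relS8`) and the monotonicity property is asserted
on the proportional form.

## Spectral colorimetry

Spectra live on a uniform grid, 300–700 nm at 1 nm by default (the avian
visible range), as fractions in $[0,1]$; CSV files use percent, the field's
common dialect, and the unit switch at I/O avoids silent 100× errors. Three
summary statistics are used throughout: brightness **B2** (plain mean
reflectance over the grid — on a uniform grid this equals the normalized
integral up to endpoint treatment), saturation **S8**
($(\max - \min)/\text{mean}$; the conventional reflectance-based form) and
hue **H1** (wavelength of maximum reflectance, ties broken to the shortest
wavelength — a deterministic rule needed because model spectra contain
exactly flat plateaus). Measured spectra are smoothed before colorimetry by
local quadratic regression with tricube weights (`stats::loess`) at span
0.3 of the grid, the span conventionally used for reflectance spectra;
constants and straight lines pass through unchanged, so smoothing cannot
manufacture color.

## Avian visual modelling

Cone spectral sensitivities are built from the Govardovskii A1 nomogram
(alpha plus beta band) at each $\lambda_{max}$, multiplied by a logistic
long-pass ocular-media transmission (half point 322 nm) and normalized to
unit integral, so a flat spectrum of reflectance $k$ yields quantum catch
$k$ in every channel. Defaults emulate a blue-tit-like UVS tetrachromat:
$\lambda_{max} = (371, 448, 503, 563)$ nm, abundances $1{:}2{:}2{:}4$,
Weber fraction 0.1 on the most abundant (long-wave) cone — giving channel
noises $e_i = 0.1\sqrt{n_{max}/n_i} = (0.2, 0.141, 0.141, 0.1)$ — and a
double cone ($\lambda_{max} = 563$ nm, $e_D = 0.1$) for luminance. The
illuminant is ideal (constant across wavelengths) and no photon-flux
conversion is applied. All of these are literature-convention defaults,
overridable in `buildVisualSystem()` and via YAML configs; the directional
results asserted by the tests do not depend on their fine values.

Relative catches (summing to 1) place a spectrum in the tetrahedral color
space: the point is $\sum_i u_i V_i$ with $V_i$ the vertices of a regular
tetrahedron of circumradius $3/4$ centred on the achromatic point, oriented
with the UV vertex on $+z$ and the SW vertex in the $+y$ half-plane (any
fixed rigid orientation is equivalent; this one is frozen for
reproducibility). Chroma is the distance from the origin (0 for achromatic
stimuli, 0.75 at a vertex); luminance is the double-cone catch.

Discriminability uses *raw* catches — the tetra space uses relative ones,
matching the split between representation and discrimination — via the
receptor-noise-limited model: $\Delta f_i = \ln(Q_i^A/Q_i^B)$ (natural log,
the raw-catch convention) and the noise-weighted Euclidean distance
$\Delta S$ in its general $k$-channel form (`rnlDistance()`), which reduces
to $|\Delta f_1 - \Delta f_2| / \sqrt{e_1^2+e_2^2}$ for a dichromat and to
the standard six-pair/four-triple expression for a tetrachromat. Luminance
contrast is $\Delta L = |\ln(Q_D^A/Q_D^B)|/e_D$. Distances above 1 JND are
theoretically discriminable; strictly above 2 is flagged "reliable" (both
thresholds strict, so a distance of exactly 1 or 2 is not flagged).

## Image-side color extraction

Calibrated RGB images are converted to cylindrical HSL (hue in degrees,
saturation and lightness in percent; hue defined as 0 where saturation is
0). Background removal is rule-based: each rule states per-channel bounds
(strict inequalities), a pixel matching *any* rule is background, and the
retained complement is the feather — the semantics are explicit because
interactive thresholding tools leave them implicit. The anchored rules are
lightness above 60% for white photographic backgrounds and below 10% for
black ones. Summaries report mean lightness and saturation over retained
pixels and hue as a circular mean (the arithmetic mean is logged too, for
comparability with naive tools; red hues straddle 0°/360° and would
otherwise average to cyan).

Hyperspectral cubes are sampled by drawing locations uniformly *with
replacement* (seeded) from the ROI pixels whose full 3×3 neighbourhood lies
inside the image, extracting at each the per-band median of the 3×3 area —
inert to single-pixel outliers — and averaging. Pixel coordinates are
0-based (row, col); a pixel belongs to a polygon when its centre lies
strictly inside, making polygons half-open on their right/bottom edges.
Sampling ROIs should be drawn interior to the physical patch: windows that
straddle the patch boundary mix in background pixels, exactly as in real
imagery.

## Synthetic data: what it emulates, and what it does not

The generators replace museum-specimen measurements with seeded,
ground-truthed stand-ins: noisy stack spectra (multiplicative Gaussian
noise, measurement-like, clamped to $[0,1]$), feather-on-background images
(stylized barb strokes of a target HSL color — the feather occupies an
exact pixel count, and its lightness jitter stays inside (10%, 60%) so the
background rules are separable by construction), hyperspectral cubes with
known region spectra, and dichromatism datasets in which both sexes share
an identical carotenoid layer and differ only in achromatic preset. Every
generator is a pure function of its configuration and seed.

Passing tests on these data show that the pipeline recovers what the
generators put in, under the noise structure they assume. They do not show
that real feathers follow the three-path model, that real backgrounds are
uniform, or that real measurement noise is multiplicative and independent —
those are empirical questions outside a simulation package.

Default study conditions: carotenoid $D = 1$, $s_c = 0.3$; structural
$\lambda_0 = 480$ nm, $H_{pk} = 0.35$, $w = 100$ nm, $s_b = 0.05$,
$a_s = 0.1$; measurement noise 1–2% multiplicative; sweep grids
$D \in [0.1, 3]$ and $H_{pk} \in [0.05, 0.8]$, 20 points each (the printed
grids are not available, so these are package choices spanning weak to
saturated color); 5 replicates per sex in dichromatism designs. Test and
acceptance problem sizes — 1000-draw fuzzing for energy conservation,
100 random stacks against the scalar oracle, 1000 random spectrum pairs
against the brute-force receptor-noise formula, 50 seeded images, 20 noisy
recovery replicates, 500-location ROI sampling — are the package's chosen
balance of statistical force against runtime.

## Numerical choices and degenerate inputs

* Saturation is undefined at zero mean reflectance (error, not NaN);
  relative quantum catches are undefined for an all-zero stimulus; log
  catch ratios error on any non-positive channel catch, naming the channel.
* Hue ties break to the shortest wavelength; the carotenoid template is
  exactly zero above 550 nm, which makes the long-pass plateau exactly flat
  and the tie-break reproducible.
* `fitOpticalDensity()` is bounded golden-section/parabolic minimization
  (`stats::optimize`, tolerance $10^{-10}$) of the residual sum of squares
  over $D$; the objective is smooth and unimodal in $D$ for fixed geometry.
* Resampling is linear interpolation with no extrapolation; values at
  shared nodes are copied bitwise.
* LOESS can undershoot slightly near zero; smoothed spectra are clamped at
  0.
* 16-bit TIFF round trips quantize at $2^{-16}$; tests tolerate exactly
  that.

## Known limitations

Single-bounce three-path summation (no interreflection series); flat,
wavelength-independent achromatic transmission; phenomenological structural
peak (no nanostructure optics, no angular/BRDF dependence); generic
template choices for pigment absorbance, A1 nomogram parameters and ocular
media; stylized rather than photorealistic synthetic imagery; no camera
calibration, UV imaging channel, or non-ideal illuminants; descriptive
group comparisons only (no hypothesis testing between sexes).
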