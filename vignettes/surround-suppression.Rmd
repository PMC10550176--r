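---
title: "In-silico surround-suppression protocols: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-silico surround-suppression protocols: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surroundscope)
```

# The problem

In visual cortex, a stimulus placed outside a neuron's classical
receptive field does not drive the neuron by itself, yet it modulates
the response to a stimulus in the center — most famously, an
iso-oriented surround grating suppresses the center response more than
an orthogonal one. `surroundscope` treats feedforward convolutional
networks as model organisms for these contextual effects: it maps each
unit's receptive-field geometry, runs the classical grating protocols
(size tuning, orientation tuning, surround suppression tuning), fits
subtractive versus divisive surround gain models, visualizes the most
suppressive and most facilitative surround by gradient optimization,
and compares surround suppression for naturalistic textures against
spectrally matched noise.

Everything runs on self-contained analytic fixture networks, so every
protocol is testable without trained weights; externally trained
networks can be described with `NetworkSpec` and supplied as `Network`
objects through the same adapter contract (forward pass to any layer,
gradients to the input).

# Receptive-field geometry

For a unit in layer $L$ the theoretical receptive field follows the
standard recursion over kernel sizes $k_i$ and strides $s_i$:
$j_0 = 1$, $r_0 = 1$,
$$j_i = j_{i-1}\,s_i, \qquad r_i = r_{i-1} + (k_i - 1)\,j_{i-1},$$
with the closed form $r_L = \sum_l (k_l - 1)\prod_{i<l} s_i + 1$.
`rfGeometry()` computes both and checks that they agree exactly. The
jump $j$ is the input-pixel distance between adjacent units of a map.

Feature maps with an even number of units have no unit exactly at the
image center; the map-center unit (`floor(h/2)`, 0-based) sits half a
unit away, which corresponds to `inputSize / (2 * h)` pixels in the
input. Stimuli are always placed at the unit's *true* center: the
displacement is kept as a real number and consumed by the continuous
coordinate grid of the stimulus renderer, never rounded.

**Padding convention.** The engine zero-pads convolutions and pooling
by $(k - s)/2$ per side when $k - s$ is even (floor/ceil split
otherwise). Under this convention every unit is centered on its
$j$-pixel input block, so the displacement formula above is *exact*:
the bounding box of input pixels that influence the center unit (the
gradient support, `empiricalRFSupport()`) has side exactly $r$ and its
centroid coincides with the displaced stimulus center. This is the
package's empirical oracle for the recursion, and it holds exactly for
architectures whose layers all have even $k - s$; a layer with odd
$k - s$ shifts the centroid by half of that layer's input jump.

# Stimuli

Stimuli live on a $[0,1]$ luminance scale with mid-gray at 0.5; a
per-network input transform (by default, subtracting 0.5) is applied by
the network adapter so the stimulus code never needs to know how a
particular network was trained. Pixel $i$ spans the continuous interval
$[i-1, i]$, so an $n$-pixel image has its center at $n/2$.

A grating of contrast $c$, period $\lambda$ and bar orientation
$\theta$ renders as
$0.5 + 0.5\,c\cos(2\pi u/\lambda + \varphi)$ inside its disc, where $u$
is the coordinate along $\theta + 90^\circ$ (the modulation direction),
and gray outside. The cosine profile makes the identity "rotating by
180° and negating the phase" hold pixel-exactly, which the constructor
uses to normalize orientations into $[0, 180)$. Responses are averaged
over `phaseSet(8)` — eight equally spaced phases, the in-silico
analogue of a drifting grating.

Composite stimuli place a center disc of diameter GSF (the grating
summation field, below), leave a gray gap ring up to GSF + 4 px, and
fill the surround annulus out to the theoretical receptive field.
Two-patch surrounds put two diametrically opposite discs at the
mid-radius of the ring, at an angle measured relative to the center's
bar orientation (angle 0 = collinear). Disc edges are hard binary
masks: no smoothing is applied, and composition is exact — the center
region of a composite is pixel-identical to the center-only rendering.

# Size and orientation protocols

`gridSearchOptimal()` scans stimulus sizes (30%, 50%, 70% of $r$),
24 spatial periods from 4 to 50 px (capped at $r$ for small fixtures)
and 12 orientations, each phase-averaged, and returns the argmax cell
with a lexicographic first-cell tie-break so runs are bit-reproducible.
The diameter tuning curve at those optimal parameters (0 to $r$ in 2-px
steps by default) yields the **grating summation field**: the smallest
diameter reaching 95% of the curve maximum. The grating **suppression
index** is the fractional drop from the curve peak to the largest
diameter; the texture protocol instead uses $(\max - \min)/\max$ with
the minimum restricted to diameters at or beyond the peak, so a rising
limb cannot inflate it.

Neurons enter population analyses only if the GSF lies between 30% and
70% of $r$ and the tuning curves show at least 0.001 variance after
normalization by the optimal-center response. The published exclusion
sentence is ambiguous about whether *both* curves must vary;
`selectNeuron(variationRule = "any")` (default) requires at least one,
`"all"` requires both.

The orientation triplet measures three curves on a shared grid, all
normalized by the optimal-center response: rotating center, rotating
surround alone, and fixed-optimal-center with rotating surround (the
surround suppression tuning curve). Derived statistics are the Pearson
correlation between center and suppression curves (negative when the
most suppressive surround matches the preferred center), the circular
variance $1 - |\sum_\theta R(\theta) e^{2i\theta}| / \sum_\theta R(\theta)$
(responses clipped at zero; the doubled angle lives on the orientation
circle — the exact formula is a documented choice, recorded in output
metadata, since conventions differ), and the orientation deviation of
the suppression minimum from the center orientation, wrapped into
$(-90, 90]$ with a first-minimum tie-break.

Off-optimal centers (offsets 0°, 15°, 30°, 45°) each get their own
suppression curve normalized by that offset's center-alone response —
a documented choice that makes curves comparable across offsets; an
offset whose center response is not positive is flagged and skipped.

The geometry protocol presents two-patch surrounds at several angles,
preferred or orthogonal orientation, and assesses patch-angle
modulation with a classical one-way repeated-measures ANOVA (subjects =
neurons, univariate decomposition, no sphericity correction).

# Contrast protocols

The low-contrast condition scales contrast to 17% of the full range.
`contrastPeakShift()` reports the peak-diameter difference (low minus
high, first-maximum tie-break). `fitContrastModels()` fits the
subtractive model $R_s = \max(0, R_c - a)$ and the divisive model
$R_s = R_c / b$, each by one-parameter least squares **on linear
responses** ($a$ by a grid-plus-golden-section bounded search over
$[0, \max R_c]$, $b$ in closed form, clipped to $[10^{-3}, 10^3]$), and
reports both mean squared errors together with their $\log_{10}$ — the
published comparison is made on the log scale, but the fitting
objective there is unstated, so fitting in linear space is the
package's documented choice. An all-zero surround response yields
$a = \max R_c$ (full suppression) and flags the divisive fit as
ill-posed.

# Two-step surround visualization

The core method optimizes images in the frequency domain: each channel
is a complex coefficient array (stored as real and imaginary parts)
multiplied by a $1/f$ amplitude profile, inverse-transformed (taking
the real part enforces conjugate symmetry) and squashed through a
sigmoid into $[0,1]$. Two regularizers only: the $1/f$ prior and
random circular jitter of the rendered image before compositing (up to
±8 px by default, drawn fresh each step from the run's seeded stream).
The reported image is always the unjittered render.

Step one maximizes the unit's **pre-activation** response (gradients
flow even when the rectifier output is flat at zero) with everything
outside the center disc held gray. Step two freezes the resulting
center, keeps the 4-px gap ring gray, and optimizes only the surround
annulus — minimizing the *signed* pre-activation for the most
suppressive surround, maximizing it for the most facilitative one.
Adam (500 iterations, learning rate 0.005 for fixture networks;
per-layer tables are supported for deep trained networks, whose early
layers need smaller rates) drives both steps. Everything is keyed on
one integer seed; identical seed, configuration and weights give
bit-identical results, and pixels outside the optimized region are
bit-identical across all iterations by construction.

Numerical choices worth knowing:

* **Initialization**: spectral coefficients start as Gaussian noise
  with standard deviation 0.01 (near mid-gray renders). If upstream
  rectifiers zero the parameter gradient at the start — likely in
  narrow fixtures where a two-channel layer can have both channels
  dead — the initialization is redrawn from the same seeded stream (up
  to 20 times) before optimization begins. An optimization that never
  sees a gradient is flagged `failed` and the bundle `converged =
  FALSE`.
* **Jitter on analytic fixtures**: the fixtures are strictly
  phase-locked (period-8 patterns), and circular shifts of up to a full
  half-period make the objective non-stationary, so fixture runs in the
  tests pass `jitterMax = 0`. The ±8 px default reflects the standard
  recipe for trained networks, where jitter suppresses pixel-level
  adversarial structure.
* **Center/gap reading**: the fixed center is the GSF disc exactly;
  the gap ring stays gray in both steps. Both readings of the
  ambiguous gap treatment are available by constructing masks directly.

`permuteCenterColors()` and `exchangeCenter()` re-run the surround step
against altered or foreign centers (bilinear resampling onto the target
GSF disc when geometries differ), which is how the "does the surround
follow the center?" experiments are expressed.

# Similarity metrics

`colorCorrelation()` is the Pearson correlation between the two
3-vectors of channel means inside the center and surround masks;
achromatic regions give `NA`, which propagates as missing, never as
zero. `featureCorrelation()` passes the composite through a reference
network, samples the unit nearest the stimulus center and the four
cardinal units nearest radius $(\mathrm{GSF} + r)/4$ (midway between
the GSF radius and the RF radius), and correlates the center feature
vector with the mean surround vector. Feature vectors are
post-activation (a documented choice; the convention is unstated in the
literature this mirrors), sampling positions are pure functions of
geometry, and a warning is issued when the reference layer's own
receptive field is large relative to the surround ring — a too-deep
reference "sees" the center from the surround positions.
`orientedEnergy()` (a quadrature Gabor bank) is instrumentation for
reading the dominant orientation of visualization outputs.

# Textures versus spectrally matched noise

`generateProceduralTexture()` builds structured grayscale sources from
sparse heavy-tailed impulses convolved with elongated oriented Gabor
kernels: images with genuinely non-Gaussian higher-order statistics
(band-pass kurtosis well above 3) but no downloads. The reduced
synthesizer `synthesizeTexture()` alternates two projections —
imposing the source's Fourier magnitude spectrum and rank-order
matching the source's full marginal histogram (which fixes mean,
variance, skewness and kurtosis simultaneously) — from a seeded noise
start. It deliberately does **not** match cross-scale wavelet
correlations of the full naturalistic-texture statistic set; externally
synthesized textures can be passed into the same protocol for full
fidelity.

Spectrally matched noise replaces the phase spectrum with that of fresh
Gaussian white noise while keeping the magnitude spectrum exactly (DC
kept from the input). The stand-alone operation rescales its output to
the input's range by default; inside `buildTextureFamilies()` each
(texture, noise) pair is instead mapped through one *shared* affine
transform into $[0,1]$, because a shared affine scales both magnitude
spectra identically and keeps the pairing exact to machine precision —
a per-image rescale would break it.

The neuron-level protocol ranks families by modulation index
$(R_\mathrm{nat} - R_\mathrm{noise})/(R_\mathrm{nat} + R_\mathrm{noise})$
at full-RF stimuli (the ranking stimulus size is a documented default;
it is unstated in the source protocol), keeps the top 5 responsive
families (fewer if fewer respond; none responsive drops the neuron),
averages diameter curves within family then across families, divides
both curves by their joint maximum, and compares suppression indices
across neurons with a paired t-test.

# What the fixtures do and do not show

The analytic fixtures plant known ground truth: a center-surround
energy unit with a preferred orientation, period and center extent
(`buildCenterSurroundGabor`), a two-pathway conceptual model with
printed gains (+1 center, −0.8 surround, rectifier, readout weights
$w_1 > w_2$) both in closed form and as a differentiable network
(`buildConceptualModel` / `buildConceptualNetwork`), an oriented
toy convolutional model (`buildToyConvModel`), and random linear conv
stacks for the geometry oracle. Two deliberate departures from the
thinnest possible reading of those models are worth stating: the
oriented stages use *rectified quadrature pairs* rather than single
linear filters, because a purely linear center-surround unit is excited
by anti-phase surround gratings and cannot reproduce the near-zero
surround-alone responses that define the protocol's baseline; and the
fixture surround gain (0.2) is set from the ring/disc area ratio so the
matched-orientation suppression trough is partial rather than floored
at zero, keeping the suppression-curve minimum well-defined.

Passing tests on these fixtures demonstrates that the protocols,
metrics and optimizer do what they claim on networks with known
structure. They do not show anything about ImageNet-trained networks:
fixtures have a handful of channels, exact symmetries and planted
optima, where trained networks have hundreds of noisy channels — the
behavior of the pipeline on such networks is exactly what the tool is
for, with weights supplied by the user. Random-weight stacks serve the
complementary null role: untrained networks are expected to lack the
suppression signatures.

# Problem sizes and determinism

Default fixture inputs are 64×64×3; visualizations run 500 Adam
iterations; the geometry oracle uses five architectures × 100 random
draws; contrast-model identification uses 200 noisy trials at 5% noise;
kurtosis calibrations use 15 seeded 96-px textures. All randomness
flows through explicit integer seeds (`withSeed` restores the caller's
RNG state), per-(neuron, protocol) streams are derived from the run's
root seed so batch composition does not change per-neuron results, and
every argmax/argmin tie-break is first-index and documented.

# Known limitations

* The engine targets fixture-scale networks in pure R; probing an
  ImageNet-scale VGG is possible through the same contract but slow —
  the design assumes users bring activations-and-gradients-capable
  networks of moderate size.
* Dense layers carry no spatial geometry and cannot be probed; only
  convolutional stages are analyzed.
* The reduced texture synthesizer matches spectrum + marginals only;
  conclusions that depend on higher-order wavelet statistics need
  externally synthesized textures.
* The annulus-based surround-extent estimation used in parts of the
  neurophysiology literature is intentionally not implemented; the
  surround's inner diameter is always GSF + 4 px.
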