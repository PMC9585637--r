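---
title: "Dynamic sparse sampling for mass spectrometry imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic sparse sampling for mass spectrometry imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(dlads)
```

## The problem

Mass spectrometry imaging (MSI) rasters a tissue section pixel by pixel (or
line by line, as in nano-DESI), acquiring a full mass spectrum at every
location; each m/z window of interest then yields one ion image. Because the
stage moves slowly relative to the information content of most tissue —
large regions are chemically homogeneous — the vast majority of dwell time
is spent confirming what a handful of measurements already imply. Dynamic
sparse sampling inverts the acquisition: after a small initial sample, the
instrument is steered toward the locations whose measurement would most
improve the reconstructed ion images, and the remaining pixels are
interpolated.

`dlads` implements this closed loop — deep-learning-assisted dynamic sparse
sampling — end to end: ground-truth phantoms, sparse reconstruction,
reduction-in-distortion (RD) supervision, a convolutional estimator of RD
(the ERD network), pointwise and segment-linewise selection policies, a
simulation harness with baselines, a file-exchange mock of the instrument
handshake, and fidelity/throughput evaluation.

## The quantity being optimised: reduction in distortion

Let $X$ be the $d$-channel ground truth over an $N \times M$ grid, $S$ the
measured locations and $\hat{X}^{(S)}$ the reconstruction from them. The RD
of an unmeasured location $u$ is the drop in total absolute reconstruction
error that measuring $u$ would produce:

$$ R(u) \;=\; \sum \bigl|X - \hat{X}^{(S)}\bigr| \;-\; \sum \bigl|X - \hat{X}^{(S \cup \{u\})}\bigr| .$$

`rd_exact()` computes this definition literally (one extra reconstruction
per candidate) and serves as the package's internal oracle. It is far too
expensive to evaluate densely during training, so training labels use the
classical surrogate of the SLADS lineage, `rd_label()`: the absolute error
$|X - \hat{X}^{(S)}|$ smoothed by a spatially adaptive Gaussian.

Two choices here deserve justification:

* **Per-pixel kernel width.** The smoothing sigma at a pixel equals its
  Euclidean distance to the nearest measured pixel (truncated at $3\sigma$,
  capped at 8 px by default). Where sampling is sparse a new measurement
  influences a wide neighbourhood, and the label should integrate error over
  that neighbourhood.
* **Unnormalised kernel.** The kernel is *not* normalised to unit mass: the
  label is a windowed error *sum*, not a windowed mean. A normalised kernel
  measures only the local error level and loses the area-of-influence
  factor; empirically it ranks candidate pixels in near-opposite order to
  `rd_exact()` on two-region images, whereas the unnormalised form places
  the label argmax in the top quantile of the exact ranking (checked in the
  test suite over 20 seeded states).

Even so, the surrogate is local by construction while the exact RD under a
global interpolator has long-range components (one measurement can "rescue"
a whole under-sampled region), so rank agreement is positive but moderate on
tiny grids; the tests pin the oracle-computed values.

## Reconstruction

Unmeasured pixels are filled by inverse-distance-weighted (IDW)
interpolation over the $k = 10$ nearest measured neighbours with weights
$1/(d^2 + 10^{-12})$, measured pixels are passed through verbatim, and all
channels share one neighbour search per state. IDW with squared inverse
distances and a small neighbourhood is the convention of this sampling
lineage; it is linear in the measured values (a property the test suite
exploits), produces convex combinations (no overshoot), and costs one
dense distance computation per iteration on desk-scale grids. An `aspect`
argument exposes anisotropic pixel spacing for scan-rate/line-pitch grids;
it defaults to isotropic because the selection policies operate on the
pixel lattice.

## The ERD network

During acquisition the ground truth is unknown, so RD is estimated by a
network $g^w$ mapping three $N \times M$ planes — the reconstruction, the
measured values (zeros where unmeasured) and the binary measured-location
indicator — to one nonnegative map. The architecture is a compact symmetric
encoder–decoder with skip connections: 3 resolution levels, one $3\times3$
convolution + LeakyReLU (slope 0.1) per level, $2\times2$ average pooling,
nearest-neighbour upsampling, and a linear $1\times1$ head (58,209
parameters at base width 16). Inputs of any size are zero-padded to a
multiple of $2^{\text{depth}-1}$ and the output cropped back.

No deep-learning framework is available to this package, so the forward
pass, backpropagation and the Nadam optimiser are implemented directly in R
(im2col gathers + BLAS matrix products); the gradients are verified against
central finite differences in the test suite, and the first Nadam step
against its closed form. Average pooling is used rather than max pooling —
for a regression target the averaging path is equally expressive and its
gradient is cheaper and smoother.

Training minimises the mean absolute error between prediction and RD label
with per-sample Nadam steps (learning rate $10^{-3}$, $\beta_1 = 0.9$,
$\beta_2 = 0.999$). Both intensity planes are divided by the maximum
measured intensity of the channel and each label by its own maximum, making
training invariant to the instrument's arbitrary intensity scale. A
validation set drives early stopping: training halts after `patience`
epochs without improvement and the best-validation weights are kept
(`patience = 0` therefore trains for exactly one epoch). Per-channel
prediction keeps the model channel-count-agnostic; multi-channel priorities
are the arithmetic mean of per-channel ERD maps (`mean_erd()`).

## Selection policies

* **Pointwise** (`select_pointwise()`): the unmeasured ERD argmax, one pixel
  per iteration; ties break to the lowest (row, col) for determinism.
* **Segment linewise** (`select_linewise_segment()`): choose the scan line
  with maximal summed ERD over its unmeasured pixels, then keep the pixels
  above an Otsu threshold of that line's ERD values. If nothing exceeds the
  threshold the single best pixel is taken; if the values are all equal
  (degenerate threshold) the whole remaining line is taken, so eligible
  lines always yield a non-empty selection.
* **Initialisation**: ERD needs data, so pointwise runs start from 1%
  random pixels (never fewer than one) and linewise runs from three
  complete lines at 25%, 50% and 70% of the sample height.
* **Stopping** (`check_stop()`): target sampling density and/or an
  iteration cap.

`otsu_threshold()` maximises the between-class variance exactly over all
splits between consecutive distinct sorted values, placing the threshold at
the midpoint of the optimal gap. A fixed-bin histogram approximation was
considered and rejected: on the short vectors a scan line produces, two
distinct values can share a bin and the binned optimum can then disagree
with the exhaustive one, while the exact search is O(n log n) and
deterministic.

Line eligibility is configurable: `line_schedule(visited_once_only = TRUE)`
models physical rasters that do not revisit lines; the simulation default
allows revisits so a run can always reach its stopping density on small
grids.

## Simulation, baselines, and the mock instrument loop

`run_dynamic()` digitally resamples a fully measured stack and loops
predict → select → measure → reconstruct. With `model = NULL` it runs in
oracle mode, using the channel-mean of max-normalised RD labels as the
priority map — this separates policy correctness from model quality and
gives an upper reference for the ERD model. Fidelity snapshots (per-channel
and mean PSNR; ERD-vs-RD cosine similarity when a model is used) are taken
at every 1% density increment in pointwise mode and at every iteration in
linewise mode. `run_baseline()` provides the non-adaptive references:
single-shot random masks and uniform line subsampling (every
$\lceil 1/\text{density} \rceil$-th scheduled line).

`mock_acquisition()` executes the identical decision loop but transports
every measurement request through a polling file exchange (request file →
responder writes a data CSV → loop resumes), emulating the handshake with
instrument-side acquisition/stage software. Responses are written with 17
significant digits so values round-trip exactly, and the bundled responder
reads the ground truth, making the mock trace bit-identical to the direct
simulation under the same seed — which the test suite asserts.

## Fidelity and throughput metrics

Reconstruction quality uses MSE and PSNR,
$\mathrm{PSNR} = 10\log_{10}(\mathrm{MAX}_I^2/\mathrm{MSE})$, computed per
channel with $\mathrm{MAX}_I$ equal to the channel's ground-truth maximum
(ion images have no fixed bit depth; the per-channel convention is the
package default and overridable) and then averaged across channels. A zero
MSE returns `Inf` as an explicit perfect-reconstruction sentinel.
ERD quality uses cosine similarity between flattened ERD and RD maps.

The throughput model reproduces raster-acquisition arithmetic:
`scheduled_line_count()` is $\lfloor \text{height}/\text{pitch} \rfloor + 1$
(both edges included) and the full imaging time is
lines × (width/scan-rate + per-line preparation). For an 11.7 × 7.5 mm
sample at 40 μm/s, 150 μm pitch and 9 s/line preparation this gives 79
scheduled lines and ≈259 min; with measured sparse-run components of
100 + 7 + 4 min the sparse total is 111 min, a 2.3-fold improvement —
the arithmetic the acceptance script recomputes.

## The phantom generator

Real MSI ground truth cannot ship with the package, so training and
evaluation use synthetic phantoms (`generate_phantom()`) that emulate the
qualitative structure dynamic sampling exploits: three concentric smooth
elliptical regions (outer ring / inner region / core — analogous to the
cortex, inner cortex and medulla of a kidney section) on an off-tissue
background, with each channel enhanced in a different region the way
different lipids localise to different anatomical structures. Pixel noise
is multiplicative lognormal with configurable coefficient of variation
(default 0.1, a realistic per-pixel CV for summed ion intensities) plus a
small nonnegative additive floor that scales with the CV, so intensities
stay nonnegative, variance grows with intensity, and the noiseless phantom
equals its region template exactly. Default weights: enhanced region 1.0,
other tissue 0.3, background 0.05.

What the phantoms deliberately do not model: spectral structure (channels
are already-extracted ion images), spatially correlated noise, instrument
drift, tissue-edge artefacts, or fine texture such as tubules. Passing
tests therefore demonstrate that the machinery — reconstruction, RD
supervision, learned ERD, policies, transports, metrics — behaves correctly
on structured multi-channel images; they do not certify reconstruction
fidelity numbers on real tissue.

## Problem sizes and numerical choices

The package's evaluation suite uses 32×32 six-channel phantoms (10 seeds)
for policy comparisons and trains the ERD network on 240 samples — 2
stacks × 4 channels × 30 resampling densities (1–30% at 1% intervals) at
64×64 — for at most 10 epochs with patience 2; these sizes give stable
averages for every qualitative comparison while keeping a full run on a
single CPU within minutes. Other defaults: IDW `k = 10`, `eps = 1e-12`;
label sigma cap 8 px; negative RD clamped to zero (a priority score must be
nonnegative; the unclamped value is kept as a diagnostic attribute);
fraction-to-count rounding is half-away-from-zero with a floor of one
pixel so initialisation is never empty; all tie-breaks are lexicographic
lowest-index; every source of randomness is an explicit seed argument.

## Known limitations

* The ERD network is deliberately small and CPU-trainable; it is not a
  reproduction of any published architecture at scale.
* The RD surrogate is local; its agreement with the exact oracle degrades
  on very small grids where single measurements have global influence.
* The imzML importer covers the continuous and processed dialects with
  external float32/float64 arrays — the subset needed to bind real ion
  images into the workflow — not the full vocabulary of the format.
* Oracle-mode simulation results bound, but do not equal, what a trained
  model achieves; both are exercised in the tests.

## A worked micro-example

```{r example, eval = FALSE}
truth <- generate_phantom(phantom_spec(shape = c(32, 32), n_channels = 6,
                                       noise_cv = 0.1, seed = 1))
trace <- run_dynamic(truth, "pointwise", criteria = list(max_density = 0.3),
                     seed = 1)
tidy(trace)        # density / PSNR snapshots at each 1% increment
glance(trace)      # final density, iterations, mean PSNR
autoplot(trace)    # PSNR-vs-density curve
```
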