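# dlads — deep-learning-guided dynamic sparse sampling for MSI

Mass spectrometry imaging (MSI) acquires a full mass spectrum at every pixel
of a tissue raster, so imaging time scales with the number of pixels even
though most of a section is chemically uninformative. `dlads` implements
dynamic sparse sampling for MSI: starting from a small seed measurement, it
repeatedly predicts which unmeasured locations are most *molecularly
informative*, steers measurement there, and reconstructs the full
multi-channel ion-image stack from the sparse samples. It is aimed at MSI
methods developers and instrument integrators who want to simulate, train,
and drive adaptive acquisition, and at anyone studying active-sampling
policies on image-like data.

## The method

For ground truth $X$ (one $N \times M$ image per m/z channel), measured set
$S$ and reconstruction $\hat{X}^{(S)}$ (inverse-distance-weighted
interpolation, $k = 10$, weights $1/(d^2+\varepsilon)$), the value of
measuring an unmeasured pixel $u$ is its **reduction in distortion**

$$R(u) = \textstyle\sum|X - \hat{X}^{(S)}| - \sum|X - \hat{X}^{(S\cup\{u\})}|,$$

computable only when $X$ is known. During acquisition a compact
encoder–decoder CNN $g^w$ — trained with Nadam on mean-absolute-error
against Gaussian-filtered RD labels from 1–30% random resamplings —
estimates it (the **ERD**) from three input planes: reconstruction, measured
values, and the measured-location mask. Per-channel ERD maps are averaged,
then a policy selects the next measurement:

* **pointwise** — the ERD argmax, one pixel per iteration;
* **segment linewise** — the scan line with maximal summed ERD, thresholded
  by Otsu into a line segment (the mode physical line-scanning stages use).

Runs stop at a target sampling density. Fidelity is scored by per-channel
PSNR $= 10\log_{10}(\mathrm{MAX}_I^2/\mathrm{MSE})$ against ground truth, ERD
quality by cosine similarity to the true RD, and acquisition speed-up by a
raster throughput model. Real data can be bound in through a minimal imzML
importer; tissue-like multi-channel phantoms (nested anatomical regions,
lognormal noise) are generated in code for training and evaluation.

## Worked example

```r
library(dlads)

truth <- generate_phantom(phantom_spec(shape = c(32, 32), n_channels = 6,
                                       noise_cv = 0.1, seed = 1))
truth
#> <channel_stack> 32 x 32 pixels, 6 channel(s)
#> channels: mz001, mz002, mz003, mz004, mz005, mz006

trace <- run_dynamic(truth, "pointwise", criteria = list(max_density = 0.3),
                     seed = 1)   # oracle-guided: priorities from true RD labels
trace
#> <dlads_trace> mode pointwise, 31 snapshot(s), final density 30.1%, mean PSNR 21.92 dB

dplyr::slice(tidy(trace), c(1, 11, 21, 31))
#>   iteration n_measured  density psnr_mean
#> 1         0         10 0.009766     12.50
#> 2        93        103 0.100586     18.32
#> 3       195        205 0.200195     20.26
#> 4       298        308 0.300781     21.92

run_baseline(truth, "random", 0.3, seed = 1)$metrics$psnr_mean
#> [1] 19.57
```

Reading the numbers: from a 1% random seed (10 pixels, 12.5 dB) the
oracle-guided pointwise run climbs to a mean PSNR of 21.9 dB across the six
channels at 30% sampled — about 2.3 dB above a single-shot random mask of
the same size, because measurements concentrate along region boundaries
where interpolation is worst. `autoplot(trace)` draws the PSNR-vs-density
curve; `run_dynamic(..., model = train_erd_model(...))` replaces the oracle
with the learned ERD, and `mock_acquisition()` runs the same loop over a
polling file exchange as an instrument would.

The throughput model reproduces raster arithmetic from the scan geometry:

```r
estimate_throughput(scan_geometry(11.7, 7.5, 40, 150), timing_model(9),
                    sparse_times = list(ms = 100, prep = 7, compute = 4))
#>   scheduled_lines full_time_min sparse_time_min fold_improvement
#> 1              79       258.725             111         2.330856
```

i.e. 79 scheduled lines, an estimated 259 min for full coverage, 111 min
for the sparse run — a 2.3-fold throughput improvement.

A thin command-line front end wrapping these functions ships in
`inst/cli/dlads.R` (subcommands `phantom`, `train`, `simulate`, `baseline`,
`evaluate`, `throughput`, `mock-acquire`), and
`vignettes/dlads-methods.Rmd` documents the models, parameters and design
choices.

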