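# censpa

Single-particle averaging (SPA) of centromere geometry from multi-channel 3D
fluorescence microscopy.

## The problem

During mitosis the human centromere has to do two things at once: assemble a
kinetochore that binds spindle microtubules, and keep the sister chromatids
glued together until anaphase. These functions map onto distinct structures —
paired CENP-A chromatin clusters facing opposite poles, a pericentromeric
cohesin axis between the sisters, and a cloud of α-satellite DNA spanning
them. Individual super-resolution images of single centromeres are too noisy
and too variable to measure this geometry; the solution is single-particle
averaging: detect hundreds of centromeres, rotate each into a common frame
defined by its CENP-A pair, and sum. `censpa` is an R implementation of that
pipeline for people who quantify centromere/kinetochore organisation in
fixed-cell 3D-SIM or confocal data, plus an interval module for the matching
ChIP-seq region statistics.

## The method in brief

For each detected CENP-A pair with refined 3D cluster centres
$c_1, c_2$ (sub-pixel, from Levenberg–Marquardt fits of 3D Gaussians), define
the lateral axis $x$ along $c_2 - c_1$ and the chromosomal axis $y$ through
the midpoint. After rotation, cropping (60×60 px) and mirror augmentation,
band-integrated intensity profiles $I(x)$ and $I(y)$ of the summed image are
fitted with $k = 1..3$ Gaussians plus offset,

$$I(t) = b + \sum_{i=1}^{k} A_i \exp\!\left(-\frac{(t-\mu_i)^2}{2\sigma_i^2}\right),$$

with $k$ selected by $\mathrm{AIC} = n\ln(\mathrm{RSS}/n) + 2(3k+1)$. The
fitted $\mu_i, \sigma_i$ carry the reported geometry: the inter-CENP-A
distance (peak-to-peak of the two-cluster fit), the cluster S.D., the lateral
S.D. of the cohesin band, the FWHM of its axial extent, and the peak offsets
and central-dip span of the satellite cloud. Cohesin patterns are classified
per particle by the center-enriched ratio (mean intensity within ±120 nm of
the centre over the 160–320 nm flank bands along $y$), ranked, partitioned
into split/uniform/central classes, and compared by Kruskal–Wallis with
Dunn/Benjamini–Hochberg post-hocs.

Because raw microscopy data cannot ship with the package, a calibrated
forward simulator (`geometry_config()`, `render_spread()`) generates
multi-channel stacks with known ground truth — paired 81 nm CENP-A clusters
562 ± 91.6 nm apart, a 190 nm-wide cohesin band extending 800 nm axially
with class-dependent centre modulation, satellite clouds with lateral maxima
at ±209 nm (or the chromosome-7 preset: 634 ± 102 nm spacing, ±206 nm
maxima, 175 nm S.D.) — so the whole pipeline is validated by parameter
recovery. The genomic module computes replicate-consensus peak sets,
peaks/Mb per region class (asHOR / CenHap / CenAdj / random nonCen),
log2 densities, mapped-read proportions and overlap fractions from BED
intervals via GenomicRanges.

## Worked example

```r
library(censpa)

run <- run_pipeline(geometry_config(), noise_config(seed = 101), n = 400)
print(run$geometry, digits = 5)
```

```
               quantity   value unit                                source
1       separation_mean 563.787   nm               per-particle refinement
2         separation_sd  90.187   nm               per-particle refinement
3 cluster_sigma_refined  81.838   nm               per-particle refinement
4       inter_cenpa_fit 562.440   nm                     average-image fit
5       cenpa_sigma_fit  94.599   nm                     average-image fit
6    cenpa_sigma_deconv  83.159   nm average-image fit, jitter-deconvolved
7  marker_lateral_sigma 192.340   nm                     average-image fit
8     marker_axial_fwhm 800.251   nm                 average-image profile
```

Reading this: 400 simulated centromeres were detected, paired, refined,
aligned and averaged (about a minute on one core). The per-particle refined
centre distances average 563.8 nm with S.D. 90.2 nm — the configured
562/91.6 nm geometry recovered. The two-Gaussian fit of the averaged lateral
CENP-A profile puts the peaks 562.4 nm apart; its raw per-peak sigma
(94.6 nm) is broadened by the particle-to-particle separation jitter, and
removing that in quadrature gives the single-cluster width of 83.2 nm
(truth: 81 nm). The cohesin band fits a lateral S.D. of 192.3 nm (truth:
190 nm) and an axial FWHM of 800.3 nm (truth: 800 nm). `plot(run)` shows the
averaged channels and the fitted profiles; `run$classes` holds the
split/uniform/central classification with its Kruskal–Wallis comparison.

A thin command-line wrapper with `simulate`, `detect`, `average`, `profile`,
`classify`, `density` and `run-all` subcommands lives at
`inst/scripts/censpa-cli.R`.

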