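---
title: "Measuring centromere core geometry by single-particle averaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring centromere core geometry by single-particle averaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(censpa)
```

## The measurement problem

On a metaphase chromosome the two sister kinetochores assemble on CENP-A
chromatin clusters that face opposite spindle poles, while cohesin holds the
sisters together at the pericentromere between them. Individual
super-resolution images of single centromeres are too noisy and too variable
to read off this geometry reliably. Single-particle averaging (SPA) solves
this the way cryo-EM does: detect many equivalent structures, put them into a
common reference frame, and average. Sub-pixel structure that survives
averaging is real, and its dimensions can be fitted.

`censpa` implements this pipeline for 3-channel 3D fluorescence stacks
(DNA counterstain / CENP-A / a second marker such as a cohesin subunit or a
satellite-DNA FISH probe), together with a calibrated forward simulator.
Because real microscopy data cannot ship with a package, the simulator is a
first-class module: its defaults encode the measured geometry of human
mitotic centromeres, and every stage of the pipeline is validated by
*parameter recovery* — simulate with known truth, run the full analysis, and
check that the measured quantities equal the configured ones.

## The forward model

Each synthetic particle is a sum of separable structures in its own frame
(lateral axis $x'$ through the two CENP-A clusters, chromosomal axis $y'$
perpendicular to it, stack axis $z$):

* **CENP-A**: two isotropic-in-$xy$ 3D Gaussians at $\pm s/2$ along $x'$,
  with per-particle separation $s \sim \mathcal N(562, 91.6^2)$ nm and
  cluster S.D. 81 nm (axial S.D. 200 nm). These defaults are the
  population-level measurements the package is calibrated to.
* **Cohesin band**: a Gaussian cross-profile of S.D. 190 nm along $x'$
  (the "lateral width" is read as a fitted Gaussian S.D.), times an axial
  top-hat of full extent 800 nm convolved with a 50 nm Gaussian. A top-hat
  with Gaussian shoulders has its half-maximum exactly at the top-hat edges,
  so the band's FWHM equals the configured extent by construction, and FWHM
  is how the pipeline measures "axial extent" downstream (the source
  measurements quote only an approximate extent, so an operational measure
  had to be fixed; FWHM is the standard choice).
* **Cohesin classes**: centromeres vary continuously from centre-depleted to
  centre-enriched cohesin. The generator realises three canonical patterns
  by modulating the band along $y'$ with a Gaussian of S.D. 120 nm
  (half the 240 nm / 6-pixel offset used by the classifier):
  `split` multiplies by $1 - 0.7\,G(y')$, `uniform` leaves the band flat,
  `central` multiplies by $1 + 1.0\,G(y')$. The depth/enhancement defaults
  were chosen once so that the three classes' center-enriched ratios
  (about 0.55, 1.0 and 1.6 noise-free) bracket the ordering seen in ranked
  montages of real spreads.
* **Satellite cloud** (CENP-B box or chromosome-specific FISH presets): two
  equal lateral Gaussians at $\pm c$. Overlapping tails pull the intensity
  maxima of the sum inward of $c$, so $c$ is solved numerically at
  configuration time such that the *maxima* sit exactly at the configured
  peak offset (±209 nm for the pan-centromeric preset; ±206 nm with
  S.D. 175 nm and a 247 nm axial spread for the chromosome-7 preset).
* **DNA counterstain**: a single diffuse ellipse, elongated along the
  chromosome. It is context only and nothing is measured from it.

Structures are drawn already blurred — the configured S.D.s are post-PSF
widths — because simulating illumination patterns or SIM reconstruction is
out of scope. Pixels (40 nm pitch, 125 nm z-step, 9 slices by default;
0-based indices with pixel centres at $(i+0.5)\cdot$pitch) are integrated
in-plane with a 3-point Gauss–Legendre rule per axis, which matches dense
numerical integration of the model to about $10^{-6}$; z is sampled at slice
centres. Noise is photon (Poisson) noise followed by additive Gaussian
camera noise (S.D. 3 intensity units against channel amplitudes of 40–100
and background 10). Everything is bit-reproducible under a fixed seed.

### What the simulator does not emulate

Real spreads have touching chromosomes, out-of-focus light, chromatic
misalignment, anisotropic PSFs, reconstruction artefacts, tilted
inter-sister axes and biological outliers (the generator keeps the axis in
the imaging plane; a z offset between clusters is supported but defaults to
0). Passing recovery tests therefore demonstrates that the *analysis* is
correct and unbiased at realistic signal levels — not that it is robust to
every pathology of real data. The detection thresholds (intensity quantile
0.999, smoothing S.D. 1 px, minimum maxima distance 3 px) are defaults a
user should expect to tune on real images.

## The analysis pipeline

1. **Detection** (`detect_peaks`): local maxima of the Gaussian-smoothed
   CENP-A stack above an intensity quantile, non-maximum-suppressed.
2. **Pairing** (`pair_peaks`): mutual nearest neighbours gated to
   separations of 200–1200 nm, which brackets both the genome-wide
   (562 ± 91.6 nm) and the chromosome-7 (634 ± 102 nm) spacings at more
   than 4 S.D. Equidistant ties go to the brighter partner, making the
   pairing deterministic and order-independent.
3. **Refinement** (`refine_center_gaussian3d`): Levenberg–Marquardt fit of
   an isotropic-in-$xy$, separate-$\sigma_z$ 3D Gaussian plus offset in an
   11×11×7 window; non-convergent or escaping fits are dropped and counted.
   Per-particle separations and their S.D. are taken from these refined
   centres.
4. **Alignment** (`align_particle`): the field is rotated about the pair
   midpoint so the inter-cluster axis is horizontal, the z-slice nearest
   the fitted midpoint is extracted, and a 60×60 px crop is centred on the
   midpoint. With an even crop there is no centre pixel; the midpoint maps
   to the corner shared by the four central pixels and all profile
   coordinates are relative to that point, which makes mirroring an exact
   index reversal. Interpolation is bilinear — monotone, no ringing next to
   tight clusters. The published convention draws the inter-cluster axis
   horizontally, and this package fixes lateral = x, chromosomal = y.
5. **Mirroring and averaging** (`mirror_augment`, `sum_particles`):
   chromosome orientation is arbitrary, so every patch is averaged together
   with its lateral mirror; lateral profiles are then exactly symmetric.
   The stored average is the *sum* (profiles are shape-invariant to the
   sum/mean choice).
6. **Profiles and fits** (`extract_profile`, `fit_gaussians`): profiles
   integrate a pixel band about the midline. The nominal band is 5 px
   (200 nm at the 40 nm raster; 155 nm on a 31 nm raster); with the even
   crop the closest symmetric band is 6 px and that is the default. For the
   CENP-A width along the chromosomal axis a 41 px zone is used so both
   off-axis peaks are encompassed. Profiles are fitted with $k = 1\ldots3$
   Gaussians plus offset; the model is selected by
   $\mathrm{AIC} = n\ln(\mathrm{RSS}/n) + 2(3k+1)$ (least-squares form; at
   $n \approx 60$ samples the small-sample correction changes no decision
   in the test suite, so it is omitted). Ties within $10^{-9}$ resolve to
   the smaller $k$.
7. **Classification** (`center_ratio`, `rank_and_partition`,
   `class_summary`): the marker's axial profile is summarised by the
   center-enriched ratio — mean intensity within ±120 nm of the centre
   divided by the mean in the 160–320 nm bands. Low ratios are split,
   high ratios central. (The alternative convention, off-centre over
   centre, is available as a mode flag; the canonical direction is the one
   under which published rank anchors — e.g. rank 1 at ratio 0.0861 being
   a split centromere — are internally consistent.) Particles are ranked
   by ascending ratio and partitioned either into the 200/150/113 rank
   blocks (default, because published per-class sample sizes depend on
   them) or into equal thirds. Class-wise inter-CENP-A distances are
   compared with a Kruskal–Wallis test and Dunn's post-hoc z tests with
   Benjamini–Hochberg adjustment (Dunn's test is implemented in-package;
   no dependency provides it).

## Operational definitions worth spelling out

**Cluster width from an averaged image.** The summed average is the true
structure convolved with the residual alignment spread: each CENP-A peak
wanders about its mean position by half the particle-to-particle separation
spread, so the fitted peak S.D. is
$\sqrt{\sigma_\text{cluster}^2 + (\mathrm{SD}_\text{sep}/2)^2}$
(about 93 nm for 81 nm clusters and a 91.6 nm separation S.D.). The
geometry report therefore lists both the raw fitted sigma and
`cenpa_sigma_deconv`, the jitter-deconvolved cluster S.D. computed with the
pipeline's own measured separation S.D. The deconvolved value is the
estimate of a single cluster's width; the per-particle 3D refinement sigma
(`cluster_sigma_refined`) provides an independent route to the same
quantity.

**Satellite dip width.** A smooth profile with maxima at ±209 nm cannot
have a central depression whose *half-depth* width is 411 nm — the
half-depth crossing would have to sit 3.5 nm inside a smooth maximum, which
forces a knife-edge peak (for the two-Gaussian cloud the half-depth width
is about 212 nm). Since 2 × 209 = 418 nm, the quoted dip width is evidently
the *span of the depression between the two flanking maxima*, and that is
the definition `cloud_metrics()` implements: locate the two maxima of the
AIC-selected fitted curve flanking the central minimum and report their
distance (along with the fractional dip depth). Under this definition the
peak offset and dip width are mutually consistent to better than 2%.

**Axial extent.** FWHM of the marker's chromosomal-axis profile, measured
against a baseline estimated from the outermost samples, with linear
interpolation between samples.

## Numerical and degenerate-input behaviour

* Peak fits run with box constraints (non-negative amplitudes, centres
  inside the profile, sigmas at least half a sample step); initial centres
  come from the largest local maxima of the lightly smoothed profile.
* A zero flank band makes the center-enriched ratio infinite; such
  particles rank last rather than erroring.
* A quantity undefined under the selected model (peak-to-peak with $k=1$,
  dip width of a unimodal cloud) is reported as `NA`, never as an error.
* Zero detected particles produce an empty result object with a warning
  (the command-line wrapper exits non-zero).
* `log2` of a zero peak density is reported `NA` — a pseudocount would
  distort cross-region comparisons.
* Random non-centromeric comparison regions default to 2 Mb, matching the
  scale of the centromere-adjacent flank regions they are compared with.

## Genomic interval module

The imaging results are complemented by an interval-arithmetic module
(backed by `GenomicRanges`) for the ChIP-side of the analysis, which starts
from called peak intervals (read alignment and peak calling are out of
scope): replicate-consensus peaks (union-reduce, then require support from
at least 2 replicates), peaks/Mb per region class with midpoint assignment
(midpoint keeps counts additive when labels partition the genome),
mapped-fragment proportions per region class, uniform random sampling of
non-centromeric comparison regions outside an exclusion set, and
query-overlap fractions.

## Validation scale and reproducibility

The package's recovery checks run the full pipeline at the study's scale:
400 simulated particles for the default and satellite configurations, 200
for the chromosome-7 preset, and 463 (the published spread count) for
classification, where the default rank boundaries reproduce the 200/150/113
class sizes exactly and ≥85% of particles recover their generating class.
Localization precision is verified over 200 single-cluster refits.
Replicate-stability and noise-scaling properties run at reduced sizes
(3 × 100 particles; 100 noise replicates), chosen to keep the default test
suite fast while leaving the full-scale checks to the recovery tests; the
scaled runs test the same invariants at looser, size-appropriate
tolerances. All randomness flows through explicit seeds; identical seeds
give byte-identical outputs, including written CSVs.

```{r example, eval = FALSE}
# a complete small run
run <- run_pipeline(geometry_config(), noise_config(seed = 1), n = 120,
                    verbose = TRUE)
print(run)
plot(run)
```

## Known limitations

* The simulator's realism gap (above) means thresholds need tuning on real
  data; the `annotations` override in `find_particles()` accepts hand-picked
  pairs for that purpose.
* The inter-sister axis is assumed to lie in the imaging plane; strongly
  tilted particles in real data would foreshorten separations.
* The z-slice extraction uses the single nearest slice rather than
  interpolating between slices; at a 125 nm step this bias is negligible
  against the 200–300 nm axial widths, but very fine z structure would be
  missed.
* Dunn's post-hoc test uses the large-sample normal approximation; for
  classes of fewer than ~10 particles its p-values are indicative only.
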