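# entolidar

Insect biodiversity estimation from entomological lidar backscatter.

An entomological lidar records everything that flies through its beam as
16-bit time–range intensity maps (2048 range bins × 35,000 exposures per
10 s block, 1.75 kHz effective sample rate after background subtraction).
Each insect transit is a ~25 ms burst whose intensity is modulated at the
wingbeat frequency and its harmonics. This package implements the full
analysis chain that turns such recordings into community-level diversity
estimates, for ecologists and lidar groups who want richness proxies
without species-level classification:

1. **Event extraction** — observations cropped as 8-connected islands in
   a Boolean map where backscatter strictly exceeds its range bin's
   median + 2·IQR, each paired with an instrument-noise fragment cut with
   the identical mask at a disjoint time.
2. **Modulation spectra** — Welch power spectra (Gaussian window of 40
   samples, FWHM 20) of every transit ≥ 25 ms, on a fixed 40-bin axis
   (40–820 Hz, 20 Hz spacing).
3. **Diversity clustering** — the core method. Spectra are
   auto-normalized and log-transformed, `v_f = log(P_f / ΣP + ε)`, and
   agglomerated under Ward's criterion by a linear-memory
   nearest-neighbour chain (no N×N distance matrix). Sorted branch
   linkages `Z_(p)` are detrended by a power law,
   `Z_comp(p) = (p/(N−1))^β · Z_(p)` with `β` the median log–log slope,
   and the cluster count is parameter-free:

   `NoC = #{ p : Z_comp(p) > median(Z_comp) + IQR(Z_comp) }`

   The identical pipeline on the paired noise fragments is the negative
   control; it plateaus flat and yields `NoC = 0`.
4. **Composition and range models** — rank-abundance fit
   `Â(c) = A0·(1 − c/(NoC+1))^γ` (γ = 0 ⇒ perfectly even), detection-range
   profile `Â(r) = A·(1 − (r/r_det)^α)^(1/α)` (α = 2 ⇒ spherical
   attenuation), per-cluster summaries and bias correlations.
5. **Spatio-temporal niches** — unique range patterns (50 geometric bins,
   5% relative width) and diel activity patterns (96 × 15-min bins)
   counted by re-applying the same cluster criterion to the
   distributions.

A ground-truthed synthetic scene generator (multi-species wingbeat
ensembles, Gaussian transit envelopes, rank-abundance compositions,
range-occupancy profiles, diel niches, raw frame blocks with an event
ledger) makes every stage testable without field data.

## Worked example

```r
library(entolidar)
report <- run_all(run_config(label = "demo", seed = 3, n_species = 4,
                             a0_true = 300, gamma_true = 0.5))
report
#> Run 'demo' (seed 3)
#>   observations: 824 (497 past transit filter)
#>   clusters: NoC = 3 (noise control: 0), beta = 0.655
#>   composition: A0 = 177.6, gamma = 0.473, A_half = 127.9, R2adj = 0.9862
#>   unique patterns: 0 range, 1 diel
```

Reading it: a 4-species synthetic scene produced 824 observations, 497 of
which carried enough wingbeat periods (≥ 25 ms) for spectral analysis.
The compensated linkages show 3 splits distinguishable from noise
(`NoC = 3`, i.e. 4 flat clusters — one per species), while the matched
noise control finds none, and the linkage decay exponent `beta` sits
below ½ as expected. The rank-abundance fit recovers an unevenness close
to the generating γ = 0.5, and one distinct diel activity pattern
separates among the clusters' daily histograms.

A command-line wrapper is installed with the package
(`inst/cli/entolidar`): `entolidar run-all --config scene.yaml`.

## Method vignette

`vignettes/entolidar-methods.Rmd` documents the model and its
assumptions, every tunable parameter with units and defaults, what the
synthetic generator does and does not emulate, and the package's
numerical choices and known limitations.
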