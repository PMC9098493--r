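# photobodykit

Quantification toolkit for light-induced nuclear condensates ("photobodies")
and the companion assays used in optogenetic condensate studies of the plant
blue-light receptor pathway. It is aimed at microscopists and plant
photobiologists who have fluorescence images of nuclei containing
condensates, FRAP traces, light-cycle time-lapses, ChIP-qPCR Ct tables or
luciferase plate-reader series, and want the standard derived statistics
reproducibly, from code instead of interactive ImageJ sessions.

## What it computes

**Condensate statistics.** Nuclei are segmented by a winsorized Otsu
threshold (largest connected component, hole-filled); condensates inside the
nucleus are pixels brighter than the within-nucleus mean + *k*·sd
(8-connected, regions < 4 px discarded). Each region is measured (area *A*,
Crofton perimeter *P*, mean intensity) and the package derives:

- circularity = 4π·*A*/*P*² (1 for a circle, < 1 for irregular shapes);
- partition ratio = photobody intensity / background intensity, where the
  background is the whole-frame mean in vitro and the whole-nucleus mean in
  vivo; a sample with no detected particles is assigned the conventional
  value 1;
- per-time-point partition ratio Σᵢ P(i) / (n·N), with P(i) the intensity of
  each photobody, n the count per nucleus and N the nucleus mean intensity;
- size-distribution fraction: count(area > 0.75) / count(total);
- condensate count per unit nucleus area, and normalized-size time series
  (first time point scaled to 1).

**FRAP.** Double normalization
I꜀₁(t) = I(t) − B, R꜀₁(t) = R(t) − B, I꜀₂(t) = I꜀₁(t)/R꜀₁(t),
I꜀₃(t) = I꜀₂(t)/I꜀₂(p), so the pre-bleach point p is exactly 1; then an
optional single-exponential fit f(t) = f₀ + (plateau − f₀)(1 − e^(−kt))
giving the mobile fraction A = (plateau − f₀)/(1 − f₀) and t½ = ln 2/k.

**Light cycles.** Partition-ratio trajectories across programmed on/off
illumination schedules (e.g. 10 min on / 10 min off), and a reversibility
index (PR_end-of-off − 1)/(PR_end-of-on − 1): 0 = full disassembly in the
dark, 1 = none.

**ChIP-qPCR.** Adjusted input = Raw Ct(input) − log₂(aliquot fraction) with
the printed percent convention (a 1.25% aliquot subtracts log₂(1.25) = 0.32;
the conventional log₂(100/fraction) correction is available via
`convention = "standard"`), and IP/Input = 2^(Ct(adjusted) − Ct(sample)).

**Bioluminescence.** First-time-point normalization, optionally followed by
division by the series maximum, plus a windowed (max − min)/2 amplitude for
pulse comparisons.

**Synthetic data.** Seeded generators for all of the above — nuclei as
bright disks with fold-enriched condensates and Gaussian read noise, FRAP
traces with known mobile fraction and rate, on/off-cycle stacks with known
residual assembly, damped-cosine luminescence rhythms, and Ct tables with
known enrichment — so every stage is testable against ground truth.

## Worked example

```r
library(photobodykit)
scene <- scene_truth(condensates = disk_condensates(3, radius = 4, fold = 5),
                     noise_sd = 100, seed = 7)
img  <- generate_condensate_image(scene)$image
cset <- detect_condensates(img, segment_nucleus(img))
cset
#> condensate_set (in_vivo): n = 3, nucleus area = 6320 px, N = 2196, background = 2196
cbind(cset$regions[, c("area", "perimeter")],
      circularity = circularity(cset$regions$area, cset$regions$perimeter))
#>   area perimeter circularity
#> 1   51    25.340       0.998
#> 2   51    25.340       0.998
#> 3   52    25.895       0.974
partition_ratio(cset)
#> [1] 4.556965
```

All three synthetic fold-5 disks are found; their circularity is ~1 (they
are circles, up to rasterization) and the measured partition ratio 4.56
matches the analytic expectation — enrichment 5 over the nucleoplasm,
diluted because the nucleus mean N includes the bright condensate pixels.

```r
tr  <- generate_frap_trace(frap_truth(mobile_fraction = 0.8, rate = 0.1,
                                      noise_sd = 0.01, seed = 7))
fit_recovery(normalize_frap(tr$trace))
#> FRAP recovery fit (99 points): mobile fraction A = 0.786, k = 0.103 /s, t1/2 = 6.72 s

chip_enrichment(generate_ct_table(enrichments = c(TBS = 8, MC = 1)))[, c(1, 7, 8)]
#>   region adjusted_input ip_over_input
#> 1    TBS       19.67807             8
#> 2     MC       19.67807             1
```

The FRAP fit recovers the simulated mobile fraction (0.8) and rate
(0.1 s⁻¹) within ~2% at 1% trace noise, and the ChIP arithmetic returns the
simulated enrichments exactly in the noiseless case (the adjusted input
shows the −0.32 cycle aliquot correction).

A pipeline driver (`run_pipeline()`, with a thin command-line wrapper in
`inst/scripts/photobodykit`) ties the stages together: `simulate`,
`quantify`, `frap`, `cycles`, `chip` and `lumin` subcommands read TIFF/CSV
inputs and write CSV artifacts plus a `run.log` with the seed and
configuration.

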