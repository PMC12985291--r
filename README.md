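# wildtrace

Computational spine of an end-to-end screening workflow for trafficked
wildlife, built for researchers and screening practitioners who need the
pipeline to be runnable, testable and auditable without access to the
(legally restricted) seized-parcel scans. The package covers three layers:

1. **Detection** — concealed-animal detection in 3D X-ray radiodensity
   volumes: organic thresholding, morphological opening, 26-connected blob
   extraction, then two classifier families: *AT.2*, a random forest over
   hand-crafted blob features (intensity distribution, size, shape), and
   *AT.3*, maximum-intensity projections (MIP) of each blob along the three
   axes, resampled to 128×128, embedded to 3×160 features and classified by
   a stack of five fully connected layers with a softmax output.
2. **Dosimetry** — an analytic pXRF exposure model: Kramers tungsten-anode
   spectra for the three-beam protocol, Beer–Lambert attenuation through a
   0.5 mm keratin scale layer (C₂₇H₅₇N₈O₁₇S₁, 1.32 g/cm³), surface-kerma
   normalisation to the measured 227 mGy, mean absorbed dose in the 20 mm
   soft-tissue layer, and the effective dose
   *E = D_soft × f_irradiated × 1.0 mSv/mGy*.
3. **Trial statistics** — detection-rate aggregation over consignments, the
   pooled one-tailed two-proportion z-test
   *z = (p̂₂ − p̂₁) / √(p̂(1−p̂)(1/n₁+1/n₂))* (no continuity correction),
   the ensemble abstention ("undetermined") rule for wild-vs-captive
   provenance calls, and seizure-register tallies.

A synthetic phantom generator (parametric lizard/fish/bird inclusions among
clutter, seeded and fully deterministic) makes every stage testable without
any data download; the trial's printed summary tables ship as CSV fixtures.

## Worked example

```r
library(wildtrace)

# -- dosimetry: the three-beam protocol through 0.5 mm keratin ----------
res <- withEffectiveDose(softTissueDose(geoChemProtocol()))
res
#> pXRF dose model result
#>   surface air kerma        : 227.0 mGy
#>   keratin flux transmission: 0.938
#>   soft-tissue fraction     : 0.347 of surface kerma
#>   soft-tissue dose         : 78.8 mGy
#>   irradiated fraction      : 0.0450
#>   effective dose           : 3.5 mSv (1.0 mSv/mGy)
```

The modelled soft-tissue dose is the fraction of the measured surface air
kerma that reaches the tissue behind the keratin scales, averaged over the
20 mm soft-tissue depth — about a third of the surface dose. Multiplying by the
irradiated-volume fraction gives the whole-body effective dose of a single
pXRF measurement; combined with the CT scanner's conservative 5 mSv bound,
`combinedExposure(5, effectiveDoseMsv(res))` stays in the range of annual
natural background exposure.

```r
# -- trial statistics from the shipped fixtures -------------------------
detectionRate(loadFixture("table1"), "AT.2")
#> $detected
#> [1] 10
#> $total
#> [1] 48
#> $percent
#> [1] 20.83

pValue(twoProportionZTest(10, 48, 27, 48))
#> [1] 0.0001819387
```

AT.2 detected 10 of 48 parcels (20.83%), AT.3 27 of 48 (56.25%); the
one-tailed pooled z-test puts the probability of an improvement this large
under the null at p ≈ 0.00018.

```r
# -- synthetic parcel through the detection front end -------------------
lv <- makeParcel(phantomSpec(gridShape = 64L, animalClass = "lizard",
                             animalScale = 80, clutterCount = 2L, seed = 3))
pb <- parcelBlobs(scanVolume(lv))
length(pb$blobs)
#> [1] 1
```

`runDetectionBenchmark()` generates a 200-parcel corpus, trains both
pipelines and reports held-out blob accuracies; `classifyParcel()` applies
a trained model to a single volume and returns a thresholded
`ParcelDecision`. Volumes read and write as NRRD or NIfTI
(`readVolume()` / `writeVolume()`), and `runPipeline()` composes the
stages into a JSON/Markdown trial report. A thin command-line wrapper
lives at `inst/scripts/wildtrace.R`.

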