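# RecruitKinetics

Quantifies the recruitment kinetics of fluorescently tagged DNA-repair
proteins (e.g. FUS-eGFP) at UV-laser micro-irradiated DNA damage sites in
live-cell time-lapse microscopy, for labs running laser micro-irradiation
assays who want an unbiased, scriptable alternative to manual ROI work.

A movie of one assay shows a nucleus, a brief laser cut, rapid accumulation
of the tagged protein along the 12 µm lesion stripe, and slower withdrawal.
The package turns such movies (or pre-extracted traces) into per-cell
kinetic parameters and cohort statistics:

* **stack I/O** — TIFF stacks with a YAML sidecar (timestamps or the
  1 fps / 0.2 fps two-rate schedule, pixel size, irradiation time),
  maximum-intensity projection;
* **preprocessing** — translation-only drift registration (FFT
  cross-correlation), mono-exponential-plus-offset photobleaching
  correction;
* **detection** — Otsu-based nucleus segmentation, damage-stripe detection
  on the post-minus-pre difference image, a two-pixel background ring,
  background-corrected intensity traces, recruiting/non-recruiting
  classification;
* **kinetics** — segmentation of each recruiting trace into lag,
  association, plateau and dissociation phases (time points A–E), robust
  non-linear fit of the first-order model

  ```
  y(t) = 0                                   t < tB
  y(t) = Δmax (1 − exp(−k_on (t − tB)))       tB ≤ t < tD
  y(t) = y(tD) exp(−k_off (t − tD))           t ≥ tD
  ```

  and the nine per-cell parameters (lag, association, plateau,
  dissociation and total duration; k_on; k_off; fold change; plateau
  flag), with E extrapolated as tD + ln(20)/k_off when dissociation is
  incomplete within the window;
* **cohort** — recruiting and plateaued fractions (mean ± SEM over
  experiments), one-way ANOVA with Tukey HSD across cell models;
* **simulate** — a forward model (nuclei, stripe, kinetics, bleaching,
  drift, EMCCD-style noise) with full ground truth, so every stage is
  testable.

## Worked example

Simulate one recruiting cell and run the full image pipeline on it:

```r
library(RecruitKinetics)

cfg <- singleNucleusConfig(recruitingProbability = 1, seed = 5L)
sim <- simulateStack(cfg)            # 128x128 movie, 217 frames, 0-600 s
res <- analyzeStack(sim$stack)
res$records[, c("recruiting", "lagTimeS", "associationTimeS",
                "foldChange", "kOn", "kOff")]
#>   recruiting lagTimeS associationTimeS foldChange        kOn       kOff
#> 1       TRUE       12         66.62113  0.8836204 0.04862718 0.00990248
```

The simulated cell was generated with a 12.77 s lag, k_on = 0.05 /s and
k_off = 0.01 /s; the pipeline recovers a 12 s lag and rates within a few
percent from the noisy movie. `res$traces[[1]]` holds the measured trace
and `traceTable(res$traces[[1]], res$fits[[1]])` a tidy frame with the
fitted curve for plotting.

Cohort statistics operate on the tidy per-cell table:

```r
recruitingFraction(records)   # % recruiting per model, mean ± SEM
plateauFraction(records)      # % of recruiting cells with a plateau
compareGroups(records$dissociationTimeS, records$cellModel,
              parameter = "dissociationTimeS")   # ANOVA + Tukey
```

A thin command-line wrapper over `runPipeline()` is installed at
`inst/scripts/run-pipeline.R`.

## Documentation

The methods vignette (`vignettes/recruitment-kinetics.Rmd`) documents the
model, every tunable threshold with its default and rationale, what the
simulator does and does not emulate, and known limitations.
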