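# radscreen

Statistical analysis of cell-based high-throughput **radiation
susceptibility** screens read out by automated counting of fluorescently
stained nuclei.

Genome-wide siRNA screens for radiosensitization targets need a survival
readout that works in 96-well plates; counting nuclei with a laser scanning
cytometer a few days after irradiation is such a readout. This package
implements the statistics that turn raw scanner output into ranked
radiosensitizer candidates:

* **Cell counting** — size-gated classification of scan objects into single
  cells (both extents in [5, 50) µm) and clusters ([50, 250] µm, counted as
  3 nuclei each); `count = n_single + 3 * n_cluster`.
* **Dose-response** — surviving fractions and linear-quadratic fits,
  `S(D) = exp(−αD − βD²)`, by intercept-free least squares on −ln S
  (negative α/β permitted), with SF2 and cross-assay regression.
* **Normalization** — one joint linear model on log2 counts removes plate,
  session and screen effects while *exactly* preserving the irradiation
  effect, because every technical factor spans both treatment arms. OLS or
  Huber-robust.
* **Hit calling** — per-siRNA treatment × silencing interaction tests
  against pooled non-targeting controls, Benjamini-Hochberg FDR, hits =
  low q + negative interaction (less survival specifically with IR).
* **Assay QC** — robust Z′-factors (median/MAD) per session and arm, plus
  between-screen replicate correlations.
* **Synthetic screens** — a generator with known ground truth (LQ killing,
  siRNA viability and interaction effects, nested technical offsets,
  lognormal noise) that makes every stage testable without instrument data.

## Worked example

Simulate the desk-scale screen (2 replicate screens × 2 sessions × 10
library plates per duplicate ±4 Gy set; 1,840 siRNAs, 5% true sensitizers),
normalize, and call hits:

```r
library(radscreen)

sim  <- simulate_screen(sim_params(seed = 20260924))
norm <- normalize_screen(sim$wells)
hits <- call_hits(screen_hit_tests(norm$wells), fdr_threshold = 0.1)
qc   <- screen_qc(norm$wells)
```

The workflow scripts under `analysis/` run exactly this and print:

```
tested 1840 siRNAs; 92 hits at FDR <= 0.10 (all sensitizer-direction)
ground truth: 99 true sensitizers; recall 0.89, empirical FDR 0.043

irradiated arm: median Z' = 0.24 (> 0: controls resolvable)
mock arm:       median Z' = -0.45 (< 0: PRKDC knockdown alone not resolvable)

between-screen replicate correlations:
  arm    r n_pairs
   ir 0.75    1840
 mock 0.70    1840
```

Read: of 99 simulated true radiosensitizers the pipeline recovers 89% at a
10% FDR target while the realized false-discovery proportion stays below
it; the positive robust Z′ under IR says PRKDC-control and non-targeting
wells separate only when irradiated — the assay window exists exactly where
radiosensitization is measured — and replicate screens correlate at 0.70–0.75.

Dose-response fitting, on the published DU145 clonogenic parameters:

```r
d   <- 0:8
fit <- fit_lq(d, lq_survival(d, alpha = 0.22, beta = 0.05))
fit
#> Linear-quadratic fit (loglinear, n = 9 points)
#>   alpha = 0.2200 +/- 0.0000 1/Gy
#>   beta  = 0.0500 +/- 0.0000 1/Gy^2
#>   R^2 (on -ln S) = 1.000
#>   SF2 = 0.527
round(fit$sf2, 1)
#> [1] 0.5
```

The numbered scripts in `analysis/` (`01_dose_response.R` …
`05_assay_qc.R`) run the complete workflow — LQ fits and SF2 for four cell
lines × three readouts, cross-assay agreement, screen simulation,
normalization, hit calling, QC — writing tables under `results/`.

## Documentation

The methods vignette (`vignettes/radiation-screen-analysis.Rmd`) describes
the models, the open design choices (size-gate tie rule, intercept-free LQ
fitting, pair-level technical factors, unmoderated interaction variance),
what the synthetic generator does and does not emulate, and known
limitations.
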