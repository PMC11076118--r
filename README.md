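# gfpsperm

Quantification and analysis of GFP-sperm occupancy in insect female
reproductive tracts.

## The problem

When males carry sperm whose heads express GFP, the fate of their
ejaculate inside a female can be watched through the translucent tract
wall: how much of the storage organs the sperm occupy (spatial spread)
and how bright the signal is (a density proxy). Experiments built on
this readout — e.g. asking whether a simulated heatwave before mating
changes how well sperm fill the bursa copulatrix and the spermatheca,
and whether that translates into lost paternity under sperm
competition — need two things:

1. an **image-quantification chain** that turns two-channel micrographs
   into per-female occupancy metrics, and
2. an **inference stage** for overdispersed factorial data built on
   those metrics.

`gfpsperm` implements both, plus a seeded synthetic-data generator that
renders ground-truthed micrographs and simulated experiments so the
entire pipeline is testable without any raw-data download.

## Methods at a glance

**Image chain** (`quantify_sample()`), in fixed order:

- rolling-ball background subtraction (grayscale opening with a
  spherical structuring element, radius 25 px);
- autofluorescence crosstalk correction: a reference ROI on a chitinous
  structure gives the factor `Int_GFP / Int_Auto`; the red channel
  scaled by this factor is subtracted from the green channel;
- intermodes thresholding: a 256-bin histogram is smoothed with a
  3-point moving mean until exactly two maxima remain; the threshold is
  the midpoint of the modes;
- ROI occupancy metrics: mean/median intensity, percentage cover
  `= 100 × (#pixels above threshold) / (ROI area)`, and a presence flag
  (≥ 1 eight-connected component of ≥ 4 pixels).

**Inference stage** (`analyze_occupancy()`, `analyze_paternity()`): per
site, percentage cover is modelled with logit-link quasi-binomial GLMs on
`cbind(percent, 100 − percent)` and mean intensity with identity-link
Gaussian GLMs, each with three two-level design factors (thermal
treatment, female mating status, time point) and two-way interactions.
Non-significant interactions are pruned by likelihood-ratio tests
(`drop1_llrt()`: F for continuous responses, scaled-deviance χ² for
proportions); main effects are never dropped. Reported per model:
per-term LLRTs, Wald post-hoc contrasts with percent changes, Pearson
dispersion, and explained deviance (pseudo-R²). Paternity counts
(focal-male vs competitor offspring) get the same quasi-binomial
treatment.

See `vignettes/gfpsperm-methods.Rmd` for the full model description,
parameter defaults, and design choices.

## Worked example

Simulate the default factorial experiment (190 females, cells
23/25/24/25/22/24/23/24) and analyse the total-tract cover response:

```r
library(gfpsperm)
rec <- simulate_experiment(seed = 42)
a <- analyze_occupancy(rec)
a$table[a$table$experiment == "total_tract_cover", ]
#>   fixed_factor  df statistic_kind statistic  p_value pseudo_r2
#>        thermal   1    chi_squared    29.543 5.47e-08     0.611
#>  female_status   1    chi_squared     0.453 5.01e-01     0.611
#>           time   1    chi_squared   243.661 6.26e-55     0.611
#>       residual 185                       NA       NA        NA
a$contrasts$total_tract_cover
#>         factor        contrast percent_change wald_statistic  p_value
#>        thermal heat vs control         -32.35          -2.28 2.38e-02
#>  female_status mated vs virgin          -4.05           1.09 2.76e-01
#>           time    24h vs 30min         -71.32         -14.43 4.03e-32
```

Reading this: the simulated heat treatment reduced the area of tract
occupied by sperm by 32% relative to controls (the generator injects a
0.68 multiplier), cover declined 71% between 30 min and 24 h (injected
0.28), and prior mating status had no effect on tract cover — exactly
the injected pattern. The quasi-binomial χ² tests agree.

The paternity assay follows the same idiom:

```r
print(analyze_paternity(simulate_paternity(seed = 5)))
#> Paternity (P2) analysis, n = 37 females
#>   male treatment: chi2(1) = 9.0, p = 0.003
#>   heat vs control: -65% paternity share (z = -2.8, p = 0.008)
#>   dispersion = 12.13, pseudo-R2 = 20%
```

An end-to-end run — render one micrograph per female, quantify both
sites through the image chain, analyse the measured records — is one
call:

```r
run <- run_full_synthetic(run_config(seed = 1, output_dir = "out"))
```

which writes the record CSVs, a JSON results file and a reproducibility
manifest to `out/`. A thin CLI with `simulate`, `quantify`, `analyze`
and `full` subcommands lives at `inst/scripts/gfpsperm`.

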