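# myodiff

Automated flow-cytometry quantification of myoblast differentiation.

## The problem

C2C12 myoblasts differentiate into myotubes under low-serum conditions;
the late differentiation marker is myosin heavy chain (MyHC), detected by
an MF20/eFluor 660 antibody in the far-red ("Red-R") channel. When cells
additionally express a GFP-tagged construct (detected in the "Green-B"
channel), the question becomes *gene-dose dependent*: what percentage of
cells differentiates at low, medium and high construct expression, and how
does a drug shift it? Answering it by hand means drawing the same gates
over and over in instrument software — slow and subjective. `myodiff`
automates the whole analysis from raw FCS 3.0 files to per-bin
differentiation percentages, for anyone running GFP-reporter
differentiation assays on a Guava-style 4-channel cytometer.

## The method

Each experiment carries a double-negative control (untransfected,
undifferentiated) and a MyHC+ control (differentiated, untransfected),
optionally a GFP+ control, plus target samples. The pipeline:

1. **Debris exclusion** — a fixed rectangular scatter gate
   (default FSC ≥ 100, SSC ≥ 50 RFU) defines `/NonDebris`.
2. **GFP threshold (quantile gate)** — for each of the two calibration
   controls, the level below which 99% of NonDebris cells fall
   (the type-7 sample quantile at q = 0.99); the GFP threshold is the
   arithmetic mean of the two control quantiles. Cells at or above it are
   `/NonDebris/GFP+`.
3. **Gene-dose bins** — up to three GFP windows, by default
   `GFP-low = [threshold, 100)`, `GFP-medium = [100, 1000)`,
   `GFP-high = [1000, 10000)` RFU.
4. **Peak splitting (mindensity)** — within each bin, the MyHC intensities
   are transformed to biexponential (arcsinh) space, a Gaussian kernel
   density with Silverman bandwidth is estimated, and the cutpoint is the
   density minimum between the two most prominent peaks; events at or
   above it are `/…/<bin>/MyHC+`. Unimodal bins fall back to a fixed
   10 RFU threshold (flagged); bins with < 50 events are not analyzable.
5. **Readout** — per sample and bin,
   `fraction = 100 · count(<bin>/MyHC+) / count(<bin>)`, with a QC flag
   when the differentiation control falls below 5%.

A seeded simulator (`simulate_experiment()`) generates complete synthetic
experiments — debris, doublets, autofluorescent background, a lognormal
GFP dose spanning ~10¹–10⁴ RFU, and differentiation assigned per cell by a
Hill-type dose–response `p(g) = p0·[1 − (1−E)·gʰ/(gʰ + Kʰ)]` — with
per-event ground truth, so every stage is testable without instrument
data.

## Worked example

```r
library(myodiff)
exp <- simulate_experiment(sim_config(seed = 42))      # 5 samples x 30,000 events
res <- run_pipeline(exp, analysis_config(), out_dir = "results")
round(res$threshold, 2)
#> [1] 12.17
subset(res$fractions, analyzable & grepl("target", sample))
#>             sample        bin myhc_pos bin_total fraction_percent             method analyzable
#>  04_target_vehicle    GFP-low     1174      3333             35.2     density_valley       TRUE
#>  04_target_vehicle GFP-medium      906      7266             12.5     density_valley       TRUE
#>  04_target_vehicle   GFP-high      183      3330              5.5 fallback_threshold       TRUE
#>     05_target_drug    GFP-low     1358      3341             40.6     density_valley       TRUE
#>     05_target_drug GFP-medium     2760      7283             37.9     density_valley       TRUE
#>     05_target_drug   GFP-high     1209      3289             36.8     density_valley       TRUE
```

The fitted GFP threshold (12.17 RFU, the mean of the two control 99%
quantiles) is the lower edge of the GFP-low bin. In the vehicle-treated
target the oncogenic construct suppresses differentiation with increasing
GFP dose (35.2% → 12.5% → 5.5% MyHC+); the drug-treated target is rescued
at every dose (≈ 37–41%, the simulator's baseline). The `method` column
records how each cutpoint was found; the vehicle GFP-high bin is almost
devoid of differentiated cells, so its MyHC distribution is unimodal and
the 10 RFU fallback applies. `run_pipeline()` also writes
`population_stats.csv` (header `sample,pop,count`, one row per population
node per sample), `differentiation.csv` and a run log with every effective
default.

The same workflow is available from a shell:

```sh
myodiff simulate --out simdata --seed 11
myodiff analyze  --input simdata --out results
myodiff report   --stats results/population_stats.csv
```

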