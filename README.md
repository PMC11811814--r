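# dropnox

Analysis toolkit for droplet-microfluidic single-cell assays that read out
NADPH-oxidase (NOX) activity, antibody secretion, lactate secretion and
intracellular reactive oxygen species (ROS) from time-lapse fluorescence of
picoliter droplets, together with the matching rule-based gating of
single-cell transcriptomes.

## Who this is for

Labs running (or simulating) droplet assays in which single B cells are
encapsulated in ~50 pL droplets under Poisson loading (λ ≈ 0.2–0.5), imaged
as a tiled 2D monolayer over ~6 frames at ~10 min intervals, and read out
through four channels: a cell stain, a fluorometric lactate probe, a
ROS-sensitive cell dye, and an oxidation-sensitive far-red probe (A647)
that doubles as the detection antibody of a bead-relocation IgG
immunoassay.

## The statistics at the core

**NOX activity.** For droplet *n* with first-frame signal
signal*ₙ*(t₁) and minimum signal over the second to last frames
signal*ₙ*(lowest), the percent signal loss is

    xₙ = 100% / signalₙ(t₁) · (signalₙ(t₁) − signalₙ(lowest))

and the classification threshold is derived from probe-only control
droplets as

    threshold = median(xₙ) + 3·SD(xₙ)

with a fixed default of 10.3%. Droplets with xₙ strictly greater than the
threshold are NOX_drop⁺.

**Secretion rates.** The bead-relocation ratio (beadline mean over
whole-droplet mean) is inverted through a saturating-exponential
calibration R(c) = baseline + span·(1 − e^(−c/c₀)) to an IgG
concentration, converted to molecules via c·V·N_A, and averaged over
per-interval increases to a rate in IgG/s; cells at ≥ 9 IgG/s gate as
IgG-secreting cells (quantitative range up to 285 IgG/s, with the
alternative printed bound 258 available by configuration). Lactate uses a
linear calibration and the same per-interval averaging (quantitative
range 0.1–0.8 amol/s; droplets with more than one cell are excluded). The
ROS slope averages the per-10-min signal increases of the cell dye up to
its maximum. NOX_drop⁺ droplets carry no IgG rate: the probe that reports
secretion is itself bleached by the NOX-derived ROS.

**Transcriptomic gating.** Cells × genes log2 fold-change matrices are
gated by marker argmax into B-cell subsets (and GC dark/light zone and
plasma-cell states), classified NOX_mRNA⁺ when any NOX-set gene (NOX1-4,
DUOX1-2, NOXO1, NOXA1, CYBA, CYBB, NCF1/2/4, DUOXA1/2) exceeds 0 log2FC,
scored for pathway modulation (mean log2FC of rank-sum DEGs at p < 0.05
in a pathway set), and checked against ten housekeeping control genes.

A synthetic-data generator (trace-level and rendered 16-bit image-level,
with planted ground truth) stands in for raw microscopy and sequencing
data, so every stage is testable end to end.

## Worked example

```r
library(dropnox)

ph <- sample_phenotypes(2000, lambda_occupancy = 0.3, nox_fraction = 0.3,
                        seed = 42)
ts <- generate_trace_set(chamber_spec(2000), acquisition_spec(), ph,
                         seed = 42)
calls <- classify_nox(signal_loss_table(ts$traces), fixed_threshold())
nox_frequency(calls, ts$truth)
#>   condition n_pos n_total  pct_pos
#> 1   control   144     519 27.74566

igg <- igg_secretion_rate(ts$traces, nox_calls = calls)
table(igg$gate)
#>         above_range           below_lod              igg_sc igg_uninterpretable
#>                  11                 272                  92                 144

fit_threshold(c(1, 2, 3))
#> NOX signal-loss threshold:5% (control_derived)
#>   median 2% + 3 x SD 1%
```

Of the 2,000 droplets, 519 contain at least one cell; 27.7% of those lose
enough A647 signal to classify NOX-active (30% planted; the shortfall is
the handful of planted losses that fall below the 10.3% boundary under
frame noise). NOX-active droplets are counted `igg_uninterpretable`
rather than given an IgG rate, 92 cells gate as IgG-secreting within the
quantitative range and 11 above it.

The full pipeline (simulate → segment → extract → classify → quantify →
gate → report) runs from one call or the thin CLI:

```r
run_pipeline(read_pipeline_config(
  system.file("extdata", "demo_config.yaml", package = "dropnox")))
```

```sh
Rscript inst/cli/dropnox.R run-all --config inst/extdata/demo_config.yaml \
    --outdir out --seed 7
```

Each stage reads and writes plain files in the output directory, so runs
are resumable stage by stage; a manifest, the resolved configuration and
all figure-underlying tables are written alongside.

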