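# octcaliper

Why do two OCT machines — or two careful graders — disagree when they put a
calliper on the same full-thickness macular hole (FTMH)? `octcaliper` is a
seeded simulator of the three mechanical answers, plus the agreement
statistics used to analyse such reading studies. It is aimed at
vitreoretinal researchers and imaging methodologists who want to understand
(or teach, or power-calculate around) measurement error in manual OCT
biometry: the minimum linear diameter (MLD), basal diameter (BD) and
nasal/temporal hole heights.

## The mechanisms

1. **Raster sampling.** A macular volume is a stack of parallel b-scans at
   spacing *s*. Modelling the MLD aperture as a circle of diameter *D*, a
   slice at offset *o* sees the chord 2·√((D/2)² − o²), and the worst raster
   phase leaves the nearest slice at *s*/2, so the minimum possible apparent
   size is √(D² − s²) (0 when *s* ≥ *D*: the hole can be missed outright).
   The relative shortfall (D − √(D² − s²))/D is strictly decreasing in *D* —
   small holes suffer most.
2. **Resolution-dependent reference points.** Calliper endpoints carry
   Gaussian jitter and a signed per-observer bias, both proportional to the
   machine's lateral resolution: measured width =
   max(0, w + b·ρ + ε_L + ε_R), ε ~ N(0, (j·ρ)²).
3. **Vertical display scaling.** A viewer that magnifies the vertical axis
   by *v* (1:2, 1:3.775 are the shipped presets) lets a "vertical" height
   calliper hide a horizontal drift of up to v·h·tan(θ) true µm inside an
   apparent angle θ, reporting the oblique length √(Δx² + h²) ≥ h.

Agreement is analysed with Bland–Altman bias and 95% limits of agreement
(bias ± 1.96·SD of paired differences) and the single-measurement
absolute-agreement intraclass correlation ICC(A,1) =
(MS_R − MS_E) / (MS_R + (k−1)MS_E + (k/n)(MS_C − MS_E)), with F-based
confidence interval and test after McGraw & Wong (1996) — the form that
penalises a systematic offset between raters.

## Worked example

Simulate the emulated study design — 8 eyes imaged on a sparse
high-resolution machine ("spectralis-like": 49 b-scans at 125 µm, 5.7 µm
lateral resolution, default vertical scale 1:3.775) and a dense
low-resolution one ("triton-like": 149 b-scans at 50 µm, 20 µm lateral
resolution, 1:2), read by two observers:

```r
library(octcaliper)

cohort <- generate_cohort(cohort_config(n_eyes = 8, seed = 42))
records <- simulate_study(cohort, list(spectralis_like(), triton_like()),
                          default_observers(), seed = 42)
nrow(records)   # 128: 8 eyes x 2 machines x 2 observers x 4 parameters

stratified_report(records, mode = "observer")
```

```
<agreement_report> mode = observer: observer1 vs observer2
  BD           n= 16  bias   -11.70 um  LoA [  -46.15,    22.75]  ICC 0.999 (0.997 to 1.000)
  HH_nasal     n= 16  bias    -0.78 um  LoA [   -4.53,     2.97]  ICC 0.998 (0.996 to 0.999)
  HH_temporal  n= 16  bias    -0.62 um  LoA [   -5.93,     4.69]  ICC 0.998 (0.995 to 0.999)
  MLD          n= 16  bias    -9.52 um  LoA [  -33.40,    14.36]  ICC 0.998 (0.988 to 0.999)
  pooled       n= 64  bias    -5.65 um  LoA [  -28.60,    17.29]  ICC 0.999 (0.998 to 1.000)
```

Agreement is excellent overall (pooled ICC ≈ 0.999), yet the horizontal
parameters carry a negative observer-1 bias of about −10 µm — the
resolution-driven reference-point effect, concentrated on the 20 µm
machine. Machine mode applies the observer-mean rule (readings averaged
over observers before pairing machines); on an 8-eye sample the
per-parameter biases are within ±7 µm and noisy, while on a 200-eye cohort
(`cohort_config(n_eyes = 200)`) the directions settle: the 125 µm-spacing
machine reads MLD lower than the 50 µm one, and the 1:3.775 viewer inflates
heights more than the 1:2 viewer.

The geometry alone answers "how small can a 457 µm hole look at 125 µm
spacing?":

```r
min_apparent_size(457, 125)
#> 439.5725
```

## Command line

A thin wrapper over the same functions lives at `inst/cli/octcaliper.R`:

```sh
Rscript inst/cli/octcaliper.R model-curve --out curve.csv
Rscript inst/cli/octcaliper.R simulate --n-eyes 8 --seed 7 --out meas.csv
Rscript inst/cli/octcaliper.R agree --in meas.csv --mode machine --out report.json
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch:
it generates the default 200-eye cohort at the given seed, simulates the
two-machine, two-observer study at default display scaling, prints the
interobserver and inter-machine agreement reports, and writes the results
JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Scope

Circular apertures only (irregular holes, radial rasters, vendor file
formats and real-cohort reproduction are out of scope). See the methods
vignette (`vignettes/measurement-error-mechanisms.Rmd`) for model details,
parameter defaults and their rationale, and known limitations.
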