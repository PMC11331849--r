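---
title: "Mechanisms of manual calliper error for macular holes on OCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanisms of manual calliper error for macular holes on OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octcaliper)
```

## The problem

Full-thickness macular holes (FTMH) are sized by hand: a grader scrolls
through a raster of parallel OCT b-scans, picks the slice on which the hole
looks widest, and drags a two-point calliper across it. The minimum linear
diameter (MLD) read off this way is the main prognostic number for hole
surgery, with the basal diameter (BD) and the nasal/temporal hole heights
close behind. Two machines — or two careful graders on the same machine —
routinely disagree by tens of micrometres even when the calliper tools
themselves are calibrated identically. `octcaliper` implements the three
mechanical reasons why, as a seeded simulator, and supplies the agreement
statistics (Bland-Altman limits of agreement, absolute-agreement ICC) with
which such reading studies are analysed.

## Mechanism 1: discrete raster sampling of a circular aperture

The MLD and BD apertures are modelled as concentric circles (irregular
holes are out of scope; the chord argument below is drawn for circles). A
b-scan at perpendicular offset $o$ from the centre of an aperture of
diameter $D$ sees the chord

$$c(D, o) = 2\sqrt{(D/2)^2 - o^2}, \qquad |o| < D/2,$$

and nothing otherwise. A raster with spacing $s$ samples offsets
$\phi + j s$ at an arbitrary phase $\phi$; the grader reads the widest
chord over slices. The worst phase straddles the centre symmetrically, so
the nearest slice sits at offset $s/2$ and the minimum possible apparent
size is

$$\mathrm{minApparent}(D, s) = \sqrt{D^2 - s^2}, \qquad s < D,$$

and $0$ for $s \ge D$ (we return 0 rather than an error: at the worst
phase the hole is simply missed, the natural limit of the formula). The
relative shortfall $(D - \sqrt{D^2 - s^2})/D$ is strictly decreasing in
$D$: small holes are proportionally the worst hit by a sparse raster. At
125 µm spacing a 457 µm hole can appear as small as
`r round(min_apparent_size(457, 125), 1)` µm; at 50 µm spacing no worse
than `r round(min_apparent_size(457, 50), 1)` µm.

`acquire_raster()` simulates the acquisition (phase uniform on $[0, s)$;
the raster is centred on the fovea plus a per-eye fixation error) and
`widest_slice()` applies the grader's selection rule with deterministic
tie-breaks (smaller absolute offset, then lower slice index). Apparent BD
gets the same chord treatment as MLD (geometrically forced); apparent
height is held independent of slice offset — height error is attributed
to display scaling, an explicit modelling assumption.

## Mechanism 2: resolution-dependent reference points

On a low-resolution scan the hole margin is blurry and graders plant the
calliper endpoints differently. `measure_horizontal()` models a reading as

$$\hat{w} = \max\left(0,\; w + b\,\rho + \varepsilon_L + \varepsilon_R\right),
\qquad \varepsilon_{L,R} \sim N(0, (j\rho)^2),$$

with $\rho$ the lateral resolution (µm/pixel), $j$ a jitter coefficient
and $b$ a signed per-observer bias coefficient. Both error terms scale
with resolution, so they fade on a high-resolution machine. The magnitudes
are not identifiable from any published number (a single disagreement
instance cannot pin a variance), so they are calibration knobs with
defaults chosen once: $j = 0.5$ (endpoint SD of half a pixel's worth of
micrometres), and $b = -0.75$ for observer 1 versus $0$ for observer 2,
giving a systematic −15 µm on a 20 µm-resolution machine and only −4 µm at
5.7 µm — one observer reading consistently short exactly where boundaries
are ambiguous.

## Mechanism 3: vertical display scaling and oblique callipers

Viewing platforms magnify the vertical axis by default (ratios of 1:2 and
1:3.775 horizontal:vertical are shipped in the two presets). A "vertical"
calliper that deviates from true vertical by up to $\theta$ degrees *as
displayed* conceals a horizontal endpoint drift of up to
$w = v\,h\tan\theta$ true micrometres at vertical scale $v$, because the
displayed height is $v$ times taller than reality. The drift is drawn
uniformly on $[-w, w]$ (the simplest maximal-entropy choice within the
tolerance cone) and the calliper reports the oblique length
$\sqrt{\Delta x^2 + h^2} \ge h$. Inflation is zero at $\theta = 0$, grows
with both $v$ and $\theta$, and is strictly larger at $v > 1$ than at
$v = 1$ for the same drift fraction. Default tolerance: 3°.

## Mechanism (1b): slice-selection error

`select_slice()` lets a grader pick a slice adjacent to the widest one
with probability `slice_error_prob` — the "different reference scans"
phenomenon. In the *default* observer pair this probability is 0: a
back-of-envelope variance budget shows that even a 1% slice-error rate on
a 125 µm raster injects chord discrepancies of order 100 µm that would
dominate interobserver variability, swamping the resolution mechanism the
default world is meant to exhibit. The mechanism is therefore opt-in
(`observer_model(slice_error_prob = ...)`) and fully tested, rather than
part of the default study.

## The synthetic cohort

No per-eye hole geometry is published for the motivating 8-eye study, so
the generator states a plausible FTMH case mix once: MLD lognormal with
log-mean $\log 350$ and log-SD 0.45 (median 350 µm, 2.5–97.5 percentiles
roughly 145–845 µm, spanning small to large holes), BD/MLD ratio uniform
on [1.5, 2.5], heights Gaussian (420 ± 60 µm, truncated positive by
redrawing), fixation error SD 50 µm. These are configurable
(`cohort_config()`) but the defaults are the stated world and are not
tuned. `simulate_study()` emulates the full design — each eye imaged once
per machine (one raster phase and one fixation offset per eye–machine
pair, shared by the observers, who read the same acquired volume), each
observer measuring four parameters — and emits
`n_eyes × machines × observers × 4` records; 8 eyes, 2 machines and 2
observers give the study's 128 measurements. Child RNG streams are
derived per eye/machine/observer from one master seed, so subsetting a
cohort leaves the surviving eyes' records bit-identical.

What a green end-to-end test establishes is directional, not numerical:
the sparse machine undermeasures MLD on average, higher vertical scaling
inflates heights more, and interobserver spread tracks lateral
resolution. The generator does not emulate media opacity, repeat
acquisitions, irregular hole shapes, or eye-tracking/averaging, so green
tests say nothing about those.

## Agreement statistics

`bland_altman()` returns the mean difference and
$\text{bias} \pm 1.96\,\mathrm{SD}$ limits of agreement (sample SD,
classical multiplier; no small-sample $t$ correction, matching standard
practice). `icc_absolute()` computes the single-measurement
absolute-agreement ICC from the two-way ANOVA mean squares,

$$\mathrm{ICC}(A,1) = \frac{MS_R - MS_E}
{MS_R + (k-1) MS_E + \tfrac{k}{n}(MS_C - MS_E)},$$

with the F-based 95% interval and the $MS_R/MS_E$ test of ICC = 0
following McGraw & Wong (1996). Single measures (not average) because
individual readings are compared; the absolute-agreement form penalises a
systematic offset between raters, which a consistency correlation would
ignore — the property the machine comparison needs. An all-constant
matrix yields a flagged degenerate report instead of NaN propagation.

`stratified_report()` applies the study's pairing rules: observer mode
pairs the two observers within each (eye, machine, parameter); machine
mode first averages the two observers within each (eye, machine,
parameter) and then pairs machines within (eye, parameter) — the
observer-mean rule. Units missing one side of a pair go to an exclusion
log rather than vanishing silently.

## Numerical choices and degenerate inputs

- All lengths are µm as doubles; no unit conversion anywhere.
- `min_apparent_size` and `chord_width` clamp the radicand at zero, so
  tangent slices return exactly 0 with no NaN.
- Perfect-knob limits are exact by construction: zero jitter and bias
  reproduce the chord exactly, and a zero oblique drift returns the true
  height without passing through `sqrt(h^2)`.
- `widest_slice` tie-breaks are deterministic (|offset|, then index), so
  simulations are reproducible across platforms.
- A raster field smaller than the hole warns and proceeds; a phase outside
  `[0, spacing)` is an error.
- The ICC residual mean square is clamped at zero against round-off; the
  reported CI is widened if necessary to contain the point estimate.

## Known limitations

Circular apertures only; heights unaffected by slice offset; observer
error magnitudes are stated, not estimated from reader data; the
two-machine presets are fixed parameter bundles, not device models; no
vendor-file input — measurement tables enter as CSV.
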