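# testune

Mechanistic modelling and flow-cytometry characterization of **tunable
expression systems (TES)** — genetic devices in which one promoter controls
transcription of a toehold-switch (THS) mRNA and a second promoter controls
transcription of a tuner small RNA that activates its translation, so a
device's response function can be moved after it is built. The package is for
synthetic biologists who design such devices (including TES-driven NOT and
NOR logic gates) and for anyone who needs a reproducible, fully offline
pipeline from single-cell fluorescence events to fitted response functions
and device performance metrics.

## The model

Four species — free THS mRNA *m*, tuner sRNA *s*, opened mRNA–sRNA complex
*c*, protein *p* — with mass-action kinetics:

```
dm/dt = u_in            − k_on·m·s + k_off·c − (δ_m + φ)·m
ds/dt = b·u_tun         − k_on·m·s + k_off·c − (δ_s + φ)·s
dc/dt = k_on·m·s − k_off·c                   − (δ_c + φ)·c
dp/dt = k_leak·m + k_act·c                   − (δ_p + φ)·p
```

`u_in`, `u_tun` are promoter activities (RNAP/min), `b` the sRNA-booster
multiplier, `φ` dilution by growth. The same reaction network feeds a
deterministic solver (exact scalar-root steady states, `lsoda` time courses,
a delay variant), a ribosome-allocation coupling for burden/retroactivity
effects, and stochastic engines (exact Gillespie SSA and a species-partitioned
adaptive tau-leap) with bit-reproducible seeding.

The characterization side implements density gating on scatter channels,
autofluorescence correction, relative-promoter-unit (RPU) calibration, the
histogram intersection statistic
`H = Σ min(x_i, y_i) / Σ x_i` (unit-mass normalized),
Hill response-function fits

```
activation:  y = y_min + (y_max − y_min)·xⁿ/(Kⁿ + xⁿ)
repression:  y = y_min + (y_max − y_min)·Kⁿ/(Kⁿ + xⁿ)
```

and the device metrics *dynamic range* (|median_on − median_off|), *fold
change* (larger/smaller median), *intersection*, and *K range* (span of
transition points across tuner levels). A synthetic-data generator produces
complete event-level datasets — conditions, replicates, autofluorescence and
RPU-standard controls — with a truth manifest, so every stage is testable
without downloads.

## Worked example

Steady state of the TES at a mid-range input and a strong tuner input:

```r
library(testune)
params <- tes_parameters()                     # nominal E. coli rates
steady_state(update_params(params, u_in = 1.5, u_tun = 38))
#> TES steady state: m=0.02513 s=296.6 c=4.032 p=349.1 (production 8.065 /min, residual 1.1e-12)
```

Nearly all mRNA is bound (m ≈ 0.03 free copies against 4 opened complexes):
at these fluxes the switch runs in the binding-dominated regime, and the
~350 protein copies come almost entirely from the activated complex.

A full in-silico characterization — generate a synthetic TES dataset
(6 tuner × 12 input levels × 3 replicates, 10⁴ events per condition), then
gate, correct, normalize, fit and summarize:

```r
spec <- synthetic_dataset_spec(device = "TES", n_events = 1e4,
                               replicate_sd = 0.05, seed = 11)
ds <- generate_device_dataset(spec)
an <- analyze_dataset(ds, gate_bins = 256)
an
#> TES characterization: 216 medians, 6 tuner levels
#>   K range: 0.0999-3.56 RPU (ratio 35.64)

an$fits[["2.6"]]        # fitted response function at the highest tuner level
#> Hill fit (activation): y_min=0.7824 y_max=5154 K=3.562 n=1.06  residual=0.267

an$metrics[["2.6"]]
#> Device metrics over 3 replicates:
#>   dynamic range: 2866 +/- 9.8 a.u.
#>   fold change:   1126 +/- 28
#>   intersection:  0.000 +/- 0
```

The fitted transition point K = 3.56 RPU recovers the manifest truth for this
dataset (3.61 RPU) to 1.2%; across tuner levels the transition point spans a
~36-fold range — the tunability the device exists for. The metrics read as:
switching the input from its off (0.002 RPU) to its on (6.6 RPU) state moves
the corrected median output by ~2870 a.u. (a 1126-fold change), with no
overlap between the off- and on-state single-cell distributions at this tuner
level.

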