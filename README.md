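# poreCas9

Simulation and analysis of solid-state nanopore recordings of barcoded
linear DNA nanostructures carrying dCas9-targetable dsDNA overhangs.

## The problem

Catalytically dead Cas9 (dCas9) binds — but does not cut — any 20-bp DNA
target with an adjacent `NGG` PAM, programmed by its crRNA spacer. Whether
a given guide actually binds its target, how efficiently, and how much a
single-nucleotide mismatch degrades that binding are guide-specific
questions that must be measured, not predicted. A nanopore assay answers
them at the single-molecule level: a ~7 kbp DNA carrier translocating
through a quartz nanopore produces a square current blockade; five
dumbbell-hairpin groups along the carrier produce a 5-bit spike **barcode**
identifying the design; a 50 bp dsDNA **overhang** presenting the target
sequence is invisible unless a dCas9 RNP is bound to it, in which case it
adds one more spike. Counting overhang spikes per barcode measures binding
specificity, relative target concentrations and position-wise mismatch
tolerance.

This package is for analysts of such recordings (and of simulated ones):
it provides a seeded phenomenological trace simulator with ground truth,
a translocation-event finder with noise (> 15 pA) and fold filters,
orientation-aware barcode decoding with per-overhang binding calls, a
sequence-level guide/target model (PAM scan, mismatch profile, wobble
classification rG·dT / rU·dG / rA·dC / rC·dA, configurable
position-dependent binding probabilities), and the assay's estimators.

## The statistics

With `N_{b,dCas9}` / `N_{b,No dCas9}` the classified unfolded events of
barcode `b` with / without a dCas9 call:

- labelled-event percentage (specificity):
  `%dCas9_b = 100 · N_{b,dCas9} / Σ_b' N_{b',dCas9}`
- relative concentration: the literal published form
  (`labelled fraction × total events of b`, normalized; `mode="printed"`)
  and an efficiency-corrected default that returns the input mixture
  fraction under equal binding efficiencies
- position-wise binding fraction `X_i = N_i⁺ / (N_i⁺ + N_i⁻)`, control
  efficiency `X_control = mean(X_control,1..3)`, and the normalized
  binding ratio `X_i / X_control` (1.0 = binds as well as the matched
  control, whose measured efficiency is 33.7%)
- binding efficiency `100 · N⁺ / (N⁺ + N⁻)`, population-SD spread and
  Wilson 95% intervals

See `vignettes/decoding-dcas9-nanopore-assays.Rmd` for the signal model,
all tunable parameters and the design decisions.

## Worked example

Run the packaged configuration — an equimolar mixture of a wild-type
carrier (barcode `11111`) and a mutant carrier (`11001`) whose overhang
differs by one PAM-proximal base, probed by the wild-type guide:

```r
library(poreCas9)
cfg <- readRunConfig(system.file("extdata", "example_run.yaml",
                                 package = "poreCas9"))
res <- runPipeline(cfg, file.path(tempdir(), "demo"))
str(res$summary)
print(res$quant)
```

which prints:

```
List of 8
 $ n_events_simulated: int 200
 $ n_events_detected : int 200
 $ n_discarded_noise : int 0
 $ n_folded          : int 136
 $ n_unfolded        : int 64
 $ n_decoded         : int 64
 $ n_classified      : int 64
 $ n_unclassified    : int 0
QuantResult over 2 barcode(s)
 barcode n_bound n_unbound pct_dcas9 efficiency_pct
   11001       1        24      7.69           4.00
   11111      12        27     92.31          30.77
relative concentration (efficiency_corrected): 11001=0.391, 11111=0.609
```

Reading it: all 200 simulated events are detected; ~70% are folded and
excluded, leaving 64 decodable events. The wild-type carrier binds its
guide at ~31% (the configured control efficiency is 33.7%), the
single-mismatch carrier at 4% (the configured seed-mismatch model gives
3.37%, plus knot artifacts at 4.5% per unbound overhang) — so 92% of
labelled events carry the matched barcode. At this small run size the
spread is dominated by counting noise; the run directory's `quant.json`
carries Wilson intervals for every fraction.

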