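---
title: "Decoding dCas9 binding on barcoded DNA carriers: model and methods"
author: "poreCas9"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding dCas9 binding on barcoded DNA carriers: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreCas9)
```

# The assay

A linear DNA carrier (~7 kbp, assembled from an M13 scaffold and staple
oligos) translocates through a solid-state nanopore and transiently blocks
the ionic current. Two kinds of engineered features ride on the carrier:

* a **barcode**: five groups of dumbbell hairpins at fixed positions, each
  group present ("1") or absent ("0"), producing five candidate current
  spikes that identify the carrier design;
* one or more **dsDNA overhangs** (50 bp) presenting a 20-bp protospacer
  plus PAM. A 50 bp duplex is below the pore's detection limit, so an
  overhang is invisible — *unless* a catalytically dead Cas9
  ribonucleoprotein (dCas9 RNP) is bound to it, in which case the bound
  protein produces an extra spike at the overhang position.

Counting, per barcode, how many events carry an overhang spike therefore
measures sequence-specific dCas9 binding at the single-molecule level:
specificity against single-nucleotide changes, relative concentrations of
mixed targets, and position-wise mismatch tolerance of a guide.

This package implements the full analysis — a synthetic-data generator
with ground truth, event detection and quality filtering, orientation-aware
barcode decoding with binding calls, a sequence-level guide/target model,
and the estimators — as testable, seedable components.

# Signal model and simulator

`simulateTrace()` generates the recording phenomenologically, not
electrokinetically. An event is a negative square pulse of depth
$\Delta I_{ds}$ (default 120 pA) below a positive open-pore baseline
(default 10 000 pA, Gaussian noise SD 6 pA, 250 kHz sampling). Each
present barcode bit and each bound overhang adds a short spike of extra
depth $\Delta I_{sp}$ (default 120 pA) at its fractional position along
the carrier. Pulse edges are smoothed by a zero-phase first-order filter
with a 50 kHz corner, standing in for the analogue Bessel filter of the
instrument; zero-phase filtering is chosen so that time reversal commutes
with the filter, which the decoder's orientation handling relies on.

Design choices worth stating explicitly:

* **Translocation direction.** Each event is forward or reverse with
  probability 1/2; reverse events mirror every fractional position
  ($q \mapsto 1-q$), implemented so that the reverse profile is exactly
  the sample-reversed forward profile for the same draws.
* **Folded events.** With probability 0.7 (matching the observed ~300
  unfolded out of 1 000 events) the blockade is doubled over a random
  leading or trailing 30–70% of the event. Exotic fold geometries are out
  of scope; the dichotomy is enough to exercise the exclusion pathway.
* **Knot artifacts.** Transient self-crossings of the carrier can mimic a
  bound protein. Each *unbound* overhang receives, with probability 0.045
  per event, one spurious spike placed uniformly inside that site's
  decode window. Placing knots in-window only is deliberate: they exist to
  exercise the false-positive pathway that the no-PAM control quantifies,
  and off-window artifacts are counted separately by the decoder anyway.
* **Dwell times** are log-normal with mean 2 ms (dispersion
  `dwellSdLog = 0.25`); no dwell distribution is prescribed by the
  measurement, and log-normal is the usual shape for translocation
  durations.
* **Spike width** defaults to 10 samples (~40 µs) at the nominal dwell
  and is expressed internally as a *fraction* of the event duration, so
  the carrier geometry is invariant to how fast a particular molecule
  translocates. The width is kept small so that the total spike occupancy
  of an event (up to 8 windows in a three-overhang design) stays well
  below the 20% sample fraction that the fold-classification rule uses —
  wider spikes would make a fully decorated unfolded event
  indistinguishable from a folded one under that rule.
* **Inter-event gaps** are exponential with a default rate of 100
  events/s. Real recordings are far sparser (hundreds of events per
  hour); baseline between events carries no information, so the generator
  compresses it to keep traces small. Tests use an even higher rate
  (250/s).
* **Polarity.** Blockades are negative deflections from a positive
  baseline, the usual convention for LiCl solid-state recordings; all
  downstream analysis is magnitude-only.

Every event is logged with its ground truth (design, direction, fold
geometry, per-site occupancy, knot positions, sample interval), which is
what the recovery tests and the acceptance checks compare against.
`simulateTrace()` seeds all draws from `SimConfig@seed` and restores the
caller's RNG state, so identical configurations give byte-identical
traces.

What the generator does **not** emulate: baseline drift and 1/f noise,
capture-rate physics and concentration-dependent event rates, pore-to-pore
variability, salt-dependent binding efficiencies, multi-level fold
geometries, and correlated (filtered) noise — the Gaussian noise is added
after the edge filter. Passing recovery tests on these traces therefore
demonstrates the correctness of the decoding and estimation logic under
the stated signal model, not robustness to every artifact of real
recordings.

# Event detection and quality filters

`estimateBaseline()` finds the open-pore level as the dominant mode of the
sample distribution by iterative exclusion (median/MAD, excluding samples
more than 4σ below the level, five passes). A trace whose estimated level
sits far (> max(50 pA, 10σ)) from the nominal baseline recorded in its
metadata is rejected: it contains no open-pore baseline to estimate. This
metadata check is the only way to recognise the degenerate "trace that is
all event" input — statistically such a trace is indistinguishable from a
clean baseline.

`findEvents()` takes maximal runs deeper than 5σ below the baseline
(standard resistive-pulse practice; the source analysis does not publish
its thresholds), extends them to the baseline re-crossing, and keeps runs
of at least 0.2 ms. Intervals are 1-based inclusive `[start, end]` sample
indices, disjoint and sorted — asserted by the `EventSet` validity method
on every construction.

**In-event noise** for the 15 pA discard rule is computed as
$\mathrm{sd}(\Delta x)/\sqrt{2}$, the high-frequency noise estimator based
on first differences. A residual-around-a-piecewise-fit definition was
considered and rejected: barcode and overhang spikes are *signal*, and at
realistic spike occupancy any level-fit residual conflates them with
noise, while the difference-based estimator is insensitive to level
structure altogether.

**Fold classification** replaces by-eye curation with a deterministic
rule: an event is folded iff more than 20% of its samples are deeper than
1.5× the dsDNA blockade. Narrow spikes (a few percent of samples at twice
the blockade) do not trigger it; a doubled-over carrier does. When the
blockade depth is not supplied, it is calibrated as the median over events
of the per-event median depth, which is robust while folded events are no
more than roughly 70% of the population with fold durations symmetric
about half the event. Only unfolded events reach decoding.

# Decoding

`detectSpikes()` finds local maxima of the extra blockade beyond the
dsDNA level that pass a height (60 pA), a raw threshold (30 pA) and a
topographic-prominence criterion (60 pA), then applies minimum-distance
suppression (5% of the event duration) in which the deeper spike wins and
ties go to the earlier position. The peak rule *is* the decoding contract
here, so it is implemented directly rather than through a generic peak
finder with different prominence/suppression semantics.

`assignBarcode()` bins spikes into slot windows (slot centre ± 40% of the
inter-slot spacing) and compares the occupancy bit vector against the
declared library in both orientations. The default slot layout
(0.3–0.7, symmetric about the carrier midpoint) makes a reverse
translocation read exactly as the reversed bit string, so orientation is
resolved by the code's own asymmetry. Three outcomes:

* unique match in one orientation → barcode and orientation assigned;
* a palindromic code matching both ways → barcode assigned, orientation
  `"ambiguous"`;
* no match, or matches to two different codes → `"unclassified"`, and the
  event is excluded from every downstream count (mirroring the exclusion
  of unclear events in manual analysis).

Matching is exact-match-only: the assay always measures declared
libraries of known codes, so fuzzy matching would only manufacture
classifications from damaged events.

`callDcas9()` then checks each overhang window (centre ± 0.04, mirrored
under reverse orientation) for a spike not consumed by a barcode slot.
When the orientation is ambiguous — a palindromic barcode such as
`11111` — the union of the forward and mirrored windows is accepted. This
cannot inflate the false-positive rate under the stated signal model
(knot artifacts are in-window by construction and nothing else produces
spikes at the mirror position), but it is the one place where a
palindromic design is weaker than an asymmetric one, and it is why
off-window spikes are reported as a separate artifact count rather than
silently ignored. Overlapping window layouts are rejected as
configuration errors before any computation.

# Guide model

The sequence layer provides PAM scanning (`findPamSites()`, every `NGG`
on the given strand, overlapping hits included; reverse-complement
scanning is the caller's job since overhangs are short oriented
constructs), position-by-position mismatch profiling (position 1 =
PAM-proximal; an RNA base matches the DNA base it is the transcript of),
and wobble classification — exactly the four tolerated RNA–DNA mispairs
rG·dT, rU·dG, rA·dC, rC·dA, position-independent by design, with all
position dependence living in the multiplier table.

`bindingProbability()` is the simulator's occupancy model: baseline
efficiency 0.337 for a perfect match (the measured matched-target control
efficiency), multiplied by a per-(position, wobble) ratio for every
mismatch, clamped to [0, 1]; no valid `NGG` PAM means probability 0 by
default. The seed region defaults to positions 1–12 (the upper end of the
8–12 nt range, exposed in configuration). The shipped ratio table — seed
mismatch 0.1, seed wobble 0.6, distal 0.9 — is an **illustrative
placeholder**: position-wise binding ratios are published only
graphically, so no numeric table can honestly claim to be measured. The
table is configuration (`inst/extdata/mismatch_ratios.yaml`), a missing
entry is an explicit error, and nothing in the package treats the
defaults as truth.

# Estimators

With $N_{b,\mathrm{dCas9}}$ and $N_{b,\mathrm{No\,dCas9}}$ the classified
unfolded events of barcode $b$ with and without a binding call:

* **Labelled-event percentage** (`pctDcas9Events`):
  $100\,N_{b,\mathrm{dCas9}} / \sum_{b'} N_{b',\mathrm{dCas9}}$ — sums to
  100 identically; generalized to $k$ barcodes by keeping all labelled
  events in the denominator.
* **Relative concentration** (`relativeConcentration`): the published
  formulas multiply each barcode's labelled fraction by that barcode's
  total event count and normalize. Evaluated literally, equal binding
  efficiencies at a 1:3 mixture give 10%/90% — each barcode is weighted
  by the *square* of its mixture fraction — while the accompanying text
  describes recovering "close to 25%/75%", which is the labelled-event
  fraction. Both computations are provided: `mode = "printed"` is the
  literal form, and the default `mode = "efficiency_corrected"` divides
  each labelled count by that barcode's own estimated efficiency
  (reducing to the barcode's total event count), which returns the input
  mixture under equal efficiencies. No intent is guessed; both numbers
  are reported by the pipeline.
* **Position-wise fraction, control efficiency, normalized binding
  ratio** (`positionBindingFraction`, `controlEfficiency`,
  `normalizedBindingRatio`): $X_i = N_i^+/(N_i^+ + N_i^-)$, the control
  is the mean of the three matched-target positions, and the ratio
  $X_i / X_{\mathrm{control}}$ is 1.0 when a position binds exactly as
  well as the control (it may exceed 1).
* **Binding efficiency** (`bindingEfficiency`):
  $100\,N^+ / (N^+ + N^-)$.
* **Spread**: `populationSd()` uses the population ($N$) divisor, the
  form used for repeat-to-repeat spread; Wilson 95% intervals
  (`wilsonCi`) are attached to every estimated fraction as supporting
  output.

# Numerical and scale choices

Fixed seeds drive every stochastic test and the simulator; tolerances on
recovered fractions are three binomial standard errors at the realized
count. Problem sizes were chosen as the smallest that make those
tolerances meaningful: 2 000 events for single-rate recovery properties
(occupancy, knot rate, the efficiency sweep over $p = 0.1\ldots0.9$),
5 000 events for the two-mixture scenarios, 500 events for
detection/fold-exclusion checks. `barcodeLibrarySize()` returns doubles,
exact for $2^n$ at any $n < 1024$ because a power of two needs a single
mantissa bit — so the 56-bit library count is exact without a big-integer
type. Event intervals, sample indices and sequence positions are 1-based
throughout, the native R convention.

# Pipeline and containers

`runPipeline()` sequences simulate → detect → decode → quantify from a
validated configuration (YAML via `readRunConfig()`, unknown keys
rejected anywhere), writes every artifact atomically (temp file + rename)
into a run directory — ground truth and decoded events as CSV, the trace
and per-event containers as HDF5, the quantification as JSON, a
provenance manifest with the seed and a configuration hash — and logs
per-stage event yields (detected, noise-discarded, folded, unclassified).
A stage failure aborts with the stage name and leaves earlier artifacts
intact. TDMS import from the native instrument format is declared as a
hook but not implemented; recordings should be converted to the HDF5
trace container.

# Known limitations

* The binding model is multiplicative and position-independent beyond the
  table; it does not model guide-intrinsic mismatch tolerance except as
  user-supplied per-guide tables, and no thermodynamic or kinetic
  modelling is attempted.
* Palindromic barcodes leave orientation ambiguous, which widens the
  overhang search window (union of mirror windows); asymmetric codes are
  preferable for single-overhang designs.
* The fold classifier assumes the two-level fold geometry the generator
  produces; real folds can be messier, and the by-eye curation it
  replaces could use context the rule cannot.
* The printed-mode concentration estimator is retained verbatim for
  comparability and is not a consistent estimator of the mixture fraction
  under equal efficiencies (see above).
* Simulated noise is white; detection thresholds may need retuning on
  recordings with correlated noise or drift.
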