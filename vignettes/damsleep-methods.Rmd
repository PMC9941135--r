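---
title: "Behavioral sleep scoring in damsleep: definitions, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral sleep scoring in damsleep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(damsleep)
```

## The measurement model

DAM monitors report, per fly and per minute, how many times an infrared beam
was crossed. Fly sleep is defined behaviorally on this signal: a **sleep
bout** is a maximal run of at least 5 consecutive zero-count minutes, and a
sleep minute is any minute inside such a bout. Every statistic in this
package derives from that rule, applied to traces aligned to Zeitgeber time
(ZT0 = lights-on; night = ZT [12, 24), day = ZT [0, 12), minute bins 0-based
and half-open).

Per fly-day, `sleep_metrics()` reports night and day sleep amount, night
bout number and mean length, latency, WASO and the consolidation index
CI = Σ lᵢ²/Σ lᵢ. CI weights each bout by its own length, so it sits between
the mean and the maximum night-bout length and rewards consolidated sleep.

### Boundary and degenerate-case conventions

The sleep literature rarely states its edge conventions, so this package
fixes them explicitly; they are design choices, not inferences:

- **Bouts straddling ZT12 or ZT24** are split at the boundary. Each minute
  counts toward the phase it occurs in, and the clipped night segment counts
  as a single night bout for bout number, length and CI. This keeps
  per-phase totals conservative and CI defined on the night window alone.
- **Latency** is 0 when a bout is already ongoing at lights-off (the fly is
  in its first night sleep episode); a night with no sleep is censored at
  720 min and flagged, and `average_metrics()` excludes censored nights
  from the latency average.
- **WASO** on a night with no sleep is reported as 0 with an
  `waso_undefined` flag, so group means can exclude it. With these
  conventions, latency + night sleep + WASO = 720 on any night that has
  sleep.
- **Invalid DAM rows** (nonzero status code) and absent minutes are imputed
  as 0 counts; each trace records its missingness fraction, and the
  pipeline excludes flies with more than 1% missing minutes. Imputing 0
  rather than interrupting the timeline keeps the 5-min rule well defined;
  the 1% guard keeps the imputation from manufacturing sleep.
- **Survival**: a terminal zero run of at least 24 h (boundary inclusive)
  marks the fly dead; dead flies are excluded before any other filter.
- **Multi-day aggregation**: metrics are computed per night, then averaged
  within fly; group statistics operate on per-fly averages. The default
  design records at least 3 baseline days.

## Perturbation assays

`delta_sleep()` scores rebound after mechanical deprivation. For the 6-h
protocol (deprived ZT12–18), Δ sleep is rebound sleep in ZT18–24 of the
deprivation night minus the same window of the baseline night. For the 12-h
protocol (ZT12–24), rebound is daytime sleep the following day minus
baseline daytime sleep, and only flies losing more than 70% of their night
sleep (strict inequality) are included. Sleep loss is always computed over
the deprived window against the matched baseline window; zero baseline sleep
makes the ratio undefined and excludes the fly with its own flag.

`classify_awakening()` applies the standard ±5-min windows around a 5-min
nocturnal light pulse: any count in the 5 min before onset excludes the fly
as already awake; otherwise any count in the 5 min after onset marks it
responding. `arousal_sleep_loss()` computes
100·(1 − sleep_after/sleep_baseline) and includes flies with ≥ 2% loss. The
post-stimulus accounting window is [stimulus ZT, ZT24) of the stimulus
night; the baseline is the *matched ZT window of the preceding undisturbed
night*. Whether the original assays used the same night's pre-stimulus
sleep or the prior night as baseline is ambiguous in the literature; the
prior-night matched window was chosen because it is unaffected by the
stimulus itself.

## Chi-square periodogram

For each candidate period P (in bins), the series is truncated to
K = ⌊N/P⌋ complete cycles — truncation keeps the statistic's chi-square
null valid — and folded into P columns:

Qp = K · Σₕ (Mₕ − M̄)² / σ̂², with σ̂² = Σᵢ(xᵢ − M̄)²/N′ over the N′ = K·P
retained points. Under no rhythm Qp ~ χ²(P−1); the significance line is the
0.95 quantile per period (α = 0.05, no multiplicity correction, matching
common periodogram-software usage). Defaults: 30-min bins, scan 16–32 h in
one-bin steps, at least 5 days of DD data.

Two conventions are deliberate reconstructions, since periodogram software
conventions for them are not published in detail:

- **Power** is Qp at the peak minus the significance line there. A raw-Qp
  threshold such as 120 would be meaningless without that reference, because
  Qp grows with the data length.
- **Width** is the contiguous span of periods around the peak whose Qp
  exceeds the line, in hours.

A fly is called rhythmic when power > 120 and width > 1.5 h. A constant
series has zero variance between phase columns, so Qp is defined as 0
everywhere and the fly is arrhythmic. Qp is invariant to rescaling counts.

## Gene-set statistics

`deg_threshold()` applies the boundary-inclusive cutoffs FDR ≤ 0.05 and
|log2FC| ≥ 0.585 (a 50% increase or 33% decrease). `hypergeom_overlap()`
computes the exact one-sided upper-tail hypergeometric p-value and *requires
the universe to be supplied explicitly* — typically all genes surviving the
1-cpm expression filter. A default universe is refused on purpose: overlap
p-values move by orders of magnitude with the universe size, and published
analyses often omit it, which makes their p-values unreproducible.
`bh_adjust()` is a thin wrapper over `stats::p.adjust(method = "BH")`.

## The simulator

`simulate_fly()` is a minute-resolution two-state Markov chain: per minute,
an awake fly falls asleep with probability p_sleep(phase) and a sleeping fly
wakes with probability p_wake(phase), where phase is day/night by ZT on LD
days and by the configured internal period on DD days (so free-running
period recovery is testable). Sleeping minutes emit 0 counts; awake minutes
emit zero-truncated Poisson counts with mean λ. Plain Poisson emissions
would let a genuinely awake fly produce runs of zero-count minutes that the
5-min rule would mis-score as sleep, divorcing the scored behavior from the
hidden state; truncation keeps them aligned.

The chain makes bout lengths geometric: mean sleep-bout length in a phase is
1/p_wake(phase). Because scoring only sees bouts of ≥ 5 min, observed bout
lengths are left-truncated with E[L | L ≥ 5] = 4 + 1/p_wake (memorylessness);
parameter-recovery checks therefore estimate 1/p_wake as the observed mean
minus 4.

Default study conditions, chosen once as typical for DAM sleep experiments
in males: 12:12 LD, 3 recording days, 32 flies per genotype (one monitor),
λ = 2 counts per awake minute, and two genotypes —

| genotype | p_sleep day/night | p_wake day/night | implied phenotype |
|---|---|---|---|
| control | 0.05 / 0.10 | 1/15 / 1/60 | ~600 min night sleep, ~60-min bouts |
| short_sleeper | 0.05 / 0.05 | 1/15 / 1/20 | ~360 min night sleep, short fragmented bouts, doubled latency |

By construction the short-sleeper genotype shows lower night sleep and CI
and higher latency and WASO in expectation — the directional pattern of a
sleep-fragmentation mutant. Deprivation (`apply_deprivation()`) converts
would-be sleep minutes in the deprived window to active minutes with a
configurable efficacy; light pulses (`apply_light_pulse()`) wake sleeping
flies with a configurable probability for a refractory time. A
`dead_fly_frac` subset of flies goes permanently inactive during the middle
third of the recording. All randomness flows from one master seed through
per-fly derived seeds, so identical configs produce identical DAM files.

### What the simulator does and does not emulate

It reproduces the statistical structure the analysis relies on:
circadian-modulated bout dynamics, Poisson-like activity, interventions,
deaths, and DAM file round-tripping. It does **not** model heavy-tailed
bout-length distributions seen in real flies, homeostatic sleep-pressure
dynamics (rebound beyond the enforced window is not emergent), siesta
structure beyond a two-phase day, startle responses to the deprivation
stimulus itself, or sensor artifacts other than whole-row invalid status.
Passing the validation suite therefore demonstrates correctness of the
scoring chain under a known generative model, not fidelity of any particular
biological claim about real flies.

## Validation scale and numerical choices

The test suite validates: bout detection against a brute-force zero-run
enumerator (1,000 random day-length traces); ten-plus hand-constructed
nights against hand arithmetic; the deprivation and arousal formulas and
their inclusion boundaries; the periodogram against an independent
fold-and-sum oracle on a noiseless 24-h square wave, period recovery at
22/24/26 h from 10-day DD simulations, and null calibration on 200 i.i.d.
noise replicates (~5% of periods above the α = 0.05 line); hypergeometric
p-values against exhaustive enumeration for all universes of size ≤ 12; and
bit-exact equality of metrics computed in memory versus after a DAM-file
round trip. Parameter recovery runs at 64 flies per genotype over 3 days.
These sizes keep the full suite under a minute on one CPU while leaving
sampling error well inside the asserted tolerances.

Ties in the periodogram peak are resolved by the first maximum of
Qp − significance line in scan order; CI of an empty bout set is 0; all
probability parameters are validated into [0, 1] at configuration time.

## Known limitations

- The rhythmicity power/width conventions are reconstructions; absolute
  power values are comparable within this package but not necessarily with
  other periodogram implementations.
- Latency censoring at 720 min biases group latency means downward on
  genotypes that frequently skip night sleep entirely; the censoring count
  is reported so users can switch to survival-style summaries.
- The DAM parser targets single-beam 32-channel activity monitors only.
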