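---
title: "Models and methods behind lickphys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lickphys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lickphys)
```

`lickphys` analyses cerebellar Purkinje-cell (PC) activity recorded while a
head-fixed mouse performs an interval-timing licking task: water is
dispensed at a fixed 10-s interval, withheld on a random 20% of trials, and
the animal responds with discrete bouts of rhythmic licking at 6--8 Hz.
The package covers the behavioral side (lick rates, bout segmentation,
peri-event lick histograms, optogenetic-trial metrics), the
electrophysiological side (PC identification from multichannel spike
footprints, spike entrainment to the lick cycle, ramping firing-rate
changes around bout initiation and termination), the dendritic
calcium-event side (climbing-fiber-driven event-rate analysis), and a
synthetic-session generator that provides ground truth for all of it.

This vignette is the package's own account of its models and the choices
behind them.

## The synthetic session generator

### Trial structure

Trials are laid back to back; each spans one inter-reward interval
(`interval_s`, default 10 s) with water delivered at the interval's end on
rewarded trials. Water omissions are drawn from a stationary two-state
Markov chain in which an omission is never followed by another omission and

$$P(\text{omit} \mid \text{rewarded}) = \frac{p}{1-p},$$

whose stationary marginal omission probability is exactly `p_unrewarded`.
The obvious alternative -- drawing i.i.d. flags and resampling after an
omission -- realizes a *deficit* (marginal $p/(1+p)$, about 16.7% for a
nominal 20%), which would contradict the task's stated 80/20 composition.
The compensated chain keeps the marginal at the nominal probability while
honoring the no-consecutive-omissions constraint; it requires
`p_unrewarded < 0.5`, which the configuration validates.

### Licking

Each trial holds at most one bout (probability `p_bout`). The task's
behavioral literature distinguishes *exploratory* licking, initiated in
anticipation of water, from *reactive* (consummatory) licking triggered by
water arrival. The generator draws the bout type with probability
`p_pre_water_bout`; exploratory onsets lead the scheduled water time by a
Gaussian lead (mean `pre_water_lead_s` = 1.5 s), reactive onsets trail it
by a Gaussian latency (mean `reactive_latency_s` = 0.36 s, matching the
tight reactive distribution trained animals show). Interlick intervals are
drawn uniformly within `intra_bout_ili_range_ms` (default 100--175 ms, the
rhythmic licking band); after water the rate is boosted by
`consummatory_rate_boost`, with realized intervals clipped back into the
rhythmic band. On rewarded trials a bout ends about `consummatory_s`
(default 1.37 s) after water; on omission trials the animal "gives up"
about `postgiveup_s` after the scheduled time. Published work does not
report bout-length or bout-count distributions, so `bout_len_range` and
the one-bout-per-trial law are plausible defaults, surfaced in the
configuration rather than buried.

### Unit firing model

A unit's intensity is

$$\lambda(t) = \big[\, r_0 + d\cos(\phi(t) - \phi_0)
  + R_{\text{init}}(t) + B(t) + R_{\text{term}}(t) + W(t) \,\big]_+$$

with baseline $r_0$, cosine tuning of depth $d$ to the interpolated lick
phase $\phi(t)$ (active only between licks closer than 200 ms), linear
ramps $R$ rising from zero at a configurable onset to a signed amplitude at
the bout's first (or last) lick, a water response $W$ (1 s box), and an
optional *bout-response envelope* $B(t)$ that continues the initiation ramp
from its end level to a peak `bout_peak_hz` at `bout_peak_t_s` after the
first lick before decaying over `bout_decay_s`.

The envelope deserves a word. A ramp that steps back to baseline exactly at
the first lick produces a trace that *falls* after the event, and a
late-onset ramp (one bin wide) then cannot contain the ascending
bin-quadruple that the initiation-ramp classifier looks for -- no detector
of that family could recover it. Physiologically, PC simple spiking tracks
the lick rate, which keeps rising for several hundred milliseconds after
the first lick; the envelope models exactly that. It is off by default
(`bout_peak_hz = 0`), preserving the plain ramp-then-step-back shape.

Initiation ramps may differ between bout contexts (`init_ramp` for
exploratory, `init_ramp_post` for reactive bouts), which is what lets the
generator express units tuned to one movement context -- and lets the
pipeline's context comparison be validated against ground truth.

Sampling is by thinning: candidates are drawn homogeneously at the
documented intensity bound (baseline + tuning depth + positive ramp
amplitudes + envelope peak + water response) and kept with probability
$\lambda(t)$ / bound. For a structure-free unit this reduces to a
homogeneous Poisson train, and the test suite checks binned counts for
Poisson dispersion (variance/mean within [0.8, 1.2] at 1000 bins).

### Footprints, calcium, optogenetics

Channel profiles emulate the probe-footprint regularity used for PC
identification: PCs receive at least 7 channels with mean spike peaks
drawn at twice the 30 µV noise floor or more, interneurons and other small
units at most 3. Calcium-event trains are Poisson at a per-dendrite
baseline inside the physiological 1--2 Hz climbing-fiber range; responsive
dendrites add a rate transient from a true onset before each bout's first
lick and around water delivery. Optogenetic perturbation thins licks
inside the stimulus window by a retention factor (`suppression = 1` is a
null stimulus, `0` silences the window), jitters surviving in-window licks,
and inserts a rebound bout after stimulus offset with probability
`rebound_prob`.

## Analysis rules and numerical choices

**Binning.** All windows are half-open $[lo, hi)$; a lick exactly at water
time counts as post-water. Binned counts use exact edge comparisons, not
histogram conventions.

**Bouts.** A new bout begins when an interlick gap reaches
`bout_break_s` = 1 s -- chosen to sit unambiguously between the rhythmic
intervals (at most 175 ms) and the 2-s isolation criterion, since the
break gap itself is not standardized. "Well-separated" bouts have at
least 2 s of preceding nonlicking.

**Entrainment.** Only licks in runs of at least three consecutive licks
with interlick intervals of 100--175 ms (inclusive, with a nanosecond
float tolerance) define lick cycles. Spike phases are linear
interpolations between bracketing licks, contact = 0 = $2\pi$; spikes
outside retained cycles are excluded entirely. The Rayleigh test uses
$Z = n\bar R^2$ with the standard second-order finite-$n$ series
correction; its calibration (uniformity of null p-values at $n = 50$,
type-I rate) is checked by simulation in the tests. Screening across
units uses Benjamini--Hochberg at FDR 0.05 via `stats::p.adjust`. The
circular density uses a wrapped Gaussian kernel of width 0.3 rad on a
360-point grid, renormalized to exact unit mass; a von Mises kernel with
matched dispersion (concentration $1/0.3^2$) is available since "kernel
width 0.3" admits either reading. The suprathreshold mask marks grid
points where the density exceeds $1.02/2\pi$, i.e. 2% above uniform.

**Baseline.** The nonlicking baseline is the rate over times at least 2 s
from every lick (mirroring the isolation criterion, since "nonlicking
periods" has no standard numerical definition), and errors out when fewer
than 10 s qualify.

**Initiation ramps.** A unit is positively modulated when its
trial-averaged rate change in 100-ms bins over $[-1, +0.5]$ s around the
first lick contains three consecutive strict bin-to-bin increases (four
ascending bins); the onset is the left edge of the first incremented bin
of the earliest such run. "Three consecutive increases" is ambiguous
between three and four ascending bins; the stricter four-bin reading is
used and covered by constructed-trace tests. Negative modulation mirrors
the rule; when both patterns occur the earlier onset wins, with ties going
to positive.

A property of this rule worth stating plainly: on a *flat* noisy trace an
ascending quadruple occurs among any four consecutive bins with
probability 1/24 (a pure order-statistics fact, independent of noise
scale), so the rule fires on stationary units with probability near 0.36
per direction over a 15-bin window, and a true onset is reported about two
bins early whenever the two bins preceding it happen to ascend by chance
(probability 1/6). These rates are amplitude- and trial-count-independent;
the test suite freezes them from an independent Monte-Carlo oracle and
verifies the pipeline stays within them, rather than pretending the rigid
rule is noise-free. Consequences: single-unit classifications should be
read as noisy votes, and population or cohort comparisons (for example,
earlier pre-water than post-water onsets) are the robust quantities --
the early-trigger bias cancels between contexts.

**Termination.** A unit is modulated at bout termination when its mean
rate in the 300 ms before the last lick deviates from the mean of the
100-ms bins in the alternative baseline window 1--5 s before the last lick
by more than 2 of that window's standard deviations (the window is
standard; the cutoff is this package's choice, configurable). Because the
test statistic averages three bins while the threshold uses single-bin
dispersion, the rule is conservative under the null.

**Calcium.** Region responsiveness and per-dendrite ramp onsets use the
3-SD rule in 100-ms bins over $[-1, +0.5]$ s around the first lick, with
the reference mean and SD computed from the bins 3 to 1 s before the first
lick (the reference distribution is not standardized; a pre-event window
is the symmetric choice). Onset estimation requires at least 20 aligned
bouts (configurable). Termination analysis admits rewarded trials only
when the last lick falls at least 2 s after water.

**PC identification.** "Significantly above the noise" is operationalized
as strictly greater than the configured 30 µV floor -- with only
per-channel mean peaks as input, a threshold is the honest reading; a
distributional test would need per-spike data the pipeline does not
consume. The putative-PC channel threshold is 7. Opto-tagging flags a
unit when the fraction of light pulses followed by a spike within a 10-ms
window (configurable; "short-latency" is not quantified) exceeds the
chance level implied by the unit's own baseline rate, by a one-sided
binomial test.

**Optogenetic metrics.** Lick variability during the stimulus is the
variance of 100-ms binned lick rates in the stimulus window divided by the
same quantity in the equal-length prestimulus window of the same trials.
Rebound probability is the fraction of stimulated trials with a
well-separated bout initiation (2 s of prior nonlicking) within 1.5 s of
stimulus offset.

## What the tests do and do not show

The suite validates every stage against the generator's ground truth:
exact bout and context recovery, analytic rate expectations for ramped
intensities, closed-form circular statistics (the von Mises resultant
$I_1(\kappa)/I_0(\kappa)$), Monte-Carlo calibration of the Rayleigh test
and of the BH screen, recovery of injected ramp onsets and calcium onsets,
and binomial recovery of opto rebound probabilities. Problem sizes are
kept at the scale of one recording session (typically 80--160 trials,
units at 40--80 Hz, a few dozen units per check), which the package treats
as its reference workload.

The generator emulates the *statistical* structure the analyses assume --
Poisson spiking around piecewise-linear intensities, uniform rhythmic
interlick intervals, clean event times. Real sessions have slow
nonstationarities, correlated trial-to-trial excitability, lick-detection
artifacts, spike-sorting contamination and bursting, none of which are
modelled. Passing tests therefore certify the implementations and their
statistical calibration under the stated model, not performance on any
particular recording.

## Known limitations

* Single-unit ramp classifications inherit the rigid rule's chance-run
  behavior described above; treat them as votes, use population summaries.
* The bout-assignment of licks to trials follows the generator's
  convention that a bout belongs to the trial whose water event it
  targets; bouts that straddle trial boundaries are not split.
* Calcium analysis consumes event times; no fluorescence processing,
  dendrite segmentation or event inference is included, and no synchrony
  analysis is attempted.
* The command surface is the R API (`run_pipeline()` and the per-module
  functions) plus `scripts/acceptance.R`; there is no standalone shell
  tool.
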