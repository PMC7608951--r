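---
title: "Cell-cycle windows and zygotic genome activation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-cycle windows and zygotic genome activation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zgawindow)
```

## The problem

In a syncytial *Drosophila* embryo the first thirteen nuclear division
cycles are simple alternations of S phase and mitosis. Mitosis is not just
a pause in transcription: every nascent transcript that has not been
completed when mitosis arrives is aborted and degraded. Large-scale zygotic
genome activation (ZGA) therefore cannot happen until the cycles slow down.
This package implements the quantitative consequences of that single fact,
together with the analysis pipeline used to classify single-embryo RNA-seq
responses when the cell cycle is arrested experimentally (by cyclin
knockdown) in cycle 12, and a synthetic-data generator that plants known
gene behaviors for end-to-end recovery testing.

## The window model

Three time scales combine per cycle:

* **lag** `lag_min` (default 4 min): after mitosis, transcription does not
  restart instantly; real-time imaging of nascent transcripts shows a delay
  of roughly 4 minutes.
* **transcriptional window**: interphase minus the lag, clamped at zero —
  the period during which transcripts can be elongated at all.
* **eclipse time**: the time from initiation to a finished transcript,
  proportional to primary transcription-unit (TU) length at
  `elongation_min_per_kb` (default 0.7 min/kb). A 20-kb gene needs 14
  minutes of uninterrupted interphase before a single full transcript
  exists.

The **productive window** is `max(0, window - eclipse)`: the part of
interphase during which initiations still finish in time. Time-averaged
**expression efficiency** divides the productive window by total cycle
time (interphase + mitosis) and is reported as a percentage. The terminal
cycle (14 by default) is set to exactly 100% regardless of TU length: the
embryo stops dividing, so the deadline disappears. A flag
(`terminal_override = FALSE`) disables this override for sensitivity
analyses; we chose the override as the default because a time average over
an unbounded interphase is otherwise ill-defined.

All computations are in minutes; seconds appear only in prose (the cycle-8
window of 0.2 min is "about 12 s").

### The default schedule

Interphase durations are only anchored at three points by published
measurements: the cycle-8 transcriptional window of about 12 s (hence
interphase 4.2 min given the 4-min lag), S phase of 7 min at cycle 10 and
15 min at cycle 13; mitosis is about 5 min throughout. Durations for
cycles 9, 11 and 12 are monotone interpolations (5.5, 9.5, 12 min). The
schedule ships both in code (`default_cycle_schedule()`) and as an
annotated, overridable TSV (`inst/extdata/default_schedule.tsv`), so the
uncertain inputs are isolated in one replaceable file while the model
itself stays exact. Whether the published 12-s figure was computed with the
full 4-min lag or a shorter early-cycle lag is not documented; we use the
single global lag and let the schedule file be the point of truth.

```{r}
efficiency_table(c(1, 2.5, 10, 25))
```

Longer TUs switch on later and more abruptly — the staircase above is the
model's central qualitative prediction.

## The abortion simulator

`simulate_completed()` is the event-level counterpart: initiations are a
homogeneous Poisson process over `(lag, interphase]` at
`initiation_rate × n_nuclei` per minute, each transcript completes iff its
start time plus the eclipse time fits inside interphase, and everything
else is aborted. Its expectation is exactly
`rate × nuclei × productive_window`, which the tests verify by Monte Carlo
(1,000 seeded replicates against the closed form, three standard errors).
Design choices:

* no re-initiation limits, polymerase collisions, or per-gene elongation
  speeds — the model has one elongation rate;
* initiations too late to ever finish ("doomed" initiations) still occur
  and are counted as aborted rather than suppressed; the alternative would
  change the aborted count but not the completed count, which is the
  quantity the model predicts;
* one root seed, with a per-cycle substream derived as
  `seed + 10007 × cycle`, so per-cycle results are independent of the
  order in which cycles are simulated.

A haploid embryo keeps fast cycles one round longer because its
nucleo-cytoplasmic (N/C) ratio lags one doubling behind. In the model this
is a one-cycle shift of the interphase sequence, and the tests check that
it shifts expression onset by exactly one cycle.

## Expression matrices and normalization

Counts are normalized per sample to counts per million (CPM) and
transformed as log2(CPM + 1); the pseudocount avoids log2(0). The library
size is the column total of counts assigned to genes in the matrix —
upstream alignment is out of scope, so no external library size exists.
Matrices carry an explicit stage tag (`counts` → `log2cpm` →
`row_scaled`) and every operation checks it, which makes double
normalization impossible by construction. Row scaling (for heatmaps) maps
constant genes to zero and flags them rather than producing NaNs.

PCA uses all genes as features, centered but not variance-scaled, because
the embryo trajectory should be driven by absolute log-abundance changes;
a top-variable-gene subset is a plotting convention we deliberately do not
default to. Condition summaries average replicates on the log2 CPM+1 scale
first, then subtract the baseline condition (control C12 by default) —
the order matters and follows the averaged-fold-change convention.

Outlier embryos are removed only via an explicit sample exclusion list
(subset the metadata before building the matrix); no automatic outlier
rule is applied because no defensible criterion exists at n = 2–3.

## Classification rules

**Zygotic identification** compares late (control C14L) to early (control
C12) condition means: a gene passes with linear fold change strictly
greater than 1.5 (computed from the difference of mean log2 CPM+1) *and*
Welch two-sample t-test p strictly below 0.05 on the replicate values. The
test is Welch's because replicate numbers are tiny and unequal variance is
the safe default; no multiple-testing correction is applied, matching the
raw-p convention of the screening step this mirrors. With 2–3 embryos per
condition the t-test is underpowered, so the intersection with prior
zygotic-gene lists (`intersect_with_prior()`) is what gives the analyzed
set its specificity.

**Arrest-response groups** use condition means relative to baseline with a
configurable margin (default 0, strict inequalities): group 1 shows no
initial decrease and is above baseline at 70 minutes of arrest; among
genes with an initial decrease (both the 30- and 50-minute means below
baseline; a switch relaxes this to "either"), group 2 re-accumulates (the
70-minute mean exceeds the lower of the 30/50-minute means) and group 3 is
the remainder. The three labels always partition the analyzed set. The
15-minute point is carried for plotting but takes no part in the rule. The
margin exists because verbal rules ("increased", "decreased") carry no
epsilon; zero is the faithful strict reading.

**Maternal clearance** keeps prior purely-maternal genes whose control
C14L mean falls below the control C12 mean. Note that CPM is
compositional: when zygotic transcripts flood the library, stable genes
also drift down in CPM. The selection is therefore only meaningful within
a prior maternal list, exactly as it is used.

**N/C- versus time-dependence** is classified from paired diploid/haploid
expression-by-cycle profiles by a transparent shift-fit: median-center
both profiles, compare the mean squared error of the haploid profile
against the diploid profile shifted by 0 versus 1 cycle (truncated
overlap), and call the strictly better fit; fits within 5% relative error
of each other are "ambiguous". Only shifts {0, 1} are considered — the
biological construct is a one-cycle delay. This is a surrogate for the
original microarray procedure, whose details live in its own report; we do
not claim to reproduce its exact gene lists, only its logic. The label is
invariant to adding a constant to both profiles and to uniform positive
rescaling.

## The synthetic generator

`make_study()` emulates the two-arm single-embryo design: control embryos
collected in cycles 12, 13, early 14 (~10 min in) and late 14 (~70 min
in), nuclei doubling each cycle (4-fold from C12 to C14), and
cycle-12-arrested embryos sampled 15/30/50/70 minutes after mitosis 11
with a fixed cycle-12 nuclear complement (2,000 by default). Three
replicate embryos per condition give 24 samples. Expected abundances
combine an exponentially decaying maternal pool with zygotic accrual
summed over the productive windows of elapsed cycles (arrested embryos
accrue continuously in their unbounded interphase). Counts are negative
binomial (dispersion 0.1) around expected CPM shares of a log-normal
library size — the standard minimal overdispersion model for RNA-seq.

Planted classes tie gene parameters to the arrest phenotypes through the
window model itself, not through hard-coded labels:

* group 1: purely zygotic, short TUs (1–4 kb), strong rates — rises from
  the first arrest time point;
* group 2: a destabilized maternal deposit (half-life 15 min, a realistic
  scale for transcripts destabilized at the maternal-to-zygotic
  transition) plus strong zygotic transcription from 62–68-kb TUs, whose
  ~45-min eclipse delays arrest accrual past the 50-minute sample — the
  abundance dips at 30/50 minutes and re-accumulates by 70;
* group 3: the same maternal decay but ultra-long TUs (95–110 kb) whose
  eclipse exceeds every sampled window — abundance only falls. These genes
  enter the analyzed set as planted prior knowledge; unlike their real
  counterparts they do not rise even in late cycle 14, a simplification
  the recovery tests do not depend on;
* maternal clearance genes decay with half-life 100 min (roughly halving
  between control C12 and C14L), alongside a stable housekeeping pool and
  a silent fraction.

What the generator does **not** emulate: spatial patterning, batch or
collection-time artifacts, transcript-length biases in counting, zygotic
mRNA turnover, and any coupling from transcription back onto the cell
cycle. Passing recovery tests therefore show that the pipeline's rules
recover the planted dynamics under realistic count noise — not that the
rules are robust to everything real embryos do.

Paired ploidy profiles (`generate_ploidy_profiles()`) are built directly
from the efficiency staircase: "nc_like" genes follow the N/C ratio, so
their haploid profile is the diploid one delayed by exactly one cycle;
"time_like" genes keep their profile; Gaussian noise is 10% of the
activation amplitude by default.

## Problem sizes and numerical choices

The shipped tests run the recovery analysis at 2,000 genes × 24 embryos
and 100 ploidy-profile genes, sizes at which every planted effect is
identifiable yet the whole suite finishes in seconds; simulator/closed-form
equivalence uses 1,000 replicates per (schedule, length) pair. Clamps (at
zero for windows, [0, 100] for efficiencies) are applied before division so
degenerate schedules cannot produce negative efficiencies; all-zero count
columns and empty gene sets are errors, not silent NAs; Welch tests on
constant rows return NA p-values and such genes are never called zygotic;
near-tied shift fits return "ambiguous" instead of an arbitrary winner.

## Limitations

The model is deliberately minimal: it bounds *when* productive expression
is possible, not how much of it promoter-specific regulation allows —
observed onsets can only be later than the model's earliest times. The
classification thresholds (fold change 1.5, alpha 0.05, margin 0) are
conventions of the screening design, not estimated quantities, and are all
surfaced in `classifier_config()`.
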