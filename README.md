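# zgawindow

Tools for asking when a rapidly dividing embryo *can* transcribe its own
genome. In syncytial *Drosophila* embryos, every mitosis aborts all nascent
transcripts, so a gene can only be productively expressed once interphase
is long enough to initiate (after a post-mitotic lag) and elongate across
its whole primary transcription unit (TU). `zgawindow` implements that
window model, a stochastic simulator of initiation/elongation/abortion
whose mean reproduces it, and the single-embryo RNA-seq classification
pipeline used to study zygotic genome activation (ZGA) when the cell cycle
is arrested in cycle 12 — plus a seeded synthetic-data generator with
planted ground truth so every stage can be verified end to end.

## The model

For cycle *c* with interphase *I(c)* and mitosis *M(c)*, a TU of length
*L* kb, lag *ℓ* (default 4 min) and elongation rate *v* (default 0.7
min/kb):

* eclipse time: *E(L) = v·L* — initiation-to-complete-transcript delay;
* transcriptional window: *W(c) = max(0, I(c) − ℓ)*;
* productive window: *P(c, L) = max(0, W(c) − E(L))*;
* expression efficiency: *100 · P(c, L) / (I(c) + M(c))* %, with the
  terminal cycle (14) set to 100% — the embryo stops dividing, so the
  mitotic deadline disappears.

The simulator draws initiations as a Poisson process at
`rate × nuclei` per minute over `(ℓ, I]`; a transcript completes iff it
finishes before interphase ends, otherwise it is aborted. Its expectation
is `rate × nuclei × P(c, L)`.

The classification pipeline covers log2(CPM+1) normalization, PCA
trajectories, zygotic-gene identification (fold change > 1.5 and Welch
p < 0.05, late C14 vs C12 controls), intersection with prior gene lists,
the three-way arrest response (rise / dip-then-reaccumulate / no
increase), maternal clearance selection, Fisher-exact feature enrichment,
and a shift-fit classifier separating N/C-ratio–dependent from
time-dependent genes in paired diploid/haploid profiles.

## Worked example

The efficiency staircase for four TU lengths under the default schedule:

```r
library(zgawindow)
efficiency_table(c(1, 2.5, 10, 25))
#> Time-averaged expression efficiency (%) by cycle and TU length (kb)
#>      tu_kb
#> cycle     1   2.5    10  25
#>    8    0.0   0.0   0.0   0
#>    9    7.6   0.0   0.0   0
#>    10  19.2  10.4   0.0   0
#>    11  33.1  25.9   0.0   0
#>    12  42.9  36.8   5.9   0
#>    13  51.5  46.2  20.0   0
#>    14 100.0 100.0 100.0 100
```

A 1-kb gene can already be expressed ~8% of the time in cycle 9; a 25-kb
gene is silenced by mitotic abortion until the cycles stop. The event-level
simulator shows the same onset, transcript by transcript:

```r
simulate_completed(8:14, tu_length_kb = 10,
                   sim_params(2, n_nuclei_by_cycle = 4, seed = 9))
#>   cycle initiated completed aborted
#> 1     8         2         0       2
#> 2     9        14         0      14
#> 3    10        25         0      25
#> 4    11        44         0      44
#> 5    12        59         9      50
#> 6    13        79        34      45
#> 7    14       540       540       0
```

A full synthetic study, analyzed end to end:

```r
study <- make_study(n_genes = 2000, seed = 1)
lc <- log2_cpm(study$counts)
analyzed <- study$truth$gene_id[!is.na(study$truth$planted_group)]
groups <- categorize_groups(lc, analyzed)
groups
#> Arrest-response categorization of 593 zygotic genes
#>   group 1:   474 (79.9%)
#>   group 2:   107 (18.0%)
#>   group 3:    12 (2.0%)
truth <- study$truth$planted_group[match(groups$genes$gene_id, study$truth$gene_id)]
mean(groups$genes$group == truth)
#> [1] 1
```

All planted labels are recovered. The group-2 fold-change profile shows
the signature the rule detects — maternal decay dominating early arrest,
zygotic re-accumulation by 70 minutes:

```r
round(mean_foldchange_profile(lc, groups$genes$gene_id[groups$genes$group == 2]), 2)
#>  control:C12  control:C13 control:C14E control:C14L  arrested:15  arrested:30
#>         0.00        -1.27        -2.83         1.63        -0.60        -1.69
#>  arrested:50  arrested:70
#>        -2.45         0.81
```

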