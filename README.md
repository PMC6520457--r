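# pairedscreen

Analysis of pooled CRISPR-Cas9 knockout (dropout) screens run in **matched
pairs of cell lines** — typically a primary cell line and its transformed
counterpart — sampled over a time course. The package answers the question
such paired screens are designed for: *which genes are essential only in the
transformed context*, i.e. candidate cancer-specific vulnerabilities.

## The method

In a pooled negative-selection screen, cells carrying a knockout of an
essential gene are outcompeted, so that gene's sgRNAs deplete from the
population. After counting sgRNA spacers per sample, abundances are
normalized to reads per million and each guide gets a log2 fold change
against the cell line's day-1 reference:

```
lfc_s(c, t) = log2( (cpm_s(c, t) + p) / (cpm_s(c, day1) + p) )
```

with pseudocount `p = 0.5`. The **CRISPR score** of gene *g* is the mean
lfc of its sgRNAs — negative for depleted (essential / pro-proliferative)
genes, positive for enriched (growth-suppressive) genes — with a two-sided
significance test per gene: a one-sample *t*-test of the guide lfcs against
0 (default) or a two-sample Kolmogorov–Smirnov test against the
non-targeting-control distribution.

Each gene is then reduced, per cell line, to one of three states
(significantly enriched / no change / significantly depleted at
`p < 0.05`), and the 3 × 3 state pairs over the transformed line **B** and
the primary line **A** define **nine groups**:

| B \ A        | sig down | ns | sig up |
|--------------|----------|----|--------|
| **sig up**   | 1        | 2  | 3      |
| **ns**       | 4        | 5  | 6      |
| **sig down** | 7        | 8  | 9      |

Group 8 — depleted only in the transformed line — holds the candidate
context-specific vulnerabilities; among them, **strict essential** genes
are those whose terminal log2 CRISPR score is ≤ −5, i.e. at least 32-fold
depleted. Screens are summarized with cumulative sgRNA-frequency (ECDF)
curves and compared via Pearson *R*² over shared genes.

The package also ships a simulator of paired screens (planted per-gene
fitness effects across all nine archetypes, Beta-distributed guide
efficiencies, log-normal cloning skew, exponential abundance dynamics,
multinomial or Dirichlet-multinomial sequencing noise) with ground-truth
labels, so every pipeline stage can be validated without deposited data.

## Worked example

Simulate a 500-gene paired screen (3 guides/gene, 10 non-targeting
controls, days 1/4/11/21, 300× coverage, 0.35 log2 units/day planted
depletion) and run the analysis:

```r
library(pairedscreen)

cfg    <- sim_config(n_genes = 500, coverage = 300, effect_size = 0.35, seed = 42)
scr    <- simulate_screen(cfg)
scores <- gene_test(sgrna_lfc(normalize_cpm(scr$counts)), scr$library, method = "t")
rows   <- classify_screen(scores_a = scores[scores$cell_line == "A", ],
                          scores_b = scores[scores$cell_line == "B", ],
                          alpha = 0.05)
group_sizes(rows)
#>   1   2   3   4   5   6   7   8   9
#>   7 169  17  14 199   8  17  64   5

calls <- call_strict_essential(rows)      # group 8 and log2 score <= -5
head(subset(calls, called), 4)
#>    gene_id group log2_ratio called
#> 10  g00010     8  -5.052183   TRUE
#> 22  g00022     8  -5.577719   TRUE
#> 43  g00043     8  -5.526892   TRUE
#> 54  g00054     8  -5.960558   TRUE

evaluate_recovery(rows, scr$truth)        # against the planted truth
#> classification recovery: accuracy 0.604
#> group 8 precision 1, recall 0.901

correlate_screens(scores[scores$cell_line == "A", ],
                  scores[scores$cell_line == "B", ])
#> screen correlation over 500 genes: r = 0.245, R^2 = 0.0602
```

The group-size vector always partitions the gene universe (7 + 169 + … +
5 = 500). The 64 genes called into group 8 are depleted only in the
transformed line; the strict calls among them are ≥ 32-fold depleted at
day 21. Recovery is evaluated against the simulator's planted labels:
group-8 precision 1.0 / recall 0.90 here. (Accuracy over all nine groups
is lower by design: under relative-abundance normalization a screen with a
sizeable depleted class shifts every neutral guide slightly upward, which
blurs the minority enriched/neutral boundaries but leaves the group-8 call
intact — see the methods vignette.)

`run_pipeline()` orchestrates the same stages from files on disk and
writes every table plus a JSON report;
`inst/cli/pairedscreen.R` exposes `simulate | count | score | classify |
correlate | run` subcommands for shell use.

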