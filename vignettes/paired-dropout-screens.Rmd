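---
title: "Scoring and classifying paired pooled CRISPR dropout screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and classifying paired pooled CRISPR dropout screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairedscreen)
```

## The screening model

A pooled knockout screen transduces a library of sgRNAs into a
Cas9-expressing cell population at low multiplicity, so that each cell
carries roughly one guide, and lets the population compete over a time
course (here days 1, 4, 11 and 21 post-transduction, day 1 serving as the
reference). Knockout of an essential gene removes its carriers from the
pool, so the gene's guides deplete; knockout of a growth suppressor lets
carriers overgrow, so its guides enrich. Sequencing the integrated spacers
per sample turns the competition into a count matrix.

Running the *same* library through a matched pair of cell lines — a
primary line (role A) and its transformed derivative (role B) — and
contrasting the outcomes separates generally essential genes from genes
whose essentiality is created by the transformation. Those
transformed-only essentials are the screen's payoff: candidate
vulnerabilities of the transformed state.

## From counts to CRISPR scores

`normalize_cpm()` scales each sample to one million reads. No
distributional model is imposed at this stage; reads-per-million is the
minimal depth correction and keeps every later quantity interpretable as a
relative abundance. `sgrna_lfc()` then computes, per cell line,

$$\mathrm{lfc}_s(c, t) \;=\; \log_2
  \frac{\mathrm{cpm}_s(c, t) + p}{\mathrm{cpm}_s(c, t_{\mathrm{ref}}) + p},$$

with pseudocount $p = 0.5$ (in cpm units) added inside the ratio only.
The pseudocount guarantees finite values when a guide drops to zero —
common for strongly depleted guides by day 21 — while leaving
well-measured guides essentially untouched; 0.5 is half the smallest
observable increment, the conventional choice. Replicates, if present, are
averaged on the cpm scale before the ratio, matching the
one-sample-per-timepoint design this assay family uses. The reference day
is each cell line's smallest sampled day unless the metadata designates
one explicitly.

The per-gene **CRISPR score** is the arithmetic mean of the gene's guide
lfcs (`gene_score()`). Mean-of-log rather than log-of-summed-abundance is
the convention of the screening literature: it weights each independent
guide equally instead of letting the most abundant guide dominate, and it
makes the score's units directly interpretable (a score of −5 means the
gene's guides are, on average, 32-fold depleted).

### Significance

`gene_test()` offers the two tests appropriate to this design:

* **`method = "t"`** (default): a two-tailed one-sample *t*-test of the
  gene's guide lfcs against 0, with $n_{\mathrm{sgRNA}} - 1$ degrees of
  freedom. With 3 guides per gene this is a df = 2 test — low-powered per
  gene but honest about the replication actually available, and the
  simulator's calibration checks confirm its type-I error tracks
  $\alpha$ under the null.
* **`method = "ks"`**: a two-sample Kolmogorov–Smirnov test of the gene's
  guide lfcs against the pooled non-targeting-control lfc distribution at
  the same condition, for libraries whose control set is large enough to
  anchor a null.

Degenerate inputs are resolved deterministically and monotonically with
the evidence: zero variance with a nonzero mean (three identical, shifted
guides) is treated as maximal evidence, $p = 0$; zero variance with zero
mean as no evidence, $p = 1$; a single surviving guide cannot support a
*t*-test and gets $p = 1$ with a warning. No multiple-testing correction
is applied by default — the classification below consumes raw per-gene
p-values — but Benjamini–Hochberg is available (`adjust = "BH"`).

## The nine-group classification

`classify_gene()` reduces each cell line to a three-level state —
significantly enriched ($p < \alpha$ and score $> 0$), significantly
depleted ($p < \alpha$ and score $< 0$), or no significant change — and
maps the state pair to groups 1–9 (see `?classify_gene` for the grid).
Three boundary rules make the map total and unambiguous:

* the boundary $p = \alpha$ is **not** significant (strict inequality);
* a score of exactly 0 carries no direction and is forced to "no change"
  whatever its p-value, because every directional rule is
  sign-conditioned;
* missing scores or p-values are an error rather than a silent NA group.

These rules give the classification clean algebra, which the test suite
verifies exhaustively: swapping the two cell lines permutes
$1\leftrightarrow 9$, $2\leftrightarrow 6$, $4\leftrightarrow 8$ (3, 5, 7
fixed); negating every score permutes $1\leftrightarrow 9$,
$2\leftrightarrow 8$, $3\leftrightarrow 7$, $4\leftrightarrow 6$; and
shrinking $\alpha$ only ever moves genes into the doubly-neutral group 5,
never out of it.

`call_strict_essential()` flags, by default within group 8 only, genes
whose terminal score in line B is $\le -5$ log2 units — a 32-fold
depletion. The threshold is expressed in log2 units so that it composes
with the score's scale; the restriction to group 8 reflects the question
the paired design asks (transformed-only essentiality), and
`restrict_to_group8 = FALSE` widens eligibility to any significantly
depleted gene in B (groups 7–9).

## What the simulator emulates

`sim_config()` + `simulate_screen()` generate a complete paired screen
with ground truth. The generative model, per sgRNA $s$ of gene $g$ in
cell line $c$ at day $t$:

$$w_s(c, t) \;=\; \pi_s \, 2^{\,e_s f_{g,c} (t - t_{\mathrm{ref}})},
  \qquad \text{counts}(\cdot, c, t) \sim
  \mathrm{Multinomial}\!\big(N,\; w(c, t) / \textstyle\sum w\big)$$

* $\pi_s$: initial abundance, log-normal with $\sigma = 0.5$ log2 units —
  the magnitude of cloning skew typical of pooled libraries.
* $f_{g,c}$: planted fitness in log2 units/day. Each gene draws one of
  the nine group archetypes from `class_fractions`; the archetype fixes
  the sign of $f$ in each line. Depleted archetypes get
  $-\texttt{effect\_size}$ (default 0.25/day, so the 20 days from day 1
  to day 21 accumulate 5 log2 units — exactly the 32-fold strict
  threshold at full efficiency). Enriched archetypes get
  $+\texttt{effect\_size} \times \texttt{enrichment\_scale}$ (default
  scale 0.2): knockout of an essential gene can abolish growth outright,
  but knockout of a growth suppressor confers only a modest proliferative
  advantage, so enrichment is simulated an order of magnitude weaker than
  depletion. Symmetric ±5 log2 effects would also be numerically
  degenerate — a few percent of 32-fold-enriched guides would dominate
  the per-sample total and shift every other guide's relative abundance
  by close to half a log2 unit.
* $e_s \in [0,1]$: per-guide knockout efficiency, Beta(17, 3) (mean 0.85,
  sd 0.08) — most guides cut well, a tail cuts poorly. Efficiency
  multiplies fitness, so a weak guide depletes slower, which is why a
  planted 32-fold gene realizes a mean score near
  $-5 \times 0.85 = -4.25$ rather than −5.
* $N$: `round(coverage × library size)` reads per sample, coverage
  defaulting to 300× — the sequencing depth this assay family targets.
  `dispersion > 0` replaces the multinomial with a Dirichlet-multinomial
  (concentration $\propto 1/\texttt{dispersion}$), one extra parameter
  with exact sampling, to mimic PCR/bottleneck overdispersion. An
  optional `bottleneck` multinomially subsamples the pool per cell line
  before day 1, summarizing transduction at low MOI plus selection.

The default `class_fractions`
(0.002, 0.02, 0.003, 0.02, 0.75, 0.02, 0.02, 0.155, 0.01 for groups 1–9)
describe a mostly-neutral screen with a substantial transformed-only
essential class and small minority classes, so that all nine archetypes
are exercised while the composition remains dominated by neutral genes —
the regime in which relative-abundance normalization is meaningful. These
are the package's reference study conditions; they were chosen once,
before measurement, and the validation targets below are stated under
them.

### What it does not emulate

Sequencing counts are the only observable; there is no explicit cell-count
dynamics, no integration-site or copy-number structure, no guide-sequence
off-target model, and no PCR chemistry beyond the optional
overdispersion. Real screens also violate the clean archetype structure —
fitness effects are continuous, not three-valued. Passing the recovery
tests therefore shows the pipeline is correct *given* exponential dropout
dynamics and multinomial sampling; it does not certify performance on any
particular real dataset.

### A known, deliberate artefact

Because only relative abundances are observed, a screen whose depleted
class carries ~19% of the genes (the default composition) loses ~15% of
its total abundance mass in line B by day 21; renormalization therefore
shifts every neutral guide's lfc up by ≈ +0.24 log2 units in that line.
Neutral genes then sit slightly on the enriched side of zero, which blurs
the enriched/neutral boundary (overall nine-group accuracy ≈ 0.6 under
defaults) while leaving the depleted side conservative — group-8 precision
stays ≈ 1 and recall ≥ 0.9. This is a property of relative-abundance
screens themselves, not of the implementation, and it is why the null
calibration check is defined on an all-neutral screen, where the shift
vanishes.

## Validation targets computed by the package

The test suite and `scripts/acceptance.R` recompute, from scratch:

* library geometry at genome scale (59,530 guides = 19,840 × 3 + 10);
* the full partition of a simulated 19,840-gene screen into nine groups
  summing to 19,840;
* the 32-fold arithmetic of the strict threshold ($2^{|-5|} = 32$);
* the exhaustive classification truth table, the swap/flip/alpha
  symmetries, cpm column sums, ECDF monotonicity, read-count
  conservation, and simulator determinism by seed;
* *t*-test p-values against an independent numeric oracle (the *t*
  density integrated with `stats::integrate`) to 10⁻⁹;
* null calibration: on an all-neutral 2,000-gene screen the fraction of
  genes with $p < 0.05$ stays within three binomial standard errors of
  0.05;
* recovery: under the default study conditions on a 2,000-gene screen,
  group-8 precision and recall are at least 0.9, and with a sparse
  essential class at high coverage the mean realized day-21 lfc of
  planted group-8 genes approaches $-5 \times$ mean efficiency.

Simulation sizes (2,000 genes for the stochastic checks, 1,000 at 2,000×
coverage for the depletion-recovery check, one genome-scale screen for the
structural checks) were chosen as the smallest sizes at which the binomial
error bands quoted above are meaningful; the whole suite runs in well
under a minute.

## Numerical and design choices

* **Exact, forward-strand spacer matching.** `count_spacers()` assigns a
  read to the unique spacer occurring as an exact substring; reads hitting
  guides of ≥ 2 distinct sgRNAs are discarded as ambiguous rather than
  fractionally assigned, keeping counts integral and order-independent.
  Mismatch-tolerant matching is deliberately out of scope.
* **Terminal-day classification.** `classify_screen()` defaults to the
  latest day shared by both score tables; any shared day can be selected.
* **Correlations on shared identifiers only.** `correlate_screens()`
  intersects gene ids and uses complete cases; mapping orthologs across
  species is out of scope.
* **Determinism.** Every `simulate_*` function is a pure function of
  (config, seed); the pipeline writes byte-identical outputs on rerun,
  and its report carries no timestamps for exactly that reason.

## Limitations

Per-gene power with three guides is intrinsically low; the df = 2 t-test
is calibrated but blunt, and real analyses often pool evidence across
guides with hierarchical models, which this package deliberately does not
do. The classification consumes raw p-values, so group occupancy scales
with the gene universe (≈ α/2 of truly neutral genes land in each
directional margin); the BH option exists for users who want FDR control
before classification. Finally, scores are relative: a screen in which
most genes are essential would violate the mostly-neutral assumption
underlying cpm normalization, as the artefact note above quantifies.
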