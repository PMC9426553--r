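---
title: "Gene coexpression connectivity: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene coexpression connectivity: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gecco)
```

## The problem

Engineering a complex phenotype — here, tolerance of an oleaginous yeast to
an ionic-liquid solvent — starts from a list of genes upregulated in a
tolerant strain. Such lists routinely contain hundreds of genes, far more
than can be validated by overexpression one at a time, and the genes with
the largest fold changes are not necessarily the ones that *drive* the
phenotype. `gecco` ranks the upregulated candidates by **coexpression
connectivity**: a gene whose expression profile moves in near lockstep with
many other candidates is treated as a hub of the transcriptional program
and prioritized.

## Scoring model

The input is a gene × sample TPM matrix from a replicated design with two
biological conditions per comparison and two sampling times (early and mid
exponential growth), three replicates each by default.

**Preprocessing.** TPM values below a floor of 5 are raised to 5, then
log2-transformed, then averaged over replicates. Flooring gives absent and
barely-detected transcripts a common baseline so that ratios of two noisy
near-zero values cannot masquerade as fold changes. The transform order
(log2 per replicate, then average) is the package default because the
replicate variance entering the scores must be computed on the log2 scale;
averaging TPM before the log2 transform is available as
`average_before_log2 = TRUE` for sensitivity analysis, and changes only the
mean, never the variance.

**Scores.** With per-gene replicate means $m$, variances $V$, and counts
$N$ indexed by condition (1, 2) and time (e, m):

$$X = \frac{m_{1e} - m_{2e}}{\sqrt{c + V_{1e}/N_{1e} + V_{2e}/N_{2e}}},
\qquad
Y = \frac{m_{1m} - m_{2m}}{\sqrt{c + V_{1m}/N_{1m} + V_{2m}/N_{2m}}},$$

$$Z = \frac{(m_{1m} - m_{1e}) - (m_{2m} - m_{2e})}
{\sqrt{c + V_{1m}/N_{1m} + V_{1e}/N_{1e} + V_{2m}/N_{2m} + V_{2e}/N_{2e}}}.$$

$X$ and $Y$ are moderated log2 fold changes at the two times; $Z$ measures
whether the *trajectory* over time differs between conditions. The
pseudovariance $c = 0.25$ bounds every denominator below by
$\sqrt{c} = 0.5$, so a zero-variance gene has $X = 2\times$ its log2 fold
change rather than an infinite statistic. The denominators take the square
root of the full sum; an un-rooted variant
(`sqrt_denominator = FALSE`) is kept as a configuration switch because the
two forms coincide in the zero-variance limit only up to scale and the
rooted form is the standard variance-stabilized statistic. Replicate
variance uses denominator $n - 1$ by default; `var_denom = "n"` is exposed
because the class counts on real data can hinge on the choice.

**Classification.** Genes fall into six classes by threshold rules on
$(X, Y, Z)$ with $t = 1$ and $r = 1.5$, evaluated in order: BC1
upregulated ($X \ge t$, $Y \ge t$), BC1 increasing ($-t < X < t$,
$Y \ge t$, $Z \ge r$), BC2 upregulated ($X \le -t$, $Y \le -t$), BC2
increasing ($-t < X < t$, $Y \le -t$, $Z \le -r$), changed regulation
($|Z| \ge r$), otherwise no change. Rule order matters: a gene meeting an
upregulated or increasing rule keeps that label whatever its $Z$, since
changed regulation is defined as the *residual* trajectory-shift class. A
gene with, say, $X \ge 1$ but $Y < 1$ and $|Z| < 1.5$ falls through every
rule and is labeled no change; no special case is carved out for it. The
boundary operators are used exactly as written (inclusive $\ge$/$\le$,
strict $<$ for the increasing window), so score values sitting exactly on
a threshold are classified deterministically.

## Network and selection

The coexpression network connects two classified genes when the Pearson
correlation of their expression profiles across the individual replicate
samples of the comparison's two conditions (2 conditions × 2 times × 3
replicates = 12 samples) reaches `r_cutoff = 0.95`. Three choices here
were genuinely open and are all exposed as flags:

* **Signed vs absolute correlation** — the default thresholds signed
  $r \ge 0.95$, reading "coexpression" as positive co-movement (up- and
  down-regulated clusters then separate in the network); `absolute = TRUE`
  also connects strong anticorrelation.
* **Raw TPM vs log2 profiles** — default is raw TPM replicate profiles;
  `use_log2 = TRUE` correlates the floored log2 values instead, which is
  less dominated by a few highly expressed samples and is what the
  package's own module-recovery checks use.
* **Replicate-level vs replicate-averaged samples** — correlations use the
  12 individual replicates. Averaging first would leave 4 points per gene,
  at which $r \ge 0.95$ is nearly unconstraining.

A gene whose profile is constant over the network samples (e.g., floored
everywhere) has no defined correlation and is kept as an isolated node
rather than raising an error.

The network is then reduced to the subgraph induced by the BC1-upregulated
genes, and **degree** — the raw number of incident edges, not normalized —
is computed on the reduced graph, so a candidate's connectivity counts only
coexpression with other candidates. Candidates are partitioned at the 75th
percentiles of degree and of average fold change $(X+Y)/2$ into four
quadrants (Q1 both, Q2 degree only, Q4 fold change only, Q3 neither).
Percentiles default to linear interpolation between order statistics
(`stats::quantile` type 7), with nearest-rank (type 1) as an option;
reaching a threshold is inclusive, which keeps boundary ties inside the
selected region. Four top-$k$ ($k = 5$) groups are reported: by degree
(Q2), overlap by degree and overlap by fold change (both Q1, ranked by the
respective metric — one gene may appear in both), and by fold change (Q4).
Ties at the $k$-th position break by the other metric, then lexicographic
gene ID, making selection deterministic and row-order independent. An
underfull quadrant returns all its members with a warning. Curated gene
lists (e.g., ontology-motivated picks) are deliberately *not* computed by
the package; they can be merged into the output downstream.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the scoring model
assumes — not RNA-seq reads. Per gene and sample the log2 expression is

baseline + class delta + module latent + module member noise + replicate
noise,

exponentiated to TPM (hence always positive). Defaults, chosen once as a
realistic bulk-RNA-seq caricature of the four-condition study design:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 1000 | keeps the full pipeline in seconds |
| `conditions` | WT/MT × 0/8% stressor | 4 conditions × 2 times × 3 reps |
| `baseline_log2_mean/sd` | 6 / 2 | median ≈ 64 TPM, wide dynamic range |
| `noise_sd` | 0.25 | typical replicate scatter on log2 TPM |
| planted classes | 50/50/50/50/25 genes, deltas ±3 | clear the rules by design (zero-noise $X = Y = 6$) |
| modules | 2 × 10 genes, latent sd 2, member noise 0.2 | within-module $r \approx 0.99$ on the log2 scale |

Two deliberate departures from pure sampling: planted-class genes and
module members have their baselines lifted clear of the 5-TPM floor (by the
effect size plus a margin, and by 3 latent standard deviations,
respectively). Without the guard, a low-baseline gene's planted effect or
latent profile is censored by the floor and the truth label becomes wrong
by construction; with it, noiseless recovery of every planted class is
exact, which is what makes the recovery tests meaningful. Floor censoring
itself is still exercised by background genes.

What the generator does **not** emulate: count-based mean–variance
structure (negative binomial sampling, library-size effects), gene-length
bias, correlated replicate batches, or biologically structured background
correlation. Passing recovery tests therefore demonstrates that the
implementation computes the intended quantities and that the method works
under its own assumptions — not that those assumptions hold for any
particular real dataset. One emergent behavior worth knowing: a module's
latent profile occasionally aligns with the condition layout by chance, in
which case its members legitimately acquire class labels; truth labels for
*classes* are only guaranteed for planted-class genes.

Determinism: all randomness flows from `seed`; the generator saves and
restores the caller's RNG state, and identical configurations produce
bitwise-identical matrices.

## Problem sizes and runtime

The test suite and the reproduction script run simulations of 60–1000
genes, 24 samples, and 20-seed Monte-Carlo recovery estimates; the full
suite completes in a few seconds and the reproduction script in well under
a minute on one CPU. Correlation matrices are computed densely
(`stats::cor` on the transposed matrix), which is comfortable to a few
thousand genes; beyond ~20k genes a blocked computation would be the next
step.

## Known limitations

* The 0.95 correlation cutoff is aggressive for 12 samples (sampling error
  of $r$ near 0.95 is roughly ±0.03); degrees should be read as a robust
  ranking signal, not as precise partner counts.
* Class thresholds ($t = 1$, $r = 1.5$, $c = 0.25$) are fixed conventions,
  not fitted quantities; there are no p-values or multiple-testing
  corrections by design.
* Reproducing published per-class gene counts for the yeast
  solvent-tolerance dataset requires the corresponding deposited TPM
  matrix as a TSV (see `load_expression()` + `run_all_comparisons()`);
  the package does not bundle or download it.
* Only degree centrality is implemented; no community detection or other
  centralities, which keeps the selection criterion identical to the
  method it implements.
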