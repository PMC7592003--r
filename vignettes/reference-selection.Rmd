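---
title: "Selecting endogenous references from RT-qPCR Cq data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting endogenous references from RT-qPCR Cq data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Relative quantification by RT-qPCR reports a target's quantification cycle
(Cq) against a reference assumed constant across samples: the familiar
$2^{-\Delta Cq}$ transform with $\Delta Cq = Cq_{target} - Cq_{reference}$.
In circulating (serum/plasma) miRNA work no universally stable reference
exists — classical choices such as U6 snRNA are notoriously variable in
serum and can differ systematically between disease groups — so candidate
normalizers must be screened and ranked empirically for each study setting.
`refstab` implements that workflow end to end on a genes × samples Cq
matrix: dispersion screening, three independent stability algorithms, a
consensus ranking, a rule for how many references to combine, combination
(multi-gene) normalizers, and a cross-normalization check of the finalists.

All computation stays on the Cq (log2) scale: Cq is $-\log_2$ expression up
to an assay-specific constant, amplification efficiency is assumed to be 2,
and no efficiency correction is applied. Undetected reactions are treated
as missing — never imputed to the cycle ceiling — and every statistic works
on pairwise-complete samples and reports how many it used.

## Dispersion screening

For each gene over its detected samples the package reports mean Cq, sample
SD (n−1 denominator), IQR and CV (= SD/mean × 100, in percent of the mean
cycle number). These are descriptive filters: a useful candidate combines a
tight Cq distribution with high abundance (low mean Cq). The quartile rule
behind the IQR is linear interpolation of order statistics (R's default
type 7); the convention is pinned because different quartile rules move the
IQR on small cohorts.

## The three stability algorithms

**geNorm.** The building block is the pairwise variation of genes $j,k$:
the SD across samples of $Cq_j - Cq_k$, i.e. the SD of their log2
expression ratio. A gene's $M$ value is the mean of its pairwise variations
against the rest of the panel; the gene with the highest $M$ is removed and
$M$ recomputed, until two genes remain. The ranking is the reverse
elimination order; the algorithm cannot order the final pair, which is
reported jointly (the consensus stage may split it using the other
methods). Each gene carries the $M$ it had when eliminated, and genes with
$M > 1.5$ — the conventional ceiling for an acceptable reference — are
flagged unstable. Ties in elimination remove the gene later in panel order,
so traces are deterministic.

The optimal reference count uses the pairwise variation series: the
normalization factor $NF_n$ of a sample is the arithmetic mean Cq of the
$n$ best genes (the geometric mean of their linear quantities), and
$V_n = SD(NF_n - NF_{n+1})$ measures how much the normalizer changes when
gene $n{+}1$ is added. The smallest $n \ge 2$ with $V_n < 0.15$ is
recommended; if none qualifies the full panel size is returned with a flag.
One caveat worth knowing: $V_n < 0.15$ is only reachable when panel genes
covary across samples (shared biological/technical variation), as real
serum panels do. On synthetic panels of independent genes every added gene
moves $NF$ by roughly its own SD$/n$, so the flag legitimately reports
that no small reference set suffices.

**NormFinder.** A model-based alternative: Cq decomposes into gene effect,
sample/group effect, gene-by-group interaction $d_{ig}$ and noise
$\varepsilon \sim N(0, \sigma^2_{ig})$. Sample effects are removed via the
per-sample average over the candidate genes (hence ≥ 3 genes are required).
The intragroup variance $\hat\sigma^2_{ig}$ is the two-way residual
variance with the small-sample bias correction of the original method,
floored at 0. The interaction $\hat d_{ig}$ (groups weighted equally) is
shrunk toward zero by $\hat\gamma^2 / (\hat\gamma^2 +
\hat\sigma^2_{ig}/n_g)$, where $\hat\gamma^2$ is the across-gene variance
of $\hat d$ minus its average sampling variance, floored at 0. The
stability value is the group average of $|\tilde d_{ig}|$ plus the
posterior SD of $\tilde d_{ig}$; lower is better. With no groups (or one)
the value reduces to the gene's bias-corrected residual SD. A single-group
input is routed to this pooled mode, which also makes "grouped with one
group" and "ungrouped" coincide exactly.

A practical caveat the validation work surfaced: when one panel member has
a strong group shift (the U6-like situation), the per-sample average that
stands in for the sample effect is itself contaminated, so *every* gene
inherits an apparent interaction. Because low-variance genes receive the
least shrinkage, their noise-driven $|\tilde d|$ term is relatively
largest, and grouped NormFinder's top pick on such a panel becomes
noisy even when the noise hierarchy is clear-cut. The pooled mode ranks
that hierarchy directly and is the mode the recovery checks use; the
grouped mode remains the right tool when the question is specifically
group-dependent bias, which its own tests exercise.

**Comparative ΔCq.** Two readings are provided and labelled. The default
centers each sample by its mean Cq over the panel and takes the per-gene SD
of the centered values across samples; a gene moving with the panel average
scores 0. The classical pairwise form is the mean over partners of the SD
of $Cq_j - Cq_k$, which is algebraically the full-panel geNorm $M$ — the
package exposes both because the method's literature describes the pairwise
form while many applications compute the sample-mean form. Both are shift
invariant (per-gene constants and sample-wide plate effects change no
stability value).

## Consensus and thresholds

Per-method ranks are combined by the arithmetic mean rank; the consensus is
the rank of that mean, with ties broken by the NormFinder value and then
panel order. Mean-rank aggregation is used because the three statistics
live on different scales; the aggregation function is deliberately simple
and swappable. Flags carried through: geNorm $M > 1.5$ (unstable
reference). Defaults throughout: $V$ threshold 0.15, $M$ threshold 1.5,
cross-normalization $\alpha$ 0.05.

## Combinations and cross-normalization

A combination reference merges members by the per-sample arithmetic mean of
their Cq — the geometric mean of their linear quantities, the standard
multi-gene normalization factor. Averaging $m$ independent equal-variance
members shrinks the normalizer's SD by $\sqrt{m}$, which is the quantitative
case for combinations, and pairing references of *similar* stability
preserves that gain, whereas pairing a stable with a noisy member mostly
inherits the noise.

To score combinations, all combination pseudo-genes are appended to the
panel at once and every member gene is removed, so each combination is
judged against the same comparator set. (Scoring each combination against
its own member-excluded panel was considered and rejected: different
combinations would face different comparators, and a stable+noisy pair can
then outscore a stable+stable pair simply because a stable comparator
remained in its panel.) Each backend ranks the combinations; agreement is
summarized by the mean pairwise Spearman correlation of the rankings.

Cross-normalization evaluates finalists without any external truth: each
candidate is normalized to every other, and the $2^{-\Delta Cq}$ expression
is tested for group differences — one-way ANOVA plus Kruskal–Wallis for
three or more groups, equal-variance t plus Mann–Whitney for two. For a
genuinely stable pair neither test should fire, so the verdict is "stable"
only when both p-values exceed $\alpha$; a larger p reads as better
stability. Constant expression vectors make the tests undefined and are
reported as degenerate, never as a silent p of 1. Pairs sharing a gene are
partially self-normalizing; they are skipped by default and only scored
(flagged) when overlap is explicitly allowed, which the pipeline does for
the paper-style top-2-plus-combination grid. No multiplicity correction is
applied — the p-values are read as stability descriptives, not hypothesis
tests.

## The synthetic cohort generator

`generate_cq()` draws
$Cq_{gs} = baseline_g + shift_{g,group(s)} + plate_s + N(0, sd_g)$,
truncated to $[0, 45]$ (a 45-cycle protocol cannot report more), with
independent per-cell dropout and an optional exogenous spike-in row. The
default design, `default_panel()`, emulates a four-arm liver-disease serum
cohort: groups HCC/CHB/cirrhosis/healthy of sizes 33/21/23/28, one
designed-stable candidate (SD 0.45 cycles at baseline 24.5 — the profile of
a strong serum normalizer), four intermediates (SD 0.9–1.5, baselines
26.5–33.2, spanning the candidate Cq range), and a U6-like gene with SD 2.0
plus a +1.5-cycle HCC shift modelling disease-dependent instability.
Within-group noise SDs between roughly 0.45 (stable) and 2 (unstable)
cycles match what serum candidate screens report.

What the generator does *not* emulate: shared biological covariation
between miRNAs (genes are independent given the optional plate effect),
amplification-efficiency differences, hemolysis artifacts, and
detection-limit-censored dropout (missingness is independent of Cq).
Passing recovery tests therefore shows the algorithms rank designed noise
hierarchies and detect designed group shifts; it does not certify behavior
under correlated biological structure, which is also why the $V$ series on
the default panel honestly recommends "use the whole panel" (see above).
The plate-effect SD defaults to 0 so the sample-centering identities of the
ΔCq method stay exercisable; setting it positive makes genes covary and is
the route to $V_n < 0.15$ panels.

## Numerical choices and edge rules

- Missing cells: pairwise-complete everywhere; $V_n$ uses samples complete
  across the $n{+}1$ genes involved; NormFinder drops samples missing any
  panel gene (its sample average must be comparable) with a warning.
- Floors: $\hat\sigma^2_{ig}$ and $\hat\gamma^2$ at 0; when
  $\hat\gamma^2 = 0$ all shrunken interactions and their posterior SDs are
  0, so identical data across groups yields stability exactly 0.
- Ties: geNorm elimination removes the later gene in panel order; per-method
  and consensus ranks break ties by value, then NormFinder value, then
  panel order. All outputs are deterministic given the input.
- Round trips: Cq tables are written at 17 significant digits so
  write-then-read is bit-identical.
- Degenerate inputs error early with named genes/samples (duplicated ids,
  < 2 complete pairs, constant expression, single-sample groups).

## Problem sizes used in validation

The test suite and the acceptance script regenerate everything from code:
oracle-equivalence batteries over 100 random panels up to 5 genes × 10
samples against loop-based brute-force reimplementations (agreement to
1e-10); 100 seeded replicates of the 6-gene × 105-sample default cohort for
rank recovery; 200 replicates for the type-I error of the
cross-normalization verdict (expected in the 2–9% band around the nominal
5%, the two tests being combined by conjunction); and 100 replicates each
for the combination-amplification and SD-$/\sqrt{2}$ checks.

## Limitations

Technical replicates are expected to be pre-collapsed (a mean-collapse
utility is provided); amplification curves, Cq calling and melting analysis
are upstream of this package; efficiency correction is not implemented; and
stability values from different cohorts are not comparable in absolute
terms — rankings, not values, transfer.
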