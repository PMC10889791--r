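---
title: "Selecting stable RT-qPCR reference genes with ctstab"
author: "ctstab authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting stable RT-qPCR reference genes with ctstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctstab)
```

## The problem

Relative quantification by RT-qPCR stands or falls with the reference
(housekeeping) genes used for normalization. A reference gene that is itself
dysregulated by the treatment biases every fold change computed against it,
and no gene is stably expressed under all conditions — so candidate panels
(commonly 10–20 genes: actins, tubulins, elongation factors, ribosomal
proteins, GAPDH, ferritin, arginine kinase, GST, ...) must be screened per
experimental condition. `ctstab` implements the standard screening workflow
on cycle-threshold (Ct) data: four stability algorithms, a consensus
ranking, a rule for how many reference genes to use, standard-curve
efficiency estimation, and 2^-ddCt validation of the final choice against a
target gene.

## Data model

A `ct_table` holds a genes x samples Ct matrix, per-sample metadata (group,
biological replicate, technical replicate) and per-gene amplification
factors $A_g = 1 + E_g/100$. Technical replicates are collapsed by
`aggregate_technical_replicates()` (arithmetic mean on the Ct scale, the
conventional choice; cells whose technical SD exceeds 0.5 cycles are
reported, since larger scatter usually indicates pipetting problems). All
stability algorithms require a complete matrix: samples with a wholly
missing gene can be dropped explicitly (`drop_incomplete_samples = TRUE`),
otherwise incompleteness is an error — silent imputation would leak into
every downstream statistic.

Ct values must lie in (0, 45]: protocols run 40 cycles, and the margin
admits instruments that report a few cycles beyond. "Undetermined" cells
parse as missing.

### Relative quantities

The ratio-based methods work on linear-scale relative quantities
$$Q_{gs} = A_g^{\min_s Ct_{g\cdot} - Ct_{gs}} \in (0, 1],$$
calibrated so each gene's most abundant sample has $Q = 1$. When no
standard curve is available $A_g$ defaults to 2 (perfect doubling). Whether
a published screen used efficiency correction is rarely stated; both paths
are supported, and because a gene-wise constant factor cancels from the
log-ratios, rankings are typically insensitive to the choice.

## The four stability algorithms

All four return a per-gene stability value with *lower = more stable* and a
rank (ties averaged by default; minimum-rank available via `ties = "min"`).

**Comparative delta-Ct** (`delta_ct_stability`). For each gene pair the SD
over samples of the Ct difference; a gene's value is the mean of its
pairwise SDs (cycles). Per-sample loading offsets cancel in the
differences.

**geNorm** (`genorm_m`, `genorm_rank`, `pairwise_variation`). The M-value
of gene $i$ is the mean over partners $j$ of
$\mathrm{SD}_s[\log_2 Q_{is} - \log_2 Q_{js}]$. `genorm_rank` removes the
highest-M gene until two remain; a gene's reported value is its M at
removal, and the final pair take ranks 1–2 ordered by their M in the last
three-gene step. Ties (never observed on continuous data, but decidable)
remove the lexicographically last name. The pairwise-variation curve
compares normalization factors built from the $n$ and $n+1$ best genes:
$V_n = \mathrm{SD}_s[\log_2(NF_n/NF_{n+1})]$, with
$NF_n$ the geometric mean of the top-$n$ quantities. $V_n < 0.15$ is the
conventional signal that the $(n{+}1)$-th gene is unnecessary.

**NormFinder** (`normfinder_stability`). A variance-decomposition model on
$z = \log_2 Q$ after centring each sample on its gene average (removing
loading). Ungrouped, the naive per-gene residual variances $v_g$ are biased
by the gene-mean subtraction; solving the bias system gives the total
$T = \sum_g v_g / (1 - 1/k)$ and
$\hat\sigma^2_g = \max\{(v_g - T/k^2)/(1 - 2/k),\, 0\}$ — hence the
requirement of $k \ge 3$ genes — and the stability value is
$\hat\sigma_g$. With groups, the same bias-corrected variances are computed
per group, systematic intergroup differences $d_{g\gamma}$ are shrunk
toward zero with weight
$\hat\gamma/(\hat\gamma + \hat\sigma^2_{g\gamma}/n_\gamma)$, and the value
is the group-average of the shrunk $|d|$ plus the standard error of the
group mean — a gene can be penalised either for noise or for a reproducible
condition response. The original add-in's exact constants are not public;
this implementation is the package's own, fixed here so results are
decidable, and it is tested for the algebraic self-consistency of the
variance total and for parameter recovery.

**BestKeeper** (`bestkeeper_stats`). Purely descriptive, on raw Ct: n,
geometric/arithmetic mean, min/max, dispersion (sample SD by default; mean
absolute deviation via `deviation = "mad"` for fidelity to the original
tool), CV = 100·dispersion/mean, and each gene's Pearson correlation with
the BestKeeper index (per-sample geometric mean Ct across the panel).
Because it never forms ratios, BestKeeper *sees* sample-loading variation:
with large loading noise and no condition effects the ratio methods report
values near zero while BestKeeper's SDs grow. That contrast is a property
of the method, worth remembering when its ranking disagrees with the other
three.

## Consensus and selection

`reffinder_geomean` merges rankings as the geometric mean of each gene's
per-method ranks (a gene ranked 15th of 15 by all four methods scores
exactly 15.00). Ties on the geomean break by arithmetic mean rank, then
name. No method weighting is applied — the web tool's undocumented
weighting variant is deliberately out of scope.

`select_optimal` takes the number of genes from the V-curve (smallest $n$
with $V_n$ below the 0.15 cutoff) and their identity from the head of the
consensus ranking; this mirrors the usual published procedure (geNorm for
*how many*, the consensus for *which*). When no $V_n$ clears the cutoff the
$n$ at the minimum V is returned with an explicit `fallback` flag — never
silently. Raising the cutoff can only decrease the selected $n$.
`run_full_analysis()` chains the whole pipeline and writes per-method TSVs,
the V-curve, the consensus table, a JSON recommendation and a run log; a
thin command-line wrapper lives at `inst/cli/ctstab.R`.

## Target-gene validation

`ddct_expression` computes multi-reference 2^-ddCt fold changes:
$\Delta Ct_s = Ct_{t,s} - \overline{Ct}_{\mathrm{refs},s}$ (arithmetic mean
of reference Ct, which equals geometric-mean-of-quantity normalization at
equal amplification factors; per-gene factors via
`efficiency_correct = TRUE`), calibrated to the mean $\Delta Ct$ of the
calibrator group, so the calibrator's mean fold change is exactly 1.
Standard errors are reported on the fold-change scale (log2-scale summaries
by flag); no error propagation through the calibrator mean is attempted.
Group comparisons use the pooled-variance Student's t test for two groups
and one-way ANOVA with Tukey HSD for three or more, summarised as compact
letters assigned by insert-and-absorb on the significance graph,
alphabetically from the largest group mean.

## The synthetic-data generator

`simulate_ct` draws from
$$Ct_{g\gamma b\tau} = \mu_g + \delta_{g\gamma} + a_{\gamma b} +
\varepsilon_{g\gamma b\tau},$$
with $\delta \sim N(0, \sigma_{\mathrm{cond},g})$ once per (gene, group) —
treatment-driven dysregulation is a reproducible group-level shift, not
per-sample jitter — $a \sim N(0, \sigma_{\mathrm{load}})$ once per
biological sample shared by all genes, and per-well technical noise
$\varepsilon$. The generator returns the ground-truth condition-SD ordering
so recovery experiments are decidable. `study_like_spec()` fixes the study
shape used throughout the tests: 15 genes with baselines spread over 17–31
cycles, six treatment groups (five insecticides plus a water control —
concentrations pooled) of 3 biological x 3 technical replicates, loading
SD 0.5 and technical SD 0.3 cycles, and graded condition SDs of 0.05–1.2
cycles so the panel spans clearly stable to clearly unstable genes. An
optional target gene carries known per-group log2 fold effects (a 2-fold
induction is a one-cycle shift at $A = 2$).

What the generator does *not* emulate: amplification-curve shape,
inhibitor-driven efficiency shifts, heteroscedastic noise near the
detection limit, missing wells, or correlated co-regulation between
candidate genes. Passing tests therefore demonstrate algorithmic
correctness and recoverability under the additive Gaussian model, not
robustness to every real-data pathology.

`simulate_dilution_series` generates standard-curve data on the exact line
$Ct = b - \log_{10}(c)/\log_{10}(A)$ over the 5-fold series
1/5 ... 1/3125, with optional Gaussian noise. Replicate wells enter the
regression as individual points. At noise SD 0.1 cycles a single
5-dilution x 3-replicate fit estimates efficiency with a standard error
near 1.1 percentage points; tests on recovered efficiency therefore
average a small number of seeded fits rather than trusting one draw.

## Numerical choices and degenerate inputs

* Sample SDs use the $n-1$ denominator throughout; $R^2$ is the squared
  Pearson correlation (identical to the OLS coefficient of determination
  for the simple regression used).
* geNorm/NormFinder log base is 2; the base scales values by a constant and
  cannot change rankings.
* NormFinder clamps negative bias-corrected variances to zero; zero
  shrinkage weights replace 0/0 when a group has no residual variance.
* A standard curve with non-negative slope is reported but flagged invalid;
  a two-group t test with zero pooled variance and unequal means returns
  p = 0 with a `degenerate` flag rather than dividing by zero.
* Two-gene geNorm input returns the trivial pair with a warning; empty gene
  lists summarise to empty tables.
* Test problem sizes are kept small (panels of 2–16 genes, 3–54 samples,
  100-seed recovery experiments), which the brute-force oracles and
  closed-form checks make fully decidable.

## Limitations

The four algorithms are this package's own specifications of the published
method families; bit-for-bit agreement with the original closed-source
Excel tools (geNorm/BestKeeper macros, the NormFinder add-in, the RefFinder
web service) is not claimed. BestKeeper's dispersion is loading-sensitive
by construction. The V-curve rule is a heuristic with a conventional 0.15
cutoff, not a test with error control; treat near-cutoff values
accordingly.
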