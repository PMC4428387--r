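---
title: "Pathway activation scoring: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway activation scoring: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(pascore)
```

## The model

`pascore` describes a case sample by one signed score per signaling
pathway. For pathway $p$ and case sample $s$,

$$\mathrm{PAS}_{p,s} \;=\; \sum_{n \in p} \mathrm{ARR}_{np}\,
\mathrm{BTIF}_{n,s}\, \lg \mathrm{CNR}_{n,s},$$

with three ingredients per member gene $n$:

* $\mathrm{CNR}_{n,s}$, the case-to-normal ratio: the gene's expression in
  $s$ divided by its arithmetic mean over the control samples, both values
  floored at a small positive constant. $\lg$ is the base-10 logarithm, so
  a 10-fold induction contributes $+1$ per unit ARR weight.
* $\mathrm{BTIF}_{n,s} \in \{0,1\}$, the beyond-tolerance-interval flag:
  1 when the case value is significantly outside the control distribution.
  The tolerance interval is a normal approximation on $\log_{10}$ control
  expression: the flag fires when the case deviates from the control mean
  by more than $z \cdot \mathrm{sd}$ (default $z = 1.96$, the two-sided
  5% bound, so "inside" means $p > 0.05$).
* $\mathrm{ARR}_{np} \in \{-1, -0.5, 0, 0.5, 1\}$, the gene's fixed
  activator/repressor role in that pathway. The same gene may carry
  different roles in different pathways; roles are annotated per
  (pathway, gene) pair.

The score is a plain weighted sum: linear in membership, invariant to
member order, and blind to pathway topology. Genes in the database but not
in the data contribute nothing; pathways with no measured member score 0
(with a warning) and report `n_contributing = 0`.

### Why summing helps across platforms

Each $\lg\mathrm{CNR}$ carries gene-level measurement error that differs
between expression platforms. Three mechanisms make the pathway sum more
platform-stable than its terms:

1. **Bias cancellation.** A gene-specific multiplicative platform bias
   (probe affinity, mappability) is constant across samples within a
   platform, so it cancels *exactly* in the case/control ratio. The
   simulator makes this property testable: with per-measurement noise and
   dropout switched off but gene-by-platform bias on, the two platforms'
   $\lg\mathrm{CNR}$ matrices agree to numerical precision
   (`test-simulate.R`, and `bias_cancellation_r_gene` in the acceptance
   script).
2. **Error averaging.** Independent per-gene noise shrinks relative to the
   pathway sum as membership grows; the tests verify that the variance of
   the normalized between-platform score difference decreases as pathways
   grow from 5 to 80 genes, and that the pathway-vs-gene concordance gap
   widens correspondingly.
3. **Significance gating.** BTIF zeroes genes indistinguishable from
   control variation, removing small-ratio noise entirely (at the price of
   also letting large noise excursions through; see Limitations).

## Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `z_threshold` | 1.96 | control sd (log10) | tolerance interval half-width; 1.96 = two-sided p > 0.05 |
| `min_fold` | 1 (off) | fold change | optional extra gate $|\lg\mathrm{CNR}| \ge \lg(\text{min\_fold})$ |
| `floor` | $10^{-6}\times$ median nonzero value | expression units | applied to case values and control means before ratios/logs |
| `control_average` | arithmetic | — | geometric available; see below |
| `normalize` | auto | — | quantile normalization on, except for sequencing-labelled matrices |

The BTIF tolerance interval needs at least two controls; with a single
control the pipeline refuses and offers `btif_all_on()` (every flag 1),
which is also useful as a sensitivity analysis of the gating itself.

## Design choices that were genuinely open

* **BTIF polarity.** The flag's verbal definition is ambiguous in parts of
  the surrounding literature; by its name and by the structure of the
  score we take BTIF = 1 for *significantly perturbed* genes, 0 for
  essentially normal ones, and treat ARR purely as a weight, never as a
  criterion. An all-zero flag row yields PAS = 0, which is the sensible
  null ("nothing in this pathway moved").
* **Control averaging.** The control reference is the arithmetic mean on
  the linear scale. A geometric mean (equivalent to averaging logs) is
  available via `control_average = "geometric"`; it is more robust to one
  extreme control but changes the reference systematically for skewed
  expression, so the simpler convention is the default.
* **Correlation estimator.** Concordance is summarized with Pearson
  correlation on the quantities actually compared (log ratios; PAS), which
  matches how such value clouds are usually plotted and summarized.
  Spearman is available behind `method = "spearman"` for rank-level
  robustness checks.
* **Replicate-averaged rows.** "Averaged over N samples" correlates the
  across-replicate *mean profiles*, not the mean of per-replicate
  correlations; averaging profiles first is the operation that actually
  reduces measurement noise and is therefore the reported default.
* **Probe aggregation.** Multiple rows per gene symbol (microarray probes)
  are collapsed by arithmetic mean on the linear scale, before
  normalization. Alias resolution is deliberately out of scope: gene
  symbols are only trimmed and upper-cased, and identifier mapping is the
  user's responsibility.
* **Quantile-normalization ties.** Tied values within a column receive the
  reference distribution interpolated at their mean rank (for a tie pair,
  the mean of the two spanned reference values). With ties present this
  tie-averaging means the output columns are no longer exact copies of the
  reference distribution, so the transform is idempotent and
  mean-equalizing only up to the tie perturbation; the test suite asserts
  the exact distribution-level identities on tie-free matrices and oracle
  agreement on heavily tied ones.

## The synthetic-data generator

`simulate_two_platforms()` emulates the experimental design that motivates
the package: the *same* biological samples profiled on two platforms.

Latent truth: each gene has a baseline $\log_{10}$ abundance
$\mathcal N(2, 0.7)$ (values centred near 100 units, spanning roughly
10–1000); each sample adds biological noise $\mathcal N(0, \sigma_{bio})$,
default $\sigma_{bio} = 0.3$, the scale of replicate cell cultures. Half
of the pathways (default `perturbed_fraction = 0.5`, a broad treatment
effect) are perturbed in case samples with direction $d_p = \pm 1$: each
member gene shifts by $d_p \cdot \delta \cdot \mathrm{sign(ARR)}$ with
$\delta = 0.5$ log10 units, so activators and repressors move oppositely
and the expected PAS sign equals $d_p$.

Observation: platform $k$ sees
$10^{(\text{latent} + \text{bias}_{g,k} + \varepsilon)}$ with fixed
gene-by-platform bias $\mathcal N(0, 0.5)$, per-measurement noise
$\varepsilon \sim \mathcal N(0, \sigma_k)$ with $\sigma = (1.0, 0.8)$
log10 units, then zeroes the value with dropout probability
$(0.1, 0.02)$ — platform A is sequencing-like (more dropout, more noise),
platform B array-like. Sample sizes default to 3 cases vs 4 controls,
typical of the treated-vs-untreated designs this analysis is aimed at.
Everything is drawn from a single integer seed and is bit-reproducible.

Pathway memberships in the fixture database are disjoint, which keeps the
expected score of each pathway analytically simple; real pathway
collections overlap heavily, and overlapping membership correlates PAS
values across pathways in ways the fixture deliberately avoids.

### What the defaults do and do not show

Under these defaults the per-gene log ratios correlate weakly between the
platforms while pathway scores correlate several-fold better, in every
seeded replicate tested, and the gap grows with pathway size — the
qualitative phenomenon of interest. The defaults do *not* push the
pathway-level correlation into the very high range one can observe with
real matched datasets. The binding constraint is the interaction of
dropout with the expression floor: a dropped-out case measurement floors
to $\lg\mathrm{CNR} \approx -6$, is always flagged (it sits far outside
any control interval), and injects a platform-specific outlier of
magnitude ~6 into its pathway's sum. At 10% dropout a 30-gene pathway
absorbs ~3 such terms per sample, which caps the cross-platform pathway
correlation around 0.2–0.35 regardless of the other settings. Real
pipelines mitigate this by filtering undetected genes or flooring at a
detection limit rather than a tiny constant; users studying the high
concordance regime should lower `dropout_rate` or raise `floor` toward the
platform's detection limit.

Passing tests on this simulator therefore demonstrate the algebraic
properties (bias cancellation, sign recovery, error averaging) and the
qualitative gene-vs-pathway contrast; they do not certify performance on
any real platform pair, where noise is neither log-normal nor independent
across genes.

## Numerical choices and degenerate inputs

* Flooring happens where division and logs happen: `compute_cnr` floors
  both the case value and the control mean, so CNR is always positive and
  finite; 0/0 becomes floor/floor = 1 (log ratio 0, the neutral value).
* If the control sd of a gene is exactly 0 (constant controls), any
  differing case value is considered beyond tolerance (the interval has
  zero width); an equal case value is not.
* Correlations are undefined (returned as `NA`, propagated as such) when
  either profile has zero variance or fewer than 2 points, rather than
  being forced to a number.
* ARR weights are written with exactly one decimal so that database files
  round-trip byte-identically; expression values are written at full
  precision for the same reason.
* PAS accepts duplicated member rows when validation is explicitly
  disabled, and doubles accordingly — this linearity is asserted in the
  tests, and validation rejects such databases in normal operation.

## Problem sizes in the test suite

The concordance and error-averaging checks run 20 seeded replicates of the
default 90 × 30 configuration plus 20 replicates at each of 5/20/80 genes
per pathway (the whole suite completes in well under a minute); unit tests
use databases of 2–10 pathways where the oracle comparisons are exact. The
acceptance script repeats the 20-replicate analysis from a user-supplied
seed.

## Known limitations

* The tolerance interval is a normal approximation with the *sample* sd of
  as few as 2–4 controls; it is deterministic but crude, and with very few
  controls the flag rate under the null is noticeably above 5%.
* BTIF gating selects large excursions, which under heavy measurement
  noise are mostly noise; the gate therefore does not protect pathway
  scores from noisy platforms (it removes small errors, not large ones).
* No multiple-testing machinery is attached to PAS values; the package
  reports scores, not significance calls.
* Identifier harmonization, background correction, and read counting are
  all upstream of this package.
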