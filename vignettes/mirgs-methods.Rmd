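---
title: "Methods: scoring miRNA impact and testing gene sets by logistic regression"
author: "mirgs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring miRNA impact and testing gene sets by logistic regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirgs)
```

## The problem and the model

A two-group miRNA differential-expression profile says little directly about
biological function: miRNAs act on pathways only through their target mRNAs,
and mostly as inhibitors. The common practice of thresholding the miRNA list,
collecting targets of the "significant" miRNAs and intersecting them with
pathway databases loses directionality and inherits every bias of the
threshold. `mirgs` instead transfers the *whole* DE profile onto genes as a
quantitative score and asks, per gene set, whether that score predicts set
membership.

**miRNA score.** Each miRNA with fold change $FC$ and p-value $p$ receives

$$S_{mirna} = -\log_{10}(p)\cdot \mathrm{sign}(\log_2 FC),$$

so magnitude encodes the strength of evidence and the sign the direction of
change. Using every measured miRNA, unfiltered, is the default: thresholding
is a second analysis choice the result should not depend on, and the
full-list formulation is what makes the downstream test competitive.

**Gene score.** With $w(i,g)\ge 0$ the affinity of interaction $i\to g$
(1 by default — no difference between interactions),

$$S_{mrna}(g) = -\sum_{i\,\in\,\mathrm{upstream}(g)} w(i,g)\, S_{mirna}(i).$$

The sign reversal encodes inhibition: an up-regulated miRNA pushes its
targets' scores negative. Opposite-signed upstream miRNAs accumulate and
cancel. Internally this is one sparse incidence-matrix–vector product
(`build_incidence()`), not a loop; a property test asserts the two are equal
to 1e-12 on random instances.

**Membership regression.** Over a gene universe of size $m$, for one gene
set with membership labels $y_i\in\{0,1\}$,

$$\Pr(y_i = 1 \mid x_i) = h_\theta(x_i) = \frac{1}{1+e^{-(\theta_0+\theta_1 x_i)}},
\qquad x_i = S_{mrna}(g_i),$$

with $\theta$ estimated by maximising the Bernoulli log-likelihood
$\sum_i y_i\log h_\theta(x_i) + (1-y_i)\log(1-h_\theta(x_i))$. The slope is
tested with the Wald statistic $\hat\theta_1/s_{\hat\theta_1}$ and p-values
are Benjamini–Hochberg adjusted across the converged sets. A positive
significant $\hat\theta_1$ reads as relief of miRNA inhibition of that set
under the experimental condition; a negative one as increased inhibition.
Interpretation is bounded: the method sees one regulatory layer (miRNA
abundance), so "relief of inhibition" is not evidence of activation.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `fc_scale` | `"log2"` | Whether the DE table's FC column is a log2 fold change or a linear ratio. Only the *sign* of the log2 value enters the score, so the choice affects results only for ratios below 1. The log2 default matches what current DE tools emit; qPCR-style linear ratios need `fc_scale = "linear"`. |
| `w` | 1 | Per-edge affinity weight, raw multiplier exactly as written above — no per-gene normalisation is applied, so supplying weights changes the scale of $S_{mrna}$ (and hence of $\theta_1$, units: log-odds per unit score). |
| `optimizer` | `"IWLS"` | Fisher scoring, the canonical GLM fitter; `"BFGS"`/`"L-BFGS-B"` maximise the same likelihood with analytic gradients and are exposed because direct optimisation scales differently and supplies an independent numerical route. |
| `df_mode` | `"normal_z"` | Wald reference distribution. The conventional choice for binomial GLMs is the standard normal; `"t_df1"` (a one-degree-of-freedom Student t, i.e. a Cauchy reference) is provided as a deliberately conservative compatibility option. |
| `tol`, `max_iter` | 1e-8, 25 (IWLS) / 200 (optim) | Relative-deviance convergence tolerance and iteration caps, matching common GLM defaults. The quasi-Newton route uses an internal relative tolerance of 1e-10 so that the two routes agree to 1e-4 absolute on coefficients. |
| `p_threshold`, `top_n` | 0.05, 15/50 | Plot-level display thresholds (adjusted p by default on the volcano y-axis, since adjusted significance is what users act on). |

## Numerical choices

- **Stability.** The log-likelihood is evaluated through `log(1+e^x)` with
  branch cutoffs, so linear predictors up to several hundred in magnitude
  neither overflow nor produce `NaN`. Working weights are floored at 1e-10.
- **Exact symmetries.** Negating every fold change must negate every
  $\hat\theta_1$ exactly, and swapping labels $y \leftrightarrow 1-y$ must
  negate both coordinates exactly, with identical p-values. These hold
  *bitwise*, not approximately: the sigmoid is evaluated as a symmetric
  $(\mu, 1-\mu)$ pair from $|\eta|$, the residual as $1-\mu$ or $-\mu$ by
  label, and the 2×2 weighted least-squares system is solved in closed form,
  so IEEE sign-flips cancel exactly.
- **Covariance.** The covariance is the inverse Fisher information
  re-evaluated at the final estimate (not at the second-to-last iterate's
  weights, where a one-step-stale information matrix costs ~1e-5 relative
  accuracy in standard errors).
- **Degeneracy and separation.** Sets with no member in the universe, or
  spanning it entirely, are reported with `converged = FALSE` and `NA`
  p-values — never dropped — and are excluded from the BH family. Complete
  separation is detected post hoc (diverging $|\hat\theta_1| > 10^3$, or an
  essentially perfect fit, log-likelihood above $-10^{-6}$) and flagged the
  same way: a Wald p under separation is meaningless.
- **p = 0 inputs** are clamped to 1e-300 before the log (score capped at
  300) with a warning, keeping the regressor finite without discarding the
  most significant miRNAs.
- **Ties** in ranking for plots are broken by set name, and figure output
  carries no timestamps, so vector output is byte-reproducible.

## Design decisions

- **Universe.** The universe is the union of all gene-set members and all
  genes with a computed score. Genes without any measured upstream miRNA
  enter with score 0 — the empty-sum value of the scoring equation,
  encoding "no measured miRNA effect" — and every set is tested against the
  same full universe (no per-set restriction), which is what makes the test
  competitive rather than self-contained.
- **Identifier space.** One gene-identifier column (Entrez by default) is
  designated per run; joins are exact string matches after whitespace
  trimming. miRNA names compare case-insensitively, because exports often
  capitalise miRBase names.
- **Duplicates.** Duplicated miRNA rows in the DE table are an error by
  default (`dedup = "first"` downgrades to a warning): a silent duplicate
  would double-count that miRNA in every downstream gene score.
- **Local-first mapping.** Interaction data are consumed from local files in
  the multi-database export schema rather than live server queries; ortholog
  conversion likewise uses a local two-column table. This makes every run
  reproducible offline. One-to-many orthologs fan out into multiple edges
  (each target is independently a potential set member); duplicate edges
  from different databases collapse to one, with provenance retained in the
  per-miRNA exports. Prediction databases without rat coverage are dropped
  automatically for `species = "rno"`.
- **FDR family.** Only converged fits enter the BH adjustment; whether
  unfittable sets should count in the family is genuinely ambiguous, and
  excluding them keeps the family's size equal to the number of tests
  actually performed.

## What the simulator emulates — and what it does not

`generate_fixture()` creates a study in which the method's assumptions hold
by construction: a fraction (default 0.3) of miRNAs are truly regulated,
with $-\log_{10} p \sim$ Gamma(shape 2, mean = `effect`) — positive and
heavy-tailed, like real DE p-values — and coherent fold-change signs; each
miRNA targets a Poisson number (mean 20) of a 2000-gene universe; planted
sets draw 60% of their members from the targets of direction-matched
regulated miRNAs, the rest uniformly, so planted signal is diluted rather
than pure; null miRNAs and null sets are fully random. Defaults (100
miRNAs, 50 sets of mean size 50, 5 planted, effect 2) are sized like a
small qPCR-panel study against a KEGG-scale collection, and keep a full
pipeline run under half a second so hundreds of replicate fixtures fit in a
routine test run. One global seed drives per-file substreams, so outputs
are byte-identical across runs and adding a file type does not perturb the
others.

What passing these simulations does **not** show: real interaction
databases are noisy and biased (prediction false positives, study-bias in
validated sets); real gene sets overlap heavily and are far from uniform
random; real miRNA DE p-values are correlated across miRNA families; and
expression is not generated from the inhibition model at all. The
simulator validates the statistical machinery, not the biology of any
particular mapping resource.

## Known limitations

- The Wald z test is mildly conservative in the default study conditions
  (~45 members per ~1800-gene universe): across pooled null fixtures the
  observed type-I rate at nominal 0.05 sits near 0.044, and a
  Kolmogorov–Smirnov uniformity check over 2000 pooled null p-values is
  sensitive enough to sit on either side of a 0.01 rejection depending on
  the replicate stream. This is the finite-sample behaviour of Wald
  statistics in sparse logistic regression (the fitter itself matches the
  reference GLM to ~1e-13), amplified slightly by dependence among sets
  that share one score vector. Discovery-level conclusions at BH 0.05 are,
  if anything, slightly conservative.
- L-BFGS-B in particular can fail to converge on ill-scaled designs; its
  convergence flag is always propagated, and flagged sets carry `NA`
  p-values rather than unreliable ones.
- Scores depend on the completeness of the supplied interaction tables:
  miRNAs absent from the tables contribute to no gene (counted in the run
  log), and mapping coverage differs widely between databases.
- The method evaluates a single regulatory layer. A set can be "released
  from miRNA inhibition" and still be transcriptionally silent.

## Problem sizes used in validation

The shipped validation suite fits ~12,000 logistic regressions: 50 random
designs of 200–5000 observations against the reference GLM (agreement
1e-6 relative), the same 50 across IWLS/BFGS (1e-4), 40 pure-null fixtures
(2000 pooled null sets) for calibration, and 200 planted fixtures (1000
planted sets) for sign-recovery power and empirical FDR. The same
computations, reseeded from the command line, are reproduced by
`scripts/acceptance.R`.
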