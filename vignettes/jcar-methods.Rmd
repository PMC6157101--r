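---
title: "Joint CAR association testing: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint CAR association testing: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jcar)
```

## The model

For a gene carrying $K$ SNPs and $L$ CpG sites, measured on $n$ possibly
related subjects with a continuous phenotype $y_i$ and covariates $x_i$
(intercept, age, sex, ...), the package models

$$y_i = x_i^\top \beta + g_i + m_i + \varepsilon_i,$$

where $g$ is a genetic random effect, $m$ a methylation random effect, and
$\varepsilon \sim N(0, \sigma^2 \mathbf{K})$ with $\mathbf{K}$ the familial
error-correlation matrix (identity for unrelated subjects).  The random
effects are specified *conditionally*, as in a conditional autoregressive
(CAR) / Gaussian Markov random field model: with $s^{(1)}_{ij}$ the genetic
similarity between subjects $i$ and $j$,

$$g_i \mid g_{-i} \sim N\!\left(\frac{\gamma_1}{\sum_{j \ne i} s^{(1)}_{ij}}
  \sum_{j \ne i} s^{(1)}_{ij}\, g_j,\;
  \frac{\sigma_g^2}{\sum_{j \ne i} s^{(1)}_{ij}}\right),$$

and analogously for $m_i$ with the methylation similarities $s^{(2)}_{ij}$
and parameters $\gamma_2, \sigma_m^2$.  Writing $S_l$ for the similarity
matrix with zero diagonal and $D_l$ for the diagonal matrix of its row
sums, Brook's lemma gives the joint law these conditionals imply:

$$g \sim N\!\left(0,\; \sigma_g^2 (D_1 - \gamma_1 S_1)^{-1}\right),
\qquad
m \sim N\!\left(0,\; \sigma_m^2 (D_2 - \gamma_2 S_2)^{-1}\right),$$

which is proper exactly when $D_l - \gamma_l S_l$ is positive definite.
`buildSimilarityPair()` enforces this with tolerance $10^{-8}$ on the
smallest eigenvalue and, on failure, reports the admissible $\gamma$
interval computed from the generalized eigenvalues of $S$ with respect to
$D$.  Since similarities are non-negative, any $\gamma \in (-1, 1)$ makes
the precision strictly diagonally dominant, hence admissible.

Association is assessed by testing $\sigma_g^2 = 0$ (genetic-only),
$\sigma_m^2 = 0$ (methylation-only), or jointly
$\sigma_g^2 = \sigma_m^2 = 0$.

## Kernels and their parameters

* **Genetic layer** — the normalized identity-by-state kernel on additive
  genotype codes,
  $s^{(1)}_{ij} = \sum_k (2 - |g_{ik} - g_{jk}|)/(2K) \in [0, 1]$.
* **Methylation layer** — the Gaussian kernel on beta-value profiles,
  $s^{(2)}_{ij} = \exp\{-\sum_l (m_{il} - m_{jl})^2 / (2\sigma^2)\}$.
  The bandwidth $\sigma$ defaults to the standard deviation of the gene's
  methylation values, pooled over all entries of the matrix with the
  unbiased $N - 1$ denominator (`defaultBandwidth()`).  Pooling per gene,
  rather than genome-wide, keeps each gene's kernel on the scale of its own
  variation; the choice can be overridden per scan (`bandwidth`).
* **Autocorrelations** — $\gamma_1$ is fixed at the average of the entries
  of the SNP-by-SNP Pearson correlation matrix, $\gamma_2$ likewise for
  CpGs (`defaultGamma()`).  The average is taken over *all* entries
  including the unit diagonal, which is the plain reading of "the entries
  of the correlation matrix"; a switch (`includeDiagonal = FALSE`) excludes
  it.  Constant markers have undefined correlations and are dropped from
  the average (but retained in the kernel, where the formulas remain well
  defined); with fewer than two non-constant markers $\gamma$ falls back to
  0 with a warning.  Because these are fixed, not estimated, sensitivity to
  their choice can be explored with the `gamma1`/`gamma2` overrides.

## The score test

The test profiles $\beta$ and $\sigma^2$ out of the restricted likelihood.
Let $r = \operatorname{rank}(X)$ (numerical rank at tolerance
$\max(n,p)\,\epsilon\,d_1$ with $d_1$ the largest singular value), let
$\mathbf{K}^{-1/2}$ be the symmetric inverse square root (by
eigendecomposition), and let $A$ be an $(n-r) \times n$ matrix whose rows
orthonormally span the orthogonal complement of the column space of
$\mathbf{K}^{-1/2} X$, so $A \mathbf{K}^{-1/2} X = 0$ and $A A^\top = I$.
With $y^* = A \mathbf{K}^{-1/2} y$, the layer score statistic is

$$S_l = \frac{n - r}{2}\,
  \frac{y^{*\top} A \mathbf{K}^{-1/2} (D_l - \gamma_l S_l)^{-1}
        \mathbf{K}^{-1/2} A^\top y^*}{y^{*\top} y^*}
  - \frac{1}{2} \operatorname{tr}\!\left(\mathbf{K}^{-1/2}
        (D_l - \gamma_l S_l)^{-1} \mathbf{K}^{-1/2}\right),$$

and the joint statistic is $S = (S_1 + S_2)/2$.  Under the null,
$y^* \sim N(0, \sigma^2 I_{n-r})$ for *any* $\sigma^2$, which is what makes
the following p-value construction exact.

**P-value.**  Write $Q = A\mathbf{K}^{-1/2}[(D_1-\gamma_1 S_1)^{-1} +
(D_2-\gamma_2 S_2)^{-1}]\mathbf{K}^{-1/2}A^\top$ and
$T = \operatorname{tr}(\mathbf{K}^{-1/2}[(D_1-\gamma_1 S_1)^{-1} +
(D_2-\gamma_2 S_2)^{-1}]\mathbf{K}^{-1/2})$ (the full $n \times n$ trace,
consistent with the statistic's definition).  Since
$S_1 + S_2 = \frac{n-r}{2}\,\frac{y^{*\top} Q y^*}{y^{*\top}y^*} -
\frac{T}{2}$, the observed ratio equals $c = (4S + T)/(n - r)$, and with
$B = Q - cI_{n-r}$ the event $\{y^{*\top} B y^* > 0\}$ is exactly
$\{\text{ratio} > \text{observed ratio}\}$.  The p-value is therefore

$$p = \Pr\!\left[z^\top B z > 0\right], \qquad z \sim N(0, I_{n-r}),$$

the scale $\sigma^2$ cancelling at threshold zero.  The observed quadratic
form $y^{*\top} B y^*$ is zero by construction (verified to $10^{-8}$ in
the tests), and because the p-value equals the exact null upper-tail
probability of the ratio statistic, it is *exactly uniform* under the null
— the calibration tests confirm this empirically.  For single-layer tests
the same cancellation with one layer gives $c = (2 S_l + T_l)/(n - r)$.
(The scalar in the joint threshold is written here as $4S = 2(S_1 + S_2)$;
a single layer's $4 S_l$ would not reproduce the observed ratio in the
joint case, so the combined statistic is the coherent reading.  Whether a
single-layer analysis reports $S_l$ or $S_l/2$ is immaterial to the
p-value under this thresholding.)

Eigenvalues of $B$ below $10^{-10}$ of the largest magnitude are dropped as
numerically null directions before the tail computation.

## Tail probabilities of quadratic forms

`daviesTail()` computes $\Pr[\sum_i \lambda_i z_i^2 > q]$ by numerical
inversion of the characteristic function (the Davies/Imhof family):

$$p = \frac12 + \frac{1}{\pi}\int_0^\infty
  \frac{\sin\theta(u)}{u\,\rho(u)}\,du,\qquad
\theta(u) = \tfrac12\textstyle\sum_i \arctan(\lambda_i u) - \tfrac12 q u,
\quad
\rho(u) = \textstyle\prod_i (1 + \lambda_i^2 u^2)^{1/4},$$

evaluated with adaptive quadrature at absolute accuracy $10^{-6}$ by
default.  Two safety nets surround it: `mcTail()` is a seed-controlled
Monte-Carlo oracle used in the tests (agreement within
$0.005 + 3\,\mathrm{SE}$ on random spectra of length up to 50), and
`momentMatchTail()` is the fallback when quadrature fails or misses its
accuracy target — a three-moment chi-square match for same-sign spectra,
and for mixed-sign spectra a gamma approximation of the positive and
negative parts combined by one-dimensional convolution (exact when each
side has a single eigenvalue).  Fallback use is flagged in the result's
diagnostics and in the scan output.

## Kinship

`kinshipCoefficients()` implements the classical recursion over a
topologically sorted pedigree: founders are unrelated and non-inbred
($\phi_{ii} = \tfrac12$), $\phi_{ii} = \tfrac12(1 + \phi_{fm})$, and
$\phi_{ij} = \tfrac12(\phi_{f(i)j} + \phi_{m(i)j})$; unknown single parents
act as unique unnamed founders, inbreeding is handled by the recursion
itself, and cycles are rejected with the offending path.  The error
covariance uses $2\Phi$ by default (`relationship` scaling, unit diagonal
for outbred subjects, so $\sigma^2$ is an outbred singleton's residual
variance); raw $\Phi$ is available via `scaleMode = "kinship"` since the
convention used in any particular prior analysis may differ.

## Preprocessing conventions

* Missing genotypes/beta values are imputed by the *column* (per-SNP,
  per-CpG) mean before kernel computation; phenotype or covariate
  missingness is handled by listwise deletion with a logged count.
* The phenotype is rank-transformed to normal quantiles,
  $\Phi^{-1}((r_i - 0.5)/n)$ with average ranks for ties (a Blom-type
  offset; no variant is canonical and this one is symmetric and centred).
* All internal coordinates are 0-based half-open; VCF positions are
  converted on input, BED intervals pass through unchanged.  A marker
  belongs to a gene iff its position lies in $[\mathrm{start} -
  \mathrm{flank}, \mathrm{end} + \mathrm{flank})$; the default flank of 0
  (gene body only) is a choice, not a fact about gene regulation, and the
  `flank` option widens it.
* The visit-difference design analyses later-minus-earlier differences of
  CpG values and of the phenotype (the difference being quantile
  transformed), restricted to subjects present at both visits.

## The simulator

`simScenario()` encodes the reference study conditions the package is
validated under: 50 nuclear quartets ($n = 200$) by default, a gene with
10 SNPs at MAFs spread over $[0.05, 0.5]$ under Hardy-Weinberg with
offspring genotypes by Mendelian gene dropping, 5 CpG sites with
logit-normal beta values (delta-method parameterization of the target
mean/SD), covariates (intercept, age, sex) with effects $(1, 0.5, 0.5)$,
kinship-correlated errors with $\sigma^2 = 1$, and CAR effects drawn from
the exact joint law $N(0, \sigma^2_\cdot (D - \gamma S)^{-1})$ with
generation autocorrelations $\gamma_1 = \gamma_2 = 0.5$.  Validation runs
use $n = 100$ (unrelated) and $n = 120$ (30 quartets) with 2000 replicates
for calibration, and $n = 200$ with 200 replicates per point of the
$\sigma_g^2 \in \{0, 0.5, 1, 2\}$ power grid.

What the simulator does *not* emulate: linkage disequilibrium between SNPs
(draws are independent per locus), mQTL coupling between genotypes and
methylation, batch or cell-composition structure in beta values, and
case-control designs.  Passing tests therefore demonstrate correctness of
the algorithms and calibration under the model's own assumptions, not
robustness to these real-data features.

## Numerical choices

| Quantity | Choice |
|---|---|
| PD tolerance for $D - \gamma S$ and $\mathbf{K}$ | smallest eigenvalue $> 10^{-8}$ / $10^{-10}$ |
| rank of $X$ | singular values $> \max(n,p)\,\epsilon\, d_1$ |
| basis construction | Householder QR (default) or SVD; results invariant |
| spectrum truncation | $|\lambda| \le 10^{-10} \max|\lambda|$ dropped |
| quadrature accuracy | $10^{-6}$ absolute, with flagged fallback |
| per-replicate seeds | derived deterministically from the scenario seed |

Degenerate inputs are errors, not silent repairs: a subject with no
similarity mass (zero row sum), a constant methylation matrix (zero
bandwidth), a phenotype lying in the covariate span ($y^* = 0$), or an
indefinite kinship matrix all stop with a diagnostic naming the culprit
(an optional jitter flag exists for near-singular kinship).  Per-gene
failures inside a scan are caught and flagged in the output row instead of
aborting the scan.

## Known limitations

* **Genetic-layer contrast.**  With a dense IBS kernel on common variants,
  similarities concentrate near their mean, so $(D_1 - \gamma_1 S_1)^{-1}$
  is close to a multiple of the identity on the residual space: the
  genetic CAR effect then looks nearly like extra residual noise, and its
  marginal variance $\sigma_g^2 / \sum_{j\ne i} s_{ij} \approx
  \sigma_g^2/(0.8\,(n-1))$ shrinks with $n$.  In unrelated samples the
  genetic-only test consequently has little power at moderate
  $\sigma_g^2$; in family samples the Mendelian-sampling contrast in IBS
  that survives kinship whitening restores a modest, measurable response
  (the validation suite quantifies it at $n = 200$).  The methylation
  layer's Gaussian kernel varies much more across pairs and carries
  correspondingly more power.
* $\gamma_1, \gamma_2$ and the bandwidth are fixed, not estimated; the
  test's sensitivity to them is exposed through overrides rather than
  resolved.
* The model adds the two omic layers; interactions between them are out of
  scope.
* Variance components are tested, never estimated; the package provides no
  REML fits or effect-size estimates.
* No multiple-testing correction is applied across genes; the scan summary
  prints a Bonferroni reference threshold only.

## A worked example

```{r example}
sc <- simScenario(nSubjects = 80L, familySizes = rep(4L, 20L), seed = 5L)
d <- simulateDataset(sc)
res <- carAssociationTest(quantileTransform(d$y), d$X,
                          genotypes = d$G, methylation = d$M,
                          kinship = d$kinship)
res
```

The two layer statistics, their combination and the tail probability are
reported together with the diagnostics (`res@diagnostics`): the
autocorrelations used, the residual degrees of freedom, and the p-value
method (`cf-inversion`, or `moment` when the fallback fired).
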