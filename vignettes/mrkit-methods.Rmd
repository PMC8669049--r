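---
title: "Methods: two-sample Mendelian randomization in mrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization in mrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrkit)
```

## The causal model

Mendelian randomization (MR) uses genetic variants as instrumental
variables for a modifiable exposure. For SNP $j$ with exposure effect
$\gamma_j$ and direct (pleiotropic) outcome effect $\alpha_j$, a causal
effect $\beta$ of the exposure on a binary outcome implies, on the
log-odds scale,

$$\Gamma_j = \beta\,\gamma_j + \alpha_j,$$

where $\Gamma_j$ is the SNP-outcome association. A valid instrument
satisfies relevance ($\gamma_j \neq 0$), independence from confounders,
and the exclusion restriction ($\alpha_j = 0$). In the two-sample design
$\hat\gamma_j$ and $\hat\Gamma_j$ come from non-overlapping GWAS, combined
purely at the summary-statistic level; disease effects are log-odds
($\beta = \ln \mathrm{OR}$).

## Instrument processing

**Selection** keeps variants with exposure $p < 5\times10^{-8}$ (strict
inequality). **Clumping** is greedy by ascending p-value against a
pairwise-$r^2$ LD reference with threshold $r^2 \le 0.001$; ties break by
lexicographic variant id, which makes the output invariant to input row
order. Variants absent from the reference are treated as independent and
counted in the audit. **Harmonization** aligns the outcome effect onto the
exposure effect allele: swapped allele pairs negate the outcome beta and
complement the frequency; strand flips are resolved by complementing
before matching; irreconcilable pairs are dropped with a reason, never
kept silently. Palindromic (A/T, C/G) variants are ambiguous: the default
policy infers orientation from allele frequencies on both sides with a
tolerance of 0.08 around 0.5, and drops the variant when either frequency
is missing or uninformative; a strict `drop` policy is also available.
The frequency-inference default is the conservative standard practice;
both policies are exposed because the choice is not neutral when
frequencies are poorly matched across cohorts.

## Estimators

Per-SNP **Wald ratios** are $\hat\beta_j = \hat\Gamma_j/\hat\gamma_j$ with
first-order delta-method SE $|se_{\Gamma_j}/\hat\gamma_j|$ (a second-order
variant adding $\hat\Gamma_j^2 se_{\gamma_j}^2/\hat\gamma_j^4$ sits behind
a flag; the first-order form is the default because it makes IVW exactly
equivalent to the zero-intercept weighted regression below).

**IVW** pools ratios with inverse-variance weights
$w_j = \hat\gamma_j^2/se_{\Gamma_j}^2$; identically, the zero-intercept
regression of $\hat\Gamma$ on $\hat\gamma$ weighted by $1/se_\Gamma^2$.
Both the fixed-effect SE $(\sum w_j)^{-1/2}$ and the multiplicative
random-effects SE (inflated by $\max(1, \sqrt{Q/df})$) are available; the
random-effects flavor is the default since the point estimate is identical
and the SE is never anti-conservative under heterogeneity.

**Median estimators**: the simple median of the ratios and the weighted
median (the ratio at cumulative normalized weight 0.5 with linear
interpolation between bracketing values, each value placed at the midpoint
of its cumulative weight step). SEs come from a parametric bootstrap that
resamples each SNP's betas from their sampling distributions — 1000
replicates by default, seed recorded in the output. The weighted median is
consistent while less than half the total weight comes from invalid
instruments.

**MR-Egger** regresses $\hat\Gamma$ on $\hat\gamma$ with a free intercept
and weights $1/se_\Gamma^2$, after orienting every instrument so
$\hat\gamma_j \ge 0$ (the intercept is only interpretable under a
consistent orientation). The slope is the pleiotropy-adjusted causal
estimate; the intercept estimates average directional pleiotropy.
Coefficient SEs use multiplicative residual scaling $\max(1, \hat\sigma)$
and t intervals with $n-2$ df. All other intervals use the normal
multiplier 1.959964.

**Diagnostics**: Cochran's $Q = \sum_j w_j(\hat\beta_j - \hat\beta_{IVW})^2$
with $df = n-1$ and a $\chi^2$ p-value; $I^2 = \max(0, (Q-df)/Q)\cdot100$,
flagged as unimportant below 40%; and the mean instrument-strength
statistic $F_j = (\hat\gamma_j/se_{\gamma_j})^2$, warning below the
conventional threshold of 10. With instruments selected at
$p < 5\times10^{-8}$, every per-SNP $F$ necessarily exceeds
$\chi^2_{1,\,5\times10^{-8}} \approx 29.7$; reported mean F values far
below that bound in the literature correspond to other, often unstated,
definitions and are not comparable to this one.

## MR-PRESSO

The observed residual sum of squares is
$\mathrm{RSS} = \sum_j w_j(\hat\Gamma_j - \hat\beta_{-j}\hat\gamma_j)^2$
with $\hat\beta_{-j}$ the leave-one-out IVW estimate. The null
distribution is built from 1000 parametric simulations of both betas under
the no-pleiotropy model, applying the identical leave-one-out machinery to
every simulated dataset; p-values use the add-one rule, so the smallest
attainable p is $1/(1+n_{sim})$. Per-SNP outlier p-values compare each
SNP's observed weighted residual with its own simulated distribution,
Bonferroni-adjusted across instruments at $\alpha = 0.05$. The distortion
test compares the raw-vs-corrected IVW shift against removal of equally
many randomly chosen instruments (1000 draws). All three stages are
deterministic given the seed. These contracts are distributional: no
numeric equality with other implementations' p-values is claimed, since
simulation nulls differ by seed policy.

## Multivariable MR

Instruments are pooled as the union of each exposure's
genome-wide-significant variants, clumped jointly (ordered by the best
p-value across exposures), and required to be present and allele-alignable
in every table; effects are expressed on the first exposure's allele
frame. The estimator is weighted least squares of the outcome betas on the
$K$ exposure-beta columns without intercept, weights $1/se_\Gamma^2$,
SEs scaled by $\max(1, Q/(n-K))$ — the same multiplicative-overdispersion
convention as the univariable default, so $K=1$ reproduces univariable IVW
to machine precision. Rank-deficient designs raise a collinearity error
naming the exposures.

## LD-score regression

Single-trait model: $E[\chi^2_j] = a + (n h^2/M)\,\ell_j$. The fit is a
two-step weighted regression — an unweighted pass gives predicted means,
the final pass uses variance-stabilizing weights $1/(2\,\hat{E}[\chi^2_j]^2)$
— with SEs from a delete-one block jackknife over 200 contiguous blocks.
An intercept above 1.3 raises a configurable confounding flag. Cross-trait:
$E[z_{1j} z_{2j}]$ regressed on $\ell_j$ estimates the genetic covariance;
$r_g$ divides by $\sqrt{h^2_1 h^2_2}$, errors loudly if either
heritability estimate is non-positive, and is clamped to $[-1,1]$ with a
warning. The jackknife recomputes the whole pipeline per deleted block, so
the $r_g$ SE propagates all three regressions. This is a deliberately
desk-scale implementation for synthetic and toy inputs; genome-scale
performance and reference LD-score panels are out of scope.

## The synthetic generator

`generate_gwas_pair()` draws, per SNP: allele frequency
$f \sim U(0.05, 0.95)$; $se_{\gamma} = 1/\sqrt{2f(1-f)n_{exp}}$ (and
analogously for the outcome); a true per-SNP $F \sim U(30, 300)$ giving
$\gamma_j = \sqrt{F_j}\,se_{\gamma_j}$, which mimics a
genome-wide-significant instrument panel where selection at
$5\times10^{-8}$ retains most variants; $\hat\gamma_j \sim N(\gamma_j,
se_{\gamma_j}^2)$ and $\hat\Gamma_j \sim N(\beta\gamma_j + \alpha_j,
se_{\Gamma_j}^2)$. Exactly `round(invalid_fraction * n_snps)` instruments
receive direct effects $\alpha_j \sim N(\mu_\alpha, \sigma_\alpha)$; a
confounding multiplier scales outcome $\chi^2$ (z times its square root).
The default scenario — 50 instruments, $\beta = 0.2$, 50,000 samples per
trait — is the reference condition for all recovery tests. Every dataset
ships its latent truth so bias and coverage are computable. In the
robustness scenario the invalid fraction is 0.40 with
$\alpha \sim N(0.1, 0.05)$: direct effects several times the per-pathway
effect $\beta\gamma_j$, a deliberately strong directional-pleiotropy
stress test.

What the generator does **not** emulate: LD between causal variants
(instruments are independent; LD enters only through the block-structured
clumping reference), sample overlap between the two GWAS, allele-frequency
mismatch between cohorts, palindromic strand ambiguity (emitted variants
are non-palindromic and strand-consistent by default; palindromic handling
is exercised by hand-built fixtures), indels and multi-allelic sites, and
case-control liability-scale subtleties (binary traits are simulated
directly on the log-odds scale). Passing recovery tests therefore show
correctness of the estimators under the stated sampling model, not
robustness to every artefact of real GWAS data.

## Problem sizes and numerical choices

The test suite and the acceptance script use: 500 replicates for
recovery/robustness (50 instruments each), 2000 replicates for Cochran's-Q
calibration (30 instruments), 500 MR-PRESSO null runs and 200
planted-outlier runs (20 instruments, 1000 simulations each), and LDSC
fits on 5000-SNP panels with 200 jackknife blocks — sizes chosen so the
whole battery runs in a few minutes on one core while keeping Monte-Carlo
error well inside the acceptance bands. Tie-breaks, tolerances and
degenerate-input behavior are pinned by contract: strict p-threshold
comparison, lexicographic clumping ties, zero-division errors for null
exposure effects, refusal (not silent repair) when MR-PRESSO flags every
instrument, and an error rather than imputation when frequencies or sample
sizes needed by an operation are missing.

## Known limitations

- **MR-Egger dilution.** With $\hat\gamma$ measured with error, Egger
  regression is attenuated by roughly
  $\lambda = \mathrm{var}_w(\gamma) / (\mathrm{var}_w(\gamma) +
  \overline{se^2_\gamma})$. At the reference conditions (per-SNP $F$ in
  30–300) $\lambda \approx 0.95$, so the Egger slope carries a structural
  bias of about $-0.01$ at $\beta = 0.2$ — visible in the recovery battery,
  where the Egger mean sits just outside the 3-Monte-Carlo-SE band that
  IVW and the weighted median satisfy. This is the known no-measurement-
  error (NOME) violation; corrections such as SIMEX are not implemented.
- The IVW weights treat $\hat\gamma_j$ as fixed; at mean $F$ above ~100
  the residual weak-instrument bias is an order of magnitude below the
  Monte-Carlo resolution of the test battery.
- LDSC here is a teaching-grade implementation; intercept SEs on small
  panels are wide, and no partitioned or constrained variants exist.
- The pipeline applies no multiple-testing correction across
  exposure–outcome pairs; reports carry raw p-values only.
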