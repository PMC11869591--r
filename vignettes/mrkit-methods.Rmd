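---
title: "Methods and design choices in mrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in mrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrkit)
```

`mrkit` implements the statistical machinery of a bidirectional, two-step
Mendelian randomization (MR) study linking gut microbial taxa, blood
metabolites and a rare binary disease outcome. This vignette records the
models, the defaults and the design decisions, in the order a study would
use them.

## The causal model and its assumptions

For SNP $j$, let $\gamma_j$ be its true effect on the exposure (a
quantitative trait: taxon abundance or metabolite level, per SD) and
$\Gamma_j$ its true effect on the outcome (log-odds of disease). Under the
instrumental-variable assumptions — the variant affects the exposure, is
independent of confounders, and touches the outcome only through the
exposure — a causal effect $\beta$ implies $\Gamma_j = \beta\,\gamma_j$,
so every valid instrument's Wald ratio
$\hat\Gamma_j/\hat\gamma_j$ estimates $\beta$. Horizontal pleiotropy adds a
direct effect $\alpha_j$: $\Gamma_j = \beta\gamma_j + \alpha_j$. The whole
estimator panel exists to be robust to different assumptions about the
$\alpha_j$: IVW assumes none (or balanced, under the random-effects model),
Egger allows a common mean (its intercept), the weighted median tolerates
up to half the weight being invalid, RAPS absorbs balanced pleiotropy into
an overdispersion variance $\tau^2$, cML-MA searches over *which* subset is
invalid, and MR-PRESSO hunts individual outliers.

## Instrument processing

* **Selection**: $p < 10^{-5}$ for taxa (the permissive threshold
  customary for microbiome GWAS, where genome-wide hits are scarce),
  $p < 5\times10^{-8}$ for metabolites; effect-allele frequency filtered on
  *both* tails (`eaf` and `1 − eaf` above 0.01), since the convention of
  which allele is "effect" varies by source and the intent is a
  minor-allele-frequency floor.
* **Clumping**: greedy by p-value, window ±10,000 kb, $r^2 < 0.001$. A SNP
  pair inside the window on the same chromosome but absent from the LD
  reference is treated as *linked* (dropped); a cross-chromosome pair as
  unlinked. The asymmetry is deliberate: falsely assuming independence
  inflates precision, the reverse only costs instruments.
* **Proxies**: an instrument missing from the outcome GWAS is replaced
  wholesale by its best proxy with $r^2 \ge 0.8$ (exposure and outcome rows
  of the proxy), requiring the proxy in both tables. Substituting only the
  outcome row would need the LD *sign*, which an $r^2$ reference cannot
  supply. Ties break by smaller outcome p-value, then lexicographic SNP id.
* **Harmonization**: swapped allele codings flip the outcome beta and
  complement its frequency; strand flips are recognised via allele
  complements. Palindromic SNPs (A/T, C/G) are dropped when the exposure
  EAF lies in [0.42, 0.58] and otherwise aligned by frequency — the
  conservative two-sample convention.
* **Strength and direction**: per-SNP $F = (\beta/se)^2$, the standard
  single-SNP approximation; sets report mean F. Steiger filtering keeps a
  SNP only if its variance explained $r^2 = t^2/(t^2+n-2)$ is larger for
  the exposure than for the outcome. The same $t$-based approximation is
  used for the binary outcome (no liability-scale correction); with a
  disease GWAS hundreds of times larger than the exposure GWAS this makes
  the filter stringent against reverse causation, which is the safe
  direction.

## Estimator details and numerical choices

* **IVW** defaults to multiplicative random effects, inflating the
  fixed-effect SE by $\max(1, \sqrt{Q/\mathrm{df}})$ — conservative and the
  de-facto default in two-sample MR practice. One instrument reduces
  exactly to the Wald ratio.
* **MR-Egger** first orients instruments so all exposure betas are
  non-negative (flipping outcome betas with them); the intercept is only
  interpretable as average directional pleiotropy under a fixed
  orientation. Orientation uses the *observed* exposure beta; with weak
  instruments occasional mis-orientation of near-zero effects biases the
  intercept slightly toward zero, which is why the intercept-recovery
  validation uses a strong-instrument scenario.
* **Weighted median**: cumulative-weight interpolation at 1/2; SE by
  seeded parametric bootstrap (default 1000 resamples; at least 2 required,
  and 0 is an error rather than a silent `NA`).
* **RAPS** maximizes the profile likelihood of
  $\hat\Gamma_j - b\hat\gamma_j \sim N(0,\; se_{Yj}^2 + b^2 se_{Xj}^2 + \tau^2)$
  over $(b, \tau^2)$ with $\tau^2 \ge 0$ enforced by squaring, BFGS with a
  500-iteration cap, and a sandwich SE from the per-SNP profile scores.
  This is the simple quadratic-loss form; a robust-loss variant is out of
  scope.
* **cML-MA**: for each assumed invalid count $K$ the constrained
  likelihood is maximized by alternating the causal effect, the per-SNP
  nuisance effects, and the selection of the $K$ SNPs with the largest
  residual chi-square; fits are combined with weights
  $\propto \exp(-\mathrm{BIC}_K/2)$, $\mathrm{BIC}_K = 2\,\mathrm{nll}_K + K\log m$,
  and the averaged SE includes the between-model spread.
* **MR-PRESSO**: the observed statistic is the inverse-variance
  standardized leave-one-out residual sum of squares; its null distribution
  comes from parametric simulation (default 1000 draws). Per-SNP outlier
  p-values use the same draws with the add-one estimator, so the smallest
  attainable p is $1/(n_{\mathrm{sim}}+1)$ — with Bonferroni correction
  across $m$ SNPs an outlier call is only *reachable* when
  $n_{\mathrm{sim}} > m/\alpha$, a granularity constraint worth knowing
  when reducing simulation counts. The distortion test compares the
  outlier-removal shift against removals of random same-size subsets.
* **P-values** are two-sided normal everywhere except the chi-square for
  Q and the simulation nulls of PRESSO and the BMA permutations.

## Multivariable MR by Bayesian model averaging

All inputs are standardized by the outcome SE
($\tilde y_j = \hat\Gamma_j / se_{Yj}$, $\tilde X_{jk} = \hat\gamma_{jk}/se_{Yj}$),
matching inverse-variance weighting. For a model $S$ the marginal
likelihood is that of $\tilde y \sim N(0, I + \sigma^2 \tilde X_S \tilde X_S^\top)$
(Gaussian effect slab, variance $\sigma^2$), evaluated via the Cholesky
factor of $\tilde X_S^\top \tilde X_S + I/\sigma^2$; collinear models fall
back to a reduced-rank basis with a warning. The model prior is independent
inclusion, $p^{|S|}(1-p)^{p_{\mathrm{tot}}-|S|}$. Defaults
$p = 0.5$ and $\sigma^2 = 0.5$ with 1000 permutations follow the reported
analysis they reproduce; a prior inclusion probability of 0.5 is permissive
relative to sparser conventions, and users comparing against other MR-BMA
analyses should set it deliberately. Enumeration is exhaustive up to 12
exposures; beyond that a seeded shotgun search (greedy add/remove moves
from random restarts, posterior normalized over all visited models) takes
over, and agrees exactly with enumeration whenever it visits the full
space.

Empirical p-values permute the outcome (beta, SE) pairs across instruments
jointly — preserving the outcome's SE structure under the null — and use
the add-one rank estimator, which never returns 0. One behaviour to know:
because the underlying regression has no intercept, when instrument effects
share a sign for exposure and outcome (as with half-normal effect
conventions), permutation leaves the mean structure intact and the test
becomes conservative. Centred (signed) exposure effects, as arise for
multi-exposure studies, do not have this issue.

## Two-step mediation

With $\beta_1$ (exposure→mediator), $\beta_2$ (mediator→outcome) and
$\beta_3$ (total), the indirect effect is $\beta_1\beta_2$ with Sobel SE
$\sqrt{\beta_2^2 se_1^2 + \beta_1^2 se_2^2}$, and the proportion mediated is
$\beta_1\beta_2/\beta_3$ with a first-order delta SE treating the three
estimates as independent — appropriate for three non-overlapping GWAS
samples. Whether $\beta_3$'s uncertainty belongs in the ratio SE is
genuinely underdetermined in practice; it is included by default and can be
dropped (`include_total_uncertainty = FALSE`), with the choice carried in
the result object. Proportions outside [0, 1] are reported with a warning
flag, never truncated — uncertainty intervals that cross the boundaries are
informative. Second-order delta terms are omitted; the Monte-Carlo
propagation oracle in the tests bounds the first-order error at about 1%
for the effect sizes used.

## Enrichment and LDSC

Over-representation uses the hypergeometric upper tail
$P[X \ge \mathrm{hits}]$ with $N$ = background size, $K$ = pathway members
in the background, $n$ = hit-list size; Expect $= K n / N$ and
Enrichment Ratio $=$ Hits/Expect (displayed at 2 decimals). The default
background is the union of pathway members; raw p-values are compared to
$\alpha = 0.10$ with no multiplicity adjustment, matching the reporting
convention being reproduced. Whether the original web platform used a
Fisher variant or FDR is not recoverable; the hypergeometric tail on raw p
is the documented choice.

LDSC is the textbook regression — $E[z^2] = 1 + (n/m)\,h^2 \ell$ for
heritability, $E[z_1 z_2] = \rho_g \sqrt{h_1^2 h_2^2}\,\sqrt{n_1 n_2}\,\ell/m$
for genetic covariance — with heteroskedasticity weights
$1/(1 + (n/m) h^2 \ell)^2$ updated once from an unweighted fit, and
delete-a-block jackknife SEs (200 blocks, reduced with a warning on small
inputs). The cross-trait regression reuses the geometric mean of the two
single-trait weight vectors, so an identical trait pair returns
$\rho_g = 1$ exactly. No MHC exclusion, annotation partitioning or
reference-panel engineering: LD scores are user-supplied (synthetic in the
tests), because the regression itself — not the panel plumbing — is the
method under study.

## The synthetic-data generator

`scenario_config()` encodes the study conditions the package is validated
under: an exposure GWAS of 7,738 individuals (taxa) with a metabolite-style
option of 8,299, and a case-control outcome GWAS of 314,355 with case
fraction 1472/314355 — a rare cancer on the log-odds scale. Per-SNP
instrument effects are half-normal (scale 0.15 by default), giving every
instrument a defined effect-allele direction like real "effect allele"
conventions and a mean F comfortably above the weak-instrument bound at the
default sample size; this is an implementer's choice of a realistic-looking
regime, *not* an estimate of any real cohort, which publishes no
effect-size distribution. Standard errors follow
$1/\sqrt{n \cdot 2f(1-f)}$ for quantitative traits and the effective-size
analogue $n_{\mathrm{eff}} = n\,c(1-c)$ for the binary outcome, so reported
SEs match the sampling noise injected into the betas by construction. LD is
block-diagonal with constant within-block $r^2$ — enough to exercise
clumping and proxy logic deterministically. One integer seed drives
everything, split into deterministic sub-streams per stage.

What the generator does **not** emulate: individual genotypes, realistic
allele-frequency spectra, LD-induced correlation between the *betas* of
linked SNPs (blocks affect the LD reference only), population
stratification, winner's curse from discovery/replication asymmetry, or
sample overlap between the two GWAS. Passing the validation suite therefore
shows the estimators are correct under their stated models, not that any
particular real-data finding would replicate.

## Validation problem sizes

The acceptance suite and `scripts/acceptance.R` use: 500 replicates of
200-SNP null and effect-recovery studies (IVW size and bias), 150
replicates of 50-SNP nulls for MR-PRESSO at 200 simulations each, 100
replicates for Egger-intercept recovery (strong instruments:
$n_X = 2\times10^5$, effect scale 0.3), 200 mediation triples of 120 SNPs
(CI coverage), 100 replicates of the 4-exposure prioritization scenario
(pairwise correlation 0.6, 50 SNPs), and 100 (tests) / 30 (script) LDSC
replicates at $m = 10{,}000$, $n = 50{,}000$. These sizes keep Monte-Carlo
error well inside each check's tolerance while the whole suite runs in a
few minutes on one CPU.

## Known limitations

Proxy substitution requires the proxy in both GWAS tables; multi-allelic
variants and indels are out of scope; the Steiger filter has no
liability-scale correction; the MR-BMA implementation omits the reference
method's influence diagnostics (Cook's distance, Q contributions); LDSC has
no annotation model; and the pipeline's "consistent with sensitivity
analyses" flag (IVW significant, sign agreement across estimators, Egger
intercept p > 0.05, PRESSO global p > 0.05 or sign-stable after outlier
removal) is one explicit, configurable operationalization of a criterion
that is usually left informal.
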