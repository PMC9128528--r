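---
title: "Methods: two-sample Mendelian randomization in mrpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization in mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

## The model

Two-sample MR works from per-SNP association summaries estimated in
non-overlapping studies. For instrument $j$, the exposure study reports
$\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj}^2)$ (per SD of the exposure) and
the outcome study $\hat\beta_{Yj} \sim N(\theta\gamma_j + \alpha_j,
\sigma_{Yj}^2)$ (log-odds of disease), where $\theta$ is the causal log odds
ratio per SD of exposure and $\alpha_j$ is the direct (pleiotropic) effect of
the variant on the outcome — zero for a valid instrument. Every estimator in
the package is a different way of combining the per-SNP Wald ratios
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ under different assumptions
about the $\alpha_j$:

- **IVW** assumes all $\alpha_j = 0$ and solves the $1/\sigma_{Yj}^2$-weighted
  regression of $\hat\beta_Y$ on $\hat\beta_X$ through the origin. Under the
  multiplicative random-effects model (the default, and the headline
  estimator) the SE is inflated by $\sqrt{\max(1, Q/(k-1))}$, where $Q$ is
  Cochran's heterogeneity statistic of the fit; the fixed-effect variant
  applies no inflation. The `max(1, ·)` floor means the test is slightly
  conservative under homogeneity (its exact size at $k = 30$ is 4.2% rather
  than 5% — see the calibration notes below).
- The **weighted median** is the inverse-variance-weighted 50% percentile of
  the ordered ratios, linearly interpolated; it is consistent when
  instruments carrying at least half the weight are valid. Its SE comes from
  a parametric bootstrap that redraws both association sets from their
  sampling distributions.
- **MR-Egger** adds an intercept to the weighted regression after orienting
  every instrument to a positive exposure effect; the intercept estimates a
  common directional pleiotropy under the InSIDE assumption (instrument
  strength independent of direct effects), and its test is the package's
  directional-pleiotropy diagnostic.
- **cML** maximizes the full bivariate summary likelihood over
  $(\theta, \gamma, \alpha)$ subject to "at most $K$ of the $\alpha_j$ are
  nonzero". Profiling the $\gamma_j$ leaves the one-dimensional objective
  $\sum_{j \in \text{valid}} (\hat\beta_{Yj} - \theta\hat\beta_{Xj})^2 /
  (\sigma_{Yj}^2 + \theta^2\sigma_{Xj}^2)$; the coordinate scheme alternates
  between choosing the $K$ largest standardized residuals as invalid and
  re-estimating $\theta$ on the valid set, with seeded random restarts.
  $\mathrm{BIC}(K) = -2\ell + K\log n_\mathrm{eff}$ selects $K$; model
  averaging weights each $K$ by $e^{-\mathrm{BIC}/2}$ and combines with the
  usual mixture variance. Both the BIC-selected and model-averaged estimates
  are reported, since reference descriptions of the method alternate between
  the two.

Sensitivity analyses: Cochran's Q on the ratio scale; a simulation-based
residual-sum outlier test (leave-one-out predictions, parametric null,
Bonferroni-corrected per-SNP outlier calls, outlier-removed re-estimate and
a distortion test against random-subset removals); leave-one-out IVW; and
funnel/scatter numeric tables.

## Instrument selection and harmonization

The funnel mirrors standard practice for summary-level MR: significance
filter (default $p < 5\times10^{-8}$), greedy clumping retaining the
lowest-p SNP per locus and discarding neighbours with $r^2 \ge 0.001$ within
10 kb (the window and threshold are configurable; ties break on SNP id so
the result is deterministic), proxy substitution at $r^2 > 0.8$ for
instruments absent from the outcome table (the proxy's own exposure record
is required — associations are never transplanted), and exclusion of
instruments showing suggestive ($p < 10^{-5}$) association with the outcome
or any supplied confounder table. Every stage reports counts; kept plus
removed always equals the input.

Harmonization aligns the outcome record to the exposure's effect allele:
identical, swapped (negate, complement the frequency), or
complement-strand reported alleles are resolved mechanically; palindromic
A/T and C/G variants carry no strand information in their alleles, so they
are aligned by allele frequency and only when the minor allele frequency is
below 0.3 in both studies — otherwise dropped as ambiguous, with a
machine-readable reason. Only biallelic SNVs are accepted: strand and
palindrome logic is undefined for indels.

One interaction worth knowing: the outcome-association exclusion is a
deliberately conservative pleiotropy guard, and when instruments are very
strong (founder-population scale, per-SD effects above ~0.14) while the
outcome study is large, a genuine causal effect of OR ≈ 1.24 makes each
instrument's outcome association individually significant at $10^{-5}$ — the
filter then removes truly causal instruments. Deposited instrument tables
from published analyses are post-selection objects and should be fed
directly to the estimators, not re-run through the funnel.

## The synthetic-data generator

`synth_generate()` draws MAFs uniformly on a configurable range, true
exposure effects $\gamma_j \sim N(0, \texttt{gamma\_sd}^2)$, and direct
effects per the pleiotropy model, then observes both studies independently
with $\sigma = 1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n}$ on the
standardized scale; binary outcomes use the effective size
$4/(1/\mathrm{cases}+1/\mathrm{controls})$ — the one deliberate
simplification relative to real case-control GWAS. Defaults emulate the
motivating study design: an exposure GWAS of 563,085 (preset `bcx`; preset
`sardinian` is 3,757 for founder-population immune phenotypes) against a
disease study of 47,429 cases and 68,374 controls (`imsgc`);
`gamma_sd = 0.02` gives instruments of realistic strength for a very large
GWAS of a polygenic trait (per-SNP F mostly 30–300 after selection).
About 15% of variants are palindromic, as in typical SNP panels, and LD is
block-diagonal — adequate for exercising clumping and proxies, but not a
realistic LD map.

Directional pleiotropy assigns each invalid SNP's $\alpha_j$ the sign of its
$\gamma_j$: "directional" is only meaningful relative to the
exposure-increasing allele, since with arbitrary allele coding a
fixed-sign $\alpha$ averages to zero across instruments and biases nothing.
The InSIDE-violating model uses $\alpha_j = c\,\gamma_j + \varepsilon$ with
`alpha_mean` playing the role of $c$.

What passing tests on these data do and do not show: they validate the
estimators, diagnostics and decision logic under exactly the structural
model the methods assume (independent two-sample noise, normal summary
statistics, known truth). They do not probe sample overlap, realistic LD,
allele-frequency mismatch between ancestries, or winner's-curse effects
beyond plain significance selection.

## Numerical choices and defaults

- 95% intervals use the normal quantile 1.959964 throughout; p-values are
  two-sided normal by default (`use_t = TRUE` switches MR-Egger to the
  $t_{k-2}$ dialect used by some implementations).
- Wald-ratio SE is first-order delta method ($\sigma_Y/|\hat\beta_X|$),
  matching the IVW weights, so a single-SNP Wald ratio is the one-SNP limit
  of IVW; a second-order option also propagates the exposure SE.
- Weighted-median bootstrap: 1,000 replicates, fixed documented seed, RNG
  state restored afterwards.
- cML: $n_\mathrm{eff}$ defaults to the smaller of the two study sizes
  carried on the instrument table; $K$ ranges to $k-2$ so two instruments
  always remain valid; 3 random restarts around the IVW start; convergence
  at $10^{-10}$ with non-convergence flagged, never silent; the SE comes
  from the curvature of the profile deviance, evaluated by central
  differences.
- Outlier test: 1,000 simulations by default, outliers at 0.05 Bonferroni
  over $k$; the global p-value is the plain empirical exceedance while
  per-SNP p-values carry a $+1/(n_{sim}+1)$ smoothing so an outlier is never
  called on a bare zero count; all stochastic results are bitwise
  reproducible given (seed, n_sim).
- Clump ties on p break lexicographically by SNP id; missing LD entries
  count as $r^2 = 0$ (conservative for sparse references); window distances
  are inclusive, positions 1-based.
- The decision rule: a trait is *robust* when the headline estimate (IVW
  multiplicative random effects, or the Wald ratio with a single instrument)
  passes the Bonferroni level (0.05 divided by the number of exposures in
  the run) with no contradiction; *suggestive* at nominal 0.05;
  *insufficient* when no instrument survives. A contradiction is any
  sensitivity estimator nominally significant with the opposite sign, or a
  significant Egger intercept — an operationalization of "no contradictory
  results in the sensitivity analyses", which is stated only qualitatively
  in most study designs.
- The MHC exclusion window for the reverse direction defaults to
  chr6:25,000,000–35,000,000 and is configurable.

## Calibration

The package's long-run operating characteristics are measured in the test
suite and the acceptance script on significance-selected instruments (the
only instruments an analysis ever sees; unselected panels contain near-zero
exposure effects whose ratios are ill-behaved). At $k = 30$, $\theta = 0$:
IVW-MRE rejects at ~4.0% (its exact size given the `max(1,·)` floor is
4.19%), MR-Egger ~4.0%, cML-MA ~5.0%, and the outlier test's global p-value
is uniform. The weighted median rejects at ~2.5%: the parametric bootstrap
overstates the sampling SD of an interpolated order statistic by roughly
10% in this regime (measured 0.066 vs a true 0.060), a known conservatism
of this SE construction which the package reproduces deliberately rather
than substituting an ad-hoc correction. Interpret weighted-median p-values
as conservative.

Problem sizes used by the suite: oracle equivalence on 1,000 random
instances; recovery over 500 replicates; robustness ordering over 200;
null calibration over 4,000 replicates with 500-draw bootstraps and
simulation nulls.

## Known limitations

- LD is consumed precomputed; there is no genotype-level LD estimation, no
  liftover, and no strand inference from a reference genome.
- The binary-outcome SE model is the effective-sample-size approximation.
- No multivariable MR, mode-based estimation, or Steiger filtering.
- The power formula is the published approximation behind the common
  web calculator for binary outcomes, and is labelled an approximation.
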