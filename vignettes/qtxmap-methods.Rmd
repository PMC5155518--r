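---
title: "Mixed-model association mapping with epistasis and environment interaction: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{qtxmap methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtxmap)
```

## The model

`qtxmap` maps quantitative trait SNPs (QTS) and quantitative trait
transcripts/proteins/metabolites (QTT/P/M) in homozygous mapping
populations observed across several environments. The phenotype of
individual $k$ in environment $h$ is modelled as

$$
y_{hk} = \mu + e_h
 + \sum_i a_i x_{ik}
 + \sum_{i<j} aa_{ij}\, x_{ik} x_{jk}
 + \sum_i ae_{hi}\, x_{ik}
 + \sum_{i<j} aae_{hij}\, x_{ik} x_{jk}
 + \varepsilon_{hk},
$$

where $x_{ik}$ is the coded predictor of locus $i$ (+1/-1 for the two
homozygote SNP classes, 0 for residual heterozygotes; standardized
abundances in QTT mode), $a_i$ are additive main effects, $aa_{ij}$
additive-by-additive epistatic effects, and $ae_{hi}$, $aae_{hij}$ their
environment interactions. The environment means $e_h$ are fixed effects;
every genetic term is a random effect, grouped into four classes (A, AA,
AE, AAE) with one variance component each, giving the matrix form
$y = Xb + \sum_v U_v e_v + \varepsilon$ with $e_v \sim (0,
\sigma^2_v K_v)$ and $K_v = I$ by default (a user-supplied kinship per
class is accepted).

Treating the genetic terms as random keeps the scan statistics and the
variance decomposition in one framework: heritability of a class is
$\sigma^2_v$ divided by the phenotypic variance $\sum_v \sigma^2_v +
\sigma^2_\varepsilon$.

## Detection: Henderson-III scans and permutation thresholds

Detection proceeds in the classical four steps: a one-dimensional scan of
every locus, a two-dimensional scan of pairs, stepwise assembly of the
candidate model, and estimation on the final model.

Both scans are F-tests built from reductions in sums of squares between
nested designs (Henderson's method III): for a tested block the statistic
is $F = \{[R(\text{full}) - R(\text{reduced})]/(r_f - r_r)\} /
\{[y'y - R(\text{full})]/(n - r_f)\}$, with ranks computed by a
rank-revealing projector (singular values below $d_{\max} \, n\,
\epsilon$ are treated as zero). Because reductions depend only on the
column spaces, the statistic is invariant to reparameterization; the
suite verifies equality with an independent least-squares oracle.

The 1D test for locus $i$ is the *joint* test of its main column and its
$H$ environment-interaction columns against the environment-means model
(a main-only variant is available). The 2D test for pair $(i, j)$ tests
the epistasis block $\{x_i x_j\}$ plus its interactions against a reduced
model that always contains both loci's main and interaction columns, so
the F isolates epistasis whether or not the loci were individually
significant. Both tested and reduced designs decompose into
environment-supported columns, so every F in either scan is assembled
exactly from per-environment cross products — this is what makes the scan
and its permutation null vectorizable over all markers, pairs and
permutations at once on a single CPU. Degenerate units (monomorphic
markers, perfectly correlated pairs whose product column is constant) are
reported as untestable rather than silently dropped.

Experiment-wise significance uses the max-statistic permutation null:
phenotype records are shuffled across individuals *within each
environment* (one shared permutation per replicate for every test in the
scan), the scan is re-run, and the maximum F recorded; the critical value
is the conservative higher quantile — the smallest null maximum whose
exceedance is at most $\alpha$ (the 100th largest of 2000 null maxima at
$\alpha = 0.05$). Defaults are $\alpha = 0.05$ and 2000 permutations,
both configurable. Under the global null the implied experiment-wise
error is $\lfloor\alpha P\rfloor/(P+1) \approx 0.0498$; the suite
measures it inside $[0.03, 0.07]$ over 1000 null genomes.

Stepwise selection starts from the profile peaks (a peak strictly exceeds
its chromosome neighbours; on a tied plateau the lower map position
wins), adds candidates in decreasing F order when their *conditional*
Henderson-III F given the current model still clears the threshold, drops
included terms whose conditional F has fallen below it (worst first), and
alternates to a fixed point. Perfectly collinear duplicates therefore
resolve to a single retained term.

## Estimation: MINQUE(1), AUP, and Gibbs sampling

Variance components of the final model are estimated by MINQUE with all
prior values set to one: with $V_1 = \sum_v U_v K_v U_v' + I$ and $Q =
V_1^{-1} - V_1^{-1} X (X'V_1^{-1}X)^{+} X'V_1^{-1}$, the estimates solve
$\sum_u \mathrm{tr}(Q V_u Q V_v)\hat\sigma^2_u = y'Q V_v Q y$. The
five-class grouping keeps this system $5 \times 5$ regardless of how
many loci were selected. Negative solutions are truncated to zero *after*
solving — the untruncated solutions are retained (`sigma2_raw`) because
they, not the truncated values, carry the estimator's unbiasedness.
Individual effects are predicted by Adjusted Unbiased Prediction: the
class score $U_v'Qy$ is rescaled by $\kappa_v = \sqrt{q_v
\hat\sigma^2_v / \|U_v'Qy\|^2}$ so the sample variance of the predicted
effects reproduces $\hat\sigma^2_v$ exactly (we use $q_v$, not
$q_v - 1$, so single-effect classes are well defined). Standard errors
come from a delete-one-individual jackknife (optionally grouped into
blocks for speed).

The same final model can be estimated by Gibbs sampling of the mixed
model equations: flat priors on fixed effects, scaled inverse-chi-square
priors on each variance ($\nu_0 = 4$, scale centred at the MINQUE(1)
estimate, falling back to $0.1\,\mathrm{var}(y)$), full-conditional
sweeps over $b$, each $e_v$, and the variances, a variance floor of
$10^{-12}\mathrm{var}(y)$ to keep conditionals proper, default chain
length 200{,}000 with thinning 10 and burn-in 20{,}000 (the suite runs
scaled-down chains). Summaries report posterior means, SDs, central 95%
intervals, autocorrelation-based effective sample sizes and Monte-Carlo
SEs.

Two estimator properties are worth knowing. First, AUP's
variance-matching constraint spends part of the class-variance budget on
score noise, so predicted effects carry a small (2–4% at the reference
design) shrinkage-style downward bias relative to planted values — well
inside the replicate-to-replicate SD, and visible only across hundreds of
simulations. Second, the Bayesian posterior mean shrinks a further few
percent relative to AUP; the two agree in sign and to a fraction of the
posterior SD, but not to MCMC precision. Related, with
environment-interaction patterns that sum to zero across environments
(the generative convention below), class-level MINQUE attributes a small
portion of A variance to AE (the A+AE total stays unbiased); users
reading per-class components for constrained interaction patterns should
keep this identifiability wrinkle in mind.

## The simulator and the reference Monte Carlo design

`simulate_ril_genotypes()` draws recombinant-inbred genotypes as
independent per-chromosome Markov chains over the coded homozygotes, with
adjacent-marker recombination at the RIL-expanded Haldane fraction
($r = (1 - e^{-2d/100})/2$; $R = 4r/(1+6r)$ for sib-mated panels such as
BXD, $R = 2r/(1+2r)$ for selfed lines). The default map is BXD-like: 20
chromosomes of 101.88 cM carrying 116 equally spaced markers each (2,320
markers, 2,037.6 cM). `simulate_expression_population()` generates the
continuous (QTT) variant with independent standard-normal predictors.

Effect sizes derive from target heritabilities: $a_i = \pm\sqrt{h^2_i
V_p}$ (coded predictors have unit variance), $aa_{ij} =
\pm\sqrt{h^2_{ij} V_p / \mathrm{Var}(x_i x_j)}$ with the empirical
product variance, and environment-interaction effects drawn once per
configuration to sum to zero across environments with mean square
$h^2_{ae} V_p$ — drawing them once keeps "power for a locus" well
defined across replicates. The residual variance is $V_p(1 -
h^2_{tot})$.

The reference QTS design is 200 genotypes, three environments, total
$h^2 = 20\%$ of $V_p = 100$, five QTSs mid-chromosome on chromosomes
1–5 and three pairs Q1×Q3, Q1×Q4, Q3×Q4. Only four additive shares are
anchored (2.33, 1.77, 3.63, 1.31%); the remainder of the allocation is a
documented reconstruction: Q3 receives 2.00% (it must exceed the 1.31%
locus, which is the smallest by design), each locus 0.20%
locus-by-environment, each pair 2.40% epistatic plus ~0.25%
epistasis-by-environment, summing to exactly 20%. The QTT variant uses
four causal transcripts (2.5, 2.0, 3.0, 1.5%) with 0.25% interaction
each and three pairs at 3.0% plus 1/3% — also exactly 20%.

Two further choices were genuinely open and were fixed by analysis, not
measurement of the acceptance outcome:

* **Replication.** With a single observation per genotype and
  environment ($n = 600$), the noncentrality of the smallest locus
  ($\lambda = n h^2 / \sigma^2_{res} \approx 10$) makes the reference
  power levels analytically unattainable at any genome-wide threshold
  under any allocation of the 20% budget. The source experiment itself
  observed several animals per strain. The default is therefore five
  replicate observations per genotype and environment ($n = 3000$),
  at which the exact noncentral-F operating characteristics place the
  anchored loci at their reported detection levels.
* **Detection window.** Power experiments thin the scanned panel to
  every fifth marker (~470, causal loci kept), as a desk-scale stand-in
  for the full panel. Thinning leaves grid markers correlated ~0.9 with
  the causal locus, so the F peak occasionally lands one grid position
  away — an artifact of thinning, not of the method. The Monte Carlo
  experiments therefore count a detection within one thinned-grid marker
  (QTS mode); the package default for `power_experiment()` remains the
  strict exact-marker match. QTT predictors are independent, so exact
  matching is used there.

What the simulator does *not* emulate: genotyping error and missing
calls, segregation distortion, linked causal loci on a shared
chromosome, non-Gaussian residuals, and expression correlation structure
among transcripts. Passing power and calibration results therefore
demonstrate the statistical machinery under the stated generative
conventions, not robustness to those real-data complications.

## Numerical conventions

Rank tolerance for all projectors is $d_{\max}\, n\, \epsilon$;
per-environment degenerate columns are excluded from ranks and degrees
of freedom rather than regularized. Missing genotype calls default to
marker-mean imputation (`code_genotypes(missing = "keep")` preserves
`NA` for per-test row dropping via the projector route). Continuous
predictors are centred and scaled to unit variance by default so
heritability targets are comparable with the coded-SNP case. Permutation
draws, genotype simulation, phenotype noise and Gibbs chains all consume
seeds derived from a single master seed, and every pipeline output is
byte-identical under a repeated run with the same seed.

## Problem sizes used by the test suite

The packaged experiments run at desk scale: 50 replicates with 200
permutations per threshold for the power studies (the acceptance script
uses 100 replicates), 50 datasets for calibration, 500 simulations for
the unbiasedness harness (at one observation per cell), 1000 null
genomes for the type-I check, and 20,000-cycle Gibbs chains for the
concordance checks. These sizes were chosen so each suite completes in
minutes while keeping Monte-Carlo error small relative to the quantities
asserted.
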