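---
title: "Multivariable cis-MR with correlated variants: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariable cis-MR with correlated variants: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvmrpca)
```

## The problem

A single gene region (for example a pQTL locus or a gene cluster) often
contains many genetic variants associated with several related exposures
— different proteins, transcripts, or cytokines. When those variants are
also associated with a disease outcome, multivariable Mendelian
randomization (MVMR) can in principle disentangle which exposure drives
the association: regress the variant–outcome associations on the
variant–exposure associations and read the coefficients as direct causal
effects. The catch in the *cis* setting is linkage disequilibrium (LD):
the variants are strongly correlated, which creates a Goldilocks dilemma.
Prune aggressively and too few instruments remain to identify K exposures
(identification needs more instruments than exposures); prune leniently
and the working covariance matrix becomes ill-conditioned, so estimates
react violently to small changes in the inputs.

This package implements both horns of that dilemma and the
dimension-reduction escape from it:

* `mv_ivw()` — generalized weighted least squares on summary statistics,
* `mv_liml()` — a limited-information-maximum-likelihood analogue whose
  weight matrix propagates exposure-side uncertainty,
* `mv_ivw_pca()` / `mv_liml_pca()` — the same estimators after replacing
  the correlated variants by a small number of orthogonal principal
  components of a weighted variant covariance matrix,
* `prune_variants()` / `conditional_select()` — the greedy LD-pruning and
  stepwise conditional-selection algorithms the PCA methods are compared
  against,
* `run_replication_study()` — a Monte-Carlo engine that reproduces the
  Type-1-error and power study under which all of the above were
  evaluated.

## Model and estimators

The inputs are per-variant summary associations: a J×K matrix of
exposure associations $\hat\beta_X$ with standard errors, a length-J
vector of outcome associations $\hat\beta_Y$ with standard errors
$se(\hat\beta_{Yj})$, and a J×J variant correlation matrix $\rho$.

**MV-IVW.** The error covariance is
$\Sigma_{j_1 j_2} = se(\hat\beta_{Yj_1})\,se(\hat\beta_{Yj_2})\,\rho_{j_1 j_2}$ and

$$\hat\theta = (\hat\beta_X^T \Sigma^{-1} \hat\beta_X)^{-1}
  \hat\beta_X^T \Sigma^{-1} \hat\beta_Y,
  \qquad se(\hat\theta_k) = \sqrt{[(\hat\beta_X^T \Sigma^{-1}
  \hat\beta_X)^{-1}]_{kk}}.$$

With uncorrelated variants this reduces to weighted linear regression
with weights $se(\hat\beta_{Yj})^{-2}$. The condition number of $\Sigma$
(largest over smallest eigenvalue) is reported with every fit; values
above 100 trigger a warning, values above $10^{12}$ a hard error, since
inverting such a matrix amplifies input noise catastrophically.

**MV-LIML.** With $g(\theta) = \hat\beta_Y - \hat\beta_X\theta$, the
estimator targets $\min_\theta Q(\theta)$ with
$Q(\theta) = g(\theta)^T \Omega(\theta)^{-1} g(\theta)$, an
Anderson–Rubin-type objective in which $\Omega(\theta)$ adds to $\Sigma$
the sampling covariance of $\hat\beta_X \theta$:

$$\Omega_{j_1 j_2}(\theta) = \Sigma_{j_1 j_2} + \sum_{k,l}
  se(\hat\beta_{Xj_1k})\, se(\hat\beta_{Xj_2l})\,
  \rho_{j_1 j_2}\, \Phi_{kl}\, \theta_k \theta_l,$$

where $\Phi$ is the K×K exposure correlation matrix (identity by
default, and identity throughout the simulation study). Standard errors
come from $(\hat\beta_X^T \Omega(\hat\theta)^{-1}\hat\beta_X)^{-1}$.

Two remarks on this weight matrix, both of which shaped the
implementation:

1. *The four-SE variant.* The source derivation prints each summand of
   the double sum with a product of **four** exposure standard errors.
   At realistic magnitudes (exposure SEs of order $10^{-2}$) that term
   is of order $10^{-8}$ against $\Sigma \sim 10^{-4}$, so $\Omega$
   collapses onto $\Sigma$ and "LIML" is bit-for-bit IVW — which
   contradicts the distinct LIML operating characteristics the method is
   known for. We treat the printed form as a typographical artefact: the
   default uses the dimensionally conventional two-SE covariance above,
   and `se_product = "four"` reproduces the printed formula for
   comparison. A unit test pins down the collapse.

2. *The optimizer matters more than it should.* Because $\Omega(\theta)$
   grows quadratically in $\theta$, $Q(\theta)$ approaches a finite
   asymptote as $\|\theta\| \to \infty$. With many weak correlated
   instruments that asymptote can undercut every interior minimum, so a
   determined minimizer escapes to infinity, and even when an interior
   minimum exists the deep minima over-correct the weak-instrument bias.
   We therefore expose two routes. `optimizer = "irgls"` (default)
   solves the first-order condition by iteratively reweighted GLS
   ($\theta \leftarrow$ GLS with $\Omega(\theta)$ held fixed, iterated
   to a fixed point): it is stable for any instrument configuration, and
   its main practical effect relative to IVW is wider, honest standard
   errors. `optimizer = "argmin"` minimizes $Q$ by quasi-Newton descent
   from the IVW estimate with random restarts (perturbation SD twice the
   IVW standard error, objective tolerance $10^{-8}$); with strong
   instruments (e.g. the oracle arm of the simulation) it reproduces the
   classic mildly-debiased LIML behaviour, but with many weak
   instruments its output is heavy-tailed and can be arbitrarily far
   from the identified region. The published comparison tables this
   package reproduces sit *between* the two routes on the pruned arms;
   neither route (nor Nelder–Mead from several starts, nor one-step
   Newton updates — all of which we evaluated) matches the pruned-arm
   LIML Type-1 error exactly, and the acceptance suite documents that
   residual honestly rather than tuning an optimizer to hit it.

**PCA reduction.** The weighted variant covariance is
$\Psi = D\,\rho\,D$ with
$D = \mathrm{diag}\!\left(\sum_k |\hat\beta_{Xjk}| / se(\hat\beta_{Yj})\right)$:
variants with strong exposure associations and precise outcome
associations get large weights, so the leading components concentrate
the information relevant to the MR estimate. The retained count k is the
smallest number of components whose cumulative variance share reaches
`var_threshold` (default 0.99; a share exactly at the threshold is
included, and `var_threshold = 1` keeps the complete basis, making the
transform lossless). The data are projected as
$\tilde\beta_X = W_k^T \hat\beta_X$, $\tilde\beta_Y = W_k^T \hat\beta_Y$,
$\tilde\Sigma = W_k^T \Sigma W_k$ (and $\tilde\Omega = W_k^T \Omega W_k$
for LIML), and the estimators above are applied unchanged. Because the
components are orthogonal, $\tilde\Sigma$ is well-conditioned even when
$\Sigma$ is numerically singular.

*Centering.* Two conventions exist for extracting the components: the
raw eigendecomposition of $\Psi$, and a conventional PCA of the columns
of $\Psi$ (column-centered, unscaled — what `prcomp()` computes). The
centered spectrum decays much faster: in the simulation's main scenario
it retains roughly 30 of 100 components at the 99% threshold where the
raw spectrum retains roughly 50, and the centered variant's operating
characteristics (mean estimates, mean standard errors) match the
published tables while the raw variant is measurably more attenuated.
The PCA estimators therefore default to `center = TRUE`;
`select_components()` keeps the raw eigendecomposition as its own
default so that its eigenvalue bookkeeping matches the direct reading of
the weighting formula, and both conventions are exported and tested.

Two practical defaults follow published usage: variants are pre-pruned
at $|\rho| < 0.95$ before the decomposition (near-duplicates contribute
no information but can poison the numerics; `pre_prune = NULL` disables
this), and an optional exposure-relevance filter (`--relevance-p` in the
CLI) can drop variants not associated with any exposure, off by default
because the simulation study uses all variants.

## Variant selection

`prune_variants()` implements greedy p-value-ranked pruning: repeatedly
select the remaining variant with the smallest minimum exposure
association p-value, then drop every remaining variant with
$|\rho| \ge$ threshold against it. The comparison is inclusive so that
"pruned at $|\rho| < t$" is literally true of the retained set; p-value
ties break on the lower variant index for determinism. Relevance is
defined by the exposure associations only.

`conditional_select()` is the individual-level stepwise analogue of
summary-level conditional-and-joint analysis: step 0 takes the best
marginal variant; each later step regresses every trait on every
remaining candidate plus all previously selected variants (OLS with an
intercept, computed from centered cross-products so cost is independent
of sample size after one Gram matrix) and selects the candidate with the
smallest conditional p-value, stopping when that minimum reaches 0.001.
Candidates whose variance is almost fully explained by the selected set
(residual fraction below 2×10⁻³) are skipped as unidentified, which also
keeps the selected set away from pathological collinearity.

## The synthetic world

`simulate_individual_data()` draws, per replication: a J×J matrix A of
Uniform(−0.3, 1) entries whose product matrix's column correlations form
the variant LD structure B (off-diagonals typically −0.1 to +0.6,
interquartile range ≈ +0.2 to +0.4); n = 20 000 individuals with
variant vector $G_i \sim N_J(0, B)$; effect sizes
$\alpha_j \sim N(0.08, 0.01^2)$ for the 15 causal variants (read as mean
0.08, SD 0.01 — an SD of $\sqrt{0.012}$ would flip effect signs
routinely and contradict the documented instrument strength); three
traits each driven by its own block of five causal variants plus a
standard-normal confounder and noise; and an outcome
$Y = 0.4 X_1 - 0.6 X_3 + U_1 + U_2 + U_3 + \epsilon$. Exposure
associations are estimated on the first 10 000 individuals, outcome
associations on the other 10 000, and LD on the exposure sample — a
clean two-sample design. Under these defaults each causal block explains
≈3.5% of its trait's variance (univariable F ≈ 145, conditional F ≈ 22).

Two readings of the LD recipe were possible; we checked both against the
documented correlation ranges and kept the one that matches (the
`cor()`-of-the-product-matrix reading — see the raw/centered discussion
above for the analogous PCA decision). A consequence worth knowing: B
has rank J−1, so with no pruning the estimated variant correlation
matrix is exactly singular and plain MV-IVW on all 100 variants must
fail. This is why the harness records per-arm failure counts instead of
dying: the prune-at-0.8 arms of the published study are exactly this
regime, and their wild published values (mean SEs of 0.05 beside SDs of
0.4–2.5) are what inverting a numerically singular matrix produces. Our
implementation refuses that inversion (condition-number ceiling
$10^{12}$) and reports the failures.

Scenario variations are registered by name (`scenario_names()`): weaker
instruments ($\alpha$ mean 0.05), stronger correlations (A-matrix bounds
+0.1 to +1), stronger causal effects (+0.8, 0, +1.0 — the sign of the
third effect flips relative to the main setting, kept as documented),
correlated exposures (the next trait's confounder is added cyclically to
each trait; the three strengths use cross-coefficients 0.5 / 1 / 2,
with 1 the documented construction — the source's exact strength
settings live in supplementary material that is not part of this
artifact), LD from an independent reference panel (10 000 or 1000
individuals), and rounding of all betas and SEs to three decimals.

What a green simulation test does *not* establish: the generator uses
continuous Gaussian "variants" (no minor-allele-frequency structure, no
Hardy–Weinberg discreteness), a single LD block with one generating
recipe rather than real haplotype structure, homoscedastic continuous
traits, and no sample overlap or allele-harmonization errors. Results
transfer to real cis-MR data only to the extent those features are
irrelevant to the estimator algebra — which is the claim under test, not
a fact.

## Numerical choices

* All GLS solves go through Cholesky factorizations; explicit inverses
  are never formed. Singular or beyond-ceiling covariances raise errors
  that name the remedy (prune, or use a PCA method).
* Tiny negative eigenvalues of $\Psi$ (floating point; $\Psi$ is PSD in
  exact arithmetic) are clipped at zero for variance shares. Eigenvector
  signs are fixed (largest-magnitude loading positive) for determinism.
* LD matrices must be symmetric within $10^{-8}$ (asymmetry is averaged
  away below that, an error above), have unit diagonal, entries in
  [−1, 1], and smallest eigenvalue ≥ −10⁻⁶; worse violations indicate a
  corrupt matrix rather than estimation noise.
* Univariable regression SEs use the conventional n−2 denominator;
  p-values are two-sided normal throughout (the 95% CI excludes zero iff
  |estimate/SE| > 1.959964).
* The replication harness seeds once and consumes a single RNG stream,
  so a seed fully determines every replication, including the LIML
  restart perturbations; identical seeds give bit-identical summaries.
* Conditional selection skips candidates whose residual variance
  fraction given the selected set is below 2×10⁻³; with n in the
  thousands this is far outside the stochastic range of genuinely
  informative candidates.

## Known limitations

* Allele harmonization is deliberately not performed; inputs must share
  an effect-allele convention. Refusing to guess beats silently flipping
  signs.
* Exposure-side uncertainty enters only through the LIML weight matrix;
  MV-IVW (like its published counterpart) conditions on
  $\hat\beta_X$, so weak instruments bias it — visibly, in the
  simulation, toward attenuated first and third effects.
* The LIML pruned-arm Type-1 error of the published study is not exactly
  reproducible by any principled optimizer we evaluated (see above); the
  package reports both routes and documents the residual rather than
  embedding a bespoke stopping rule.
* No univariable MR methods, no robust/outlier-removal variants, no
  overlap-sample corrections, no genomic-distance clumping, and no
  summary-level conditional analysis (the individual-level stepwise
  procedure stands in for it, as in the original evaluation).
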