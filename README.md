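# mvmrpca

Multivariable *cis*-Mendelian randomization with correlated genetic
variants.

## The problem this package addresses

When a single gene region harbours variants associated with several
related exposures (different proteins, cytokines, transcripts), it is
hard to tell which exposure drives an association between the region and
a disease. Multivariable Mendelian randomization (MVMR) answers this
with summary statistics: regress the variant–outcome associations
$\hat\beta_Y$ on the variant–exposure associations $\hat\beta_X$ and
read the coefficients $\theta$ as direct causal effects. In a *cis*
analysis the instruments are in strong linkage disequilibrium (LD),
which creates a Goldilocks dilemma: prune variants to near-independence
and too few remain to identify the K exposures; keep them all and the
working covariance
$\Sigma_{j_1 j_2} = se(\hat\beta_{Yj_1}) se(\hat\beta_{Yj_2}) \rho_{j_1 j_2}$
becomes ill-conditioned, so estimates flip sign under tiny input
perturbations.

`mvmrpca` implements:

* **MV-IVW** — generalized least squares
  $\hat\theta = (\hat\beta_X^T\Sigma^{-1}\hat\beta_X)^{-1}\hat\beta_X^T\Sigma^{-1}\hat\beta_Y$,
  with condition-number diagnostics (warn > 100, error > 1e12);
* **MV-LIML** — minimizes an Anderson–Rubin-type objective
  $g(\theta)^T\Omega(\theta)^{-1}g(\theta)$ whose weight matrix
  propagates exposure-side uncertainty; two solution routes (stable
  fixed point, direct minimization) are provided and documented;
* **MV-IVW-PCA / MV-LIML-PCA** — the same estimators after replacing the
  J correlated variants with the top principal components of the
  weighted matrix $\Psi = D\rho D$,
  $D = \mathrm{diag}(\sum_k|\hat\beta_{Xjk}|/se(\hat\beta_{Yj}))$,
  retaining components that explain 99% of its variance;
* **instrument selection** — greedy p-value-ranked LD pruning and
  stepwise conditional selection from individual-level data;
* **a simulation engine** — the two-sample data-generating model
  (100 correlated variants, 3 traits with 5 causal variants each,
  effects +0.4 / 0 / −0.6, 10 000 + 10 000 individuals) and a
  replication harness that reproduces the published Type-1-error and
  power study, with named scenario variations (weak instruments, strong
  LD, reference-panel LD, rounded inputs, correlated exposures).

See `vignettes/mvmr-pca-methods.Rmd` for the model, the numerical
choices, and the places where the implementation had to adjudicate
ambiguities in its sources.

## Worked example

A small synthetic two-sample dataset ships with the package
(25 correlated variants, 3 exposure traits, true effects
+0.4 / 0 / −0.6, generated by `scripts/make_fixtures.R`):

```r
library(mvmrpca)
dat <- read_summary_data(system.file("extdata", "synthetic_summary.tsv",
                                     package = "mvmrpca"))
ld  <- read_ld_matrix(system.file("extdata", "synthetic_ld.tsv",
                                  package = "mvmrpca"), dat$variant_ids)
mv_ivw_pca(dat, ld)
#> Multivariable MR estimate (mv-ivw-pca), 9 instrument(s)
#>   trait estimate      se         p     method n_instruments condition_number
#> 1    X1   0.3194 0.07598 2.620e-05 mv-ivw-pca             9            9.173
#> 2    X2  -0.1770 0.14628 2.264e-01 mv-ivw-pca             9            9.173
#> 3    X3  -0.4870 0.08206 2.950e-09 mv-ivw-pca             9            9.173
#> Condition number of working covariance: 9.173
```

Nine orthogonal components stand in for the 25 correlated variants. The
two truly causal traits are recovered with the right signs and
magnitudes (X1: 0.32 ± 0.08 against a truth of +0.4; X3: −0.49 ± 0.08
against −0.6; mild attenuation is expected weak-instrument behaviour),
the null trait X2 is not significant (p = 0.23), and the transformed
covariance is well-conditioned (condition number 9.2). Compare pruning
at |ρ| < 0.4 followed by plain MV-IVW:

```r
keep <- prune_variants(min_pvalue_per_variant(dat), ld, 0.4)
mv_ivw(dat[sort(keep$selected)], ld[sort(keep$selected)])
#> Multivariable MR estimate (mv-ivw), 7 instrument(s)
#>   trait estimate      se         p method n_instruments condition_number
#> 1    X1   0.2932 0.07925 2.159e-04 mv-ivw             7            7.132
#> 2    X2  -0.1403 0.15398 3.623e-01 mv-ivw             7            7.132
#> 3    X3  -0.4500 0.08707 2.363e-07 mv-ivw             7            7.132
#> Condition number of working covariance: 7.132
```

Same qualitative answer here, but from only 7 of 25 variants — on
larger, more correlated regions the pruned fit loses power or becomes
unstable, which is what the simulation study quantifies.

A command-line interface wraps the same functionality
(`fit`, `prune`, `simulate`, `strength` subcommands):

```sh
Rscript -e 'mvmrpca::mvmr_cli()' fit \
  --summary inst/extdata/synthetic_summary.tsv \
  --ld inst/extdata/synthetic_ld.tsv \
  --method mv-ivw-pca --out estimates.tsv
```

Every run writes a `.manifest` sidecar with resolved parameters, seed,
package version and input digests.

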