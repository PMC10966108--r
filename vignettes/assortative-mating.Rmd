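---
title: "Genetic similarity between relatives under assortative mating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic similarity between relatives under assortative mating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amkin)
```

## The model

Assortative mating — the non-random pairing of partners with similar trait
values — induces cross-partner correlations between everything associated
with the trait, including additive genetic factors. `amkin` implements the
path-analytic bookkeeping of those correlations in extended families, a
forward-time simulator that realizes them mechanically, and the estimators
used to detect assortment and date its onset from cohort data.

The equilibrium model is a path diagram in which each individual's
phenotype $P$ is determined by an additive genetic factor $A$ (path $h$)
and a unique environment $E$ (path $e = \sqrt{1 - h^2}$), with partners
linked by a copath of strength $\mu$, the phenotypic correlation
attributable to assortment. Tracing chains gives:

* partners: $\rho_g = \mu h^2$;
* first-degree relatives (parent–offspring and full siblings):
  $r_{g_1} = (1 + \rho_g)/2$;
* $k$-th degree relatives: $r_{g_k} = \left((1+\rho_g)/2\right)^k$,
  because every chain between their genotypes passes sequentially through
  the genotypes of intermediate first-degree relatives;
* affinal (in-law) chains: products of blood segments
  $((1+\rho_g)/2)^k$ and partner copaths $\rho_g$, e.g. a sibling-in-law
  has correlation $r_{g_1}\rho_g$.

A measured polygenic index (PGI) shares only a fraction $s^2$ of its
variance with the true additive factor (the *genetic signal*), so partner
PGI correlations attenuate to $\rho_{pgi} = \mu h^2 s^2$, while
relative PGI correlations are pulled towards the coefficient of
relationship $0.5^k$ rather than towards zero — the measurement error
itself runs in families. Substituting $\rho_{pgi}$ into the $k$-th degree
formula is an approximation from below: the true PGI correlation between
distant relatives can be slightly higher when the signal is weak. Package
tests assert both facts separately.

```{r}
expectations <- equilibrium_expectations(trait_params(mu = 0.5, h2 = 0.5))
expectations$r_g_by_degree
```

Under unit phenotypic variance at equilibrium, Mendelian segregation must
regenerate exactly the variance that assortment-induced linkage
disequilibrium removes between families, giving the segregation variance
$V_K = (1 - \mu h^2)/2$ (`recombination_variance()`). The simulator does
not assume this value; it emerges from finite-locus segregation, which is
one of the cross-checks in the test suite.

## Disequilibrium: the approach to equilibrium

When assortment of constant strength $\mu$ begins in a random-mating
population, additive variance and familial correlations rise over
generations towards an equilibrium. `disequilibrium_trajectory()` iterates
the infinitesimal-model recursion, in units of the baseline genic
variance ($v_a(0) = 1$, segregation variance fixed at $1/2$,
environmental variance fixed at $v_e = (1-h^2_0)/h^2_0$):

$$v_a(t+1) = \tfrac12 v_a(t)\,(1 + \rho_t) + \tfrac12, \qquad
  \rho_t = \mu\,\frac{v_a(t)}{v_a(t) + v_e}.$$

The fixed point solves a quadratic
(`equilibrium_additive_variance()`). Two consequences matter for
inference:

1. **Q**: offspring-generation variance exceeds parental variance during
   disequilibrium, so the intergenerational variance ratio is above 1.
2. **U**: the parent–offspring correlation is depressed relative to the
   equilibrium prediction $(1+\rho)/2$ because the offspring generation is
   more variable. The statistic
   $U = (2 r_{po} - 1)/\rho$ measures the observed increase as a share of
   the increase expected at equilibrium.

```{r}
mu <- 0.14 / 0.5 # baseline rho_0 = 0.14 with h2 = 0.5
c(one_generation = expected_u_after_generations(mu, 0.5, 1),
  three_generations = expected_u_after_generations(mu, 0.5, 3),
  equilibrium = expected_u_after_generations(mu, 0.5, Inf))
```

Generation counting is explicit because it is easy to get wrong: "$g$
assorting generations" means generations $0,\dots,g-1$ mate assortatively
and U is evaluated on the $(g-1, g)$ parent–offspring pair. The
denominator of U uses the *parental generation's* partner correlation —
what is observable in data — not the eventual equilibrium value.

Heritability is not constant along the trajectory: $v_a$ grows while
$v_e$ stays fixed. A trait described as "$h^2 = 50\%$ under assortment at
equilibrium" must therefore *start* below 50%;
`founder_h2_for_equilibrium(mu, h2_eq)` performs that calibration
(e.g. $3/7$ for $\mu = 0.5$, $h^2_{eq} = 0.5$). Simulation studies in
this package state their heritability at equilibrium and calibrate
founders accordingly.

## The simulator

`run_cohort()` simulates a closed, monogamous, discrete-generation
population: biallelic causal loci in linkage equilibrium at founding,
normally distributed effect sizes scaled to unit additive variance,
phenotypic assortment by Gaussian-copula rank matching (latent bivariate
normal pairs with correlation $\mu$, each margin matched rank-for-rank to
the observed phenotypes), and per-locus Mendelian segregation. Defaults
(4,000 individuals/generation, 1,000 loci, 2 offspring per couple,
balanced sexes) are sized for statistical power at desk scale.

Design choices worth knowing:

* **Finite loci, not Gaussian transmission.** Segregation variance and
  assortment-induced linkage disequilibrium arise mechanically, so the
  simulator validates rather than assumes the theory — including the
  inflation of the realized genetic signal $s^2$ above the PGI locus
  subset's naive variance share under assortment.
* **PGI construction by causal-locus subsetting** (`pgi_fraction`), not by
  adding noise, precisely so that inter-locus correlations can inflate the
  realized signal.
* **PGI scaling.** PGIs are centered and scaled by *founder-generation*
  moments. Within-generation standardization would mechanically force the
  intergenerational variance ratio to 1 and blind the equilibrium test;
  founder-moment scaling leaves all within-generation correlations
  untouched and preserves variance ratios.
* **Vertical transmission** (`vertical_gamma`) adds
  $\gamma (P_{mother} + P_{father})$ to each child's phenotype, creating
  gene–environment correlation. This leaves first-degree expectations
  anchored at the observed partner correlation but pushes third- and
  fourth-degree correlations above the $k$-th degree overlay — the
  signature the package's tests reproduce; `sib_env` adds a shared sibling
  environment.
* **Pairing is unconstrained**, so in small populations relatives can
  occasionally pair; at the population sizes used in tests the resulting
  inbreeding is negligible.

`emit_cohort()` writes the pedigree and PGI tables as TSV (missing
parents coded 0, the PLINK `.fam` convention), attaches a couple- and
family-structured nuisance covariate (a stand-in for ancestry principal
components or batch) that can be made to contaminate the PGI
(`confound`), and masks PGI values by nuclear-family missingness patterns
(complete trios, partners only, single-parent–child).

## Kinship and dyad enumeration

Relatedness in simulated cohorts is known from the pedigree, so
`kinship_coefficient()` implements the classic recursion
($\varphi_{ij} = \tfrac12[\varphi_{i,f_j} + \varphi_{i,m_j}]$, descending
on the later generation) rather than genotype-based inference; it is
cross-checked in the tests against an independent common-ancestor
path-counting oracle on exhaustively enumerated small pedigrees.
`classify_dyad()` applies the standard powers-of-two inference ranges
(first degree (0.1770, 0.3540], second (0.0884, 0.1770], third
(0.0442, 0.0884]). `enumerate_dyads()` lists partner, blood (degrees
1–5) and named in-law dyads structurally, each unordered pair once.

## Dyadic correlations

`dyad_correlation()` computes Pearson correlations over dyads with
Fisher-z confidence intervals. Symmetric dyads are entered once in
randomized member order; double entry would shrink the intervals
artifactually. Individuals appearing in multiple dyads make dyads
non-independent; the intervals ignore this, matching standard practice
for these analyses, and the randomized ordering is governed by the
caller's RNG state so runs are reproducible under `set.seed()`.
`expectation_overlay()` anchors the random-mating ($0.5^k$) and
equilibrium ($((1+r)/2)^k$, chain products for in-laws) expectations at
the *observed* partner correlation, which makes the overlay valid whether
the values are genotypic or PGI-based.

## The trio equilibrium test

`fiml_fit()` models one mother–father–offspring triple per nuclear family
(`assemble_trios()` samples one offspring per couple) as multivariate
normal with role-specific means and the transmission-structured
covariance

$$\Sigma = \begin{pmatrix} v_p & c & d \\ c & v_p & d \\ d & d & v_o
\end{pmatrix}, \qquad d = \tfrac{v_p + c}{2}, \quad v_o = d + v_{kf},$$

where $d$ is *structural* (the parent–offspring covariance implied by
Mendelian transmission plus the assorted co-parent) and $v_{kf} > 0$ is
the free residual transmission variance. Every observed-data pattern with
at least two members contributes its own multivariate-normal
log-likelihood (full-information maximum likelihood), evaluated from
per-pattern sufficient statistics. The equilibrium hypothesis "equal
variance across generations" is the single constraint
$v_{kf} = (v_p - c)/2$, i.e. $v_o = v_p$, tested by a 1-df likelihood
ratio (`lrt_equilibrium()`).

Derived targets are $Q = v_o / v_p$ and
$U = (2 d / \sqrt{v_p v_o} - 1)/(c / v_p)$, both computed from the
model-implied moments so that their profile-likelihood intervals
(`profile_ci()`; endpoints where the profile drops by
$\chi^2_{1,0.95}/2 = 1.9207$, found by bisection with warm starts) are
coherent with the point estimates. Numerical choices: optimization by
`nlminb` on $(\log v_p, \operatorname{atanh}(c/v_p), \log v_{kf})$, which
keeps the implied covariance positive definite without explicit barriers;
convergence at relative log-likelihood change $10^{-12}$; a constrained
log-likelihood exceeding the free one beyond tolerance is treated as an
optimizer failure, never silently clipped. The constrained model
constrains variances only, not means; means are free per role.

An observed $Q_{pgi}$ understates the true genetic variance ratio by the
genetic signal: `true_variance_ratio(q_pgi, s2)` scales the excess by
$1/s^2$ (a 2.46% PGI excess with $s^2 = 1/3$ implies roughly a 7.4% true
excess).

## Dating the onset of assortment

`infer_generations()` inverts the deterministic U trajectory: for each
heritability on a grid, $\mu$ is set so the baseline genotypic partner
correlation matches the observed partner PGI correlation, U is computed
for $g = 1, 2, \dots$ and the estimate is interpolated at
$U(g) = \hat u$. U is deliberately insensitive to the assumed
heritability, which the sensitivity grid documents. $\hat u \ge 1$ is
reported as "at or beyond equilibrium"; values below the one-generation
value interpolate towards $U(0) = 0$ (no assortment yet, no increase), so
sampling noise around the first-generation value still maps to a history
near one generation.

```{r}
infer_generations(0.90, partner_pgi_r = 0.14)
```

## What the synthetic cohorts do and do not show

The simulator emulates the features of a real pregnancy-cohort release
that this pipeline consumes: multigenerational pedigrees with partner,
parent–offspring, sibling, avuncular, grandparent, cousin and in-law
dyads; standardized PGIs whose partner correlation equals
$\mu h^2 s^2$; nuisance covariates that residualization must remove; and
realistic trio missingness mixes. It does **not** emulate sequence-level
genetics (no chromosomes, recombination maps or mutation), selection,
overlapping generations, divorce or remarriage, population stratification,
participation bias, or multidimensional assortment. Passing tests
therefore demonstrate the internal consistency of theory, simulator and
estimators — not that any particular real trait satisfies the model's
assumptions.

## Problem sizes and runtime

The validation studies are sized to run comfortably on one CPU: the
simulator-versus-theory study uses 20,000 individuals per generation,
1,000 loci and 12 generations (roughly half a minute); the null
calibration of the equilibrium test uses 200 replicates of 5,000 trios;
the disequilibrium power check uses 35,000 trios with a cohort-like
missingness mix; pipeline-level pattern checks use 6,000–8,000
individuals per generation over 10–11 generations. Monte-Carlo
tolerances in tests are stated as multiples of the correlation standard
error $(1 - r^2)/\sqrt{n}$.

## Known limitations

* The disequilibrium recursion assumes the infinitesimal model with
  constant $\mu$; time-varying assortment lengthens the implied history.
* Closed-form expectations for dominance and shared environment are not
  implemented; the simulator offers mechanism-level options
  (`vertical_gamma`, `sib_env`) instead.
* Dyad-level confidence intervals ignore the reuse of individuals across
  dyads.
* Inbred pedigrees are handled by the kinship recursion but monogamous
  simulated cohorts essentially never produce them, and dyad
  classification tests exclude them.
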