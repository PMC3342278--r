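---
title: "Methods: censored species sensitivity distributions for salinity tolerance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: censored species sensitivity distributions for salinity tolerance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltssd)
```

## The problem

Rising salinity is one of the main anthropogenic pressures on rivers. A
standard way to quantify the risk it poses to a macroinvertebrate community is
the species sensitivity distribution (SSD): the cumulative distribution of
per-species tolerance values, here acute 72-h LC50s expressed as electrical
conductivity in mS/cm. From the SSD one reads off hazardous concentrations —
HCp, the conductivity at which p% of species have their tolerance exceeded —
and, conversely, the potentially affected fraction (PAF) at a given salinity.

Rapid toxicity tests expose animals to a finite ladder of salt concentrations,
so an LC50 is rarely observed exactly: it is either *interval-censored*
(bracketed between two tested concentrations, "35–40 mS/cm") or
*right-censored* (the species tolerated the highest concentration tested,
">30 mS/cm"). Ignoring this censoring biases every summary of the SSD. This
package provides two complementary treatments:

1. **Nonparametric**: Kaplan-Meier (product-limit) SSDs with restricted
   means, medians and HCp percentiles, and weighted log-rank tests for
   comparing them. Interval records are imputed to their mid-point (the
   mid-point rule) so that only right-censoring has to be handled
   nonparametrically.
2. **Parametric, hierarchical, Bayesian**: a censored-data likelihood that
   uses interval and right censoring exactly (no mid-point rule), pools
   species into quasi-taxonomic groups, and reweights the groups by regional
   species richness so the resulting SSD describes the *regional assemblage*
   rather than the species that happened to be tested.

## Data model

A record is one species' 72-h LC50: taxon, region, order or class, one of
seven quasi-taxonomic groups, a censoring triple (`point`, `interval` with
`lo < hi`, or `right` with `hi = Inf`), and an optional abundance class. The
seven groups — Coleoptera & Odonata, Crustaceans, Diptera & Hemiptera,
Ephemeroptera, Hydracarina, Non-arthropods, Trichoptera & Plecoptera — pool
orders whose members have broadly similar salinity tolerance, keeping group
sample sizes workable. The order-to-group lookup is fixed and bundled;
Lepidoptera and Megaloptera, each represented by a single tested species in
the motivating datasets and never pooled, are deliberately left unmapped and
drop out of group-level analyses rather than being forced into a group.

All analyses run in mS/cm; tables recorded in µS/cm (conductivity at 25 °C)
are divided by exactly 1000 at load time and the unit is tracked per table so
the conversion cannot be applied twice. Decimal commas are tolerated on
input. When regional datasets are pooled, a taxon tested in several places
contributes one value: the narrower censoring wins (point over interval over
right-censored bound), ties going to the smaller midpoint.

## The Kaplan-Meier SSD

With right-censored tolerances the empirical CDF is biased downward at high
conductivities, so the SSD is estimated on the survivor scale by the
product-limit estimator; at tied values events precede censorings, the
standard convention. Greenwood's formula supplies pointwise variances.

Three numerical choices deserve note:

* **Restricted mean.** The mean tolerance is the area under the survivor
  curve truncated at the largest observed or censoring value, whether or not
  that value is censored. This matches common statistical-package behaviour
  and yields finite means even under ~50% right-censoring; when *every*
  record is censored the "mean" equals the largest bound and is flagged as a
  lower bound only. Its confidence interval is a normal approximation on the
  restricted-mean scale at a fixed 95% level, chosen so that "non-overlapping
  95% CIs" can serve as the between-group significance rule summarised by
  letter codes.
* **HCp on a step function.** The percentile p/100 may be attained exactly
  (reported as a value), fall below the first step (reported as "&lt;min"),
  fall inside a jump (reported as the bracketing interval "a–b"), or never be
  reached under heavy censoring (reported as "&gt;max"). The point `estimate`
  is always the smallest support value whose CDF reaches p/100.
* **Median CIs** invert the pointwise survivor confidence band (the
  `quantile.survfit` construction). The exact CI method behind published
  KM-median intervals is rarely stated; this choice is recorded in the output
  so downstream users know what they are looking at.

The product-limit fit itself is delegated to the survival package; the
package's own tests verify it against an independent step-area oracle and,
on uncensored data, against the empirical CDF, mean and order statistics.

## Comparing SSDs

`logrank_test()` implements the weighted k-sample log-rank family directly:
at each distinct event value the observed-minus-expected event counts per
sample are accumulated with weight 1 (Mantel-Cox), the number at risk
(Breslow / generalised Wilcoxon, sensitive to differences among sensitive
species) or its square root (Tarone-Ware), and the quadratic form is referred
to chi-square with k−1 degrees of freedom. The at-risk-count weights are not
the G-rho family offered by `survival::survdiff`, which is why the statistic
is computed in-package; survdiff serves as an independent cross-check for the
Mantel-Cox case in the test suite, alongside an exhaustive permutation null
on a small sample. No multiplicity correction is applied to pairwise tests.

`anova_sqrt()` compares non-censored values (interval mid-points included,
right-censored records excluded — they carry no usable magnitude) across one
or two factors after a square-root transform, which stabilises the variance
of concentration data. Factor levels with fewer than two usable values are
dropped with a warning. For unbalanced layouts Type II sums of squares are
used: the design was genuinely open here, and Type II is the standard choice
when interest centres on main effects; the choice is recorded in the output
metadata.

## The hierarchical Bayesian model

On the log10 scale each quasi-taxonomic group g has mean tolerance $\mu_g$
and all groups share one within-group variance $\sigma^2$ (the analyses that
motivated the grouping found broadly similar within-group spread). The group
means are exchangeable a priori:

$$y_{is} \sim N(\mu_{g(i)}, \sigma^2), \qquad \mu_g \sim N(\mu_\text{hyper}, \tau^2_\text{hyper}).$$

Censoring enters the likelihood exactly: an interval record contributes the
normal probability of its bracket, a right-censored record the upper tail
beyond its bound. Priors are deliberately vague: Inverse-Gamma(0.001, 0.001)
on $\sigma^2$, N(0, 10^6) on $\mu_\text{hyper}$, and Uniform(0, 10) on the
hyper SD $\tau$ — a bounded uniform on the SD scale being better behaved for
hierarchical scale parameters than a vague inverse-gamma on the variance. An
Inverse-Gamma(0.001, 0.001) prior on $\tau^2$ is available as a sensitivity
alternative, and the test suite checks that the weighted HC5 is stable across
the two prior families. No expert-elicited informative priors are used.

### Sampling

The sampler is written in the package rather than delegated to an external
MCMC engine: the censored hierarchical likelihood is the scientific core
here, and an in-package Gibbs sampler can be validated directly against
conjugate closed forms (the test suite fixes $\sigma$ and $\tau$ and checks
the posterior of $\mu_g$ against the normal-normal posterior). The updates:

* latent log10 LC50s of censored records: truncated normal draws via the
  inverse-CDF method, clamped away from the numerical tails;
* $\mu_g$, $\mu_\text{hyper}$, $\sigma^2$: conjugate draws;
* $\tau$: stepping-out slice sampling on (0, 10) under the uniform prior
  (conjugate inverse-gamma draw under the alternative prior).

Groups requested but absent from the data — e.g. present in the richness
weights — receive $\mu_g$ draws from the hyper-population; exchangeability
makes them predictive, which is exactly what reweighting an untested group
requires.

Defaults are 4 chains × 20,000 iterations with the first 10,000 discarded;
chains start at mid-point-imputed group means, the pooled variance, the grand
mean and $\tau = 1$, with later chains jittered so that the split-$\hat R$
diagnostic sees overdispersed starts. A seed is required; chain c uses
seed + c − 1. Summaries refuse to run when any split-$\hat R$ exceeds 1.05
unless forced. Groups whose records are all right-censored have weakly
identified, heavy-tailed posteriors that mix slowly under data augmentation;
when the gate fails the remedy is simply a longer run.

### The ecologically weighted SSD

Given richness weights $w_g$ (fractions of regional species richness per
group, normalised to one), each posterior draw defines an assemblage SSD

$$\text{PAF}(x) = \sum_g w_g \, \Phi\!\left(\frac{\log_{10} x - \mu_g}{\sigma}\right),$$

and HCp solves PAF(x) = p/100, found by bisection on the log10 axis to
1e-10. Draws are summarised by their median and central 95% credible
interval; per-draw HCp is strictly increasing in p, and the bisection is
tested against a dense-grid inversion. Because the published richness
percentages behind the original regional weights are not available as
numbers, weights are always a user input here; `default_france_weights()` is
a clearly labelled synthetic stand-in (see below).

## Representativeness of the tested sample

If q% of a region's species belong to an order, a representative testing
programme would draw about q% of its tested species from that order.
`representativeness_fit()` aligns per-order regional and tested counts
(case-insensitive exact matching; unmatched orders count zero), converts to
percentages, and reports the Pearson correlation (p from the t transform on
n−2 df, the conventional test when no method is stated), the least-squares
line, and residuals from the identity line y = x. Because proportionality is
scale-free the correlation is identical on counts or percentages while the
slope is not; both slopes are reported. Orders can be excluded and the
percentages renormalised — useful when one dominant order (true flies in
wet-temperate Europe) is grossly under-tested and drags the fit.

## The synthetic assemblage generator

`generate_assemblage()` draws data with exactly the structure the
hierarchical model assumes — group means from $N(\mu_\text{hyper}, \tau^2)$,
species multinomially assigned by richness weight, latent log10 LC50s from
$N(\mu_g, \sigma^2)$ — and then censors them the way a rapid test design
does: each latent value is reported as the ladder interval containing it, or
right-censored at the top rung. Defaults are the package's fixed study
conditions:

| parameter | default | why |
|---|---|---|
| `mu_hyper` | 1.26 log10 mS/cm (≈18 mS/cm) | posterior hyper-mean of a wet-temperate European assemblage |
| `tau` | √0.0868 ≈ 0.29 | matching posterior hyper-variance |
| `sigma` | √0.0517 ≈ 0.23 | matching posterior within-group variance |
| `n_species` | 92 | a realistic regional testing campaign |
| `ladder` | 2.5, 5, 10, 15, 20, 27.5, 35, 45, 55 mS/cm | spans the observed LC50 range (≈2–78 mS/cm) of river macroinvertebrates |
| `weights` | `default_france_weights()` | synthetic wet-temperate richness: Diptera & Hemiptera–dominated (~55%), non-arthropods 6% |

Latent values below the bottom rung (about 1% of species under the defaults)
are emitted as the interval (0.1, min ladder) mS/cm, 0.1 mS/cm being typical
dilute-freshwater background conductivity; the data model has no left-censor
kind and a positive lower bound is required. Records are emitted as intervals
rather than mid-points deliberately, so the Kaplan-Meier path (which imputes)
and the Bayesian path (which does not) are both exercised.

What the generator does *not* emulate: taxonomic misassignment, between-test
temperature differences, non-normal within-group tails, correlation between
abundance and tolerance, or any time-course of mortality. Passing recovery
tests therefore show that the estimation machinery is sound under the model's
own assumptions — not that real assemblages satisfy those assumptions.

`recovery_experiment()` wraps the loop generate → fit → score: per-parameter
posterior-mean bias and empirical coverage of the 95% credible interval with
a binomial confidence band, excluding (and counting) replicates that fail the
split-$\hat R$ gate. The packaged acceptance checks run 100 replicates at 200
species with 2 chains × 1,500 iterations per fit — sizes chosen to give
stable coverage estimates at desk-scale runtime — and require hyper-mean
coverage inside [89%, 99%].

## Known limitations

* The Kaplan-Meier path relies on the mid-point rule for interval records by
  design; a Turnbull-type interval-censored NPMLE is deliberately out of
  scope because the nonparametric analyses it would feed are defined on
  mid-point-imputed data.
* Between-region comparisons treat each species' LC50 as one independent
  observation; phylogenetic non-independence within groups is ignored beyond
  the grouping itself.
* The hierarchical model assumes a single shared within-group variance and
  log10-normal group SSDs; groups with all-censored records are only weakly
  identified and inherit most of their posterior from the hyper-population.
* Richness weights are taken as known constants; uncertainty in regional
  richness estimates is not propagated.
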