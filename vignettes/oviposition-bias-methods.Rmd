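---
title: "Models and methods for sex-biased oviposition analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for sex-biased oviposition analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovibias)
```

## The scientific question

In gynodioecious plants, female (male-sterile) and hermaphrodite individuals
coexist, and the stability of that breeding system hinges on small
differences in seed fitness between the sexes. Nursery pollinators — moths
that pollinate flowers but lay eggs whose larvae eat developing fruits —
can shift those differences if their oviposition is sex-biased. `ovibias`
implements the statistical workflow for asking, with field survey data of a
two-sex host plant:

1. Do eggs (or damage) fall on one sex more often than expected from the
   sex ratio of the sampled units?
2. Which plant and floral traits predict oviposition, and does sexual
   dimorphism in those traits explain any observed sex bias?
3. What does receiving an egg cost the plant, in fruits lost to predation,
   total fruit production, and seed set of the egg-receiving flower?

The package couples each analysis to a synthetic-data generator that
emulates the three field designs (multi-population stem transects,
single-population whole-plant monitoring, age-matched flower pairs), so the
whole pipeline is testable end to end without field data.

## The proportional null and the test battery

Every sex-bias test shares one null hypothesis: units receive eggs or
damage *in proportion to the sex ratio of the sample*. With $n_F$ female
and $n_H$ hermaphrodite units and $E$ eggs, females are expected to hold
$E\,n_F/(n_F+n_H)$ of them (`expected_null_share()`).

Three complementary machines test departures from that null:

**Binomial GLMs with likelihood-ratio tests.** Egg receipt (0/1) is
modelled on the logit scale; a sex term, population term, or sex-by-
population interaction is judged by the deviance difference between two
fits differing only in that term, referred to $\chi^2_{\Delta df}$. Fitting
is by iteratively reweighted least squares written in the package
(`ovb_glm()`), with `stats::glm()` serving only as an independent
cross-check in the test suite. When overdispersion is expected the quasi
families estimate a Pearson dispersion $\hat\phi = X^2/df_{res}$ and the
nested comparison becomes the quasi-likelihood F test
$F = (\Delta D/\Delta df)/\hat\phi$ on $(\Delta df,\ df_{res})$ degrees of
freedom (`lr_test(kind = "f")`).

**Stratified permutation.** At the flower level,
`flower_sexbias_permutation()` reshuffles the egg indicators uniformly
among flowers *within each population* and counts hermaphrodite flowers
bearing eggs. Holding per-population egg totals fixed makes the test
immune to confounding between population-level egg pressure and
population-level sex ratio. Under within-population reshuffling the
statistic is a sum of independent hypergeometric draws, so for small
problems the package computes the null exactly by convolving the
per-population hypergeometric pmfs — identical to enumerating every
distinct egg placement, and validated against explicit `combn()`
enumeration and `dhyper()` in the tests.

**Within-pair sign flips.** For age-matched flower pairs,
`paired_swap_permutation()` swaps the egg/control labels of each pair
independently with probability 1/2; the statistic is the mean within-pair
difference. Up to 20 pairs the full $2^n$ sign-flip distribution is
enumerated (a doubling recursion over the pair differences, validated
against bit-mask enumeration). `paired_t()` gives the classical paired t
companion used for the larger trait comparisons.

### The doubled-tail p-value and ties

Both permutation tests report a two-tailed p equal to **twice the null
tail beyond the observed statistic**, in the direction of the observed
departure from the analytic null mean, capped at 1. On the discrete nulls
these tests produce, the treatment of ties matters: counting only strictly
more extreme values shifts each rejection threshold by one lattice unit
and makes the test anticonservative, while counting ties as extreme (the
conventional permutation rule) is mildly conservative. The package
defaults to the inclusive rule so that null rejection rates never exceed
the nominal level; the strict variant remains available
(`extremity = "strict"`) and every result records which rule and which
tail denominator (`count/B` or `(count+1)/(B+1)`) produced it. The
calibration check in the test suite measures the empirical size of the
default rule directly; on fine-grained nulls it sits slightly *below* the
nominal 0.05, the price of exactness on a lattice — a property of the
doubled-tail construction, not of the implementation.

### Backward selection

`backward_select()` starts from the full model, repeatedly removes the
least significant removable term with $p > \alpha$ (interactions always
before their main effects), and stops when everything remaining is
significant at $\alpha = 0.05$. Each *dropped* term is then re-tested by
adding it alone back to the final model, so reported statistics for
non-retained terms always compare "final" vs "final + term". For
log-link models `exponentiate_report()` pairs each coefficient $\beta$
with $e^{\beta}$, the multiplicative effect of a one-unit predictor
increase on the expected response.

The central inference pattern the workflow targets: if flower depth and
stem number are retained while sex is dropped, sexual dimorphism in the
*measured* traits explains the observed sex bias in oviposition.

### Exact binomial intervals

All reported proportions carry Clopper–Pearson intervals
(`clopper_pearson()`), computed from beta quantiles:
$L = B_{\alpha/2}(x,\ n-x+1)$, $U = B_{1-\alpha/2}(x+1,\ n-x)$, with
$L = 0$ at $x = 0$ and $U = 1$ at $x = n$. The beta form is numerically
stable; the tests verify it against direct bisection of the binomial tail
probabilities to $10^{-9}$ and enumerate coverage $\ge$ 95% across
$n \le 30$ and a grid of true proportions. These intervals are asymmetric
about the point estimate, which is why the error bars drawn by
`plot_proportions()` have unequal arms.

## The synthetic population

`sim_config()` fixes one parameterization for all three designs. The
defaults describe a population in which:

| Parameter | Default | Why |
|---|---|---|
| female frequency | 0.5 | balanced monitoring design (80 + 80 plants) |
| flower depth (mm) | F 17.0, H 18.0, SD 1.5 | hermaphrodites ~1 mm deeper; the dimorphic trait that mediates sex bias |
| stems, open flowers | NB, mean 10 / 6 | counts are overdispersed, matching the quasi-likelihood analyses |
| oviposition log-odds | +0.50 per mm depth, +0.15 per stem, sex term 0 | bias runs entirely through dimorphic traits |
| single-egg probability | 0.71 | most oviposition events deposit one egg |
| fruits lost (egg / no egg) | 3.85 / 1.84, NB | light predation against ~30.75 fruits produced |
| calyx-width offset (egg flower) | +0.50 mm | the within-plant trait difference; between/within-plant SDs (1.05 / 0.67 mm) back-solved so a 36-pair paired t lands near 3 |
| zero-seed probability (egg / control) | 0.61 / 0.39 | egg-receiving flowers usually fail to set seed |

Continuous traits are per-sex normals truncated at zero; counts are
negative binomial. Trait standard deviations are *assumed* plausible
values, not field measurements — the field sources report standard errors
for only a few quantities. `sim_config_null()` zeroes every slope,
dimorphism, damage asymmetry and arm difference: the global null under
which every downstream test should reject at its nominal rate.

Two design details deserve emphasis:

* **Stem-level survey intercept.** The stem-level survey draws egg receipt
  from the depth (and direct sex) coefficients with a survey-specific
  intercept (`ovi_intercept_survey`), because the parent plant's stem
  count is latent when single stems are sampled along a transect. The
  default intercept puts stem-level egg receipt in the realistic 18–36%
  range.
* **Flower-level exchangeability.** The flower-level permutation test
  assumes flowers within a population are exchangeable. When eggs are
  assigned per *stem* and stems carry variable flower numbers, the
  per-flower egg probability depends on stem size and that assumption
  fails — the test's null variance is then misstated even with no sex
  effect, a feature of the field design itself (stems, not flowers, are
  the sampling unit). The calibration checks therefore run the flower
  test on single-flower stems, where iid stem-level assignment
  conditional on the egg total is exactly the within-population uniform
  reshuffle. Users analysing multi-flower stems should read the
  flower-level permutation as conditional on the realized flower
  composition, and prefer the stem-level GLM when stems are the unit of
  oviposition.

What the generator does *not* emulate: spatial structure along transects,
year-to-year survival of perennials, moth movement between neighbouring
plants, correlated egg placement across censuses, and measurement error
in the floral traits. Passing tests therefore certify the statistical
machinery under the stated sampling models, not robustness to those
field realities.

## Numerical choices

* IRLS: mean-response initialization, convergence when the relative
  deviance change falls below $10^{-8}$, at most 100 iterations; linear
  predictors are clamped to ±30 to keep weights finite.
* Rank-deficient designs abort naming the aliased term; non-convergence
  warns. Quasi-complete separation is flagged when any slope exceeds 15
  on the logit scale (25 for the intercept, whose natural scale depends
  on raw covariate location).
* Exact permutation paths switch on when the enumeration is cheap: the
  product of per-stratum $\binom{n_g}{k_g}$ at most $10^6$, or at most
  $2^{20}$ sign assignments. Monte-Carlo paths use the analytic null
  mean (hypergeometric expectation; 0 for sign flips) so the extremity
  direction never depends on sampling noise.
* Degenerate inputs: zero eggs give a flagged $p = 1$; zero-variance
  paired differences abort; pairs missing one arm are dropped with a
  reported count; single-sex populations drop the interaction with a
  warning; empty CSVs are valid empty datasets.
* CSV round trips are exact: doubles are written with 17 significant
  digits and re-parsed with base R's correctly rounded reader.
* Egg counts among egg-receiving units are compared between sexes with a
  Poisson log-link model — a documented choice, since a count family for
  that comparison is not dictated by the designs; with at most a handful
  of eggs per unit the Poisson is the simplest defensible form. Likewise
  the stem-level bias test treats "received at least one egg" as a
  Bernoulli response, with the separate egg-number test covering
  intensity.

## Verification scale

The property checks run at sizes chosen to make Monte-Carlo error small
relative to the tolerances they enforce: generator moments at 50,000
units within 3 Monte-Carlo SEs; null calibration of the four headline
tests over 2,000 replicate datasets of 200 units with 2,000 permutation
replicates each (permutation resolution $5\times10^{-4}$ is ample at
$\alpha = 0.05$); trait-selection recovery over 500 replicates of the
160-plant monitoring design; oracle equivalence over every small
permutation instance at $B = 10{,}000$. The acceptance script reruns the
full pipeline at the field-design scale (300 stems over 6 populations,
160 plants, 36 + 10 pairs).

## Known limitations

* No mixed models: plants and stems are treated as independent units, as
  in the analyses the pipeline reproduces; clustering of flowers within
  plants is handled by pairing or stratification, not random effects.
* No multiple-testing correction: each test is reported at raw
  $\alpha = 0.05$, and reports carry a count of tests run so readers can
  judge the family size.
* The doubled-tail permutation p is conservative on coarse discrete
  nulls (and its strict-tie variant anticonservative); mid-p compromises
  are deliberately not offered, to keep the reported rule simple and
  auditable.
* Backward selection inherits the usual caveats of stepwise procedures;
  it is provided because it is the protocol the workflow mirrors, with
  the dropped-term re-testing convention making reported statistics
  well-defined.
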