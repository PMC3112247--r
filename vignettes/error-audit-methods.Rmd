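---
title: "Auditing genotyping errors in a microsatellite DNA register"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing genotyping errors in a microsatellite DNA register}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Individual-based DNA registers store one multilocus microsatellite profile
per individual and identify new samples by exact profile matching. The
Norwegian minke whale DNA register -- ten microsatellite loci, four
laboratories, catches from 1997 onward -- is the motivating system for this
package. Genotyping errors break exact matching: what matters for register
operation is not the per-locus error rate but the probability that a
profile mismatches at one or more loci, and how strongly errors cluster
within individual samples. A re-genotyping audit (a random subsample typed
afresh, deviations resolved by repeated consensus runs) yields, per
individual and locus, a binary error indicator plus an error taxonomy:
single or double false allele size, false homozygote (a true heterozygote
recorded as a homozygote), and false heterozygote (the converse), each with
the base-pair shift of the wrong allele(s).

`genoaudit` implements the full audit workflow: profile comparison and
error classification, empirical rate tables, a logistic mixed model for the
error probability fitted by its own marginal-likelihood code, AIC/Akaike
weight model selection, Monte-Carlo population averaging of per-locus and
multilocus error rates, cluster-bootstrap standard errors, and a synthetic
register generator standing in for the confidential register data.

## The model

With `y_il` the error indicator at locus `l` of individual `i`, the model
is a logistic regression with random intercepts:

$$\mathrm{logit}\, p_{il} = \eta_{il} = \beta_0 + \beta_{\mathrm{locus}(l)}
  + \beta_{\mathrm{year}} (t_i - 2001) + b_i + b_{im(l)},$$

where `b_i ~ N(0, sigma_IND^2)` is shared across all loci of individual `i`
(sample quality) and `b_im ~ N(0, sigma_MP:IND^2)` across the loci of one
multiplex PCR assay of that individual (assay handling). Candidate models
take fixed effects from {LOCUS, YEAR, LAB} -- YEAR and LAB are confounded
by the laboratory schedule and never co-occur -- and random effects from
{IND, MP:IND}, giving an 18-model candidate set. Models are ranked by AIC
and weighted by `w_k = exp(-Delta_k/2) / sum_j exp(-Delta_j/2)`.

The YEAR covariate is the calendar year minus 2001, the middle of the
1997--2008 period; this centering makes the intercept-plus-locus-offset
predictors directly comparable with the published per-locus rates at 2001,
which the acceptance checks reproduce. Treatment contrasts use the
alphabetically first retained level as reference (configurable); marginal
rates, the quantities of scientific interest, are contrast-invariant.

### Marginal likelihood

The likelihood marginalizes the random effects. Per individual (or per
multiplex block),

$$L_i(\beta, \sigma) = \int \prod_l p_{il}(b)^{y_{il}}
  (1-p_{il}(b))^{1-y_{il}} \, \phi(b; 0, \sigma^2)\, db ,$$

evaluated by adaptive Gauss--Hermite quadrature: each group's integrand is
recentered at its conditional mode (found by a damped Newton iteration)
and rescaled by the Laplace curvature, then integrated with a 20-node rule
(Golub--Welsch nodes). With both random effects present the individual
integral nests the per-multiplex integrals inside the individual-level
one, with the outer mode found by Newton on numerically differentiated
inner integrals. With no random effect the expression reduces -- exactly,
not approximately -- to the ordinary logistic log-likelihood.

Maximization is over `(beta, log sigma)` with L-BFGS-B, multi-started from
the ordinary-logistic solution with `sigma` in {0.1, 1}, followed by a
tight polishing pass. The gradient is analytic: the derivative of the
marginal integral is the posterior expectation of the conditional score,
computed with the same quadrature rule. The convergence flag is
diagnostics-driven -- a scaled gradient norm below `1e-5 * max(1, |logLik|)`
and a positive-definite observed information on the non-boundary
parameters -- because the optimizer's own status is unreliable when the
starting value already is the optimum. `sigma` estimates below 5e-3 are
reported as boundary solutions. AIC counts every coefficient plus one
parameter per random term.

Zero-information factor levels -- loci or laboratories with no observed
errors (EV001 and Lab 3 in the register audit) -- are removed before
fitting, reproducing the audit's rule and avoiding perfect separation;
retaining them triggers an explicit separation warning instead.

### Quadrature accuracy

Order 20 is the default throughout; the suite verifies that order 20
agrees with order 40 to below 1e-6 log-likelihood units and with exact
one-dimensional integration to 1e-8 on small instances. The large
parameter-recovery study fits with order 12, which is indistinguishable at
these cluster sizes (nine Bernoulli observations per individual) and
roughly halves the fit cost.

## Population-averaged and multilocus rates

Individual-specific probabilities are averaged over the random-effect
distribution by Monte Carlo: `p_l = E[plogis(mu_l + eta)]` with
`eta ~ N(0, sigma^2)`, estimated from `N = 1e6` draws (standard error about
1e-4 on rates of a few percent; the draw count is configurable and every
Monte-Carlo entry point takes a seed). Loci excluded for zero observed
errors enter the rate tables with rate 0.

For the profile-level summary, `E` counts the loci of one profile with at
least one wrong allele. Under independence the closed forms
`P(E>0) = 1 - prod(1-p_l)` and `P(E=1) = sum_l p_l prod_{k!=l} (1-p_k)`
apply; under dependence one shared draw `eta_i` shifts all loci of a
simulated individual and the same expressions are averaged over draws.
Both halves report `P(E>0)`, `P(E=1)`, `P(E>1)` and `P(E>1 | E>0)` in
percent. The dependence effect is the audit's headline: with a shared
individual effect, profiles carrying any error are concentrated in
error-prone individuals, so `P(E>1|E>0)` rises severalfold while `P(E>0)`
falls slightly.

## Cluster bootstrap

Standard deviations for fitted quantities come from resampling individuals
(whole locus sets) with replacement to the original sample size and
refitting; duplicated individuals receive fresh random-effect levels. The
SD is taken across converged replicates; a second variant counts every
non-converged replicate's estimate as zero, bounding the effect of
non-convergence from above. More than half non-converged replicates flags
the result as unreliable. The default is B = 500 replicates; the analysis
script uses B = 100 to keep its runtime in minutes.

## The synthetic register generator

The register data are not public, so the generator emulates the audit's
design: 20 individuals per catch year 1997--2008 with the year-to-lab
schedule (Lab1 1997--2002, Lab2 2003--2005, Lab3 2006, Lab4 2007--2008),
minus six failed samples (two from 1997, one each 1998, 2000, 2006, 2008
-- three of the six years are part of the audited design, the others were
allocated to reproduce the per-lab analyzed counts 116/60/19/39). True
genotypes are Hardy--Weinberg pairs from per-locus spectra drawn once from
a symmetric Dirichlet over a repeat-unit ladder spanning each locus's
observed length range; the real spectra are unpublished, and no
population-level target depends on them -- they only set heterozygosity.
Error indicators follow the mixed logistic model above with the best
model's published coefficients as generative defaults (intercept -4.74,
year slope -0.36, individual variance 1.81, per-locus offsets from 1.59
for GATA417 down to -1.08 for GATA098; EV001 is a structural zero). The
ten loci are partitioned into three multiplexes (the published design
names three assays but not their composition; the package fixes
MP1 = {GT509, GT310, GT211, GT023}, MP2 = {GATA098, GATA417, GATA028},
MP3 = {GT575, EV001, EV037}, which reproduces the audit's 3-blocks-per-
individual group counts).

On an error, the error type is drawn from the audited class mixture
(12 single, 6 double, 10 false homozygote, 3 false heterozygote out of 31)
renormalized to the types compatible with the true genotype's class:
heterozygotes draw from {single, double, false homozygote}; homozygote
errors surface as false heterozygotes -- a single shifted copy of a
homozygote *is* a false heterozygote to the auditor, so letting
homozygotes draw "single false allele" would corrupt the audited
proportions. Mutations shift an allele by 1 bp with probability 0.45
(matching the audited 13-of-31 1-bp share) and otherwise by one repeat
unit, rejecting shifts that would land on the partner allele and silently
change the audited class. Double false alleles must land both copies off
the true pair for the same reason.

What the generator does not emulate: allele-frequency structure of the
real population, the 1-bp ladder quirk behind the cluster of 221-to-220
miscalls at one locus (ladder-spaced spectra cannot produce 1-bp-adjacent
false homozygotes), quality heterogeneity of the six excluded samples, and
any systematic between-lab calibration shift (the audit found none).
Passing tests therefore demonstrate correctness of the statistical
machinery under the model's own assumptions, not properties of the real
register data.

## Validation design

Every computational stage is tested against an independent oracle:
classification against exhaustive enumeration of genotype pairs; empirical
rate tables against the published audit tables (rebuilt from the published
count data); the quadrature against exact one-dimensional integration,
brute-force Monte-Carlo integration, and an independent GLMM
implementation (lme4) on the same likelihood surface; independence
multilocus formulas against enumeration over all 2^L error patterns; the
bootstrap against the analytic binomial SD of the intercept-only model.
A 20-seed parameter-recovery study at about 5000 simulated individuals
checks that fitting the generating model recovers the year trend and the
individual variance within 95% Wald intervals at the nominal rate; a
40-seed calibration study during development confirmed empirical
SD-to-reported-SE ratios near 1 (1.08 for the year slope, 0.99 for the log
random-effect SD). Wald intervals from the observed information are used
throughout for recovery checks -- bootstrap intervals around every
simulated fit would multiply the computation by the replicate count
without changing what is being verified.

## Numerical choices and limitations

* Allele pairs are unordered multisets; the allele error count minimizes
  substitutions over the two possible pairings, with ties broken by the
  smaller total base-pair shift. Only this convention reproduces the
  published per-allele rates from the published count table.
* The bp-shift class is `eq_1bp` if every wrong allele moved exactly 1 bp,
  `gt_1bp` if every one moved more, `mixed` otherwise (the published
  tables contain no mixed cells; double errors can produce them).
* A true heterozygote observed as a homozygote of a *novel* allele is
  classified false homozygote with two allele errors -- a corner never
  observed in the audit, flagged by its count.
* Missing loci are integrity errors, not missing data: the register's
  design requires complete profiles, and the audit compares complete
  consensus profiles.
* Error rates of exactly zero (empty groups) yield zero SDs; empty groups
  are rejected.
* The dependence computation uses the individual effect only, matching the
  selected model (the multiplex variance is estimated at zero whenever the
  individual effect is present); `multilocus_dependent()` accepts any
  predictor vector, so multiplex-level dependence can be computed by
  passing block-level predictors.
* Fits at a variance boundary report `sigma` near zero with the boundary
  flag set; their AIC still counts the variance parameter, matching the
  candidate-set bookkeeping.
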