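---
title: "Methods: case-control SNP association and minor-allele burden analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control SNP association and minor-allele burden analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdburden)
```

## Scope and data model

`vdburden` analyzes a candidate-gene case-control design: a panel of
biallelic SNPs with *declared* major and minor (risk) alleles, and
subjects carrying case/control status, sex, age and one genotype call per
SNP. The built-in panel holds the four vitamin D pathway loci (*DHCR7*
rs12785878, *GC* rs2282679, *CYP2R1* rs2060793, *CYP24A1* rs6013897) with
non-Finnish European reference MAFs 0.278, 0.288, 0.403 and 0.197.

The minor allele is fixed from the reference population rather than
re-estimated from the sample. For a SNP with sample MAF near 0.5
(here *CYP2R1*, 0.42-0.44), estimating the minor allele per dataset can
flip between groups or bootstrap replicates, silently reversing the
direction of odds ratios and of the burden score. Declaring it once in
the panel makes every downstream sign stable.

Genotypes are stored as unphased allele pairs in canonical order (major
allele first), so RFLP-style tabular input and VCF input are symmetric;
minor-allele dosage (0/1/2) is computed on demand. Missing calls (assay
failure) propagate as `NA` and every single-SNP statistic is per-SNP
complete-case: a subject missing one SNP still contributes to the other
three. This is why the per-SNP totals of a real cohort differ slightly
across SNPs.

## Hardy-Weinberg testing

For each SNP and group, the allele frequency q is estimated from that
group's own genotypes and observed counts are compared with
n(p^2, 2pq, q^2) by the chi-squared goodness-of-fit statistic on
**1 degree of freedom** (three classes, minus one, minus one estimated
parameter). No continuity correction and no exact test: the plain
goodness-of-fit test is what a reader of the result tables expects, and
at n of several hundred the chi-squared approximation is adequate (our
null simulations give rejection rates of 4-5% at alpha = 0.05, mildly
conservative at smaller n, which we accept and document). Monomorphic
samples are returned as chi2 = 0 and flagged untestable rather than
erroring, so panel-wide sweeps do not abort. Both groups are tested and
reported separately; deviation in controls flags genotyping artefacts or
stratification, deviation in cases can itself reflect association.

## Association models

Minor-allele dosage d is encoded per inheritance model: dominant
(d >= 1), recessive (d = 2), overdominant (d = 1), log-additive (d
itself), codominant (separate heterozygote and minor-homozygote
indicators). Case status is regressed on the encoding by maximum
likelihood logistic regression (binomial `glm`, IRLS, deviance tolerance
1e-12, max 100 iterations; coefficients with |beta| > 15 are flagged as
likely separation instead of being reported silently).

Reported effects are OR = e^beta with Wald 95% limits e^(beta +/- 1.96 SE).
The multiplier is the conventional fixed 1.96, not `qnorm(0.975)`:
published tables are computed that way and the two differ in the fifth
decimal. For the three 1-df collapses the Wald interval coincides (to the
IRLS convergence precision, about 1e-6 relative) with the closed-form
Woolf interval on the collapsed 2x2 table,
exp(ln OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)), and the test suite
verifies this equivalence on randomly generated tables. "Log-additive"
is logistic-on-dosage, *not* the allele-count 2x2: the two differ in the
third decimal and result tables are computed from the regression.

P-values: Wald for 1-df models, with the likelihood-ratio p reported
alongside (the convention of the published tables is not stated, and the
two can differ in the third decimal — bare p-values are therefore treated
as descriptive, not as exact reproduction targets); the codominant model
reports a 2-df likelihood-ratio p.

Covariate adjustment enters sex as a male indicator and age as a
continuous linear term. Model selection is minimum AIC across the five
models fitted on the identical subject subset (enforced, since AIC is
only comparable on equal data); ties within 1e-8 break by the fixed
order codominant, dominant, recessive, overdominant, log-additive and
are flagged. Multiple testing across the panel uses Bonferroni:
threshold alpha/m = 0.05/4 = 0.0125.

## Minor-allele burden

Each completely genotyped subject gets a score Sum(d) over the panel
(0..8 for four SNPs); subjects with any missing call are excluded and
counted. The headline test dichotomizes at >= t minor alleles (default
t = 3) and compares groups by Pearson chi-squared **without** Yates
correction plus the Woolf OR interval. The continuity-corrected test
would give p ~ 0.032 instead of the 0.027 the uncorrected test yields on
the study distribution; the uncorrected version is both the stated
method and standard at these margins. Because t = 3 has no stated
rationale beyond being the published cut, `burden_threshold_sweep()`
always exposes every threshold, discouraging post-hoc cherry-picking.
The burden OR is unadjusted — on the study distribution the published
value equals the raw cross-product ratio to 2 decimals, indicating no
covariate adjustment was applied to it.

One reproduction note: on the study's dichotomized table the Woolf
interval is (1.0359, 1.8047), which prints as 1.04-1.80 at two decimals,
while the published table shows 1.04-1.81. No standard interval
reproduces 1.81 (test-based gives 1.804, Fisher's exact 1.82), and the
same Woolf formula reproduces every published genotype-row CI exactly;
we report the formula's value and note the one-final-digit difference
rather than special-casing it.

## Power analysis

`power_cc()` computes two-sided normal-approximation power for a
two-proportion comparison with control exposure probability = MAF and
case probability odds-scaled by the OR, using the pooled variance under
the null and unpooled variances under the alternative — so the size at
OR = 1 is exactly alpha. Two sampling-unit conventions are exposed
because they answer different questions:

* `unit = "subjects"`: each person is one dichotomous draw with
  prevalence MAF. This is what standard sample-size software computes
  for a dichotomous risk factor, and it is the convention under which
  350/490 subjects at alpha 0.05 and power 0.8 give minimum detectable
  ORs of about 1.48-1.58 across MAF 0.20-0.40.
* `unit = "alleles"`: the 2n chromosomes per group are the draws (the
  additive allele-count approximation). Under the per-allele logistic
  disease model, the genotype distribution in cases is exactly HWE with
  odds-scaled allele frequency, so this variant tracks the power of the
  logistic-on-dosage test itself — around 0.97 at OR 1.5, MAF 0.30,
  i.e. far above the per-subject figure at the same OR.

The simulation cross-check (`power_cc_sim()`: simulated cohorts plus the
log-additive Wald test) therefore validates the `"alleles"` variant; the
agreement is within about 0.01-0.02 at low and high power and degrades
to about 0.03 on the steepest part of the power curve, where the Wald
test's finite-sample behaviour departs most from the two-proportion
normal approximation. `detectable_or()` inverts `power_cc()` by
bisection (`uniroot`) to 1e-4 in power and defaults to `"subjects"`,
matching how detectable-OR statements for this design are convention-
ally produced.

## The cohort simulator

`simulate_cohort()` draws from the generative model the analysis
assumes: independent per-SNP genotypes under HWE at the panel reference
MAFs (the four study loci lie in different genomic regions; linkage
disequilibrium between them is assumed absent), a logistic liability
logit P(case) = b0 + Sum(beta_s d_s) + beta_sex male + beta_age age, and
retrospective sampling — candidates are drawn in batches from the
prospective population until the case and control quotas fill, the
standard generative counterpart of a case-control design. The default
baseline logit log(350/490) keeps the marginal case fraction near the
study's and quotas fill in one or two batches; an unreachable quota
aborts with the observed case fraction after a batch cap.

Covariates: sex and age distributions are supplied per group (cases
29.0 +/- 11.1 years, 52.6% male; controls 32.2 +/- 11.2, 50.2% male —
the study's summaries). In a generative model, per-group covariate
distributions are *outcomes*, not inputs, whenever covariates affect
liability; the simulator therefore uses them directly (drawn per group
after status assignment) only in the default case of zero sex/age
effects, where covariates are independent of status. With nonzero
effects, candidates draw covariates from the control-group values as
the population proxy and group differences emerge from the liability.
Ages are normal truncated at zero. Missingness is completely at random
per SNP (assay failure; study rates 0.4%, 0.1%, 0.1%, 1.2%),
independent of status and genotype. All randomness is fixed by a single
seed; an identical seed yields a byte-identical cohort file.

What the simulator does **not** emulate — and hence what passing tests
do not certify about real data: linkage disequilibrium, population
stratification, genotyping *error* (miscalls, as opposed to missing
calls), informative missingness, age/cohort effects on recruitment, and
the major non-vitamin-D genetic architecture of type 1 diabetes (HLA and
other loci). It validates the statistical machinery under the model the
analysis itself assumes, nothing stronger.

## Fixture expansion from printed tables

No subject-level data were available, so `expand_fixture()` rebuilds
analyzable cohorts from the published counts. With genotype tables
alone, each group's size is the largest per-SNP total and each SNP's
genotype column is laid out independently — per-SNP tables reproduce the
printed counts cell by cell, but the joint distribution across SNPs is
arbitrary (such fixtures validate single-SNP statistics only). With the
published burden distribution supplied as well, a joint assignment is
constructed: the group size becomes the smallest N at which the implied
missingness pattern is feasible (every incompletely genotyped subject
carries >= 1 of the N - n_s missing calls per SNP; for the study tables
this recovers the true 350/490); complete-case subjects then receive
dosage 4-tuples summing exactly to their target burden, chosen greedily
(most extreme burdens first) to deplete the per-SNP genotype-class pools
proportionally. The burden distribution is matched exactly (348 scored
cases, 478 controls); per-SNP marginals land within one subject per cell
on the study tables. The exact joint distribution is unidentified from
printed margins, and the attached sex/age values are synthetic draws
from the group summaries — consequently, covariate-adjusted estimates
computed on fixture cohorts do **not** reproduce the source study's
adjusted ORs and are never claimed to.

## Numerical and display conventions

Full precision is kept internally; display tables round half away from
zero (ORs and CIs to 2 decimals, percentages to 1), matching the
rounding convention of published tables and avoiding banker's-rounding
mismatches. Rendered TSV and markdown tables carry identical numbers,
with full-precision companion files written alongside. Zero cells in a
2x2 are an error by default, with an explicit Haldane-Anscombe +0.5
option; degenerate burden margins and rank-deficient designs abort with
stage-tagged messages rather than returning NaN.

## Problem sizes used in validation

The test suite works at sizes chosen to make Monte Carlo error small
relative to the tolerances while keeping a full run in about a minute:
HWE proportions at 10,000 per group; null calibration of the single-SNP
and burden tests at 120/120 over 500 replicates (rejection rate 0.05 +/-
0.03); CI coverage of a per-allele OR 1.5 at 400/400 over 300 replicates
(expected within 0.90-0.99); effect recovery at 20,000 per group
averaged over 8 seeds (|bias of log-OR| < 0.02); power simulation at the
study's 350/490 with 1,500-2,500 replicates per grid point. The
acceptance computations on the fixture cohorts are deterministic and run
in seconds.

## Known limitations

* Wald intervals and p-values can misbehave under near-separation; the
  separation flag is reported but no Firth-type correction is applied.
* The burden score weights every minor allele equally; no effect-size
  weighting or trend test across the 0-8 range is provided.
* The exact-test alternative to the chi-squared HWE test is not
  implemented; at candidate-gene sample sizes the difference is
  immaterial, at n below ~50 per group it would not be.
* Multi-allelic sites, phasing, imputation, X-linked loci and pedigree
  structure are out of scope.
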