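---
title: "Methods: exposome-gut microbiome-health mediation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exposome-gut microbiome-health mediation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific question

Environmental and lifestyle exposures (diet, antibiotics, air pollutants,
persistent organic pollutants, mycotoxins, the urban microbiome) are
associated with many self-reported health outcomes. Some of that
association may be transmitted through the gut microbiome: an exposure X
shifts a community property M, and M in turn shifts the outcome Y. This
package implements the full chain needed to ask that question
quantitatively at cohort scale: exposure derivation, mediator indices,
association screening, and formal mediation with interval estimates for
the indirect effect.

Because the cohort data this design targets are not redistributable, the
package ships a synthetic-cohort generator with *planted* structural
coefficients. All statistical validation is parameter recovery against
that planted truth.

## The mediation model

For each eligible triplet (X, M, Y), with adjustment covariates C (age and
sex by default) entering every fit:

* total effect: `Y = i1 + c X + g1'C + e1`
* exposure-mediator path: `M = i2 + a X + g2'C + e2`
* joint model: `Y = i3 + c' X + b M + g3'C + e3`

The indirect (microbiome-mediated) effect is `ab`, the direct effect is
`c'`, and the proportion mediated is `ab / c`. X is Z-scored on the
listwise-complete analysis sample, so path units are per SD of exposure.
With a continuous Y and shared covariates across the three OLS fits the
decomposition `c = c' + ab` is an algebraic identity; the package asserts
it to 1e-10 on every run as a self-check of the fitting path.

With a dichotomous Y, c, c' and b come from logistic fits and are
log-odds; a remains linear. Because the two scales differ, the indirect
effect's sampling distribution is not normal even asymptotically, and
`ab` gets its confidence interval from the exact distribution of the
product of two independent normal estimates (below). The proportion
mediated `ab/c` is still reported on this mixed scale, flagged with a
non-collapsibility caveat: logistic coefficients from models with and
without M are not strictly comparable even absent confounding.

Classification of a pathway:

* `none` - the ab interval includes 0;
* `full` - ab significant, c' not (an interpretive rule: only the
  partial/inconsistent boundary is conventionally defined, so we complete
  the taxonomy by letting a non-significant direct path mean the mediator
  carries the detectable signal);
* `partial` - both significant, same sign;
* `inconsistent` - both significant, opposite signs (the indirect path
  offsets part of the direct effect; `ab/c` then falls outside [0, 1] and
  is flagged).

### Interval estimation

*Continuous outcomes* use a nonparametric bootstrap: rows are resampled
with replacement, a and b are refit, and the 2.5/97.5 percentiles of the
resampled `a*b` form the interval (5000 resamples by default; percentile
rather than BCa because the estimand is smooth and the intervals are
re-derived thousands of times in a screen).

*Binary outcomes* use the distribution-of-product interval. If
`A ~ N(a, se_a^2)` and `B ~ N(b, se_b^2)` are independent, the CDF of AB
is

    F(t) = E_A[ P(B <= t/A | A > 0) + P(B >= t/A | A < 0) ],

evaluated by adaptive quadrature with A integrated in standardized units
over +/-10 SD (truncation error < 1e-20, far below the 1e-6 CDF tolerance
used for root-finding the 2.5% and 97.5% quantiles). The finite range
matters numerically: the inner CDF has a near-step where `t/x` crosses b
when `se_b` is small, and an infinite-range quadrature spends unbounded
effort resolving it under a mass of ~1e-200. The implementation is
verified against 2e6-draw Monte-Carlo quantiles on a grid of standardized
ratios `a/se, b/se in {0, 0.5, 1, 2, 5}`, evaluated at the standard-error
magnitude typical of fitted paths (se = 0.1); at unit standard errors the
Monte-Carlo oracle's own quantile noise (~0.01 at the outer grid points)
would dominate the comparison. Far from the origin the interval converges
to the Sobel normal approximation, which the tests also check.

## The ten mediator indices

Per sample, from a genus-level count table: Shannon entropy (base 2, with
a natural-log option), observed features, Fisher's alpha (the positive
root of `S = alpha ln(1 + N/alpha)`, solved to a residual of 1e-9;
all-singleton samples have no finite root and are flagged), the first two
principal coordinates of the Bray-Curtis dissimilarity matrix,
Firmicutes/Bacteroidetes and Gram-positive/Gram-negative ratios, and the
summed relative abundances of three functional guilds (risk-associated,
butyrate-producing, lactate-producing taxa).

Numerical and policy choices:

* **No rarefaction.** Indices are computed on raw counts; the synthetic
  generator draws all samples at equal depth, so depth confounding is not
  present in validation data. Real data at uneven depth inherit the usual
  caveats for richness-type metrics.
* **PCoA** uses Gower double-centering and eigendecomposition; negative
  eigenvalues (Bray-Curtis is non-Euclidean) are dropped with a warning
  rather than Cailliez-corrected, and each axis's sign is fixed so the
  lexicographically first sample loads non-negatively, making runs
  reproducible across platforms.
* **Taxon matching is exact on the full name.** The butyrate guild mixes
  genera and named species; a genus-prefix fallback exists but is off by
  default to avoid silently double-counting.
* **Phylum and Gram lookups are configuration**, shipped for the taxa the
  synthetic generator emits; real tables must supply their own, since
  genus strings alone do not determine phylum or Gram status.
* Ratios with a zero denominator are flagged missing, never infinite.

## Exposure derivation

Questionnaire responses are coded to average daily occurrences: never = 0,
rarely = 2/30.4, occasionally = 1.5/7, often = 4/7, every day = 1; binary
yes/no to 1/0; ordinal options to 0..N-1 in the supplied order (the
option order is per-question configuration; no universal order exists).
The exact quotients are stored - the familiar 0.066/0.214/0.571 are their
3-decimal roundings - so downstream regressions do not compound rounding.

Missingness filtering is two-step and strict: variables missing in more
than 50% of participants are dropped first, then participants missing
more than 50% of the surviving variables. Collinear exposures are pruned
at Spearman |rho| > 0.85; since the convention for which pair member to
drop is not standardized, the package drops the member with more missing
values (tie: the lexicographically later name), processes pairs in
descending |rho|, and logs every decision so runs are auditable.

Time-varying environmental exposures are averaged over the three calendar
years preceding sample collection, falling back to the three most recent
available preceding years (flagged) and to a short window when fewer
exist - averaging what exists mirrors a best-available-estimate policy
rather than discarding the participant. Mycotoxin dose combines a regional
representative concentration `C = D x M` (detection rate times median
concentration, ug/kg) with coded intake frequencies of grains, dairy, and
nuts under weights (0.5, 0.3, 0.2) reflecting the contamination-risk
hierarchy of those food groups; the result is in ug/day. Participants are
assigned to a city when within 5 km (haversine, mean Earth radius
6371 km) of its center, nearest center first, lexicographic tie-break.

## Association screen

Every exposure is regressed on every mediator index and every outcome
separately (bivariate by design - the screen is a filter, not a causal
model), with HC1 sandwich standard errors and a t-based 95% Wald interval.
A pair is significant only under the dual criterion: BH-FDR < 0.05 *and*
adjusted R^2 > 0.005 *and* the CI excludes zero. The FDR family defaults
to per-dependent-variable (each index or outcome is its own
multiple-testing family, matching how screen results are organized and
read), with a global family available; the choice is recorded in the
output metadata. The signed effect-size matrix (`sign(beta) x adjR^2`,
zero where the criterion fails) is the heatmap-ready export.

## Group statistics

Mann-Whitney U uses the exact null distribution when `n1*n2 <= 400` and
there are no ties, otherwise the tie-corrected normal approximation.
PERMANOVA computes the pseudo-F directly from squared distances via the
Gower identity with a seeded permutation stream and the add-one p-value
convention (minimum p = 1/(n_perm+1)); vegan's adonis2 is the independent
cross-check in the tests, never the implementation. The quartile
prevalence-shift analysis contrasts taxon prevalence between samples
strictly above the 75th and strictly below the 25th exposure percentile
(boundary ties excluded, group sizes logged), with two-sided Fisher exact
tests and BH adjustment across taxa; Fisher's exact test was chosen as
the standard two-proportion procedure since no specific test is
conventionally attached to prevalence contrasts.

## Environmental standardization

Unevenly sampled per-city collections are standardized by (1) retaining
cities with more than 14 samples, (2) setting the target to the median
retained size (lower median on even counts so the target is an achievable
size; overridable), and (3) for cities above target, repeatedly drawing
uniform subsets until the subset's per-sample alpha-diversity
distribution is indistinguishable from the full city's by a two-sample
KS test (p > 0.05), defaulting to Fisher's alpha as the gating metric.
Cities between the eligibility floor and the target pass through
unsubsampled. The KS comparison uses per-sample distributions - the only
reading under which a two-sample test is defined - and the asymptotic
p-value, since subset and full set share observations and exact p-values
are undefined under ties. That sharing also makes the test conservative:
overlap deflates the KS statistic, so acceptance is near-certain for iid
cities (the tests verify >= 90% first-draw acceptance) and the iteration
cap (default 1000) is a safety valve whose exhaustion error carries the
best subset seen. A corollary worth knowing: with very small targets the
two-sample KS test has essentially no power, so the gate cannot detect a
subset forced into one mode of a bimodal city - the gate certifies
distributional compatibility at the resolution the sample sizes allow,
not representativeness in a stronger sense.

## The synthetic generator

Two modes, by design:

* **Abstract triplets** (default for validation): X ~ N(0,1), M = aX + e
  with e ~ N(0, noise_sd_m), and Y either Gaussian
  (`baseline + c'X + bM + e`, residual SD `noise_sd_y`) or Bernoulli with
  a logistic link on the same linear predictor. Age ~ N(45, 15) truncated
  to [18, 90], sex ~ Bernoulli(0.5), both optionally entering Y with small
  coefficients so covariate adjustment is testable. This isolates
  statistical correctness of the engines from ecological plumbing.
* **End-to-end cohorts**: genus counts are Dirichlet-multinomial with
  per-taxon concentrations scaled by `exp(shift x X)` for the planted
  effect taxa. The default effect taxa are butyrate producers (boosted)
  and risk-associated taxa (suppressed), and the realized mediator is the
  butyrate-guild relative abundance computed from the generated counts -
  so the exposure-mediator path is mechanical (the exposure shifts the
  very taxa the index sums) rather than assumed. Outcomes are generated
  from the *centered* realized mediator (the baseline is the outcome
  level at the average community state) with mediator-scale coefficients;
  the default `b = 5` per unit relative abundance reflects that the guild
  abundance varies by only a few percentage points across samples, and
  much smaller values would plant effects below detectability at cohort
  sizes of a few hundred. Missingness is injected completely at random;
  the missingness filters only count missing cells, so no richer
  mechanism is needed.

The `synthetic_truth` container carries one field beyond the structural
coefficients and noise SD of M: `noise_sd_y`, the residual SD of a
continuous outcome (default 1), without which the continuous model would
have no noise scale.

What the generator does *not* emulate - phylogenetic correlation among
taxa, sequencing error, uneven depth, spatial autocorrelation of
exposures - bounds what passing tests mean: they certify the statistical
machinery (estimation, intervals, error control, bookkeeping), not
robustness to those real-data features.

## Problem sizes and runtime choices

Validation experiments are sized for a single CPU: parameter recovery
uses 500 replicates of n = 5000 with 800 bootstrap resamples per
replicate (the full default of 5000 resamples is for single analyses, not
500-fold simulation); the Monte-Carlo check of the product CI uses 2e6
draws per grid point; null error-control runs use 10 replicates of the
50 x 10 screen at n = 1000 and 500 replicates of the group tests, with
PERMANOVA at 199 permutations per replicate in simulation (999 remains
the analysis default). The end-to-end workflow scripts use a cohort of
600 and eight synthetic cities.

## Known limitations

* Mediation here is associational: no sensitivity analysis for unmeasured
  confounding, single mediator per model, no exposure-mediator
  interaction, no longitudinal structure.
* Binary mediators are unsupported (all ten indices are continuous).
* The screen is bivariate by construction; multivariable adjustment
  happens only inside the mediation fits.
* `ab/c` on the mixed linear/logistic scale inherits non-collapsibility;
  treat the flagged proportions as descriptive.
* The workflow-shape decision: the package exposes everything as
  functions plus numbered analysis scripts; there is no shell-level
  subcommand interface, because the intended user drives the pipeline
  from R.
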