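---
title: "Methods: male-male bonds, coalitions and reproductive success in Guinea baboons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: male-male bonds, coalitions and reproductive success in Guinea baboons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`baboonbonds` implements, as a tested and reusable pipeline, the analysis
chain used to study whether male-male social bonds pay off reproductively in
wild Guinea baboons (*Papio papio*): behavioural-event ingestion, the dyadic
composite sociality index and bond metrics, daily reproductive-unit
composition, microsatellite parentage, and Poisson/beta mixed-model
inference. A synthetic-data generator with a ground-truth table stands in
for the field data, so every stage can be validated against known truth.
This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic data can and cannot show.

## The sociality index and bond metrics

The dyadic composite sociality index (DSI) measures how much a male-male
dyad's affiliation deviates from its party's typical level. For dyad $xy$,

$$\mathrm{DSI}_{xy} = \frac{1}{d}\sum_{i=1}^{d} \frac{f_{ixy}}{\bar f_i},$$

where $f_{ixy}$ is the rate of behaviour $i$ in dyad $xy$, $\bar f_i$ the
arithmetic mean of that rate over all included dyads of the party-year, and
$d = 5$ behaviours: grooming frequency and duration, contact-sit frequency
and duration, and the frequency of approaches within 1 m. The index is
non-negative and averages exactly 1 by construction; values above 1 mark
above-average ("strong") bonds. Per male and year, *bond strength* is the
sum of his three largest DSI values and the *number of strong bonds* counts
his DSI values strictly greater than the party-year mean.

Decisions the index rests on, each fixed and documented here because the
underlying field protocols leave them open:

* **Exposure.** Rates are focal events (or focal seconds) per *dyad contact
  hour*: the sum of the party's daily session durations over days on which
  the census marks both males present. Presence is resolved at day
  granularity; within-day arrivals are not modelled. Party contact time
  during dyad co-presence (rather than per-dyad focal time) is the
  denominator — a documented choice, since focal and party effort are
  proportional under balanced protocols.
* **Approach redundancy filter.** An approach within 1 m is excluded when
  any other recorded social event (positive or negative, any recording
  source) between the same dyad starts within 10 s after it, so approaches
  that merely initiate a grooming or contact-sit bout are not double
  counted. Removing the filter can only increase approach rates, which the
  test suite asserts as a monotonicity property.
* **Dyad inclusion.** Every male-male dyad with positive contact hours in
  the party-year enters both $\bar f_i$ and the index table; dyads that
  never interacted score 0. A behaviour whose party-year mean rate is zero
  is dropped from the index with a warning and $d$ reduced; real field data
  never hit this case.
* **Ties at the third-largest DSI.** The three summands of bond strength
  are fixed by ordering on (descending DSI, partner id), so output is
  deterministic; the sum itself is unaffected by how a tie is broken.
* **Strong bonds** use *strictly greater than* the party-year mean. A value
  exactly at the mean (e.g. an index of exactly 1) does not count.

Coalitionary support — two male allies simultaneously directing aggression
at a common male target — is tallied per dyad from focal and ad libitum
records combined, because aggression is rare, and expressed per dyad
contact hour.

The *affiliation-time proportion* of a male-year is the fraction of his
focal observation time spent grooming or contact-sitting with other males
(as focal actor or receiver). Its denominator requires each male's focal
time, which the `focals` table of the dataset carries (date, male,
duration); males without focal time are flagged and excluded from the beta
model rather than silently dropped.

## Unit composition

Females in this multi-level society exchange far more affiliative and
sexual interactions with their unit's ("primary") male than with any other
male, so daily unit membership is inferred from the interaction record.
For each female-day, interaction occurrences with each male are summed over
a trailing window (`window_days = 30`); the incumbent male keeps the female
unless another male *strictly* exceeds his windowed count (hysteresis), and
ties with no incumbent leave the female unassigned. The source methodology
is unpublished detail, so the rule here is deliberately simple,
deterministic and exposed in the configuration. A male's yearly unit size
is the *mode* of his daily number of associated females over his presence
days, with ties broken toward the larger value (arbitrary but fixed and
tested); a male is "primary" on days with at least one female, else
"bachelor".

On generator output without transfers the inferred assignments match the
truth table almost exactly once the first window has passed; with the
default transfer process agreement stays above 95%.

## Parentage

Locus QC computes, per microsatellite locus: allele frequencies by
counting; observed heterozygosity; expected heterozygosity with the
small-sample correction $n_g/(n_g-1)$ on $n_g$ gene copies; $F_{IS} = 1 -
H_{obs}/H_{exp}$; a Monte-Carlo exact test of Hardy-Weinberg proportions
(alleles permuted among genotypes, the conditional probability of the
genotype table as statistic, $10^4$ permutations under a fixed seed); and
the Brookfield (1996) estimator 1 of null-allele frequency, $r = (H_e -
H_o)/(1 + H_e)$ on the uncorrected $H_e$. Loci with $r$ above
`null_threshold = 0.05` are excluded — on a 24-locus panel with one
null-allele locus this reproduces the "23 retained loci" situation of the
field study.

Paternity uses a trio-likelihood with known mother:

$$\mathrm{LOD} = \sum_{\ell} \ln
  \frac{P(g_o \mid g_m, g_c, \varepsilon)}
       {P(g_o \mid g_m, \varepsilon)},$$

summed over retained loci, with missing loci contributing 0. The error
model is a single per-allele mistyping rate $\varepsilon \in (0, 0.5)$
applied to the offspring's observed alleles: an observed allele equals the
true one with probability $1-\varepsilon$ and is otherwise a random draw
from the locus allele frequencies. Restricting the error to the offspring
keeps the likelihood a small closed form; mistyped *parents* are absorbed
by the mismatch tolerance below. The unit test checks the locus likelihood
against a full enumeration over parental transmissions.

Candidates are all genotyped adult males, including extra-party males. The
best candidate's $\Delta$ (LOD gap to the second-best) is compared with
critical values from `sim_cycles = 10000` simulated paternity tests
(parents drawn from the allele frequencies, Mendelian offspring plus the
error model, true father sampled with probability `prop_sampled = 0.9`):
the strict level demands 95% simulated correctness above the critical
$\Delta$, the relaxed level 80%. An assignment is *accepted* only under the
strict criterion with at most one mismatched locus. Mothers are verified
first: a genotyped mother-offspring pair with more than
`max_maternity_mismatches` mismatching loci is a hard error. The default
tolerance of 0 is the strict field criterion; on genotypes that carry
typing error it should be raised to 1, in line with the trio rule's
one-mismatch tolerance. Offspring without genotypes are imputed to the mother's
primary male at conception (birth date minus `gestation_days = 184`, a
configurable assumption: published accounts of this population do not
report one),
mirroring the high within-unit paternity certainty (91.7%) of the study
population. Yearly sired-offspring counts attribute each offspring to its
accepted or imputed father in the birth year; extra-party fathers count
toward no study male.

## Models

Three confirmatory analyses and one post hoc analysis, all with year and
party as centred dummy-coded fixed controls and all covariates z-scored
(DSI is log-transformed first, adding half the smallest positive value
because zeros exist — the handling of zeros is not printed in the source
analyses and is exposed as a documented constant):

1. **Coalitions ~ DSI** (dyad-year level): Poisson, log link, log dyad
   contact hours as offset; random intercepts for both male identities and
   the dyad, and uncorrelated random slopes of the index within both male
   identities. The year-dummy random slopes of a fully maximal structure
   are omitted from the pipeline default: on synthetic data they fit
   singular, leave the index estimate unchanged to three decimals, and
   multiply runtime severalfold; the full structure can still be fitted by
   passing an explicit formula to `fit_glmm()`.
2. **Unit-size mode ~ bond strength + number of strong bonds** and
3. **Sired offspring ~ bond strength + number of strong bonds** (male-year
   level): Poisson, log link, male random intercept with an uncorrelated
   bond-strength slope. The z-scored presence-day count enters as a fixed
   control — the field analysis controlled for presence time in all
   analyses without printing the mechanism, and a yearly *mode* response
   admits no exposure offset.
4. **Post hoc: affiliation proportion ~ unit size** (male-year level): beta
   error structure with logit link (glmmTMB), male random intercept. The
   response is squeezed off the boundary with
   $x' = (x(N-1) + 0.5)/N$ before fitting, so 0 maps to $0.5/N$ and 0.5 is
   a fixed point. The coefficient table is additionally reported with
   overdispersion-adjusted standard errors,
   $SE_{adj} = SE\sqrt{\hat\phi}$, $z = \hat\beta/SE_{adj}$,
   $p = 2\,\Phi(-|z|)$.

Poisson models are fitted by maximum likelihood with lme4's adaptive
Laplace approximation and the bobyqa optimizer (deterministic given the
data); beta models with glmmTMB. Every model carries the same validation
suite: a likelihood-ratio test of the full model against a null holding
only the controls and the random structure (avoiding cryptic multiple
testing), per-predictor likelihood-ratio tests by single-term deletion,
percentile 95% intervals from a seeded parametric bootstrap, variance
inflation factors computed on the fixed-effects-only linear design
($VIF_j = 1/(1-R^2_j)$), and the dispersion parameter $\hat\phi = \sum
r^2_{Pearson} / \mathrm{df}_{res}$. For the beta family the Pearson
residuals use the full beta variance $\mu(1-\mu)/(1+\phi_{prec})$, since
glmmTMB's raw Pearson residuals omit the precision factor and would make
$\hat\phi$ meaninglessly small. Marginal and conditional $R^2$ for Poisson
models use the trigamma method for the observation-level variance
($\psi_1(\lambda)$ at the fixed-effects mean count); they are reported, not
tested quantitatively. Non-convergence and boundary cases (such as an
all-zero count response, whose log-link intercept sits at $-\infty$) are
flagged on the returned object.

`inference_suite()` defaults to 1000 bootstrap draws, a standard size for
stable percentile intervals. The *pipeline* default is 25 draws per model — a deliberately small quick-look size chosen so a default
end-to-end run completes in a few minutes; increase `n_boot` in
`pipeline_config()` for publication-grade intervals.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, not
the animals themselves:

* **Community**: 2 parties of 15 focal males and 20 adult females
  (plus 19 genotyped extra-party males, giving the study's 49 candidate
  fathers), observed over 4 calendar years with ~110 contact sessions per
  party-year of mean 4.5 h — about 1980 contact hours per party, matching
  the scale of the field study. Some adults arrive late or leave early, so
  presence varies as in a real census.
* **Affiliation**: a latent log-normal dyadic affinity $a_{xy}$ with mean 1
  (sdlog 1.6) multiplies all affiliative rates of a dyad. The sdlog was
  chosen from the model: $P(a > 1) = \Phi(-\sigma/2) \approx 0.21$,
  matching the right-skewed field distribution in which about a fifth of
  dyads sit above the party average. Baseline focal-hour rates (groom
  0.12/h, contact-sit 0.15/h, approach 0.4/h per dyad) are free parameters
  documented in the configuration, not claims about the field data — the
  source reports no raw rates; they are set so the median dyad has a
  handful of focal events per year, i.e. a small but mostly positive median
  index, as in the field.
* **Observation model**: the underlying event process is thinned to focal
  records with probability $\min(1, 2\varphi)$ per event, where $\varphi =
  0.03$ is each male's focal coverage of party contact time (the field
  study's ~1550 focal hours against ~3900 contact hours imply a similar
  fraction). Grooming is additionally recorded ad libitum with probability
  0.3, aggression always, mirroring the recording protocol. A quarter of
  recorded affiliative bouts are preceded within 10 s by an approach, so
  the redundancy filter is exercised on realistic input.
* **Trade-off**: each male's affiliative rates carry a factor
  $\exp(\gamma\,u_m(t))$ with $u_m(t)$ his current unit size and $\gamma
  \le 0$ (default $-0.2$), mapping directly onto the log-link models. With
  $\gamma = 0$ affiliation is independent of unit size (tested as a flat
  regression slope); with $\gamma < 0$ the generated data reproduce the
  qualitative trade-off.
* **Units and paternity**: females hold a primary male (weights drawn from
  a sparse Dirichlet so unit sizes range from 0 to ~6 with a yearly-mode
  average near 1), transfer rarely (0.001/day), and give birth at a daily
  rate tuned to ~40-50 infants per study; an offspring's father is the
  mother's primary male at conception with probability 0.917 (the study's
  printed within-unit paternity certainty), otherwise a random other male
  (rarely an extra-party male). 72% of infants are genotyped, as in the
  field study (36 of 50).
* **Genotypes**: 24 loci with 2-7 alleles (mean ~4), Dirichlet allele
  frequencies, Mendelian inheritance, optional per-allele mistyping and
  optional null alleles (a null heterozygote appears homozygous; a null
  homozygote appears missing).

One master seed is split into per-component sub-streams, so adding a
component does not perturb the others and a fixed seed reproduces the whole
dataset byte for byte.

What passing tests on this generator do *not* show about real data: the
generator has no temporal autocorrelation in behaviour beyond the unit
process, no observer effects, no seasonality, no greeting rituals,
infanticide, predation or spatial structure, and its affinities are static
over years. Recovery results are therefore statements about the method
under the stated model, not about field inference quality.

## Problem sizes used in validation

The validation suite runs at sizes chosen to exercise the methods at the
study's scale: index and bond oracles on 10-male parties; parentage
recovery on 49 candidates x 23 loci x 36 offspring, with 20 replicate
studies for the error and QC checks (1000 confidence-simulation cycles per
replicate; the pipeline default is 10000); count-model recovery on 200
simulated male-year tables of n = 92 with a true bond-strength effect of
-0.75, with percentile-bootstrap coverage (249 draws, fast penalized-least-
squares fits) evaluated on 100 replicates against the nominal band with an
explicit Monte-Carlo allowance; and two full default-configuration pipeline runs compared byte
for byte.

## Known limitations

* The unit-assignment rule is a plausible formalisation, not the original
  unpublished procedure; its window and hysteresis are configuration, not
  estimates.
* The trio-likelihood error model places mistyping on the offspring only;
  highly error-prone parent genotypes would be handled solely by the
  one-mismatch tolerance.
* The beta model is fitted at male-year level; exact replication of the
  source coefficient tables is not attempted anywhere (different optimizer
  and data), only sign, significance pattern and parameter recovery.
* Marginal/conditional $R^2$ values are descriptive output without
  guarantees for models with heavy random-slope structure.
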