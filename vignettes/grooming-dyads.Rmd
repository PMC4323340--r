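---
title: "Methods: dominance, friendship and dyadic grooming models"
author: "dyadgroom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dominance, friendship and dyadic grooming models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadgroom)
```

## The problem

Allogrooming is the most conspicuous affiliative behavior of group-living
primates, and who grooms whom carries information about the forces that
structure a social group: maternal kinship, the dominance hierarchy, dyadic
"friendship", and the exchange of grooming for grooming or for rank-related
commodities such as feeding tolerance. `dyadgroom` implements the complete
quantitative chain used to analyze grooming distribution in a troop of
adult female macaques observed by focal continuous sampling (30-minute
follows) combined with instantaneous scan sampling (2-minute intervals):

1. dominance statistics from a displacement matrix;
2. directed grooming, aggression and scan-based affiliation measures;
3. an asymmetric contact-based friendship index;
4. crossed-random-effects linear mixed models on directed dyads;
5. a focal-sampling simulator with known ground truth, so that every stage
   has a parameter-recovery test.

## Dominance hierarchy statistics

Displacements (one animal drives another from a resource and the displaced
animal accepts the subordinate position) are tabulated into a square
sociometric matrix per season, with entry $(i,j)$ the number of times $i$
displaced $j$.

**Dyadic dominance index corrected for chance.** For a dyad with
$n_{ij} = w_{ij} + w_{ji} > 0$ interactions and win proportion
$P_{ij} = w_{ij}/n_{ij}$,

$$D_{ij} = P_{ij} - \frac{P_{ij} - 0.5}{n_{ij} + 1},$$

which shrinks the observed win proportion towards 0.5 in small samples.
Dyads never observed interacting ("unknown" dyads) are assigned the
no-information value $D_{ij} = D_{ji} = 0.5$. This convention keeps David's
scores defined in matrices with unknown relationships, which real female
hierarchies regularly contain.

**David's scores.** With $w_i = \sum_j D_{ij}$,
$w2_i = \sum_j D_{ij} w_j$, $l_i = \sum_j D_{ji}$ and
$l2_i = \sum_j D_{ji} l_j$,

$$DS_i = w_i + w2_i - l_i - l2_i, \qquad
  NDS_i = \frac{DS_i + N(N-1)/2}{N}.$$

$DS$ sums to zero; $NDS$ lies in $[0, N-1]$ with mean $(N-1)/2$ and is the
cardinal rank value used by everything downstream. Individuals are ranked
by descending NDS; exact ties are broken lexicographically by id and
flagged.

**Steepness.** The absolute OLS slope of NDS against the descending rank
positions $1..N$. A fully decided linear hierarchy has steepness 1
($NDS = (2,1,0)$ on positions $(1,2,3)$ for $N=3$); equal scores give 0.
The randomization test redraws each observed dyad's wins as
$\mathrm{Binomial}(n_{ij}, 0.5)$, recomputes $D_{ij}$, NDS and steepness,
and reports the one-tailed proportion of null matrices at least as steep as
observed. Unknown dyads stay at 0.5 under the null, matching their
treatment in the observed statistic.

**Linearity.** "$i$ dominates $j$" means strictly more wins than losses in
the dyad. With $V_i$ the number of individuals $i$ dominates, Landau's
index is

$$h = \frac{12}{N^3 - N} \sum_i \left(V_i - \frac{N-1}{2}\right)^2 .$$

The improved index $h'$ handles unknown and tied dyads by resolving each
with a fair coin in every replicate and averaging $h$ across replicates.
For the reported $h$ we award 0.5 to each member of a randomized dyad, so
that $h' = h$ exactly when none exist, and in expectation
$h' = h + 6u/(N^3 - N)$ with $u$ randomized dyads — a relation the test
suite verifies against exhaustive enumeration of all $2^u$ resolutions for
small matrices. The p-value is the proportion of fully random dominance
matrices (every dyad a fair coin) with $h \ge h'$.

**Directional consistency.** $DCI = \sum (H - L) / \sum (H + L)$ over
observed dyads, where $H$ and $L$ count the dyad's more and less frequent
direction; unknown dyads are excluded.

Randomization defaults are 10,000 replicates, one-tailed (right),
p reported as the plain proportion, and every test takes a seed so the same
seed reproduces the same p exactly.

## Affiliation measures

**Grooming acts.** A grooming act is terminated only when it stops for at
least 20 s. Recorded segments of the same directed pair in the same focal
session merge into one act while gaps are under 20 s; act duration is the
sum of segment lengths, so within-act pauses are not counted as grooming
time and merging conserves total recorded time.

**Directed rates.** The grooming rate of $A \to B$ in a season is the
number of acts divided by the *combined* focal hours of the two
individuals, and grooming time is minutes per combined hour. The combined
denominator reflects that a directed interaction is observable whenever
either member is focal. Aggression rates are computed the same way;
the model covariate "aggression received" for the row $(A,B)$ is the rate
of aggression $B \to A$.

**Scan-based time.** Each scan in a state contributes `scan_interval`
minutes; the two focal perspectives of a dyad are summed, giving symmetric
contact and proximity matrices. The co-provisioning percentage is 100
times the dyad's co-provisioning scans over all scans in which either
member was focal — a sampling-level reading of "percentage of time", which
we flag as an interpretation.

**Friendship.** The friendship of $A$ toward $B$ is

$$F(A,B) = \frac{x_{AB}}{\frac{1}{N-1}\sum_{k \ne A} x_{Ak}},$$

with $x$ the contact-minute matrix: the time $A$ spends in contact with
$B$ relative to $A$'s average contact time with all other females,
zero-contact partners included in the average. The index is deliberately
asymmetric — $F(A,B) \ne F(B,A)$ because the two row means differ — and
every row with positive contact averages exactly 1. Contact is the default
basis; proximity-, approach- and grooming-based variants are available and
their Spearman correlations can be tabulated per season
(`friendship_correlations()`), since all four are expected to be positively
correlated.

## The dyadic grooming model

The model table has two rows per dyad and season ($A{\to}B$ and $B{\to}A$;
$N(N-1)$ rows per season, 272 for 17 females). The response is
$\log(\text{rate} + \delta)$ or $\log(\text{time} + \delta)$; by default
$\delta$ is half the smallest positive observed value of that response,
recorded in the fit metadata. Nine fixed effects enter: age difference,
kinship (reference *kin*), cardinal rank distance
$|NDS_A - NDS_B|$, relative rank of the groomer (reference *dominant*),
friendship $F(A,B)$, grooming received (the raw reverse-direction
measure), co-provisioning percentage, aggression received and season
(reference first season). Groomer and groomee identities are crossed
random intercepts; fitting is delegated to `lme4::lmer` (REML).

Confidence intervals are Wald, $b \pm 1.96\,\mathrm{SE}$ — closed-form and
reproducible, at the price of being slightly narrower than profile or
bootstrap intervals. A term is flagged significant when its CI excludes
zero, and model significance is a likelihood-ratio test (ML refits)
against the intercept-plus-random-effects null.

Because the response is logged, a coefficient $b$ multiplies the expected
response by $e^{b\Delta}$ per $\Delta$ units of the predictor;
`effect_interpretation()` reports $(e^{b\Delta} - 1) \cdot 100$ rounded to
the nearest integer ("71% lower" for $b = -1.222$, "22% higher" for
$b = 1.959$ at $\Delta = 0.1$).

The rank-distance split partitions the pooled two-season table at its mean
rank distance (strictly above = high subset) and refits both subsets,
asking whether grooming reciprocation and rank-related exchange differ
between dyads close in rank and distant in rank. A factor that is constant
within a subset (e.g. season in a single-season table) is dropped from
that fit with a message.

## The synthetic focal-sampling study

The generator emulates the observational design of a semi-free-ranging
Barbary macaque troop: 17 adult females (ages 3–26) in six matrilines of
sizes 4, 3, 3, 3, 2, 2 — all within-matriline pairs are maternal kin —
observed for 15.5 focal hours per female per season over two seasons, in
30-minute sessions with 2-minute scans (31 sessions per female per season;
the focal budget is met exactly).

Ground truth consists of a latent linear hierarchy in which matrilines
hold contiguous rank blocks (nepotistic rank inheritance), and a symmetric
log-normal dyadic affinity with a kin bonus (0.7 on the log scale), decay
in scaled rank distance (1.5) and dyadic noise (SD 1.0). The affinity SD
is deliberately large: row-normalizing affinity the same way the
friendship index normalizes contact gives true friendship values spanning
roughly 0–6, the strongly differentiated relationship structure reported
for real female macaques. Feeding tolerance (which drives co-provisioning
scans) shares the kin/rank structure of affinity at half strength but has
its own dyadic noise — tolerance at a food source is a related but
distinct construct from body-contact affinity, and giving it independent
variation prevents the co-provisioning covariate from acting as a second
measurement of friendship.

Directed grooming acts per season are Poisson with log rate

$$\log \lambda_{A \to B} = \beta_0 + \beta_{kin}\,\mathrm{kin}
 + \beta_{sub}\,[A \text{ subordinate}] + \beta_{friend} F_{true}(A,B)
 + d_{AB} + a_A + r_B,$$

with exposure the pair's combined focal hours, a *symmetric* dyadic effect
$d_{AB}$ (SD 0.3) inducing reciprocity, and actor/receiver effects (SD 0.3
each). Act durations are exponential with mean 4.6 minutes. Defaults
($\beta_0 = -3.7$, $\beta_{kin} = 0.6$, $\beta_{sub} = 0.6$,
$\beta_{friend} = 0.4$) calibrate the pooled output to about 0.17 grooming
acts and 0.8 grooming minutes per focal hour per partner, the rates
observed in the emulated study design; the bout mean is their ratio
(0.79/0.17 ≈ 4.6 min). Displacements arrive at 0.12 events per dyad per
combined hour (roughly 500 interactions and a handful of unknown dyads per
season) and are directed down the latent hierarchy with probability 0.985,
which reproduces directional consistency indices near 0.97. Aggression is
directed within dyads at a baseline of 0.04 events per combined hour,
increasing with affinity (log-slope 0.5), so that spatially associated
dyads both groom and fight more — the association reported in tolerant
macaques. Scans record at most one state per sample (contact 10%,
proximity 12%, co-provisioning 4% of scans in expectation), with the
partner drawn proportional to affinity (tolerance for co-provisioning).

Every stage draws from its own RNG stream derived from the master seed by
a fixed offset, so identical configurations reproduce byte-identical logs
and adding a behavior never shifts existing draws. Within-session event
times are uniform; no downstream statistic uses within-session timing
except the 20-second bout rule, which the generator respects by spacing
the acts of a directed pair at least 21 s apart.

What the generator does *not* emulate: males and immatures, seasonal
reproduction, within-season rank changes, tourist disturbance,
observer effects, and any within-day temporal structure of behavior.
Passing recovery tests therefore show that the chain correctly recovers
structure *of the kind it models*, not that real field data meet the
model's assumptions.

## What parameter recovery can and cannot show

With the default conditions and generative effects
$\beta_{friend} = 0.4$, $\beta_{sub} = 0.6$, the full pipeline — simulate,
estimate the hierarchy from displacements, estimate friendship from scans,
assemble, fit — recovers the *signs* of the friendship and relative-rank
coefficients in essentially every simulated troop (the acceptance script
computes the observed rates).

Nominal CI *coverage* of the generative values is not achieved, and we
document why rather than hide it, because the reasons are instructive
about what the fitted coefficients estimate:

1. the response is $\log(\text{rate} + \delta)$ of a Poisson count at
   about 2.7 acts per directed dyad-season, and
   $\mathbb{E}[\log(y + \delta)]$ is an attenuated function of the
   generative log rate at such counts (slope ≈ 0.88 at these conditions);
2. the grooming-received covariate shares the symmetric dyadic effect and
   the (nearly symmetric) friendship value with the response, so
   conditioning on it absorbs part of the marginal friendship and rank
   effects — the fitted model estimates *conditional* effects given the
   partner's grooming, a genuinely different estimand from the marginal
   generative coefficient;
3. scan-estimated friendship carries measurement error relative to
   $F_{true}$ (correlation about 0.9 at the default scan design), which
   further attenuates its coefficient.

The fitted coefficients are therefore systematically closer to zero than
the generative values while retaining their signs — a caution that applies
equally to interpreting effect sizes from real focal data with this model
family.

## Numerical choices and problem sizes

- Randomization tests: 10,000 replicates by default; the test suite and
  acceptance script use 100–4,000 replicates, sizes at which the
  properties under test (calibration bands, enumeration agreement within
  3 Monte-Carlo SEs) are already sharp.
- Calibration experiments use 50–200 replicates and troops of 6–10
  females where the property is scale-free (null false-positive rate,
  CI coverage under a null generator), and the full 17-female two-season
  design where the property is about the study conditions (parameter
  recovery, 20 seeds).
- Ties in NDS are broken lexicographically and flagged; ties and unknown
  dyads in the linearity index are randomized per replicate; a steepness
  or linearity test on fewer than 100 replicates warns, on fewer than 1
  errors.
- Degenerate inputs fail loudly: all-unknown matrices (DCI), all-zero
  responses (log offset), empty split subsets, constant factors, and
  rank-deficient designs each raise a classed error naming the problem.

## Known limitations

- Wald CIs understate uncertainty in small tables (tens of rows); the
  package targets the dyad-table sizes of a full study season.
- The LMM treats log-transformed rates as Gaussian; heavy zero inflation
  at much sparser observation budgets than the default design would call
  for a count model instead.
- $h'$ p-values compare against fully random dominance matrices; no
  continuity correction is applied, so p = 0 simply means "none of the
  replicates reached the observed value".
- The simulator's reciprocity is a static shared dyadic effect, not a
  time-lagged exchange process, so it cannot be used to study the
  *dynamics* of grooming exchange.
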