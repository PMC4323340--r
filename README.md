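# dyadgroom

Who grooms whom, and for what? `dyadgroom` is an R package for analyzing
the distribution of allogrooming among female primates observed with the
classic two-method field design — focal continuous sampling (30-minute
follows with timed events) combined with instantaneous scan sampling
(partner states every 2 minutes). It is aimed at behavioral ecologists
working with dyadic sociometric data from small groups (a dozen to a few
dozen individuals), and implements the full chain from raw observation
logs to fitted dyadic models:

- **Dominance hierarchy** from displacement matrices: dyadic dominance
  indices corrected for chance
  (`Dij = Pij − (Pij − 0.5)/(nij + 1)`), David's scores and normalized
  David's scores (`DS = w + w2 − l − l2`,
  `NDS = (DS + N(N−1)/2)/N`), rank order, hierarchy steepness (|OLS slope|
  of NDS on rank position) and Landau/de Vries linearity
  (`h = 12/(N³−N) · Σ (Vi − (N−1)/2)²`, improved `h′` via random
  resolution of unknown and tied dyads), both with seeded randomization
  tests, and the directional consistency index
  (`DCI = Σ(H−L)/Σ(H+L)`).
- **Affiliation measures**: grooming acts merged under the 20-second
  bout-termination rule, directed grooming rate and time per combined
  observation hour, directed aggression rates, scan-based contact /
  proximity / co-provisioning time, and the asymmetric friendship index
  `F(A,B) = contact(A,B) / mean contact of A with all others`.
- **Dyadic models**: the directed dyad table (two rows per dyad per
  season; 272 rows per season for 17 females), Gaussian linear mixed
  models of log grooming rate/time with nine fixed effects and crossed
  groomer/groomee random intercepts (via `lme4`), Wald CIs, null-model
  likelihood-ratio tests, exp-scale percent-change interpretation of
  coefficients, and the rank-distance split analysis.
- **A focal-sampling simulator** with known ground truth (latent linear
  hierarchy with nepotistic matriline blocks, log-normal dyadic affinity,
  Poisson grooming with kin/rank/friendship/reciprocity effects on the
  log scale), so the entire pipeline has parameter-recovery tests and can
  be exercised with no external data.

See the methods vignette (`vignettes/grooming-dyads.Rmd`) for the models,
conventions and their rationale.

## Worked example

Simulate a troop under the default study design (17 adult females in six
matrilines, two seasons, 15.5 focal hours per female per season), then run
the chain:

```r
library(dyadgroom)
cfg   <- group_config(seed = 2)
grp   <- generate_group(cfg)
study <- simulate_study(grp$roster, grp$truth, effect_config(), cfg)

m1 <- displacement_matrix(study$events, season = "1",
                          ids = grp$roster$individual_id)
dominance_summary(m1, n_randomizations = 1000, seed = 1)
```

```
Dominance hierarchy summary
  17 individuals, 486 interactions, 3/136 unknown dyads
  linearity    h' = 0.935 (h = 0.934, u = 3), p = 0
  steepness    0.706, p = 0
  directional consistency (DCI) = 0.967
  rank order: F05 > F07 > F06 > F14 > F15 > F10 > F09 > F08 > F02 > F01 > F03 > F04 > F12 > F13 > F11 > F17 > F16
```

The hierarchy is near-linear (`h'` close to 1, p = 0: no random matrix
reached it), displacements flow almost entirely down the hierarchy
(DCI 0.97), and only three of the 136 dyads were never observed
interacting.

```r
pipe <- groom_pipeline(study$events, study$scans, study$sessions,
                       grp$roster, n_randomizations = 0)
print(pipe$fit_rate)
```

```
Crossed-random-effects LMM of log(grooming_rate + 0.01613), n = 544 rows
                     term estimate    se ci_low ci_high significant
              (Intercept)   -2.883 0.183 -3.241  -2.524          NA
           age_difference    0.008 0.006 -0.004   0.020       FALSE
           kinshipnon-kin   -0.510 0.116 -0.737  -0.282        TRUE
            rank_distance   -0.021 0.014 -0.049   0.007       FALSE
 relative_ranksubordinate    0.393 0.098  0.201   0.584        TRUE
               friendship    0.214 0.043  0.131   0.298        TRUE
           groom_received    0.651 0.304  0.056   1.246        TRUE
      co_provisioning_pct    0.001 0.091 -0.176   0.179       FALSE
      aggression_received    0.522 0.667 -0.785   1.829       FALSE
                  season2    0.036 0.060 -0.082   0.155       FALSE
Random intercept variances: groomer_id = 0.07936, groomee_id = 0.1077, Residual = 0.4955
Null-model LRT: chisq = 200.68, df = 9, p = 2.39e-38
```

The generator planted kin, relative-rank, friendship and reciprocity
effects; the fit flags exactly those four terms (non-kin dyads groom less,
subordinates groom up the hierarchy, friends and reciprocators groom
more), and the co-provisioning and age-difference controls stay at zero.
Coefficients of the log response convert to percent changes:

```r
effect_interpretation(c(-1.222, -0.012))
```

```
       b delta    percent percent_rounded     label
1 -1.222     1 -70.535970             -71 71% lower
2 -0.012     1  -1.192829              -1  1% lower
```

— a kinship CI of (−1.222, −0.012) means non-kin dyads groom 1% to 71%
less than kin dyads.

A thin command-line wrapper with `simulate`, `dominance`, `affiliation`,
`dyads`, `fit` and `report` subcommands is installed at
`system.file("scripts", "dyadgroom-cli.R", package = "dyadgroom")`.

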