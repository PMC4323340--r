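Package: dyadgroom
Title: Dominance, Friendship and Dyadic Grooming Analysis for Focal-Sampled
    Primate Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analyzing the distribution of allogrooming in small
    primate groups observed by focal continuous and instantaneous scan
    sampling. Computes the full dominance-hierarchy statistic suite from
    displacement matrices (dyadic dominance indices corrected for chance,
    David's scores, hierarchy steepness and Landau/de Vries linearity with
    randomization tests, directional consistency), derives directed grooming
    rates and times with the 20-second bout-termination rule, builds an
    asymmetric contact-based friendship index, assembles directed dyad tables
    and fits linear mixed models with crossed groomer/groomee random effects,
    including exp-scale effect interpretation and rank-distance split
    analyses. A focal-sampling simulator with known ground-truth social
    structure supports end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
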