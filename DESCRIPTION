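Package: pawsway
Title: Centre-of-Pressure Posturography for Quadruped Quiet Standing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for stabilometric analysis of quiet standing in
    quadrupeds measured simultaneously on a force platform and a
    pressure mat. Computes centre-of-pressure (CoP) trajectories from
    force-plate moment channels and from pressure-mat sensel grids,
    derives the four standard postural-stability measures (maximum
    anterior-posterior range, maximum medial-lateral range, sway path
    and 95% confidence-ellipse area), and provides the full
    method-comparison battery: Bland-Altman agreement with limits of
    agreement and proportional-bias trend, Pearson validity
    correlations, and two-way mixed-effects intraclass correlation
    ICC(A,k) with F-based confidence intervals for inter-trial
    reliability. A synthetic quiet-stance cohort generator renders
    paired device recordings from a shared first-order autoregressive
    sway model, with configurable demographic effects of age and body
    weight on the stability measures, so every stage of the pipeline
    is testable without access to animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
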