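Package: antestiarisk
Title: Temperature-Driven Infestation Risk Mapping for the Coffee Antestia Bug
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stage-structured thermal life-table simulation and infestation
    risk mapping for the antestia bug (Antestiopsis thunbergii), a pest of
    Arabica coffee on east African elevation gradients. Provides
    temperature-response functions for each life stage, life-table parameters
    at constant temperature (GRR, R0, T, Dt, rm, lambda), three annual risk
    indices computed from daily minimum/maximum temperature series (the
    establishment risk index ERI, the generation index GI and the activity
    index AI), thin-plate-spline interpolation of station indices over a
    digital elevation model with elevation as a covariate, an
    overdispersion-corrected Poisson regression of farm survey counts on
    elevation and season, paired Wilcoxon signed-rank comparisons of current
    versus future indices by elevation band, and a synthetic-data generator
    that reproduces the statistical structure of the Mt. Kilimanjaro transect
    study design so the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
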