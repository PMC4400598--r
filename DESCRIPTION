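Package: gcorient
Title: Oriented Granulosa-Cell Division and Ovarian Follicle Census Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the orientation of mitotic granulosa-cell divisions around
    the oocyte in annotated ovarian follicle sections. Builds the oocyte-basal-membrane
    axis and the mitotic spindle axis from point annotations (metaphase plates or
    separating anaphase chromatid masses), scores the division angle theta in
    [0, 90] degrees, and tests the angle distribution against a uniform null with
    one-sample and two-sample Kolmogorov-Smirnov machinery (asymptotic series and
    exact Durbin/Marsaglia small-sample p-values). Group comparisons use a
    Mann-Whitney test with the Hodges-Lehmann shift estimate and its
    distribution-free confidence interval. Also implements the companion ovarian
    follicle census: Pedersen-Peters stage classification, one-in-five serial-section
    counting, and Welch group comparisons, plus mating-pair fertility summaries. A
    synthetic-annotation generator plants known division angles, per-stage follicle
    counts and fertility records with full seed control, so every stage of the
    pipeline is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
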