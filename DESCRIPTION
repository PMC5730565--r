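Package: parkdays
Title: Social-Media User-Days for Protected-Area Visitor Monitoring
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates visitation to national parks and other protected areas
    from geotagged social-media posts. Posts are assigned to park polygons by
    containment plus a metric buffer, deduplicated into social-media user-days
    (SUD; one count per user, park, calendar day and platform), and aggregated
    into monthly and annual series. Provides the evaluation statistics used to
    benchmark SUD against official visitor counts: Spearman popularity ranking,
    monthly-proportion standardisation with Pearson pattern correlation,
    ACF/PACF autocorrelation screening of short monthly series, and
    cross-platform comparison via Kruskal-Wallis with Dunn's post hoc test and
    Holm-Sidak adjustment. Includes a seeded synthetic-data generator that
    emulates seasonal visitation, platform adoption and participation
    inequality, so the whole pipeline is testable without access to restricted
    platform data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    polyclip,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    sp,
    withr
biocViews: Spatial, TimeCourse, DataImport
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
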