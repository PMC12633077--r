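Package: rhythmr
Title: Cosinor Rhythmometry for Cross-Sectional Circadian Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-cosinor rhythmometry for cross-sectional circadian
    designs: ordinary-least-squares fitting of MESOR, amplitude and
    acrophase at a fixed period, the zero-amplitude F-test for rhythm
    detection, Wald-type between-group comparison of rhythm parameters
    with circular handling of acrophase, and population-mean cosinor by
    averaging of linearized coefficients. A pipeline applies the analysis
    per feature across a long-format cohort table and renders a
    publication-style rhythm table with Benjamini-Hochberg adjusted
    p-values, with companion per-timepoint t-tests. A microbiome stage
    turns taxon count tables into rank-aggregated relative abundances,
    runs per-taxon rhythm analysis, and provides Bray-Curtis and
    PERMANOVA community-level testing. Seeded generators simulate
    cosinor cohorts and Dirichlet-multinomial communities with
    oscillating taxa so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
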