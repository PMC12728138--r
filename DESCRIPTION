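Package: erplatency
Title: Dynamic Template Matching for ERP Component Latency Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts subject-level event-related potential (ERP) component
    latencies, with a focus on the P3, by fitting a dynamically transformed
    grand-average template to each subject's waveform. The template is scaled
    along the amplitude axis and stretched along the time axis (spline
    interpolation); the optimal stretch factor recovers the subject's latency
    as a multiple of the grand-average latency. Provides the distance
    (MINSQ) and weighted-correlation (MAXCOR) objectives with configurable
    weighting windows and tapers, an extreme-stretch penalty, a
    weighted-correlation fit statistic for screening poor matches, classical
    peak and fractional-area latency extractors (including two
    relative-baseline variants), a latency-shift parameter-recovery
    simulation, absolute-agreement intraclass correlation and two-part
    split-half alpha, and a synthetic-ERP generator for validation.
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
    lhs,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
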