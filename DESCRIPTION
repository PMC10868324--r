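Package: deltamin
Title: Refined Canonical DNA Minimizers via a Strand-Decision Delta Operator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Standard and refined canonical DNA minimizer selection under
    pluggable total orders (lexicographic or seeded random). The refined
    scheme computes a window composition statistic delta = pT + pG - pC - pA
    and scans only the strand on which delta is positive, which keeps
    selection strand-symmetric while reducing the repeated selection of the
    smallest k-mers. Includes rolling delta updates for streaming, a
    solo-window skipping heuristic, evaluation statistics (density, k-mer
    frequency percentiles, Kullback-Leibler divergence against the uniform
    k-mer distribution, expected hits, expected per-type occurrence), an
    analytic operation-cost speedup model, and random-sequence simulators
    for verifying the scheme's limit properties.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
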