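Package: rosrenew
Title: Kinetics and Hit Calling for Pulse-Chase Rod Outer Segment Renewal Screens
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for stripe-based (pulse-chase) screens of rod
    photoreceptor outer segment renewal in larval zebrafish. Decomposes the
    position of a heat-shock-induced fluorescent stripe into post-induction
    growth and shedding rates, pools week-matched vehicle controls into
    benchmarks, fits per-week random-intercept mixed models (rods nested in
    fish) by restricted maximum likelihood, performs Dunnett many-to-one
    comparisons against the weekly control with quasi-Monte-Carlo adjusted
    p-values and Satterthwaite degrees of freedom, and applies combined
    biological (percent-change) and statistical thresholds to call hits
    across five content areas. Includes a hierarchical synthetic-screen
    generator with known ground truth so the full pipeline can be validated
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    mvtnorm,
    jsonlite
Config/testthat/edition: 3
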