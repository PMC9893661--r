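Package: rehabcua
Title: Cost-Utility Analysis of Seven-Days-Per-Week Acute Stroke
    Rehabilitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Markov cohort cost-utility model comparing a 7-days-per-week
    acute-stroke rehabilitation schedule against the conventional
    5-/6-days-per-week schedule under the Japanese public healthcare and
    long-term-care payer perspectives. Simulates monthly occupancy of three
    modified Rankin Scale (mRS) states from month 3 to the end of the time
    horizon, calibrates state-specific mortality risk ratios and a
    first-year recovery probability against life-table-anchored survival
    targets, prices acute-stage rehabilitation from the national fee
    schedule with time-windowed surcharges, maps disability grades to
    long-term-care needs levels and costs, and reports discounted costs,
    QALYs and incremental cost-effectiveness ratios with full
    deterministic and probabilistic sensitivity analysis and scenario
    runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
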