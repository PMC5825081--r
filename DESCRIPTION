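Package: dbcahe
Title: Dual Boundary Classification for Acute Hypotensive Episode Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts acute hypotensive episodes (AHE) from minute-sampled
    vital-sign time series using a dual boundary classifier: an interval
    margin (mu_A + kappa*sigma_A, mu_NA - kappa*sigma_NA) learned from
    per-patient observation-window means splits the feature space into an
    AHE region, a non-AHE region and an uncertainty region, where a
    closed-form squared-deviation distance rule decides. Supports offline
    cross-validated fitting and an online predict-then-update mode built on
    incremental (Welford) mean/variance recurrences, the [O,P,T]
    observation/prediction/test window protocol, sliding-window AHE event
    detection, cohort filters, a seeded synthetic ICU cohort generator, and
    sensitivity/specificity evaluation over window-parameter grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
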