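Package: tojreplay
Title: Reaction-Time Analysis of Time-Compressed Memory Replay in
    Temporal-Order Judgement Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for temporal-order judgement (TOJ)
    reaction-time experiments designed to detect serial, time-compressed
    forward replay of encoded video episodes. Provides LATER
    (Linear Approach to Threshold with Ergodic Rate) rise-to-threshold
    model fitting with shift-versus-swivel BIC model comparison,
    representational similarity analysis of segment-wise reaction-time
    patterns against an offset-parameterised family of replay models with
    bootstrap Spearman inference, reciprocal-latency regression and
    polynomial trend tests, derived behavioral statistics (replay
    compression factor, clip-wise contrasts, inverse efficiency scores),
    perceptual image-similarity metrics, and a synthetic trial generator
    reproducing the factorial task design so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    png,
    optparse
Config/testthat/edition: 3
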