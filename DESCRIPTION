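Package: clawbench
Title: Claw-Health Benchmarking for Dairy Herds from Hoof-Trimming,
    Locomotion and Culling Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds percentile-band claw-health benchmarks for dairy herds
    from four routinely recorded data streams: hoof-trimming lesion records
    coded with an ICAR Claw Health Atlas style vocabulary, five-point
    locomotion scorings, herd rosters and culling records. Provides validated
    ingestion with a machine-readable rejection ledger, weighted Cohen's
    kappa interobserver-reliability gating of recorders, per-herd key
    performance indicators (lameness incidence risk by threshold and cow
    group, incidence risks of 13 claw-lesion groups, painful 'alarm' lesion
    incidence, digital-dermatitis endemicity, annual claw/limb culling risk),
    percentile benchmark tables and per-farm comparison reports, plus a
    seeded synthetic-herd generator that emulates the statistical structure
    of routinely recorded dairy data so the whole pipeline can be exercised
    without access to the original records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
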