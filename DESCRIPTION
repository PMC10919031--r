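Package: cbsengine
Title: Community-Based Surveillance Alert Engine and System-Attribute Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for community-based surveillance (CBS) programmes in which
    lay volunteers report coded health signals by SMS. Parses coded reports,
    evaluates community case definition (CCD) alert thresholds including a
    spatiotemporal cluster rule for acute diarrhoeal disease, tracks the
    verification-escalation-closure alert lifecycle in an auditable ledger,
    and computes the standard surveillance-system attribute metrics
    (usefulness, simplicity, data quality, sensitivity proxies, timeliness).
    Includes a synthetic-programme simulator and deterministic fixture
    builders so every metric can be exercised without access to programme
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
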