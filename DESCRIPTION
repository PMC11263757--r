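Package: fixclust
Title: Activity-Cluster Analysis of GPS Telemetry for Field Site-Visit Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forms activity clusters from GPS collar fixes by buffer overlap
    (fixes whose x-meter buffers overlap, i.e. lie within 2x of each other,
    form connected components; components with at least y members become
    clusters), in either the default spatial mode or a consecutive-in-time
    mode. Supports incremental re-analysis that keeps previously issued
    cluster IDs stable while clusters grow, merge, or appear; fix-rate
    regularisation by z-minute subsampling for burst/proximity data; cluster
    attribute tables (locations inside/outside, percent time, mean centers);
    GeoJSON cluster layers with a plain-text settings sidecar; GPX waypoint
    and CSV table export; a static HTML map; and a synthetic-track generator
    with planted stationary bouts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    geosphere,
    igraph,
    mgcv,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
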