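Package: ecoextent
Title: Ecosystem Extent-Loss Accounting and Protected-Area Gap Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for terrestrial ecosystem accounting on categorical
    rasters. Estimates long-term loss in extent of hierarchically
    classified ecosystem types by overlaying potential-distribution maps
    with a composite land-conversion layer fused from multiple land-cover
    products via class crosswalks and majority resampling; categorizes
    types under IUCN Red List of Ecosystems criterion A3; and assesses
    protected-area representation against both potential and current
    extent with CBD Aichi Target 11 reporting. A synthetic-landscape
    generator supplies Voronoi-patch mosaics, conversion layers and
    protected-area networks with known truth so every pipeline stage is
    verifiable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
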