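Package: cultimap
Title: Pixel-Based Cultivated-Land Mapping from Multispectral Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised pixel-based classification of cultivated land from
    4-band (blue, green, red, near-infrared) multispectral digital-number
    rasters. Computes the common vegetation and water indices (NDVI, MNDWI,
    EVI, SAVI, GCI, CVI, DVI), builds normalized per-pixel feature stacks,
    and segments scenes into background, bare soil and crops with a
    from-scratch seeded Lloyd's K-means, alongside NIR-threshold,
    NDVI-threshold and raw-band K-means baselines. Includes area accounting
    (cultivated-area percentage and relative error against a binary ground
    truth mask), a synthetic scene generator with known truth, and a small
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
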