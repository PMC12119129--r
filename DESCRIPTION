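Package: tileforge
Title: On-Demand Deep Zoom Tile Serving for Multiplexed Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts multi-channel microscopy images (TIFF/OME-TIFF) into
    chunked multiscale pyramid stores (NGFF/OME-ZARR layout) and serves Deep
    Zoom Image (DZI) tiles rendered on demand with client-chosen channel
    colors and intensity windows. Per-channel chunking means a tile request
    reads only the chunks of the requested channels, so arbitrarily many
    fluorescence channels can be browsed over low bandwidth through any
    DZI-compatible viewer. Includes a watch-folder ingestion pipeline, a
    deterministic synthetic-fixture generator, and a bytes-transferred
    benchmark harness comparing on-demand tile serving against raw plane
    delivery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    jpeg,
    png,
    tiff,
    xml2
Suggests:
    callr,
    httpuv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
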