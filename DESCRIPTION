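Package: sealscope
Title: Hierarchical Dual-Model Detection Toolkit for UAV Surveys of Spotted Seals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating the two-stage UAV / ground-station
    detection workflow used in spotted seal (Phoca largha) haul-out surveys. The
    package assembles lightweight onboard (FF-YOLOv10) and high-precision
    ground-station (PP-YOLOv7) detector graphs from declarative layer specs with
    exact inference-time parameter accounting, implements the underlying neural
    building blocks (partial convolution, FasterNet blocks, C2f-Faster, focal
    modulation, ELAN variants) as pure array operators, provides a single-class
    detection evaluation stack (greedy IoU matching, precision/recall, average
    precision, weather-stratified false-positive/false-negative reporting), a
    screen-then-verify survey pipeline with count reconciliation, a synthetic
    aerial-scene generator emulating low-contrast mudflat imagery, and readers
    and writers for Pascal-VOC XML and YOLO-format annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    xml2,
    png,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
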