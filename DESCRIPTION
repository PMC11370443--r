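Package: myoquant
Title: Color-Based Detection, Isolation and Quantification of Myocardial
    Infarct and Diffuse Fibrosis in Stained Histological Sections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pixel-wise color-threshold segmentation of myocardial infarct
    regions in scanned histological sections stained with Masson's
    trichrome (MTS), hematoxylin and eosin (H&E), 2,3,5-triphenyltetrazolium
    chloride (TTC) or picrosirius red (PSR), together with whole-section
    tissue masking, artifact exclusion, relative infarct size and physical
    area computation, serial-section volume integration with a
    removed-tissue assumption, a diffuse-fibrosis analyzer for MTS-stained
    sections, a multi-section slide splitter, and a synthetic phantom
    generator with known ground truth for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jpeg,
    optparse,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
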