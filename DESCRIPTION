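Package: samaraflight
Title: Autorotating Samara Descent Analysis with a Coning-Angle Drag Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the autorotating descent of winged Acer
    seeds (samaras). Implements silhouette morphometry (span, chord, plan
    area), a vertical force balance that lumps drag and lift into a single
    coning-angle-projected drag term and estimates an interspecific drag
    coefficient, wing-loading comparison, allometric power-law scaling, and
    reduced-variable analysis of mass-alteration and wing-ablation
    experiments. A seeded synthetic-population generator emulates
    multi-species samara datasets for parameter-recovery testing of every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    png,
    EBImage
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
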