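Package: habitatmapr
Title: Rule-Based Mapping and Validation of IUCN Habitat Types from Raster Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for classifying co-registered raster layers
    (land cover, climate zones, terrain, wetlands and land-use pressure data)
    into the two-level IUCN habitat classification scheme with a sequential
    first-match decision tree, anthropogenic classes taking precedence over
    natural ones. Includes builders for derived pressure masks (pastureland
    from livestock-unit densities, rural gardens, plantation forests, expanded
    wetlands, montane splits), fractional and majority aggregation to coarser
    grids, and an occurrence-record validation module computing per-class
    sensitivity, specificity and balanced accuracy from buffered point and
    polygon matches. A seeded synthetic-world generator produces internally
    consistent input stacks with known ground truth so every stage is testable
    without global datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    caret,
    withr
Config/testthat/edition: 3
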