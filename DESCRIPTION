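Package: smartdesign
Title: Design and Analysis Strategies for Conveyor-Greenhouse Phenotyping Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and evaluation framework for experimental designs in
    conveyor-equipped phenotyping greenhouses (Smarthouses). Generates
    uniformity-trial data with the microclimate structure typical of such
    facilities (west-to-east position trends, south-to-north lane trends with
    shading, optional heterogeneous zone variances and AR1 correlation along
    positions), implements four plant-relocation tactics (bench, same-lane,
    half-lane, next-lane) with exposure accounting, constructs blocked,
    row-column, resolved incomplete-block and (nearly) trend-free designs with
    their restricted randomizations, fits null and treatment mixed models, and
    compares designs by relative precision and by a Monte-Carlo relative
    efficiency criterion based on a modified A-optimality criterion.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
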