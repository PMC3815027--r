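Package: spermfish3d
Title: Quantitative 3D-FISH Analysis of Sperm Nuclear Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the three-dimensional organisation of FISH signals in
    paddle-shaped sperm nuclei from multi-channel confocal stacks: global
    intensity-threshold segmentation with 3D connected-component labelling,
    telomere and centromere cluster counting, object-based colocalization
    classing of chromosome-territory pairs, normalized antero-posterior and
    medio-lateral positioning, territory morphology classing, and the group
    statistics used to compare control animals against heterozygous carriers
    of a Robertsonian 13;17 centromeric fusion. Includes a confocal-like
    synthetic image generator with per-nucleus ground truth for validating
    every stage of the pipeline, and a Mendelian segregation model giving the
    expected territory-proximity proportions in carrier sperm.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
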