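Package: weedsight
Title: UAV-Based Monitoring of Grass Weeds in Wheat Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring graminaceous (grass) weeds in wheat fields
    from UAV imagery: a synthetic scene and field-trial generator that
    emulates the joint RGB / hyperspectral / ground-truth structure of such
    campaigns, reflectance calibration and tiling utilities, an
    encoder-decoder semantic segmenter with atrous spatial pyramid pooling
    for the three-class soil/wheat/weed problem, segmentation and regression
    accuracy metrics, narrowband NDVI band-pair selection and support-vector
    weed biomass estimation from canopy cover plus vegetation indices, and
    descriptive analysis of weed impact on wheat dry weight and grain yield.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    e1071,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
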