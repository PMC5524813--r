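Package: gasphantom
Title: Dissolved-Gas Dynamics and Bubble Analysis in 3D Tissue Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying cell-bubble interactions in cell-seeded
    collagen tissue phantoms exposed to hyperbaric pressure profiles. Includes
    a 3D reaction-diffusion simulator for dissolved oxygen (with
    Michaelis-Menten cellular consumption) and nitrogen over a masked
    cylindrical lattice using an Alternating Direction Explicit finite
    difference scheme; construction of compression/hold/decompression
    pressure schedules; a virtual dissolved-oxygen probe experiment; bubble
    segmentation and tracking in time-lapse images; robust
    exponential-plateau fitting of bubble radial trajectories; nucleation
    counting; live/dead viability bookkeeping; and seeded synthetic-data
    generators with ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    minpack.lm,
    tibble,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
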