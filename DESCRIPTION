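Package: bonemorph
Title: Automated Static, Dynamic and Cellular Bone Histomorphometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated bone histomorphometry from multi-channel fluorescence
    scans of non-decalcified bone sections. Assembles overlapping tile scans by
    k-th law nonlinear (phase-weighted) FFT correlation, registers enzymatic
    stain scans (TRAP, AP) to the mineral/label reference scan with fiducial
    bead landmarks and a least-squares similarity transform, removes
    illumination shading by large-window median subtraction, segments each
    channel with iteratively cascaded Otsu thresholding, extracts and repairs
    the trabecular/cortical surface, selects femoral or vertebral regions of
    interest, projects mineralization labels and cell signals onto the bone
    surface along surface normals, and reports the full static (BV/TV, Tb.Th,
    Tb.N, Tb.Sp), dynamic (labeled surfaces, inter-label thickness, MAR, BFR)
    and cellular (AP, TRAP surface fractions) measurement set. A phantom
    generator produces synthetic sections with exact analytic ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
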