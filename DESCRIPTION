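Package: larvacurv
Title: Larval Body Curvature, Calcium Response, and Connectome Summaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies Drosophila larval body posture during nocifensive
    escape from thresholded silhouette videos: a closed 300-point
    arclength-uniform boundary is extracted per frame, a signed curvature
    index (the reciprocal circumradius of each point and its two flanking
    neighbors, signed by a midpoint in/out-of-outline test) is computed at
    every boundary point, boundary points are aligned across frames by
    minimizing summed squared displacement to build curvature kymographs,
    and concave curvature is summarized per animal as the percentage of
    low- versus high-curvature boundary points for group comparison.
    Companion analyses cover ratiometric calcium imaging (lowest-decile and
    pre-stimulus baselines, asynchronous probe-temperature interpolation and
    binning) and connectome edge-list summaries (per-class input fractions,
    top-hit outputs, bounded-depth pathway enumeration). A synthetic-data
    module generates larval silhouette scenes, thermal-ramp fluorescence
    traces, and toy connectomes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    igraph,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv
Config/testthat/edition: 3
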