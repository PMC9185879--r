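Package: rootmorph
Title: Three-Dimensional Morphometry and Diagnostics for Conical Tooth Roots
Version: 0.1.0
Authors@R: person("M.", "Keller", email = "mkeller@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative assessment of single-root tooth morphology
    from triangle-mesh surface models, as used in cone-beam computed tomography
    (CBCT) studies of root abnormalities. Generates synthetic tooth meshes with
    quadrature ground truth; computes root length, root surface area and root
    volume by splitting closed meshes at the cemento-enamel junction plane with
    exact cap accounting; implements the periapical root-width parameter (PRW)
    construction; provides ROC/AUC diagnostics with Youden-optimal cut-offs,
    2x2 accuracy metrics, intraclass correlation and two-group sample-size
    calculations; and builds registered mean shape models with signed
    surface-distance colour maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
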