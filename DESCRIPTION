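Package: triplexkit
Title: Modelling and Stability Metrics for GAA/TTC Triple Helices and
    Collapsed R-Loops
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Enumerates the non-equivalent DNA and DNA.RNA:DNA triple
    helices that can be assembled from GAA and TTC trinucleotide-repeat
    strands, builds idealized atomic models of them (and of A/B-form
    duplexes), and scores single conformations or multi-model PDB
    trajectories with third-strand stability metrics: the effective
    hydrogen-bond number, the effective pi-pi stacking area, per-plane
    hydrogen-bond pattern classification, base-pair step parameters,
    Zp-based A/B-form classification, base-step overlap areas and triplex
    groove widths.  Includes a generator of labelled synthetic
    trajectories (stable, detaching, base-flipping and stacked-but-
    detached scenarios) so that every analysis stage can be exercised
    without molecular-dynamics input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
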