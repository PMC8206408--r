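Package: lgnencoder
Title: Visual Encoding Models of Thalamic LGN Spiking Activity
Version: 0.1.0
Authors@R:
    person("LGN", "Encoder Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating visual encoding models of
    lateral geniculate nucleus (LGN) neurons at millisecond resolution:
    binary stimulus generators (single-pixel, balanced checkerboard,
    geometrical shapes, full-field), a linear-nonlinear-Poisson population
    simulator with controllable ON/OFF and transient/sustained phenotypes,
    spike detection and PCA/K-means sorting, firing-rate binning and PSTHs,
    responsiveness and receptive-field characterization via spike-triggered
    averaging, a dual-branch temporal convolutional firing-rate encoder with
    visual and firing-history inputs (plus single-branch ablations), a
    Poisson generalized linear model baseline with spike-history filters,
    and cross-validated correlation-based evaluation including
    checkerboard-to-shapes generalization.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
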