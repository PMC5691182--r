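Package: blowthrough
Title: Continuing Dynamics Through Finite-Time Blow-Up
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Numerical continuation of ordinary and one-dimensional partial
    differential equations through finite-time blow-up. Detects asymptotically
    self-similar approach to infinity on the fly, constructs the matching
    singular transformation (e.g. y = x^(1-p)) whose "good" equation crosses
    zero instead of infinity, and switches regimes so integration proceeds
    past the singularity. For PDEs the transformation is confined to
    adaptively tracked singular buffer regions glued to the regular domain by
    an explicit-interface/implicit-interior scheme, with tracking of the
    propagating infinity-crossing locus. Companion constructions are included:
    circle/sphere compactifications that render infinity a regular point,
    complexified dynamics that regularize real collapse (with closed-form
    orbits, a conserved quantity and transit-time contour integrals), and
    MN-dynamics (co-exploding frame) scaling calculus with empirical
    amplitude/width exponent fits. Integrate-and-fire neuron models without a
    voltage cutoff are the flagship applications.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
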