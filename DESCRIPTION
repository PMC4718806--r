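Package: cryofocus
Title: Masked 3D Classification with Residual Signal Subtraction for
    Single-Particle Cryo-EM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Focused (masked) multi-reference maximum-likelihood
    classification of single-particle cryo-EM images in which the
    CTF-affected projection of the part of the consensus map outside a
    region of interest is subtracted from every particle image before
    classification, so that only the region of interest drives class
    assignment.  Includes MRC2014 and STAR input/output, a ZYZ
    Euler-angle/CTF/Fourier-filter toolkit, Fourier-slice projection and
    direct Fourier (Wiener) reconstruction, soft-mask construction, a
    forward simulator with colored noise and ground-truth bookkeeping,
    FSC-based validation with high-resolution noise substitution, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
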