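Package: satspline
Title: Saturating Splines and Sparse Additive Models by Conditional
    Gradient over Measures
Version: 0.1.0
Authors@R:
    person("satspline", "developers", email = "satspline@example.org",
           role = c("aut", "cre"))
Description: Fits adaptive degree-one regression splines constrained to
    extend as constants outside the data range ("saturating splines").
    The fitting problem is posed as a convex program over signed measures
    on the knot domain, with a total-variation budget and a zero-net-mass
    (saturation) constraint, and solved by a fully-corrective conditional
    gradient method whose linear minimization oracle is exact and linear
    time.  A generalized additive model extension attaches each knot to a
    coordinate and performs simultaneous knot selection and feature
    selection.  Includes squared, logistic and pseudo-Huber losses,
    warm-started regularization paths with duality-gap certificates, a
    synthetic-data generator with known piecewise-linear ground truth, an
    independent gridded reference solver, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
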