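Package: lassopoly
Title: Statistics of Lasso-Shaped Polymers: Threading Probability and Loop Shape
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the statistical study of lasso-shaped polymers: uniform
    sampling of equilateral closed polygons with random-walk tails, threading
    classification by spanning a near-minimal triangulated surface on the loop
    and counting signed tail piercings, estimation of trivial-lasso
    probabilities and piercing spectra with double-exponential decay fits,
    Metropolis Monte Carlo simulation of an excluded-volume bead loop threaded
    by a periodic thread of variable thickness, gyration-tensor shape
    descriptors (radius of gyration, distension, asphericity, prolateness) with
    their scaling-law fits, and a bridge to protein structures with
    disulfide-closed backbone loops.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
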