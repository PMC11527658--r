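Package: callusim
Title: Strain-Based Simulation of Bone Fracture Healing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An iterative mechanobiological simulator of secondary bone
    fracture healing. Couples an axisymmetric linear-elastic finite-element
    model of an osteotomy, its callus and a nonlinear external-fixator spring
    to a fuzzy-logic biological controller in which minimum principal,
    maximum principal and distortional strains drive intramembranous
    ossification, chondrogenesis, cartilage calcification and endochondral
    ossification. Healing outcome is quantified by the inter-fragmentary
    movement history and by a three-dimensional virtual bending test of the
    final construct, discriminating union from non-union.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
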