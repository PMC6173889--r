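Package: etflow
Title: Intrauterine Mixing Flow and Embryo Transport During Embryo Transfer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-volume simulation of the intrauterine flow driven by
    catheter injection during embryo transfer, and of the embryos carried by
    it. The transferred medium and the uterine fluid are modelled as a
    homogeneous incompressible mixture whose composition is tracked by a
    volume fraction; the flow is advanced with a SIMPLE pressure-velocity
    coupling on a rectilinear grid with solid blanking for the catheter,
    including catheter withdrawal as a moving wall. Embryos are tracked as
    inertial spheres with a piecewise empirical (Morsi-Alexander) drag law.
    Post-processing provides the dispersion-pattern contour of the
    transferred medium, embryo transport distances relative to the catheter
    tip, upstream/downstream delivery classification, withdrawal drag-back
    distances, and the injection driving force.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
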