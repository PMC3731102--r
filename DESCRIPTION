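Package: ceph3d
Title: 3D Cephalometric Analysis of Craniofacial Symmetry from Landmark
    Coordinates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies craniofacial symmetry from cone-beam CT (CBCT)
    derived 3D landmark coordinates. Twelve named cephalometric landmarks
    yield 21 inter-landmark distances and 7 diagnostic triangles; the
    apex angle of the condyle-menton triangle is split at the
    inter-condylar midpoint into two semiangles whose difference
    classifies mandibular symmetry, complemented by left-right distance
    ratios, nine mandibular ramus/body ratios, and millimetric
    discrepancy checks. Includes cohort-level aggregation, readers and
    writers for landmark CSV, 3D Slicer FCSV fiducials and JSON, a
    synthetic-skull cohort generator with known ground truth for
    validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
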