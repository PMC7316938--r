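Package: implantdev
Title: Accuracy Analysis for Guided Dental Implant Placement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how accurately dental implants were placed
    relative to a virtual surgical plan. Implements the standard planned-versus-
    placed deviation metrics at the implant shoulder (global, lateral, depth and
    angular deviation via the point A/B/C/D construction), closed-form and
    trimmed iterative rigid point-set registration for aligning pre- and
    post-operative surface scans, principal-axis pose fitting of segmented
    implant point clouds, descriptive and inter-observer agreement statistics
    (two-way absolute-agreement single-measures intraclass correlation), and a
    seeded synthetic-cohort generator that emulates template seating error,
    drill-sleeve wobble and unguided insertion depth so the full pipeline can be
    exercised without clinical data. Includes readers and writers for pose
    tables (CSV/JSON) and implant surface clouds (STL/XYZ/PLY), a Table-1-style
    report writer, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
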