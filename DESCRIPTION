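Package: vmicro
Title: Virtual Microscope Toolkit: Pyramidal Slide Tiling, Collaborative
    Annotation, Practical Exams and Usage Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale toolkit for web-based virtual microscopy teaching
    systems. Converts large single-plane microscopy rasters into pyramidal
    sets of 256x256 JPEG tiles in the standard XYZ slippy-map layout, with
    exact tile-count arithmetic, lossless round trips and level assembly.
    Models the collaborative side of a virtual microscope deployment: slide
    metadata and access tiers, pushpin and image-sequence markers with peer
    voting and score-based removal, free-text tag clouds, yearly course
    resets and a polling change-sync contract. Supports practical-exam mode
    with seeded per-student randomized slide assignment, partial-credit
    grading and CSV grade export, plus the usage analytics a course team
    reports: per-student view statistics, lab-window shares, dwell-time
    estimation from view logs, marker authorship shares, faculty precepting
    hours and a Welch two-sample comparison computed from summary statistics
    alone. Includes seeded synthetic generators for histology-like images,
    view logs, marker stores and exam cohorts so the whole pipeline runs
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, jsonlite, jpeg, png, tiff
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
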