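Package: removalaccess
Title: Facility Readiness and Geographic Access Modeling for
    Contraceptive Implant Removal Services
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for auditing a health system's capacity to provide
    contraceptive implant removal services. Classifies surveyed facilities
    as ready for regular or difficult removals from SARA-style checklist
    data (general service readiness, human resources, minimum equipment),
    builds referral networks from survey-reported referral destinations and
    audits whether receiving facilities can absorb the cases referred to
    them, and models one-way travel time to the nearest ready facility with
    two complementary approaches: a public-transport road-network model
    with Thiessen-polygon neighborhood catchments for urban districts, and
    a walking-plus-road raster cost surface accumulated by multi-source
    shortest paths for rural districts. Includes seeded synthetic-data
    generators for facility surveys and small urban/rural geographies so
    the whole pipeline is testable without confidential survey data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
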