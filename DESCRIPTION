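Package: phcprofile
Title: Regional Health Care Profiles for Primary Health Care Catchment Areas
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates regional health care profiles for envisaged primary
    health care units. Computes car-travel-time isochrone catchment areas on
    a weighted municipality road network, aggregates a 35-indicator health
    and health-service catalogue over the catchment, compares against the
    indicator distribution over political districts (range, quartiles,
    median, national reference, rank), and renders a multi-page printable
    PDF profile. Includes a seeded synthetic country generator emulating
    Austria's scale (2122 municipalities in 116 districts) so the whole
    pipeline is testable without restricted administrative data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
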