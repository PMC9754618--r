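Package: scanpath3d
Title: Expertise Comparison of Sculpture-Viewing Scanpaths Across Multiple Perspectives
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for mobile eye-tracking studies of visual expertise
    with free-standing sculpture. Classifies fixations into global (ambient) and
    local (focal) viewing by a duration threshold, computes switching rates, and
    compares scanpaths between participants with a double-mapping nearest-neighbour
    distance in (x, y, scaled duration) space evaluated per viewing perspective and
    averaged across the eight reference images of a sculpture. Pairwise distances
    are summarised by the divergence of the participants' expertise levels.
    Also provides basic-feature (area-of-interest) coverage and revisit metrics,
    a synthetic fixation-cohort generator with known ground truth for validation,
    and delimited-text readers/writers for fixation tables, AOI polygon sets and
    participant metadata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
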