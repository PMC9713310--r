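Package: mycomaps
Title: Grid-Based Mapping and Analysis of Arbuscular Mycorrhizal Root
    Colonization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative assessment of arbuscular-mycorrhizal
    colonization in roots from grid-coded microscopy fields. Builds
    mycorrhizal maps (one cell per grid position, coded by the fungal
    structure present), computes the standard colonization parameters
    (frequency, intensity, arbuscule/vesicle/spore shares, non-mycorrhizal
    area, colonization degree and derived ratios), classifies colonization
    strategies by intensity and arbuscule/vesicle thresholds, extracts
    representative maps by median ranking and structure maxima, compares
    colonized areas across maps position by position, and fits stepwise
    AIC-selected linear models that forecast later-stage parameters from
    earlier phenophases. A synthetic-study generator emulating a
    variants x replicates x segments x fields microscopy design makes every
    stage testable without raw micrographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    tibble,
    dplyr,
    tidyr,
    rlang,
    yaml,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    MASS,
    vegan,
    ggplot2,
    withr
Config/testthat/edition: 3
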