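Package: switchgrow
Title: Genotype-Specific Switchgrass Growth Simulation and Yield Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A daily-time-step, process-based growth simulator for upland and
    lowland switchgrass (Panicum virgatum L.). Daily weather and a soil profile
    drive a degree-day phenology state machine, a soil-water bucket with
    Campbell retention-curve pedotransfer functions, Beer's-law canopy light
    interception, and temperature- and water-modulated radiation-use
    efficiency, producing leaf area index and dry-matter trajectories,
    winter/drought/frost kill events, and spring-harvestable yield. Includes
    ecotype parameter registries, goodness-of-fit statistics against packaged
    field-trial yield pairs, a synthetic weather and grid generator, and
    per-cell gridded simulation with optimal-ecotype yield mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
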