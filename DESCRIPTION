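Package: flysin
Title: Social Interaction Networks and Behavioral Phenotyping for Drosophila
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds social interaction networks (SINs) from fly trajectory
    tables, detecting directed interaction events by distance, facing-angle
    and minimum-duration criteria, and scores the resulting directed weighted
    graphs with global efficiency, clustering coefficient, betweenness and
    closeness centrality. Observed metrics are normalized to z-scores against
    a chimeric-group null model that reassembles groups from flies drawn
    across recordings of the same condition. Companion modules analyse
    beam-break locomotor data (day/night activity, sleep bouts, free-running
    circadian period via chi-square periodogram), negative-geotaxis climbing
    assays, and glutathione/ROS plate-reader assays, with a group-comparison
    statistics layer (ANOVA/Tukey or Kruskal-Wallis/Dunn). A synthetic-data
    generator with known ground truth drives calibration and recovery tests
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
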