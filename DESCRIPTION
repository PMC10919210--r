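Package: heatscene
Title: Annotated Cluster Heatmaps as Serializable Scenes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A layout engine for richly annotated cluster heatmaps. Builds
    clustered and split heatmaps with annotation tracks on all four sides
    (color bars, bar and stacked-bar plots, boxplots, scatter points, and
    merged evenly-distributed labels with leader lines), dot heatmaps
    encoding up to five variables (row, column, size, color, marker),
    oncoPrint-style alteration grids with mutual-exclusivity sample
    ordering, and multi-panel composites with a governing main panel and
    shared legends. All layout is emitted as a serializable scene of styled
    drawing primitives in normalized figure coordinates, which renders to
    SVG or PNG and is directly testable; hierarchical clustering with four
    linkage methods, three metrics, deterministic tie-breaking and tree-cut
    or metadata splitting is built in.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    grid,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'clustermap.R'
    'composite.R'
    'cli.R'
    'clustering.R'
    'dotmap.R'
    'fixtures.R'
    'io.R'
    'layout.R'
    'legends.R'
    'oncoprint.R'
    'scene.R'
    'render.R'
    'scales.R'
    'tracks.R'
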