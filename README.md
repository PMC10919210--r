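# heatscene

Annotated cluster heatmaps as serializable scenes.

`heatscene` is a layout engine for the figure genomics people actually make:
a clustered matrix (expression, methylation beta values, correlations,
alteration calls) surrounded by annotation tracks on all four sides, split
into panels by metadata or by the clustering tree, with merged and evenly
distributed labels, shared legends, and optionally several such panels
joined into one composite. It is aimed at people who need these figures to
be *reproducible and testable*: every builder resolves the full layout into
a `Scene` — a flat list of drawing primitives (rects, lines, polylines,
texts, markers) in normalized figure coordinates — before anything is
rendered. The scene serializes canonically, so byte equality of two scene
documents is equality of two layouts, and the figure can be checked
mechanically (cell coverage, panel tiling, label placement, legend
completeness) in a test suite. SVG and PNG rendering are thin maps from the
scene.

## What is inside

* **Clustering** — agglomerative linkage (single, complete, average, Ward)
  over euclidean, cityblock or correlation ($d = 1 - r$) distances, with
  pairwise-complete missing handling and a fixed tie rule (the candidate
  pair with the lexicographically smallest node indices merges first), so
  trees are exact and platform independent. Leaf order is a left-first
  traversal; flat clusters come from undoing the top $k-1$ merges.
* **Splits** — rows/columns split by an integer $k$ (tree cut of the global
  tree) or a categorical vector (first-appearance group order, per-group
  re-clustering); panels proportional to group sizes, exact tiling.
* **Tracks** — `annoSimple` (with contrast-colored block text),
  `annoBar` (auto plain/stacked, conserving stacked heights), `annoBox`
  (type-7 quartiles, 1.5 IQR whiskers), `annoScatter`, and `annoLabel`,
  which merges runs of equal adjacent labels and distributes slot centers
  strictly evenly at $L(i-\tfrac12)/m$ with crossing-free 3-segment leaders.
* **Dot heatmaps** — a long-form table drives up to five channels: row,
  column, size (area-linear, $r = r_{max}\sqrt{(v-v_{min})/(v_{max}-v_{min})}$),
  color, and marker shape via hue.
* **oncoPrint** — genes × samples alteration glyphs with the waterfall
  ("memo") sort: genes by frequency descending, samples by descending
  lexicographic binary profile; frequency side-bars with percent text.
* **Composite** — panels joined horizontally/vertically; the main panel's
  row (or column) order and grouping govern every other panel; legends are
  merged and deduplicated.
* **Synthetic generators** — seeded fixtures (grouped normal matrices,
  Bernoulli alteration tables, five-variable dot tables) so everything is
  testable offline.

## Worked example

```r
library(heatscene)

fx  <- makeFixtureMatrix(20, 8, n_col_groups = 2, group_shift = 3, seed = 1)
grp <- annotationColumn(fx$annotation, "group")

fm <- buildClustermap(fx$matrix,
  col_split = unname(grp),                      # metadata split (per-group trees)
  row_split = 2,                                # cut of the global row tree
  top_annotation = annoSimple(grp, title = "group", add_text = TRUE),
  right_annotation = annoBar(
    setNames(abs(values(fx$matrix)[, 4]), rowIds(fx$matrix)), title = "abs S4"))

fm
#> FigureModel: 20 x 8 ids, 215 primitives, 2 legend(s)
fm@rowSplit
#> SplitResolution: 2 group(s): 1(19), 2(1)
head(colOrder(fm))
#> [1] "S1" "S3" "S2" "S4" "S5" "S6"
length(scenePrimitivesOf(fm, "rect", "row_id"))
#> [1] 160
legends(fm)[[2]]
#> Legend 'group' <categorical_patches>: 2 entries

renderScene(fm, "example.svg")        # or .png
writeScene(fm, "example.scene.json")  # canonical scene document
```

Reading the output: the figure resolved all 20 × 8 = 160 cells (one tagged
rect each), split the rows into a 19/1 blocking from the tree cut, ordered
the columns within their two metadata groups (S1, S3, S2, … — each group
clustered on its own members), and collected two legends: the main value
colorbar plus the `group` patches. The scene document is canonical JSON;
building the same figure twice yields byte-identical documents.

A command-line wrapper (`inst/scripts/heatscene`) exposes the same
builders as subcommands — `clustermap`, `dotmap`, `oncoprint`, `compose`,
`fixtures` — with flags or a YAML config (`--out figure.svg`,
`--dump-scene scene.json`).

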