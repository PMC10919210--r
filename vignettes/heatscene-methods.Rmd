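---
title: "heatscene: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{heatscene: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatscene)
```

## What the engine computes

`heatscene` turns a labeled numeric matrix plus per-row/per-column metadata
into a fully resolved figure: an annotated cluster heatmap, a dot heatmap
encoding up to five variables, an oncoPrint alteration grid, or a composite
of several such panels. The defining design choice is that *layout is data*:
every builder emits a `Scene` — a flat list of styled primitives (`rect`,
`line`, `polyline`, `text`, `marker`) in normalized figure coordinates —
plus legend models and the resolved display orders, all before any pixel is
drawn. The scene serializes canonically (sorted keys, fixed 1e-6 float
precision), so two figures lay out identically if and only if their
documents are byte-identical. Rendering to SVG or PNG is a thin, geometry-
preserving map from that scene.

This makes the whole layout machinery testable: cell coverage, panel
tiling, track disjointness, label placement and legend completeness are all
checked mechanically from the scene, not by inspecting images.

## Coordinate conventions

One convention is used everywhere to prevent off-by-one drift. In data
space, cell $(i, j)$ occupies the half-open unit square
$[j, j+1) \times [i, i+1)$ with row 0 at the **top**. Figure space is
$[0,1]^2$ with the origin at the bottom-left; each panel carries an affine
map from data space into its rectangle. Text labels may bleed at most 0.01
outside the unit square; everything else must stay inside. Positional
indices exposed by the clustering layer (leaf indices, split members) are
0-based, matching the data-space convention; R matrix indexing adds one
internally.

## Hierarchical clustering

The engine implements its own agglomerative clustering rather than wrapping
`stats::hclust`, because its contract pins details that `hclust` does not
guarantee:

* **Methods**: single, complete, average (UPGMA) and Ward, via
  Lance–Williams updates (Ward on squared distances, heights reported on the
  distance scale, as in the `ward.D2` convention). Other method names are
  rejected loudly.
* **Metrics**: euclidean, cityblock, and correlation ($1 - r$, Pearson).
  Distances are *pairwise-complete* over co-observed entries with no
  rescaling; a pair with no co-observed entries, an all-missing item, or a
  zero-variance item under the correlation metric is a hard error naming the
  offending item — never a silent zero.
* **Tie-breaking**: when several cluster pairs attain the minimal distance,
  the pair whose (left, right) node indices are lexicographically smallest
  merges first. Node indices are 0-based: leaves $0..n-1$, merge $t$
  creating node $n+t-1$. This makes results exact and platform-independent,
  which the test suite exploits: an independent brute-force agglomerator
  (recomputing cluster distances from the original matrix at every step)
  must agree *exactly* on hundreds of random matrices, and `stats::hclust`
  serves as an external cross-check on tie-free data.
* **Leaf order**: depth-first, with the left child of each merge being the
  subtree that contains the lowest-indexed leaf (equivalently, the cluster
  occupying the lower slot of an in-place agglomeration). We prefer this
  over ordering by raw node index because it keeps early-merging
  low-index leaves on the left, which is what users expect of a
  deterministic dendrogram; either rule would be internally consistent, so
  the choice is fixed here once and mirrored by the test oracle.

Tree cuts undo the last $k-1$ merges; flat-cluster labels are assigned by
first appearance in leaf order, so group 1 is always the leftmost display
block, and `cutTreeK(link, k)` provably refines `cutTreeK(link, k - 1)`.

The default method/metric is **average linkage + euclidean** — a common,
conservative default for expression- and methylation-style matrices; all
four methods and three metrics are accepted.

## Splits

Rows or columns can be split three ways: not at all; by an integer $k$
(cut of the *global* tree — the cut re-uses the tree built on the whole
axis, so split blocks are genuine subtrees and a single spanning dendrogram
remains meaningful); or by a categorical vector (groups in first-appearance
order, or an explicit `levels` order). With a categorical split and
clustering enabled, each group is re-clustered *on its own members*, so
every block is internally ordered and gets its own dendrogram; a global
tree would conflict with an order imposed by metadata. Missing split values
are an error listing the offending ids.

Panels are laid out with widths proportional to column-group sizes and
heights proportional to row-group sizes; the default gap is 1% of the plot
extent per gap. Tiling is exact: panel extents plus gaps reproduce the plot
rectangle to 1e-9.

## Annotation tracks

Five flavors, one code path per flavor, all orientation-agnostic (left and
right tracks are the top/bottom geometry under a 90° frame transform):

* **simple** — one filled cell per position. With `add_text`, one text per
  contiguous same-category block at the block center, colored white when
  the fill's relative luminance (linearized sRGB) is below 0.5 and black
  otherwise — a deterministic, testable contrast rule.
* **bar** — a single series gives plain bars on a value axis anchored at 0
  (so bar *area* is meaningful) reaching the data maximum at the track's
  outer edge; a matrix with two or more named columns switches to stacked
  mode automatically. Stacking requires nonnegative values (violations name
  the position and column), stacks segments in column order, and conserves
  height: segment heights sum to the row-sum height to 1e-9. One value axis
  is shared across split panels so bars remain comparable.
* **box** — five-number summaries with quartiles by linear interpolation
  between order statistics (the common type-7 rule), whiskers at the most
  extreme samples within 1.5 IQR, and outlier markers beyond; a shared
  value axis spans the data range with 5% padding.
* **scatter** — one marker per position on the same padded shared axis.
* **label** — see below.

## Label merging and even distribution

`mergeLabelRuns` collapses maximal runs of equal adjacent labels to one
anchor at the run center (non-adjacent repeats are *not* merged; unlabeled
positions produce nothing — which is how "label only the selected features"
works). `distributeLabels` then places slot centers strictly evenly: with
`extend = TRUE` at $L(i - \tfrac12)/m$ over the whole axis $[0, L]$; with
`extend = FALSE` by the same rule over the interval from the first anchor
minus half the mean run width to the last anchor plus half of it, clipped
to the axis. The operation receives anchors, not runs, so run widths enter
as an optional argument (the label-track renderer passes them); without
them the mean run width defaults to $L/m$. Slots keep the anchors' order,
which guarantees leader lines never cross — verified by brute-force segment
intersection over a thousand random anchor sets. Each leader is three
segments: a stub from the anchor over the inner 25% of the track, a
diagonal across the middle 50%, and a stub to the text. A `min_slot` guard
rejects label sets too dense for the interval, advising fewer labels;
adapting slots to rendered text widths is deliberately out of scope (slot
geometry would then depend on the rendering backend).

## Color, size and legends

Continuous color specs map affinely from `[vmin, vmax]` (default: data
range; optional q01/q99 robust clipping) into named ramps defined by
explicit control-point tables interpolated linearly in sRGB — so colors are
identical on every backend. Out-of-range values clip rather than error; a
constant vector maps to the ramp midpoint so degenerate fixtures still
render. Categorical specs are explicit mappings with a fallback palette
assigned in first-appearance order; an unmapped category with no fallback
is an error. All colors normalize to 8-digit hex RGBA.

Dot sizes use the area-linear encoding $r = r_{max}\sqrt{(v - v_{min})/
(v_{max} - v_{min})}$ (clipped), so perceived area tracks the value;
$v = v_{min}$ gives radius 0 and no marker at all. $r_{max}$ is capped at
0.45 cell half-extents so adjacent dots never touch across gaps.

Legends are *models*, not pixels: one legend per distinct (title, kind,
entries), deduplicated in first-use order with the main heatmap's colorbar
first. Size legends show three reference radii (minimum, midpoint,
maximum); hue legends map levels to a fixed marker vocabulary (circle,
square, triangle, diamond, cross, star) in first-appearance order. The
renderer draws legend models into the right-hand legend column at draw
time, keeping the canonical scene free of presentation-only duplicates.

## Dot heatmaps and oncoPrints

`buildDotmap` pivots a long-form table (row key, column key, value, color
value, hue) into a grid — rows/columns in first-appearance order, absent
pairs missing — then clusters, splits and annotates exactly like the
cluster heatmap. Five channels can carry five distinct variables: row,
column, size, color, marker. Hue and marker are treated as one channel
(hue selects the marker shape); color may re-encode the size value or an
independent variable — the binding is always explicit, never inferred.

`buildOncoprint` pivots (sample, gene, category) records into a genes ×
samples grid of category *sets* (co-occurring alterations per cell are
kept). Its default ordering is the waterfall ("memo") sort: genes by
alteration frequency descending with stable ties, samples by descending
lexicographic comparison of their binary altered/not vectors read in gene
order, stable on ties — validated against an exhaustive permutation search
on small grids. Cells draw a neutral background (90% of the cell) plus one
horizontal band per present category, equal bands in global category order
by default; an optional per-category fraction/offset table reproduces the
classic full-height-CNV / middle-third-SNV style. Built-in side bars show
per-sample stacked counts (top) and per-gene percent altered with the
rounded percentage as text (right).

## Composites

`composite` joins panels along one axis under a governing *main* panel,
built first. For horizontal joins every other panel is rebuilt with the
main's final row order (and row grouping) imposed and its own row
clustering and row dendrogram suppressed — one coherent row blocking and a
single row tree per joint figure; panels are only reordered, never
re-clustered, so their cell values are untouched. Widths default to
column-count proportions; the inter-panel gap defaults to 2% of the figure
width; legends from all panels are merged and deduplicated. A single-panel
composite is scene-identical to the standalone figure.

## Synthetic data

The generators are first-class package code and define the test conditions:

* `makeFixtureMatrix` — standard-normal entries with contiguous column
  groups shifted by multiples of `group_shift`, plus a matching annotation
  table (group labels and one uniform numeric column). This emulates the
  simulated inputs of the worked examples: clean group structure on an
  elsewhere-exchangeable background.
* `makeFixtureAlterations` — independent Bernoulli alterations per
  (sample, gene) at per-gene rates, categories uniform over {SNV, AMP,
  DEL}.
* `makeFixtureDotTable` — uniform size values, independent normal color
  values, cyclic hue levels: five genuinely distinct variables.

All three use one named generator (Mersenne–Twister, Inversion normals,
Rejection sampling) seeded per call, so equal seeds give bitwise-equal
fixtures and the caller's RNG state is untouched. What these fixtures do
*not* emulate: bounded methylation beta values, heavy tails, correlated
feature blocks, batch effects, or missingness patterns of real assays.
Passing tests therefore demonstrate the correctness of clustering, layout
and encoding — not robustness to real-data pathologies, which enter only
through the documented missing-value and degenerate-input rules.

## Numerical choices and problem sizes

Canonical serialization rounds every number to 1e-6 (normalizing negative
zero), which is far below visible resolution and far above double-precision
noise. Dendrogram depth is normalized to the track extent with the root at
the outer edge, so uniform height rescaling leaves geometry unchanged.
Constant axes under standardization become all-zero and are flagged in the
result's metadata rather than erroring. The test suite runs its clustering
oracle on matrices up to 8×8 (hundreds of cases), label-placement
properties on 1000 random anchor sets, and figure-level checks on matrices
around 14×9 — sizes at which brute-force oracles are exact and the whole
suite completes in well under a minute.

## Known limitations

No optimal leaf ordering, k-means/density clustering, polar layouts,
interactivity, or repulsion-based label placement; bar tracks share one
axis across panels by design; composite supports one row or column of
panels. The canonical scene is the compatibility surface — image output is
intentionally minimal (solid fills, basic markers, sans-serif text).
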