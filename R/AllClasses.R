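#' @import methods
NULL

setClassUnion("OptionalCharacter", c("character", "NULL"))
setClassUnion("OptionalNumeric", c("numeric", "NULL"))

#' LabeledMatrix: a numeric grid with row and column identifiers
#'
#' The body of every heatmap: a 2-D numeric matrix (missing values allowed)
#' whose rows and columns are addressed by ordered, unique string identifiers.
#'
#' @slot values numeric matrix; \code{NA} marks missing cells.
#' @slot rowIds character vector of unique row identifiers, in display order.
#' @slot colIds character vector of unique column identifiers, in display order.
#' @slot metadata list of free-form annotations (e.g. standardization flags).
#' @exportClass LabeledMatrix
setClass("LabeledMatrix",
  representation(values = "matrix", rowIds = "character",
                 colIds = "character", metadata = "list"),
  prototype(metadata = list()),
  validity = function(object) {
    v <- object@values
    if (!is.numeric(v)) return("'values' must be a numeric matrix")
    if (nrow(v) < 1L || ncol(v) < 1L) return("matrix needs >= 1 row and >= 1 column")
    if (nrow(v) != length(object@rowIds))
      return(sprintf("%d rows but %d row ids", nrow(v), length(object@rowIds)))
    if (ncol(v) != length(object@colIds))
      return(sprintf("%d columns but %d column ids", ncol(v), length(object@colIds)))
    if (anyDuplicated(object@rowIds))
      return(sprintf("duplicate row id '%s'", object@rowIds[duplicated(object@rowIds)][1L]))
    if (anyDuplicated(object@colIds))
      return(sprintf("duplicate column id '%s'", object@colIds[duplicated(object@colIds)][1L]))
    TRUE
  })

#' Construct a LabeledMatrix
#'
#' @param values numeric matrix (a plain vector is reshaped only if it is
#'   already a matrix; dimnames are harvested when ids are not given).
#' @param rowIds,colIds character identifiers; default to dimnames.
#' @param metadata optional list.
#' @return a \linkS4class{LabeledMatrix}
#' @examples
#' m <- LabeledMatrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("r1", "r2"), c("a", "b", "c"))))
#' dim(m)
#' @export
LabeledMatrix <- function(values, rowIds = NULL, colIds = NULL, metadata = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rowIds)) rowIds <- rownames(values)
  if (is.null(colIds)) colIds <- colnames(values)
  if (is.null(rowIds)) rowIds <- paste0("r", seq_len(nrow(values)))
  if (is.null(colIds)) colIds <- paste0("c", seq_len(ncol(values)))
  dimnames(values) <- list(rowIds, colIds)
  new("LabeledMatrix", values = values, rowIds = as.character(rowIds),
      colIds = as.character(colIds), metadata = metadata)
}

#' AnnotationTable: per-row or per-column metadata
#'
#' Columns are tagged either categorical (character) or numeric; the tag
#' decides annotation-track defaults downstream. Categorical level order is
#' first-appearance order, never lexicographic, because split and legend
#' ordering depend on it.
#'
#' @slot indexIds character, unique, ordered.
#' @slot columns named list; each element a vector of length(indexIds).
#' @slot types named character, "categorical" or "numeric" per column.
#' @exportClass AnnotationTable
setClass("AnnotationTable",
  representation(indexIds = "character", columns = "list", types = "character"),
  validity = function(object) {
    if (anyDuplicated(object@indexIds))
      return(sprintf("duplicate index id '%s'",
                     object@indexIds[duplicated(object@indexIds)][1L]))
    if (length(object@columns) != length(object@types))
      return("one type tag per column required")
    n <- length(object@indexIds)
    for (nm in names(object@columns)) {
      if (length(object@columns[[nm]]) != n)
        return(sprintf("column '%s' has %d entries, expected %d",
                       nm, length(object@columns[[nm]]), n))
    }
    if (!all(object@types %in% c("categorical", "numeric")))
      return("types must be 'categorical' or 'numeric'")
    TRUE
  })

#' Construct an AnnotationTable
#'
#' @param indexIds character identifiers.
#' @param columns named list of vectors; character columns are tagged
#'   categorical, numeric columns numeric. A column that is character but
#'   fully numeric-parsable stays categorical unless converted by the caller
#'   (readers apply the auto-tag rule at parse time).
#' @return an \linkS4class{AnnotationTable}
#' @export
AnnotationTable <- function(indexIds, columns) {
  types <- vapply(columns, function(x)
    if (is.numeric(x)) "numeric" else "categorical", character(1))
  columns <- lapply(columns, function(x) if (is.numeric(x)) as.double(x) else as.character(x))
  new("AnnotationTable", indexIds = as.character(indexIds),
      columns = columns, types = types)
}

#' AlterationTable: long-form (sample, gene, category) records
#'
#' MAF-like input to the oncoPrint builder. A (sample, gene) pair may repeat
#' with different categories: co-occurring alterations in one cell.
#'
#' @slot records data.frame with character columns sample, gene, category.
#' @slot dropped integer count of records discarded on read (empty category).
#' @exportClass AlterationTable
setClass("AlterationTable",
  representation(records = "data.frame", dropped = "integer"),
  prototype(dropped = 0L),
  validity = function(object) {
    r <- object@records
    if (!all(c("sample", "gene", "category") %in% names(r)))
      return("records needs columns sample, gene, category")
    if (nrow(r) > 0L && any(!nzchar(r$sample) | !nzchar(r$gene) | !nzchar(r$category)))
      return("records with empty fields are not allowed")
    TRUE
  })

#' @param sample,gene,category character vectors of equal length.
#' @param dropped integer, records discarded upstream.
#' @rdname AlterationTable-class
#' @export
AlterationTable <- function(sample, gene, category, dropped = 0L) {
  new("AlterationTable",
      records = data.frame(sample = as.character(sample),
                           gene = as.character(gene),
                           category = as.character(category),
                           stringsAsFactors = FALSE),
      dropped = as.integer(dropped))
}

#' DotTable: long-form input of a dot heatmap
#'
#' One record per (row key, column key, hue); carries the dot's size-driving
#' value, its color-driving value (numeric or category) and an optional hue
#' category that selects the marker shape.
#'
#' @slot records data.frame with columns row_key, col_key, value,
#'   color_value, hue.
#' @exportClass DotTable
setClass("DotTable",
  representation(records = "data.frame"),
  validity = function(object) {
    r <- object@records
    need <- c("row_key", "col_key", "value", "color_value", "hue")
    if (!all(need %in% names(r)))
      return(paste("records needs columns", paste(need, collapse = ", ")))
    if (nrow(r) > 0L) {
      if (!all(is.finite(r$value))) return("dot values must be finite")
      key <- paste(r$row_key, r$col_key, r$hue, sep = "\r")
      if (anyDuplicated(key))
        return(sprintf("duplicate (row, col, hue) record: %s",
                       gsub("\r", ", ", key[duplicated(key)][1L])))
    }
    TRUE
  })

#' @param row_key,col_key character keys.
#' @param value numeric, finite; drives dot size.
#' @param color_value numeric or character; drives dot fill. Defaults to value.
#' @param hue optional category selecting the marker shape.
#' @rdname DotTable-class
#' @export
DotTable <- function(row_key, col_key, value, color_value = value, hue = NA_character_) {
  n <- length(row_key)
  new("DotTable", records = data.frame(
    row_key = as.character(row_key), col_key = as.character(col_key),
    value = as.double(value), color_value = color_value,
    hue = rep_len(as.character(hue), n), stringsAsFactors = FALSE))
}

#' LinkageResult: an agglomerative merge tree
#'
#' Merge i joins two existing nodes at a height; node indices are 0-based:
#' leaves are 0..n-1 and merge i creates node n+i-1, so indices run to 2n-2.
#' Heights are non-decreasing for the supported (monotone) linkages.
#'
#' @slot merges numeric (n-1) x 3 matrix, columns left, right, height, with
#'   left < right at merge time.
#' @slot nLeaves integer.
#' @slot method one of single, complete, average, ward.
#' @slot metric one of euclidean, correlation, cityblock (or "precomputed").
#' @exportClass LinkageResult
setClass("LinkageResult",
  representation(merges = "matrix", nLeaves = "integer",
                 method = "character", metric = "character"),
  validity = function(object) {
    n <- object@nLeaves
    m <- object@merges
    if (n < 1L) return("need >= 1 leaf")
    if (n > 1L) {
      if (nrow(m) != n - 1L || ncol(m) != 3L)
        return("merges must be (n-1) x 3")
      idx <- c(m[, 1L], m[, 2L])
      if (any(idx != floor(idx)) || any(idx < 0) || any(idx > 2L * n - 2L))
        return("node indices must lie in 0..2n-2")
      if (any(m[, 3L] < 0)) return("merge heights must be nonnegative")
    }
    TRUE
  })

#' SplitResolution: an ordered partition of axis positions
#'
#' Groups in display order; member indices (0-based positions into the input
#' axis) in final display order within each group.
#'
#' @slot labels character group labels, display order.
#' @slot members list of integer vectors, parallel to labels.
#' @exportClass SplitResolution
setClass("SplitResolution",
  representation(labels = "character", members = "list"),
  validity = function(object) {
    if (length(object@labels) != length(object@members))
      return("one member vector per label")
    all_m <- unlist(object@members, use.names = FALSE)
    n <- length(all_m)
    if (n > 0L && !identical(sort(as.integer(all_m)), 0:(n - 1L)))
      return("members must partition 0..n-1")
    TRUE
  })

#' ColorSpec: categorical or continuous color mapping
#'
#' Colors are 8-digit lowercase hex RGBA strings so output is backend
#' independent. Continuous specs name a built-in ramp and map affinely from
#' [vmin, vmax]; values outside the range are clipped. A constant vector
#' (vmin == vmax) maps to the ramp midpoint.
#'
#' @slot mode "categorical" or "continuous".
#' @slot mapping named character, category -> color (categorical mode).
#' @slot fallback character palette for categories absent from mapping;
#'   empty means unmapped categories are an error.
#' @slot ramp ramp name (continuous mode), see \code{\link{rampNames}}.
#' @slot vmin,vmax numeric range (continuous mode).
#' @slot missingColor color for missing values.
#' @slot title legend title.
#' @exportClass ColorSpec
setClass("ColorSpec",
  representation(mode = "character", mapping = "character",
                 fallback = "character", ramp = "character",
                 vmin = "numeric", vmax = "numeric",
                 missingColor = "character", title = "character"),
  prototype(mapping = character(), fallback = character(),
            ramp = "viridis-like", vmin = 0, vmax = 1,
            missingColor = "#bdbdbdff", title = "value"),
  validity = function(object) {
    if (!object@mode %in% c("categorical", "continuous"))
      return("mode must be 'categorical' or 'continuous'")
    if (object@mode == "continuous" && !anyNA(c(object@vmin, object@vmax)) &&
        object@vmin > object@vmax)
      return("vmin must be <= vmax")
    TRUE
  })

#' SizeScale: value-to-radius encoding for dot heatmaps
#'
#' Radius is \code{rMax * sqrt((clip(v) - vmin) / (vmax - vmin))}: dot area is
#' linear in value. rMax is a fraction of the cell half-extent.
#'
#' @slot vmin,vmax numeric, vmin < vmax.
#' @slot rMax numeric in (0, 1].
#' @exportClass SizeScale
setClass("SizeScale",
  representation(vmin = "numeric", vmax = "numeric", rMax = "numeric"),
  prototype(vmin = 0, vmax = 1, rMax = 0.45),
  validity = function(object) {
    if (object@rMax <= 0 || object@rMax > 1) return("rMax must be in (0, 1]")
    if (object@vmin >= object@vmax) return("vmin must be < vmax")
    TRUE
  })

#' @param vmin,vmax numeric value range.
#' @param rMax maximal radius as a fraction of the cell half-extent.
#' @rdname SizeScale-class
#' @export
SizeScale <- function(vmin = 0, vmax = 1, rMax = 0.45)
  new("SizeScale", vmin = vmin, vmax = vmax, rMax = rMax)

#' Scene: a flat list of styled drawing primitives
#'
#' All layout resolves to a Scene: primitives (rect, line, polyline, text,
#' marker) in normalized figure coordinates, origin bottom-left, with a small
#' bleed tolerance of 0.01 outside [0, 1] for labels. The scene serializes
#' canonically, so byte equality of documents is layout equality.
#'
#' @slot primitives list of primitive records (plain lists).
#' @slot meta list: provenance, effective configuration.
#' @exportClass Scene
setClass("Scene",
  representation(primitives = "list", meta = "list"),
  prototype(primitives = list(), meta = list()))

#' Legend: one legend model
#'
#' @slot title character.
#' @slot kind one of categorical_patches, colorbar, marker_set, size_set.
#' @slot entries list of list(label=, swatch=) in display order.
#' @exportClass Legend
setClass("Legend",
  representation(title = "character", kind = "character", entries = "list"),
  validity = function(object) {
    if (!object@kind %in% c("categorical_patches", "colorbar", "marker_set", "size_set"))
      return("unknown legend kind")
    labs <- vapply(object@entries, function(e) as.character(e$label), character(1))
    if (anyDuplicated(labs)) return("legend entry labels must be unique")
    TRUE
  })

#' Track: one annotation lane
#'
#' Bound to per-row or per-column data by id; rendered into an allocated
#' track rectangle by the assemblers. Construct with \code{\link{annoSimple}},
#' \code{\link{annoBar}}, \code{\link{annoBox}}, \code{\link{annoScatter}} or
#' \code{\link{annoLabel}}.
#'
#' @slot kind simple, bar, box, scatter or label.
#' @slot data named vector (simple/scatter/label), named-column matrix (bar)
#'   or named list of sample vectors (box).
#' @slot color ColorSpec or NULL for defaults.
#' @slot extent track thickness as a figure fraction.
#' @slot title legend/track title.
#' @slot options list: add_text, merge, extend, rotation, min_slot, ...
#' @exportClass Track
setClass("Track",
  representation(kind = "character", data = "ANY", color = "ANY",
                 extent = "numeric", title = "character", options = "list"),
  validity = function(object) {
    if (!object@kind %in% c("simple", "bar", "box", "scatter", "label"))
      return("unknown track kind")
    if (object@extent <= 0) return("extent must be > 0")
    TRUE
  })

#' PanelGrid: the panel rectangles implied by row/column splits
#'
#' Panels tile the plot rectangle exactly (up to gaps); widths are
#' proportional to column-group sizes, heights to row-group sizes. Row group
#' 1 is at the top.
#'
#' @slot plotRect numeric c(x, y, w, h) in figure coordinates.
#' @slot panels list of rows; panels[[rg]][[cg]] is a numeric c(x, y, w, h).
#' @slot rowSizes,colSizes integer group sizes.
#' @slot rowGap,colGap figure-fraction gaps between panels.
#' @slot trackRects list with elements top, bottom, left, right: ordered
#'   lists of track rectangles stacking outward from the plot rectangle.
#' @exportClass PanelGrid
setClass("PanelGrid",
  representation(plotRect = "numeric", panels = "list",
                 rowSizes = "numeric", colSizes = "numeric",
                 rowGap = "numeric", colGap = "numeric",
                 trackRects = "list"),
  prototype(trackRects = list(top = list(), bottom = list(),
                              left = list(), right = list())))

#' LabelPlacement: evenly distributed label slots with leader lines
#'
#' @slot anchors numeric data-axis anchor coordinates, increasing.
#' @slot slotPos numeric slot (text) coordinates, same order as anchors.
#' @slot texts character labels.
#' @slot rotation numeric degrees.
#' @slot leaders list of 3-segment polylines (each a list(xs=, ys=)) in the
#'   label track's local [0,1] x [0,1] coordinates.
#' @exportClass LabelPlacement
setClass("LabelPlacement",
  representation(anchors = "numeric", slotPos = "numeric",
                 texts = "character", rotation = "numeric", leaders = "list"),
  validity = function(object) {
    m <- length(object@anchors)
    if (length(object@slotPos) != m || length(object@texts) != m)
      return("anchors, slotPos and texts must have equal length")
    if (m > 1L) {
      if (any(diff(object@anchors) <= 0)) return("anchors must be strictly increasing")
      if (any(diff(object@slotPos) <= 0)) return("slots must preserve anchor order")
    }
    TRUE
  })

#' FigureModel: a fully laid-out figure
#'
#' Panels, scene, legends and the resolved row/column display orders for one
#' heatmap (cluster, dot or oncoPrint) or a composite.
#'
#' @slot grid PanelGrid (or NULL for annotation-only figures).
#' @slot scene Scene.
#' @slot legends list of Legend, display order.
#' @slot rowOrder,colOrder character id permutations, final display order.
#' @slot rowSplit,colSplit SplitResolution or NULL.
#' @exportClass FigureModel
setClass("FigureModel",
  representation(grid = "ANY", scene = "Scene", legends = "list",
                 rowOrder = "character", colOrder = "character",
                 rowSplit = "ANY", colSplit = "ANY"),
  prototype(grid = NULL, rowSplit = NULL, colSplit = NULL))
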