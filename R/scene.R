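#' @include AllClasses.R
NULL

.BLEED <- 0.01  # labels may bleed this far outside the unit square

.chk_coord <- function(x, what) {
  if (any(!is.finite(x))) stop(sprintf("non-finite coordinate in %s", what))
  if (any(x < -.BLEED | x > 1 + .BLEED))
    stop(sprintf("coordinate outside [-0.01, 1.01] in %s", what))
  as.numeric(x)
}

#' Scene primitives
#'
#' Constructors for the five primitive kinds all layout resolves to. All
#' coordinates are in normalized figure space, origin bottom-left; colors are
#' 8-digit hex RGBA; stroke widths are figure-fraction units. \code{tags} is
#' a named list of strings carried for mechanical checking (e.g. cell rects
#' carry row_id/col_id); renderers drop tags.
#'
#' @param x,y position (rect: lower-left corner).
#' @param w,h rect extents.
#' @param x0,y0,x1,y1 line endpoints.
#' @param xs,ys polyline vertices.
#' @param fill,stroke colors (any R color; normalized), or NA for none.
#' @param stroke_width stroke width.
#' @param label text string.
#' @param size text height.
#' @param anchor "start", "middle" or "end".
#' @param rotation degrees counter-clockwise.
#' @param color text color.
#' @param radius marker radius.
#' @param shape marker shape, one of \code{\link{markerShapes}}.
#' @param tags named list of strings.
#' @name primitives
NULL

.col_or_none <- function(x) if (length(x) == 0L || is.na(x[1L])) "none" else .norm_color(x)

#' @rdname primitives
#' @export
sceneRect <- function(x, y, w, h, fill = "#000000ff", stroke = NA,
                      stroke_width = 0, tags = list()) {
  list(kind = "rect", x = .chk_coord(x, "rect"), y = .chk_coord(y, "rect"),
       w = as.numeric(w), h = as.numeric(h),
       fill = .col_or_none(fill), stroke = .col_or_none(stroke),
       stroke_width = as.numeric(stroke_width), tags = tags)
}

#' @rdname primitives
#' @export
sceneLine <- function(x0, y0, x1, y1, stroke = "#000000ff", stroke_width = 0.001) {
  list(kind = "line",
       x0 = .chk_coord(x0, "line"), y0 = .chk_coord(y0, "line"),
       x1 = .chk_coord(x1, "line"), y1 = .chk_coord(y1, "line"),
       stroke = .col_or_none(stroke), stroke_width = as.numeric(stroke_width))
}

#' @rdname primitives
#' @export
scenePolyline <- function(xs, ys, stroke = "#000000ff", stroke_width = 0.001,
                          tags = list()) {
  if (length(xs) != length(ys)) stop("xs and ys must have equal length")
  list(kind = "polyline", xs = .chk_coord(xs, "polyline"),
       ys = .chk_coord(ys, "polyline"),
       stroke = .col_or_none(stroke), stroke_width = as.numeric(stroke_width),
       tags = tags)
}

#' @rdname primitives
#' @export
sceneText <- function(x, y, label, size = 0.015, color = "#000000ff",
                      anchor = "middle", rotation = 0, tags = list()) {
  if (!anchor %in% c("start", "middle", "end")) stop("bad text anchor")
  list(kind = "text", x = .chk_coord(x, "text"), y = .chk_coord(y, "text"),
       label = as.character(label), size = as.numeric(size),
       color = .col_or_none(color), anchor = anchor,
       rotation = as.numeric(rotation), tags = tags)
}

#' @rdname primitives
#' @export
sceneMarker <- function(x, y, radius, shape = "circle", fill = "#000000ff",
                        stroke = NA, stroke_width = 0, tags = list()) {
  if (!shape %in% .MARKERS) stop(sprintf("unknown marker shape '%s'", shape))
  list(kind = "marker", x = .chk_coord(x, "marker"), y = .chk_coord(y, "marker"),
       radius = as.numeric(radius), shape = shape,
       fill = .col_or_none(fill), stroke = .col_or_none(stroke),
       stroke_width = as.numeric(stroke_width), tags = tags)
}

#' Construct a Scene
#'
#' @param primitives list of primitives (from the \code{scene*} constructors).
#' @param meta named list of provenance/config entries.
#' @return a \linkS4class{Scene}
#' @export
Scene <- function(primitives = list(), meta = list()) {
  new("Scene", primitives = primitives, meta = meta)
}

#' Filter a scene's primitives
#'
#' @param x a Scene or FigureModel.
#' @param kind primitive kind to keep, or NULL for all.
#' @param tag,value keep only primitives whose \code{tags[[tag]] == value}
#'   (tag alone: primitives carrying that tag).
#' @return list of primitives
#' @export
scenePrimitivesOf <- function(x, kind = NULL, tag = NULL, value = NULL) {
  prims <- scenePrimitives(x)
  if (!is.null(kind)) prims <- Filter(function(p) p$kind == kind, prims)
  if (!is.null(tag)) {
    prims <- Filter(function(p) !is.null(p$tags[[tag]]), prims)
    if (!is.null(value))
      prims <- Filter(function(p) identical(as.character(p$tags[[tag]]),
                                            as.character(value)), prims)
  }
  prims
}

# ---- canonical serialization -------------------------------------------

# Canonical JSON: object keys sorted, every number printed with fixed
# 6-decimal precision (so byte equality of documents is equality of layouts
# at 1e-6), no insignificant whitespace.
.canon_num <- function(x) {
  v <- round(as.numeric(x), 6)
  v[v == 0] <- 0  # normalize -0
  sprintf("%.6f", v)
}

.canon_str <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  paste0("\"", x, "\"")
}

.canon_json <- function(x) {
  if (is.null(x)) return("null")
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) {
      o <- order(nm)
      return(paste0("{", paste0(.canon_str(nm[o]), ":",
                                vapply(x[o], .canon_json, character(1)),
                                collapse = ","), "}"))
    }
    return(paste0("[", paste0(vapply(x, .canon_json, character(1)),
                              collapse = ","), "]"))
  }
  if (length(x) != 1L) {
    return(paste0("[", paste0(vapply(as.list(x), .canon_json, character(1)),
                              collapse = ","), "]"))
  }
  if (is.logical(x)) return(if (is.na(x)) "null" else if (x) "true" else "false")
  if (is.numeric(x)) return(if (is.na(x)) "null" else .canon_num(x))
  .canon_str(as.character(x))
}

#' Serialize a scene to its canonical text document
#'
#' The document is canonical — sorted keys, fixed 1e-6 float precision, no
#' incidental whitespace — so two scenes lay out identically if and only if
#' their documents are byte-identical.
#'
#' @param scene a \linkS4class{Scene} or \linkS4class{FigureModel}.
#' @return a single character string (JSON)
#' @export
serializeScene <- function(scene) {
  if (is(scene, "FigureModel")) scene <- scene@scene
  stopifnot(is(scene, "Scene"))
  doc <- list(heatscene_scene = 1L, meta = scene@meta,
              primitives = scene@primitives)
  .canon_json(doc)
}

#' Write a scene document to a file
#' @param scene a Scene or FigureModel.
#' @param path output path.
#' @return invisibly, \code{path}
#' @export
writeScene <- function(scene, path) {
  writeLines(serializeScene(scene), path, useBytes = TRUE)
  invisible(path)
}

.deserialize_prim <- function(p) {
  p <- lapply(p, function(f) if (is.list(f) && is.null(names(f))) unlist(f) else f)
  num_fields <- c("x", "y", "w", "h", "x0", "y0", "x1", "y1", "xs", "ys",
                  "stroke_width", "size", "rotation", "radius")
  for (f in intersect(names(p), num_fields)) p[[f]] <- as.numeric(p[[f]])
  if (is.null(p$tags)) p$tags <- list()
  p
}

#' Read a scene back from its canonical document
#'
#' @param x a file path or a JSON string (as from
#'   \code{\link{serializeScene}}).
#' @return a \linkS4class{Scene}
#' @export
deserializeScene <- function(x) {
  txt <- if (length(x) == 1L && file.exists(x)) paste(readLines(x, warn = FALSE),
                                                      collapse = "\n") else x
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  if (is.null(doc$heatscene_scene)) stop("not a scene document")
  prims <- lapply(doc$primitives, .deserialize_prim)
  meta <- doc$meta
  Scene(primitives = prims, meta = if (is.null(meta)) list() else meta)
}
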