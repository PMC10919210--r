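#' @include AllClasses.R
NULL

#' Accessors
#'
#' Small accessor generics for the package's S4 containers; user code should
#' use these instead of reaching into slots.
#'
#' @param x an object
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))
#' @rdname accessors
#' @export
setMethod("values", "LabeledMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("rowIds", function(x) standardGeneric("rowIds"))
#' @rdname accessors
#' @export
setMethod("rowIds", "LabeledMatrix", function(x) x@rowIds)

#' @rdname accessors
#' @export
setGeneric("colIds", function(x) standardGeneric("colIds"))
#' @rdname accessors
#' @export
setMethod("colIds", "LabeledMatrix", function(x) x@colIds)

#' @rdname accessors
#' @export
setMethod("dim", "LabeledMatrix", function(x) dim(x@values))

#' @rdname accessors
#' @param ... ignored
#' @export
setMethod("as.matrix", "LabeledMatrix", function(x, ...) x@values)

#' @rdname accessors
#' @export
setGeneric("indexIds", function(x) standardGeneric("indexIds"))
#' @rdname accessors
#' @export
setMethod("indexIds", "AnnotationTable", function(x) x@indexIds)

#' @rdname accessors
#' @export
setGeneric("columnTypes", function(x) standardGeneric("columnTypes"))
#' @rdname accessors
#' @export
setMethod("columnTypes", "AnnotationTable", function(x) x@types)

#' Extract one annotation column
#' @param x an AnnotationTable
#' @param name column name
#' @return the column vector, named by index ids
#' @export
annotationColumn <- function(x, name) {
  stopifnot(is(x, "AnnotationTable"))
  if (!name %in% names(x@columns))
    stop(sprintf("no annotation column '%s'", name))
  stats::setNames(x@columns[[name]], x@indexIds)
}

#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname accessors
#' @export
setMethod("records", "AlterationTable", function(x) x@records)
#' @rdname accessors
#' @export
setMethod("records", "DotTable", function(x) x@records)

#' @rdname accessors
#' @export
setGeneric("nLeaves", function(x) standardGeneric("nLeaves"))
#' @rdname accessors
#' @export
setMethod("nLeaves", "LinkageResult", function(x) x@nLeaves)

#' @rdname accessors
#' @export
setGeneric("merges", function(x) standardGeneric("merges"))
#' @rdname accessors
#' @export
setMethod("merges", "LinkageResult", function(x) x@merges)

#' @rdname accessors
#' @export
setGeneric("splitLabels", function(x) standardGeneric("splitLabels"))
#' @rdname accessors
#' @export
setMethod("splitLabels", "SplitResolution", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("splitMembers", function(x) standardGeneric("splitMembers"))
#' @rdname accessors
#' @export
setMethod("splitMembers", "SplitResolution", function(x)
  stats::setNames(x@members, x@labels))

#' @rdname accessors
#' @export
setGeneric("scenePrimitives", function(x) standardGeneric("scenePrimitives"))
#' @rdname accessors
#' @export
setMethod("scenePrimitives", "Scene", function(x) x@primitives)
#' @rdname accessors
#' @export
setMethod("scenePrimitives", "FigureModel", function(x) x@scene@primitives)

#' @rdname accessors
#' @export
setGeneric("figureScene", function(x) standardGeneric("figureScene"))
#' @rdname accessors
#' @export
setMethod("figureScene", "FigureModel", function(x) x@scene)

#' @rdname accessors
#' @export
setGeneric("legends", function(x) standardGeneric("legends"))
#' @rdname accessors
#' @export
setMethod("legends", "FigureModel", function(x) x@legends)

#' @rdname accessors
#' @export
setGeneric("rowOrder", function(x) standardGeneric("rowOrder"))
#' @rdname accessors
#' @export
setMethod("rowOrder", "FigureModel", function(x) x@rowOrder)

#' @rdname accessors
#' @export
setGeneric("colOrder", function(x) standardGeneric("colOrder"))
#' @rdname accessors
#' @export
setMethod("colOrder", "FigureModel", function(x) x@colOrder)

#' @rdname accessors
#' @export
setGeneric("panelGrid", function(x) standardGeneric("panelGrid"))
#' @rdname accessors
#' @export
setMethod("panelGrid", "FigureModel", function(x) x@grid)

setMethod("show", "LabeledMatrix", function(object) {
  cat(sprintf("LabeledMatrix: %d x %d (%d missing)\n",
              nrow(object@values), ncol(object@values),
              sum(is.na(object@values))))
  cat("  rows:", paste(utils::head(object@rowIds, 4), collapse = ", "),
      if (length(object@rowIds) > 4) "..." else "", "\n")
  cat("  cols:", paste(utils::head(object@colIds, 4), collapse = ", "),
      if (length(object@colIds) > 4) "..." else "", "\n")
})

setMethod("show", "AnnotationTable", function(object) {
  cat(sprintf("AnnotationTable: %d ids, %d columns\n",
              length(object@indexIds), length(object@columns)))
  for (nm in names(object@columns))
    cat(sprintf("  %s <%s>\n", nm, object@types[[nm]]))
})

setMethod("show", "LinkageResult", function(object) {
  cat(sprintf("LinkageResult: %d leaves, %s linkage, %s metric\n",
              object@nLeaves, object@method, object@metric))
})

setMethod("show", "SplitResolution", function(object) {
  sizes <- vapply(object@members, length, integer(1))
  cat(sprintf("SplitResolution: %d group(s): %s\n", length(object@labels),
              paste(sprintf("%s(%d)", object@labels, sizes), collapse = ", ")))
})

setMethod("show", "Scene", function(object) {
  kinds <- vapply(object@primitives, function(p) p$kind, character(1))
  cat(sprintf("Scene: %d primitives", length(kinds)))
  if (length(kinds))
    cat(" (", paste(sprintf("%s:%d", names(table(kinds)), table(kinds)),
                    collapse = ", "), ")", sep = "")
  cat("\n")
})

setMethod("show", "Legend", function(object) {
  cat(sprintf("Legend '%s' <%s>: %d entries\n", object@title, object@kind,
              length(object@entries)))
})

setMethod("show", "Track", function(object) {
  cat(sprintf("Track <%s> '%s', extent %.3f\n", object@kind, object@title,
              object@extent))
})

setMethod("show", "FigureModel", function(object) {
  cat(sprintf("FigureModel: %d x %d ids, %d primitives, %d legend(s)\n",
              length(object@rowOrder), length(object@colOrder),
              length(object@scene@primitives), length(object@legends)))
})
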