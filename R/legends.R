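#' @include AllClasses.R
NULL

#' Construct a Legend
#'
#' @param title legend title.
#' @param kind one of categorical_patches, colorbar, marker_set, size_set.
#' @param entries list of list(label=, swatch=) in display order; swatch is
#'   a named list (color/shape/radius as applicable).
#' @return a \linkS4class{Legend}
#' @export
Legend <- function(title, kind, entries) {
  new("Legend", title = title, kind = kind, entries = entries)
}

#' Legend model from a resolved color specification
#'
#' Categorical specs yield patch legends over the observed categories (in
#' mapping insertion order, i.e. first appearance); continuous specs yield a
#' colorbar with five reference stops.
#'
#' @param spec a resolved \linkS4class{ColorSpec}.
#' @param values optional observed values (restricts a categorical legend to
#'   observed categories).
#' @return a \linkS4class{Legend}
#' @export
legendFromColorSpec <- function(spec, values = NULL) {
  if (spec@mode == "categorical") {
    cats <- names(spec@mapping)
    if (!is.null(values)) {
      obs <- unique(as.character(values))
      cats <- cats[cats %in% obs]
    }
    Legend(spec@title, "categorical_patches",
           lapply(cats, function(ct)
             list(label = ct, swatch = list(color = unname(spec@mapping[[ct]])))))
  } else {
    ts <- c(0, 0.25, 0.5, 0.75, 1)
    vals <- spec@vmin + ts * (spec@vmax - spec@vmin)
    Legend(spec@title, "colorbar",
           lapply(seq_along(ts), function(i)
             list(label = format(signif(vals[i], 3)),
                  swatch = list(color = .ramp_eval(spec@ramp, ts[i])))))
  }
}

#' Legend model from a size scale
#'
#' Three reference dots at vmin, the midpoint and vmax; swatch radii are
#' relative to the maximal radius.
#'
#' @param scale a \linkS4class{SizeScale}.
#' @param title legend title.
#' @return a \linkS4class{Legend}
#' @export
legendFromSizeScale <- function(scale, title = "size") {
  vals <- c(scale@vmin, (scale@vmin + scale@vmax) / 2, scale@vmax)
  Legend(title, "size_set",
         lapply(vals, function(v)
           list(label = format(signif(v, 3)),
                swatch = list(radius = unname(mapSizes(v, scale) / scale@rMax)))))
}

#' Legend model from a hue-to-marker assignment
#'
#' @param assignment named character: hue level -> marker shape.
#' @param title legend title.
#' @param colors optional named colors per level (default neutral gray).
#' @return a \linkS4class{Legend}
#' @export
legendFromMarkers <- function(assignment, title = "hue", colors = NULL) {
  Legend(title, "marker_set",
         lapply(names(assignment), function(lv)
           list(label = lv,
                swatch = list(shape = unname(assignment[[lv]]),
                              color = if (!is.null(colors)) unname(colors[[lv]])
                                      else "#555555ff"))))
}

#' Collect and deduplicate figure legends
#'
#' Keeps one legend per distinct (title, kind, entries) in first-use order;
#' callers put the main heatmap's colorbar first. NULL elements are dropped.
#'
#' @param legend_list list of \linkS4class{Legend} (and NULLs).
#' @return list of unique \linkS4class{Legend}
#' @export
buildLegends <- function(legend_list) {
  legend_list <- Filter(Negate(is.null), legend_list)
  keys <- vapply(legend_list, function(lg)
    .canon_json(list(t = lg@title, k = lg@kind, e = lg@entries)), character(1))
  legend_list[!duplicated(keys)]
}
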