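#' @include clustermap.R
NULL

#' Capture a figure specification for later building
#'
#' A thin deferred call: \code{composite} re-invokes the builder with layout
#' and ordering overrides, so the main panel can govern the joint figure.
#'
#' @param builder a figure builder (\code{\link{buildClustermap}},
#'   \code{\link{buildDotmap}}, \code{\link{buildOncoprint}}).
#' @param ... arguments for the builder.
#' @return a figure spec (list with class "heatsceneFigureSpec")
#' @export
figureSpec <- function(builder, ...) {
  structure(list(builder = builder, args = list(...)),
            class = "heatsceneFigureSpec")
}

.spec_matrix_ids <- function(spec, axis) {
  a <- spec$args
  m <- a$matrix %||% a[[1L]]
  if (is(m, "LabeledMatrix"))
    return(if (axis == "rows") m@rowIds else m@colIds)
  if (is(m, "DotTable")) {
    piv <- pivotDotTable(m)
    return(if (axis == "rows") piv$values@rowIds else piv$values@colIds)
  }
  stop("cannot determine shared ids for this spec")
}

# per-id group labels from a figure's split resolution, or NULL
.split_labels_by_id <- function(res, ids_in_order) {
  if (is.null(res) || length(res@labels) <= 1L) return(NULL)
  labs <- character(length(ids_in_order))
  off <- 0L
  for (gi in seq_along(res@labels)) {
    k <- length(res@members[[gi]])
    labs[off + seq_len(k)] <- res@labels[gi]
    off <- off + k
  }
  stats::setNames(labs, ids_in_order)
}

#' Join figures along one axis under a governing main panel
#'
#' Builds the main figure first; for a horizontal join its final row order
#' (and row-split grouping) is imposed on every other panel, whose own row
#' clustering is skipped and whose row dendrograms are suppressed — one
#' coherent row blocking across the joint figure. Vertical joins share the
#' column order analogously. Panels are placed along the axis with widths
#' proportional to \code{width_ratios} (default: each panel's column — or
#' row — count); legends from all panels are merged and deduplicated.
#'
#' @param specs list of \code{\link{figureSpec}} objects.
#' @param main index (1-based) of the governing panel.
#' @param axis "horizontal" (panels side by side, shared rows) or
#'   "vertical" (stacked, shared columns).
#' @param width_ratios optional positive reals, one per panel.
#' @param legend_side "right" or "bottom" (recorded for the renderer).
#' @param gap gap between composed panels, figure fraction.
#' @param band c(start, extent) of the joint plot band along the axis.
#' @return a \linkS4class{FigureModel}: concatenated scene, merged legends,
#'   the main panel's orders and split
#' @export
composite <- function(specs, main = 1L, axis = c("horizontal", "vertical"),
                      width_ratios = NULL, legend_side = "right", gap = 0.02,
                      band = c(0.15, 0.70)) {
  axis <- match.arg(axis)
  np <- length(specs)
  if (np < 1L) stop("composite needs at least one figure spec")
  if (main < 1L || main > np) stop("main panel index out of range")
  stopifnot(all(vapply(specs, inherits, logical(1), "heatsceneFigureSpec")))
  shared_axis <- if (axis == "horizontal") "rows" else "cols"
  ids0 <- .spec_matrix_ids(specs[[main]], shared_axis)
  for (k in seq_len(np)) {
    idk <- .spec_matrix_ids(specs[[k]], shared_axis)
    if (!setequal(idk, ids0)) {
      d <- union(setdiff(idk, ids0), setdiff(ids0, idk))
      stop(sprintf("panels do not share %s ids; differing: %s", shared_axis,
                   paste(d, collapse = ", ")))
    }
  }
  if (is.null(width_ratios))
    width_ratios <- vapply(specs, function(s)
      length(.spec_matrix_ids(s, if (axis == "horizontal") "cols" else "rows")),
      numeric(1))
  if (length(width_ratios) != np || any(width_ratios <= 0))
    stop("width_ratios must be positive, one per panel")
  W <- band[2L] - gap * (np - 1L)
  if (W <= 0) stop("gaps too large for the composite band")
  widths <- W * width_ratios / sum(width_ratios)
  starts <- band[1L] + c(0, cumsum(widths + gap))[seq_len(np)]

  default_pr <- c(0.15, 0.02, 0.70, 0.83)
  # vertical joins stack top-down: panel 1 at the top
  ybots <- band[1L] + band[2L] - cumsum(widths + gap) + gap
  panel_rect <- function(k) {
    if (axis == "horizontal") c(starts[k], default_pr[2L], widths[k], default_pr[4L])
    else c(default_pr[1L], ybots[k], default_pr[3L], widths[k])
  }
  build_one <- function(k, overrides = list()) {
    args <- utils::modifyList(specs[[k]]$args, overrides)
    args$plot_rect <- panel_rect(k)
    do.call(specs[[k]]$builder, args)
  }
  fm_main <- build_one(main)
  impose <- if (axis == "horizontal") {
    lab <- .split_labels_by_id(fm_main@rowSplit, fm_main@rowOrder)
    function(ids) {
      ov <- list(row_order = fm_main@rowOrder)
      if (!is.null(lab)) ov$row_split <- unname(lab[ids])
      ov
    }
  } else {
    lab <- .split_labels_by_id(fm_main@colSplit, fm_main@colOrder)
    function(ids) {
      ov <- list(col_order = fm_main@colOrder)
      if (!is.null(lab)) ov$col_split <- unname(lab[ids])
      ov
    }
  }
  figs <- vector("list", np)
  figs[[main]] <- fm_main
  for (k in seq_len(np)) {
    if (k == main) next
    # split labels must align with panel k's own input id order
    ids_k <- .spec_matrix_ids(specs[[k]], shared_axis)
    figs[[k]] <- build_one(k, impose(ids_k))
  }

  prims <- do.call(c, lapply(figs, function(f) f@scene@primitives))
  legend_items <- do.call(c, lapply(figs, function(f) f@legends))
  scene <- Scene(prims, meta = list(
    figure = "composite", axis = axis, main = main, n_panels = np,
    legend_side = legend_side,
    panel_figures = lapply(figs, function(f) f@scene@meta$figure)))
  new("FigureModel", grid = fm_main@grid, scene = scene,
      legends = buildLegends(legend_items),
      rowOrder = fm_main@rowOrder, colOrder = fm_main@colOrder,
      rowSplit = fm_main@rowSplit, colSplit = fm_main@colSplit)
}
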