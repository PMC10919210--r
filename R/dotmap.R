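#' @include clustermap.R
NULL

#' Pivot a long-form dot table to grids
#'
#' Rows are the distinct row keys in first-appearance order, columns the
#' distinct column keys; absent (row, col) pairs become missing cells (no
#' dot). Returns the size-driving value grid as a
#' \linkS4class{LabeledMatrix} plus parallel color-value and hue grids.
#'
#' @param table a \linkS4class{DotTable}.
#' @return list(values, color, hue)
#' @export
pivotDotTable <- function(table) {
  stopifnot(is(table, "DotTable"))
  r <- table@records
  if (!nrow(r)) stop("empty dot table")
  rows <- unique(r$row_key); cols <- unique(r$col_key)
  key <- paste(r$row_key, r$col_key, sep = "\r")
  if (anyDuplicated(key))
    stop(sprintf("duplicate (row, col) record for %s",
                 gsub("\r", ", ", key[duplicated(key)][1L])))
  ri <- match(r$row_key, rows); ci <- match(r$col_key, cols)
  vals <- matrix(NA_real_, length(rows), length(cols),
                 dimnames = list(rows, cols))
  vals[cbind(ri, ci)] <- r$value
  colg <- matrix(if (is.numeric(r$color_value)) NA_real_ else NA_character_,
                 length(rows), length(cols), dimnames = list(rows, cols))
  colg[cbind(ri, ci)] <- r$color_value
  hue <- matrix(NA_character_, length(rows), length(cols),
                dimnames = list(rows, cols))
  hue[cbind(ri, ci)] <- r$hue
  list(values = LabeledMatrix(vals, rows, cols), color = colg, hue = hue)
}

#' Build a dot heatmap (up to five channels)
#'
#' Pivots the long-form table, clusters and splits the pivoted value grid
#' like a cluster heatmap (missing cells handled pairwise-complete), and
#' draws one marker per present cell: position encodes row and column, the
#' area-linear radius encodes \code{value}, fill encodes \code{color_value},
#' and the marker shape encodes \code{hue} (levels assigned shapes in
#' first-appearance order). Cells at the size minimum get radius 0 and no
#' marker. Legends: color first, then size references, then a marker legend
#' when more than one hue level is present.
#'
#' @param table a \linkS4class{DotTable}.
#' @param size_scale a \linkS4class{SizeScale}; default spans the data range
#'   with rMax 0.45.
#' @param color \linkS4class{ColorSpec} for color_value; default inferred
#'   (continuous viridis-like, or categorical).
#' @param top_annotation,bottom_annotation,left_annotation,right_annotation
#'   annotation tracks, as in \code{\link{buildClustermap}}.
#' @param row_split,col_split,cluster_rows,cluster_cols,method,metric as in
#'   \code{\link{buildClustermap}}.
#' @param row_gap,col_gap,plot_rect,track_pad geometry options.
#' @return a \linkS4class{FigureModel}
#' @export
buildDotmap <- function(table, size_scale = NULL, color = NULL,
                        top_annotation = list(), bottom_annotation = list(),
                        left_annotation = list(), right_annotation = list(),
                        row_split = NULL, col_split = NULL,
                        cluster_rows = TRUE, cluster_cols = TRUE,
                        method = "average", metric = "euclidean",
                        row_gap = 0.01, col_gap = 0.01,
                        plot_rect = c(0.15, 0.02, 0.70, 0.83),
                        track_pad = 0.005) {
  piv <- pivotDotTable(table)
  mat <- piv$values
  nr <- nrow(mat@values); nc <- ncol(mat@values)
  row_split <- .check_split_arg(row_split, nr, "row")
  col_split <- .check_split_arg(col_split, nc, "column")
  tr_top <- .track_list(top_annotation); tr_bot <- .track_list(bottom_annotation)
  tr_left <- .track_list(left_annotation); tr_right <- .track_list(right_annotation)
  .check_track_ids(c(tr_top, tr_bot), mat@colIds, "columns")
  .check_track_ids(c(tr_left, tr_right), mat@rowIds, "rows")
  rowp <- .axis_pipeline(mat, "rows", row_split, cluster_rows, method, metric)
  colp <- .axis_pipeline(mat, "cols", col_split, cluster_cols, method, metric)
  row_order_ids <- mat@rowIds[rowp$positions + 1L]
  col_order_ids <- mat@colIds[colp$positions + 1L]
  sides <- list(top = tr_top, bottom = tr_bot, left = tr_left, right = tr_right)
  side_ext <- lapply(sides, function(tr) vapply(tr, function(t) t@extent, numeric(1)))
  body_rect <- .shrink_plot_rect(plot_rect, side_ext, track_pad)
  grid <- computeGrid(lengths(rowp$resolution@members),
                      lengths(colp$resolution@members),
                      body_rect, row_gap, col_gap)
  rcells <- cellIntervals(grid, "rows")
  ccells <- cellIntervals(grid, "cols")

  vals <- mat@values[rowp$positions + 1L, colp$positions + 1L, drop = FALSE]
  colv <- piv$color[rowp$positions + 1L, colp$positions + 1L, drop = FALSE]
  huev <- piv$hue[rowp$positions + 1L, colp$positions + 1L, drop = FALSE]

  finite_vals <- vals[is.finite(vals)]
  if (is.null(size_scale)) {
    vmin <- min(finite_vals); vmax <- max(finite_vals)
    if (vmin == vmax) { vmin <- vmin - 0.5; vmax <- vmax + 0.5 }
    size_scale <- SizeScale(vmin, vmax, rMax = 0.45)
  }
  r_cap <- min(size_scale@rMax, 0.45)  # adjacent dots never touch across gaps
  color_spec <- resolveColorSpec(
    if (!is.null(color)) color
    else if (is.numeric(colv)) colorSpecContinuous(title = "color")
    else colorSpecCategorical(title = "color"), colv)

  # hue -> marker by first appearance in the input records
  hue_levels <- unique(table@records$hue)
  hue_levels <- hue_levels[!is.na(hue_levels)]
  markers <- stats::setNames(rep_len(.MARKERS, max(length(hue_levels), 1L)),
                             if (length(hue_levels)) hue_levels else "all")

  prims <- list()
  for (i in seq_len(nr)) {
    hrow <- (rcells$lo[i] + rcells$hi[i]) / 2
    half_h <- (rcells$hi[i] - rcells$lo[i]) / 2
    fills <- mapColors(colv[i, ], color_spec)
    rads <- rep(0, nc)
    ok <- is.finite(vals[i, ])
    rads[ok] <- mapSizes(vals[i, ok], size_scale)
    for (j in seq_len(nc)) {
      if (!is.finite(vals[i, j]) || rads[j] <= 0) next
      half <- min(half_h, (ccells$hi[j] - ccells$lo[j]) / 2)
      shape <- if (!is.na(huev[i, j]) && huev[i, j] %in% names(markers))
        markers[[huev[i, j]]] else "circle"
      prims[[length(prims) + 1L]] <- sceneMarker(
        (ccells$lo[j] + ccells$hi[j]) / 2, hrow,
        min(rads[j], r_cap) * half, shape = shape, fill = fills[j],
        tags = list(row_id = row_order_ids[i], col_id = col_order_ids[j]))
    }
  }

  legend_items <- list(legendFromColorSpec(color_spec),
                       legendFromSizeScale(size_scale))
  if (length(hue_levels) > 1L)
    legend_items[[length(legend_items) + 1L]] <- legendFromMarkers(markers)

  for (side in names(sides)) {
    tracks <- sides[[side]]
    if (!length(tracks)) next
    rects <- allocateTracks(side, side_ext[[side]], body_rect, pad = track_pad)
    grid@trackRects[[side]] <- rects
    axis_cells <- if (side %in% c("top", "bottom")) ccells else rcells
    order_ids <- if (side %in% c("top", "bottom")) col_order_ids else row_order_ids
    for (ti in seq_along(tracks)) {
      out <- renderTrack(tracks[[ti]], order_ids, rects[[ti]], axis_cells, side)
      prims <- c(prims, out$primitives)
      if (!is.null(out$spec))
        legend_items[[length(legend_items) + 1L]] <-
          legendFromColorSpec(out$spec, if (tracks[[ti]]@kind == "simple")
            .track_values(tracks[[ti]], order_ids) else NULL)
    }
  }

  scene <- Scene(prims, meta = list(figure = "dotmap", method = method,
                                    metric = metric, n_rows = nr, n_cols = nc))
  new("FigureModel", grid = grid, scene = scene,
      legends = buildLegends(legend_items),
      rowOrder = row_order_ids, colOrder = col_order_ids,
      rowSplit = rowp$resolution, colSplit = colp$resolution)
}
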