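#' @include AllClasses.R
NULL

#' Standardize a matrix by rows or columns
#'
#' Subtracts the axis mean and divides by the axis (population, ddof = 0)
#' standard deviation, computed over observed entries. Constant axes become
#' all-zero and are flagged in the result's metadata
#' (\code{constant_rows}/\code{constant_cols}).
#'
#' @param x a \linkS4class{LabeledMatrix}.
#' @param mode "none", "rows" or "cols".
#' @return a standardized \linkS4class{LabeledMatrix}
#' @export
standardizeMatrix <- function(x, mode = c("none", "rows", "cols")) {
  mode <- match.arg(mode)
  if (mode == "none") return(x)
  v <- x@values
  byrow <- mode == "rows"
  if (!byrow) v <- t(v)
  mu <- rowMeans(v, na.rm = TRUE)
  sd0 <- sqrt(rowMeans((v - mu)^2, na.rm = TRUE))
  const <- which(sd0 == 0 | !is.finite(sd0))
  sd0[const] <- 1
  z <- (v - mu) / sd0
  z[const, ] <- 0
  if (!byrow) z <- t(z)
  ids <- if (byrow) x@rowIds else x@colIds
  md <- x@metadata
  md[[if (byrow) "constant_rows" else "constant_cols"]] <- ids[const]
  LabeledMatrix(z, x@rowIds, x@colIds, metadata = md)
}

.check_split_arg <- function(split, n, what) {
  if (is.null(split)) return(NULL)
  if (is.numeric(split) && length(split) == 1L) return(split)
  if (length(split) == n) return(as.character(split))
  stop(sprintf("%s split must be NULL, a single integer, or a vector of length %d",
               what, n))
}

# positions (0-based) in display order from a SplitResolution
.split_positions <- function(res) unlist(res@members, use.names = FALSE)

# per-axis clustering + split resolution; returns orders, resolution, links
.axis_pipeline <- function(mat, axis, split, cluster, method, metric) {
  v <- .axis_items(mat, axis)
  n <- nrow(v)
  link <- NULL
  categorical <- !is.null(split) && length(split) > 1L
  if (cluster && n >= 2L && !categorical)
    link <- linkageTree(pairwiseDistance(mat, axis, metric), method, metric = metric)
  full <- .resolve_split_full(mat, axis, split, link = link,
                              cluster = cluster && n >= 2L,
                              method = method, metric = metric)
  list(resolution = full$resolution, link = link,
       group_links = full$group_links,
       positions = .split_positions(full$resolution))
}

.track_list <- function(x) {
  if (is.null(x)) return(list())
  if (is(x, "Track")) return(list(x))
  stopifnot(all(vapply(x, is, logical(1), "Track")))
  x
}

.check_track_ids <- function(tracks, ids, axis_name) {
  for (tr in tracks) {
    nm <- if (is.matrix(tr@data)) rownames(tr@data) else names(tr@data)
    extra <- setdiff(nm, ids)
    if (length(extra))
      stop(sprintf("annotation id '%s' (track '%s') absent from matrix %s",
                   extra[1L], tr@title, axis_name))
  }
}

# Reserve per-side room for annotation stacks inside the outer plot area:
# the heatmap body is the outer rectangle minus each side's track extents
# (pads included), so defaults always fit on the page.
.shrink_plot_rect <- function(plot_rect, side_extents, pad) {
  res <- vapply(side_extents, function(e)
    if (length(e)) sum(e) + pad * length(e) else 0, numeric(1))
  body <- c(plot_rect[1L] + res[["left"]],
            plot_rect[2L] + res[["bottom"]],
            plot_rect[3L] - res[["left"]] - res[["right"]],
            plot_rect[4L] - res[["top"]] - res[["bottom"]])
  if (body[3L] <= 0 || body[4L] <= 0)
    stop("annotation tracks leave no room for the heatmap body")
  body
}

# leaf centers (figure coords, indexed by 0-based leaf id) from cells +
# display positions
.leaf_centers <- function(cells, positions) {
  centers <- numeric(length(positions))
  mid <- (cells$lo + cells$hi) / 2
  centers[positions + 1L] <- mid
  centers
}

#' Build an annotated cluster heatmap
#'
#' The full pipeline: standardize, cluster each axis (four linkage methods,
#' three metrics, deterministic tie-breaking), resolve row/column splits
#' (tree cut via an integer, metadata via a categorical vector), compute the
#' split panel grid, paint one rect per cell (missing cells in the missing
#' color), stack and render annotation tracks on all four sides, draw
#' dendrograms on the outermost position of their side, and collect
#' deduplicated legends. Deterministic: the same inputs give a byte-identical
#' serialized scene.
#'
#' @param matrix a \linkS4class{LabeledMatrix}.
#' @param top_annotation,bottom_annotation column annotation tracks (a
#'   \linkS4class{Track} or list of them), innermost first.
#' @param left_annotation,right_annotation row annotation tracks.
#' @param row_split,col_split NULL, an integer k (tree cut), or a
#'   categorical vector along the axis.
#' @param cluster_rows,cluster_cols enable clustering per axis.
#' @param method,metric linkage method and distance metric.
#' @param color cell \linkS4class{ColorSpec}; default a viridis-like
#'   continuous spec over the data range.
#' @param standardize "none", "rows" or "cols" (z-score before clustering
#'   and painting).
#' @param show_row_dendrogram,show_col_dendrogram draw trees (default: when
#'   the axis is clustered). With a categorical split, one tree per group;
#'   with an integer split, one global tree spanning the gaps.
#' @param row_gap,col_gap gap between split panels (figure fraction).
#' @param plot_rect the heatmap body rectangle; the default leaves a right
#'   legend column and margins for annotations.
#' @param dendrogram_extent,track_pad geometry defaults.
#' @param row_order,col_order optional explicit display orders (character
#'   ids): clustering on that axis is skipped and the order imposed — used
#'   by \code{\link{composite}} to let the main panel govern joined panels.
#' @return a \linkS4class{FigureModel}
#' @examples
#' fx <- makeFixtureMatrix(12, 8, n_col_groups = 2, group_shift = 2, seed = 7)
#' fm <- buildClustermap(fx$matrix, row_split = 2,
#'   col_split = annotationColumn(fx$annotation, "group"))
#' fm
#' @export
buildClustermap <- function(matrix,
                            top_annotation = list(), bottom_annotation = list(),
                            left_annotation = list(), right_annotation = list(),
                            row_split = NULL, col_split = NULL,
                            cluster_rows = TRUE, cluster_cols = TRUE,
                            method = "average", metric = "euclidean",
                            color = NULL, standardize = "none",
                            show_row_dendrogram = NULL, show_col_dendrogram = NULL,
                            row_gap = 0.01, col_gap = 0.01,
                            plot_rect = c(0.15, 0.02, 0.70, 0.83),
                            dendrogram_extent = 0.05, track_pad = 0.005,
                            row_order = NULL, col_order = NULL) {
  stopifnot(is(matrix, "LabeledMatrix"))
  if (!is.null(row_order)) {
    if (!setequal(row_order, matrix@rowIds))
      stop("row_order must be a permutation of the matrix row ids")
    perm <- match(row_order, matrix@rowIds)
    matrix <- LabeledMatrix(matrix@values[perm, , drop = FALSE],
                            row_order, matrix@colIds, matrix@metadata)
    if (!is.null(row_split) && length(row_split) > 1L) row_split <- row_split[perm]
    cluster_rows <- FALSE
    if (is.null(show_row_dendrogram)) show_row_dendrogram <- FALSE
  }
  if (!is.null(col_order)) {
    if (!setequal(col_order, matrix@colIds))
      stop("col_order must be a permutation of the matrix column ids")
    perm <- match(col_order, matrix@colIds)
    matrix <- LabeledMatrix(matrix@values[, perm, drop = FALSE],
                            matrix@rowIds, col_order, matrix@metadata)
    if (!is.null(col_split) && length(col_split) > 1L) col_split <- col_split[perm]
    cluster_cols <- FALSE
    if (is.null(show_col_dendrogram)) show_col_dendrogram <- FALSE
  }
  mat <- standardizeMatrix(matrix, standardize)
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

  show_col_d <- show_col_dendrogram %||% (cluster_cols && nc >= 2L)
  show_row_d <- show_row_dendrogram %||% (cluster_rows && nr >= 2L)
  sides <- list(top = tr_top, bottom = tr_bot, left = tr_left, right = tr_right)
  dendro_side <- list(top = if (show_col_d) "cols", bottom = NULL,
                      left = if (show_row_d) "rows", right = NULL)
  side_ext <- lapply(names(sides), function(side) {
    e <- vapply(sides[[side]], function(t) t@extent, numeric(1))
    if (!is.null(dendro_side[[side]])) e <- c(e, dendrogram_extent)
    e
  })
  names(side_ext) <- names(sides)
  body_rect <- .shrink_plot_rect(plot_rect, side_ext, track_pad)

  grid <- computeGrid(lengths(rowp$resolution@members),
                      lengths(colp$resolution@members),
                      body_rect, row_gap, col_gap)
  rcells <- cellIntervals(grid, "rows")
  ccells <- cellIntervals(grid, "cols")

  cell_spec <- resolveColorSpec(
    if (is.null(color)) colorSpecContinuous(title = "value") else color,
    mat@values)
  vals_disp <- mat@values[rowp$positions + 1L, colp$positions + 1L, drop = FALSE]
  prims <- vector("list", nr * nc)
  k <- 0L
  for (i in seq_len(nr)) {
    fills <- mapColors(vals_disp[i, ], cell_spec)
    for (j in seq_len(nc)) {
      k <- k + 1L
      prims[[k]] <- sceneRect(ccells$lo[j], rcells$lo[i],
                              ccells$hi[j] - ccells$lo[j],
                              rcells$hi[i] - rcells$lo[i],
                              fill = fills[j],
                              tags = list(row_id = row_order_ids[i],
                                          col_id = col_order_ids[j]))
    }
  }

  legend_items <- list(legendFromColorSpec(cell_spec))
  for (side in names(sides)) {
    tracks <- sides[[side]]
    extents <- side_ext[[side]]
    dend <- dendro_side[[side]]
    if (!length(extents)) next
    rects <- allocateTracks(side, extents, body_rect, pad = track_pad)
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
    if (!is.null(dend)) {
      drect <- rects[[length(rects)]]
      ax <- dend
      axp <- if (ax == "cols") colp else rowp
      axcells <- if (ax == "cols") ccells else rcells
      if (length(axp$group_links)) {
        # one tree per categorical group, spanning that group's cells
        off <- 0L
        for (gi in seq_along(axp$resolution@labels)) {
          memb <- axp$resolution@members[[gi]]
          gl <- axp$group_links[[axp$resolution@labels[gi]]]
          if (!is.null(gl) && gl@nLeaves >= 2L) {
            sub <- axcells[off + seq_along(memb), , drop = FALSE]
            centers <- .leaf_centers(sub, leafOrder(gl))
            prims <- c(prims, dendrogramGeometry(gl, side, drect, centers))
          }
          off <- off + length(memb)
        }
      } else if (!is.null(axp$link)) {
        # global tree (integer split spans the gaps)
        centers <- numeric(axp$link@nLeaves)
        centers[axp$positions + 1L] <- (axcells$lo + axcells$hi) / 2
        prims <- c(prims, dendrogramGeometry(axp$link, side, drect, centers))
      }
    }
  }

  scene <- Scene(prims, meta = list(
    figure = "clustermap", method = method, metric = metric,
    standardize = standardize, n_rows = nr, n_cols = nc,
    row_gap = row_gap, col_gap = col_gap))
  new("FigureModel", grid = grid, scene = scene,
      legends = buildLegends(legend_items),
      rowOrder = row_order_ids, colOrder = col_order_ids,
      rowSplit = rowp$resolution, colSplit = colp$resolution)
}

#' Lay out annotation tracks without a heatmap body
#'
#' The same track machinery stacked over a zero-height baseline: tracks keep
#' their order (first track nearest the baseline), positions share one axis,
#' and legends are still collected.
#'
#' @param tracks a \linkS4class{Track} or list of tracks (at least one).
#' @param axis "cols" or "rows" (orientation of the position axis).
#' @param order character ids in display order.
#' @param plot_rect baseline rectangle; its width (cols) or height (rows)
#'   spans the positions.
#' @param track_pad gap between tracks.
#' @return a \linkS4class{FigureModel} (grid is NULL)
#' @export
annotationOnly <- function(tracks, axis = c("cols", "rows"), order,
                           plot_rect = c(0.15, 0.10, 0.70, 0.0),
                           track_pad = 0.005) {
  axis <- match.arg(axis)
  tracks <- .track_list(tracks)
  if (!length(tracks)) stop("annotationOnly needs at least one track")
  order <- as.character(order)
  n <- length(order)
  side <- if (axis == "cols") "top" else "left"
  if (axis == "cols") {
    edges <- plot_rect[1L] + plot_rect[3L] * (0:n) / n
    cells <- data.frame(lo = edges[-(n + 1L)], hi = edges[-1L])
    base <- c(plot_rect[1L], plot_rect[2L], plot_rect[3L], 0)
  } else {
    top <- plot_rect[2L] + plot_rect[4L]
    span <- if (plot_rect[4L] > 0) plot_rect[4L] else 0.7
    edges <- top - span * (0:n) / n
    cells <- data.frame(lo = edges[-1L], hi = edges[-(n + 1L)])
    base <- c(plot_rect[1L] + plot_rect[3L], top - span, 0, span)
  }
  prims <- list(); legend_items <- list()
  extents <- vapply(tracks, function(t) t@extent, numeric(1))
  rects <- allocateTracks(side, extents, base, pad = track_pad)
  for (ti in seq_along(tracks)) {
    out <- renderTrack(tracks[[ti]], order, rects[[ti]], cells, side)
    prims <- c(prims, out$primitives)
    if (!is.null(out$spec))
      legend_items[[length(legend_items) + 1L]] <-
        legendFromColorSpec(out$spec, if (tracks[[ti]]@kind == "simple")
          .track_values(tracks[[ti]], order) else NULL)
  }
  scene <- Scene(prims, meta = list(figure = "annotation_only", axis = axis))
  new("FigureModel", grid = NULL, scene = scene,
      legends = buildLegends(legend_items),
      rowOrder = if (axis == "rows") order else character(0),
      colOrder = if (axis == "cols") order else character(0))
}
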