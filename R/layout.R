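#' @include AllClasses.R
NULL

# Coordinate convention, used everywhere: data cell (i, j) occupies the
# half-open unit square [j, j+1) x [i, i+1) in data space with row 0 at the
# TOP; panels carry an affine map from data space to normalized figure
# space (origin bottom-left, y up).

#' Compute the panel grid implied by row/column splits
#'
#' Panel widths are proportional to column-group sizes and heights to
#' row-group sizes after removing the fixed inter-panel gaps; the panels
#' plus gaps tile the plot rectangle exactly. Row group 1 is at the top.
#'
#' @param row_group_sizes,col_group_sizes positive integer group sizes, in
#'   display order.
#' @param plot_rect numeric c(x, y, w, h) in figure coordinates.
#' @param row_gap,col_gap gap between adjacent panels (figure fraction).
#' @return a \linkS4class{PanelGrid}
#' @export
computeGrid <- function(row_group_sizes, col_group_sizes,
                        plot_rect = c(0.15, 0.02, 0.7, 0.83),
                        row_gap = 0.01, col_gap = 0.01) {
  if (any(row_group_sizes <= 0) || any(col_group_sizes <= 0))
    stop("group sizes must be positive")
  nr <- length(row_group_sizes); nc <- length(col_group_sizes)
  W <- plot_rect[3L]; H <- plot_rect[4L]
  if (col_gap * (nc - 1L) >= W || row_gap * (nr - 1L) >= H)
    stop("gaps too large for the plot rectangle")
  widths <- (W - col_gap * (nc - 1L)) * col_group_sizes / sum(col_group_sizes)
  heights <- (H - row_gap * (nr - 1L)) * row_group_sizes / sum(row_group_sizes)
  xs <- plot_rect[1L] + c(0, cumsum(widths + col_gap))[seq_len(nc)]
  # row group 1 at the top: walk down from the top edge
  ytops <- plot_rect[2L] + H - c(0, cumsum(heights + row_gap))[seq_len(nr)]
  panels <- lapply(seq_len(nr), function(rg)
    lapply(seq_len(nc), function(cg)
      c(xs[cg], ytops[rg] - heights[rg], widths[cg], heights[rg])))
  new("PanelGrid", plotRect = as.numeric(plot_rect), panels = panels,
      rowSizes = as.numeric(row_group_sizes), colSizes = as.numeric(col_group_sizes),
      rowGap = row_gap, colGap = col_gap,
      trackRects = list(top = list(), bottom = list(), left = list(), right = list()))
}

#' Per-position intervals along one axis of a panel grid
#'
#' Concatenates the grid's panels (display order, gaps included) into one
#' interval per data position: the figure-coordinate span of each heatmap
#' column (axis = "cols", left to right) or row (axis = "rows", top to
#' bottom).
#'
#' @param grid a \linkS4class{PanelGrid}
#' @param axis "cols" or "rows"
#' @return data.frame with columns lo, hi (for rows: hi is the top edge)
#' @export
cellIntervals <- function(grid, axis = c("cols", "rows")) {
  axis <- match.arg(axis)
  if (axis == "cols") {
    sizes <- grid@colSizes
    rects <- grid@panels[[1L]]
    lo <- hi <- numeric(0)
    for (g in seq_along(sizes)) {
      r <- rects[[g]]
      edges <- r[1L] + r[3L] * (0:sizes[g]) / sizes[g]
      lo <- c(lo, edges[-length(edges)]); hi <- c(hi, edges[-1L])
    }
  } else {
    sizes <- grid@rowSizes
    lo <- hi <- numeric(0)
    for (g in seq_along(sizes)) {
      r <- grid@panels[[g]][[1L]]
      top <- r[2L] + r[4L]
      edges <- top - r[4L] * (0:sizes[g]) / sizes[g]   # walking down
      hi <- c(hi, edges[-length(edges)]); lo <- c(lo, edges[-1L])
    }
  }
  data.frame(lo = lo, hi = hi)
}

# map a data-axis coordinate u (cell i spans [i, i+1)) to figure coords
.data_to_figure <- function(cells, u) {
  n <- nrow(cells)
  i <- pmin(pmax(floor(u), 0), n - 1L)
  frac <- u - i
  cells$lo[i + 1L] + frac * (cells$hi[i + 1L] - cells$lo[i + 1L])
}

#' Stack annotation track rectangles on one side of the plot
#'
#' The first track sits adjacent to the heatmap; later tracks stack farther
#' out. Track rectangles share the plot rectangle's full cross-axis span
#' (gaps included) so annotation cells align with split panels.
#'
#' @param side "top", "bottom", "left" or "right".
#' @param track_extents ordered positive figure-fraction thicknesses.
#' @param plot_rect numeric c(x, y, w, h).
#' @param pad gap inserted before each track.
#' @return list of numeric c(x, y, w, h), one per track (possibly empty)
#' @export
allocateTracks <- function(side = c("top", "bottom", "left", "right"),
                           track_extents, plot_rect, pad = 0.005) {
  side <- match.arg(side)
  if (!length(track_extents)) return(list())
  if (any(track_extents <= 0)) stop("track extents must be positive")
  x <- plot_rect[1L]; y <- plot_rect[2L]; w <- plot_rect[3L]; h <- plot_rect[4L]
  offs <- pad + c(0, cumsum(track_extents + pad))[seq_along(track_extents)]
  rects <- lapply(seq_along(track_extents), function(i) {
    e <- track_extents[i]; o <- offs[i]
    switch(side,
      top = c(x, y + h + o, w, e),
      bottom = c(x, y - o - e, w, e),
      left = c(x - o - e, y, e, h),
      right = c(x + w + o, y, e, h))
  })
  for (r in rects)
    if (r[1L] < -1e-9 || r[2L] < -1e-9 || r[1L] + r[3L] > 1 + 1e-9 ||
        r[2L] + r[4L] > 1 + 1e-9)
      stop(sprintf("track stack on side '%s' leaves the figure", side))
  rects
}

#' Rectangular dendrogram geometry
#'
#' One 3-segment bracket per merge (n-1 polylines). Leaves sit at their cell
#' centers on the inner (heatmap-adjacent) edge; merge depth is proportional
#' to merge height, normalized so the root reaches the outer edge.
#'
#' @param link a \linkS4class{LinkageResult}
#' @param orientation side the tree is drawn on ("top": inner edge is the
#'   rectangle's bottom; etc.).
#' @param rect numeric c(x, y, w, h) track rectangle.
#' @param centers optional per-leaf along-axis figure coordinates (indexed
#'   by 0-based leaf id); defaults to even slots in display (leaf) order.
#' @return list of polyline primitives
#' @export
dendrogramGeometry <- function(link, orientation = c("top", "bottom", "left", "right"),
                               rect, centers = NULL) {
  orientation <- match.arg(orientation)
  n <- link@nLeaves
  if (n < 2L) return(list())
  along_horiz <- orientation %in% c("top", "bottom")
  if (is.null(centers)) {
    ord <- leafOrder(link)
    slot <- integer(n); slot[ord + 1L] <- seq_len(n) - 1L
    a0 <- if (along_horiz) rect[1L] else rect[2L] + rect[4L]
    span <- if (along_horiz) rect[3L] else -rect[4L]   # rows walk down
    centers <- a0 + span * (slot + 0.5) / n
  }
  m <- link@merges
  hmax <- max(m[, 3L], 1e-12)
  pos <- c(centers, rep(NA_real_, n - 1L))   # node -> along-axis coord
  dep <- c(rep(0, n), rep(NA_real_, n - 1L)) # node -> normalized depth
  prims <- vector("list", n - 1L)
  to_fig <- function(a, d) {
    # a: along-axis figure coord; d: depth fraction 0 (inner) .. 1 (outer)
    switch(orientation,
      top = list(x = a, y = rect[2L] + d * rect[4L]),
      bottom = list(x = a, y = rect[2L] + rect[4L] - d * rect[4L]),
      left = list(x = rect[1L] + rect[3L] - d * rect[3L], y = a),
      right = list(x = rect[1L] + d * rect[3L], y = a))
  }
  for (t in seq_len(n - 1L)) {
    l <- m[t, 1L] + 1L; r <- m[t, 2L] + 1L
    d <- m[t, 3L] / hmax
    p1 <- to_fig(pos[l], dep[l]); p2 <- to_fig(pos[l], d)
    p3 <- to_fig(pos[r], d); p4 <- to_fig(pos[r], dep[r])
    prims[[t]] <- scenePolyline(c(p1$x, p2$x, p3$x, p4$x),
                                c(p1$y, p2$y, p3$y, p4$y),
                                stroke = "#000000ff", stroke_width = 0.0012)
    node <- n + t
    pos[node] <- (pos[l] + pos[r]) / 2
    dep[node] <- d
  }
  prims
}

#' Collapse runs of equal adjacent labels to anchors
#'
#' Maximal runs of consecutive equal labels collapse to one anchor at the
#' run's center (positions occupy unit cells [i, i+1)); unlabeled positions
#' (NA or "") produce nothing; non-adjacent equal labels are NOT merged.
#'
#' @param labels character vector, one label (or NA) per axis position.
#' @return list with anchors (numeric, data-axis units), labels (character)
#'   and widths (run lengths)
#' @export
mergeLabelRuns <- function(labels) {
  labels <- as.character(labels)
  labels[!is.na(labels) & !nzchar(labels)] <- NA_character_
  anchors <- numeric(0); labs <- character(0); widths <- numeric(0)
  i <- 1L; n <- length(labels)
  while (i <= n) {
    if (is.na(labels[i])) { i <- i + 1L; next }
    j <- i
    while (j < n && !is.na(labels[j + 1L]) && labels[j + 1L] == labels[i]) j <- j + 1L
    anchors <- c(anchors, (i - 1L + j) / 2)   # cells (i-1)..(j-1): center
    labs <- c(labs, labels[i])
    widths <- c(widths, j - i + 1L)
    i <- j + 1L
  }
  list(anchors = anchors, labels = labs, widths = widths)
}

#' Distribute labels evenly along an axis with leader lines
#'
#' Slot centers are evenly spaced: with \code{extend = TRUE} over the full
#' axis interval [0, L], slot i at L(i - 0.5)/m; with \code{extend = FALSE}
#' the same rule over [first anchor - half mean run width, last anchor +
#' half mean run width], clipped to [0, L]. Slots keep the anchors'
#' left-to-right order, so leader lines never cross. Each leader is a
#' 3-segment polyline: a stub from the anchor (25% of the track extent), a
#' diagonal to the slot over the middle 50%, and a stub to the text.
#'
#' @param anchors strictly increasing data-axis coordinates.
#' @param labels character, one per anchor.
#' @param axis_interval axis length L (cells span [0, L]).
#' @param extend spread slots across the whole axis.
#' @param min_slot minimal slot spacing; an error advises fewer labels when
#'   m * min_slot exceeds the interval.
#' @param run_widths optional run widths (from \code{\link{mergeLabelRuns}})
#'   used for the extend = FALSE interval; defaults to L/m each.
#' @param rotation text rotation in degrees.
#' @return a \linkS4class{LabelPlacement}; leader ys are track-local in
#'   [0, 1] (0 = inner edge), xs in data-axis units
#' @export
distributeLabels <- function(anchors, labels, axis_interval, extend = TRUE,
                             min_slot = 0, run_widths = NULL, rotation = 0) {
  m <- length(anchors)
  if (m < 1L) stop("need at least one label")
  if (length(labels) != m) stop("one label per anchor required")
  if (m > 1L && any(diff(anchors) <= 0)) stop("anchors must be strictly increasing")
  L <- axis_interval
  if (extend) { a <- 0; b <- L }
  else {
    mrw <- if (!is.null(run_widths)) mean(run_widths) else L / m
    a <- max(0, anchors[1L] - mrw / 2)
    b <- min(L, anchors[m] + mrw / 2)
  }
  if (m * min_slot > (b - a) + 1e-12)
    stop(sprintf("%d labels need %.3g axis units at min_slot=%.3g; use fewer labels",
                 m, m * min_slot, min_slot))
  slots <- a + (b - a) * (seq_len(m) - 0.5) / m
  leaders <- lapply(seq_len(m), function(i)
    list(xs = c(anchors[i], anchors[i], slots[i], slots[i]),
         ys = c(0, 0.25, 0.75, 1)))
  new("LabelPlacement", anchors = as.numeric(anchors), slotPos = slots,
      texts = as.character(labels), rotation = as.numeric(rotation),
      leaders = leaders)
}
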