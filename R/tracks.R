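#' @include AllClasses.R
NULL

#' Annotation track constructors
#'
#' One constructor per track flavor. Data are bound to the heatmap axis by
#' name: names must be a subset check against the matrix ids at build time.
#'
#' @param data simple/scatter/label: a named vector; bar: a named vector or
#'   a matrix with one row per position (named columns = series; 2+ series
#'   switch to stacked mode automatically); box: a named list of numeric
#'   sample vectors, or a matrix whose named rows are positions.
#' @param color optional \linkS4class{ColorSpec}; defaults are derived from
#'   the data (categorical palette or viridis-like ramp).
#' @param extent track thickness, figure fraction.
#' @param title legend/track title.
#' @param add_text label contiguous category blocks (simple tracks).
#' @param merge merge runs of equal adjacent labels (label tracks).
#' @param extend spread label slots over the whole axis.
#' @param rotation label text rotation, degrees.
#' @param min_slot minimal label slot spacing, figure fraction.
#' @return a \linkS4class{Track}
#' @name annotations
NULL

#' @rdname annotations
#' @export
annoSimple <- function(data, color = NULL, extent = 0.03, title = "annotation",
                       add_text = FALSE) {
  new("Track", kind = "simple", data = data, color = color, extent = extent,
      title = title, options = list(add_text = isTRUE(add_text)))
}

#' @rdname annotations
#' @export
annoBar <- function(data, color = NULL, extent = 0.08, title = "bar") {
  new("Track", kind = "bar", data = data, color = color, extent = extent,
      title = title, options = list())
}

#' @rdname annotations
#' @export
annoBox <- function(data, color = NULL, extent = 0.08, title = "box") {
  new("Track", kind = "box", data = data, color = color, extent = extent,
      title = title, options = list())
}

#' @rdname annotations
#' @export
annoScatter <- function(data, color = NULL, extent = 0.08, title = "scatter") {
  new("Track", kind = "scatter", data = data, color = color, extent = extent,
      title = title, options = list())
}

#' @rdname annotations
#' @export
annoLabel <- function(data, extent = 0.08, title = "labels", merge = TRUE,
                      extend = TRUE, rotation = 0, min_slot = 0) {
  new("Track", kind = "label", data = data, color = NULL, extent = extent,
      title = title, options = list(merge = isTRUE(merge), extend = isTRUE(extend),
                                    rotation = rotation, min_slot = min_slot))
}

# ---- orientation frame --------------------------------------------------

# A track frame maps (along figure coord, cross fraction in [0,1], 0 = the
# edge nearest the heatmap) to figure coordinates; one code path serves all
# four sides.
.track_frame <- function(side, rect) {
  x <- rect[1L]; y <- rect[2L]; w <- rect[3L]; h <- rect[4L]
  pt <- switch(side,
    top = function(a, c) list(x = a, y = y + c * h),
    bottom = function(a, c) list(x = a, y = y + h - c * h),
    left = function(a, c) list(x = x + w - c * w, y = a),
    right = function(a, c) list(x = x + c * w, y = a))
  rect_prim <- function(a0, a1, c0, c1, ...) {
    p0 <- pt(min(a0, a1), min(c0, c1)); p1 <- pt(max(a0, a1), max(c0, c1))
    xs <- sort(c(p0$x, p1$x)); ys <- sort(c(p0$y, p1$y))
    sceneRect(xs[1L], ys[1L], max(xs[2L] - xs[1L], 0), max(ys[2L] - ys[1L], 0), ...)
  }
  list(pt = pt, rect = rect_prim, horizontal = side %in% c("top", "bottom"))
}

.track_values <- function(track, order) {
  d <- track@data
  if (is.matrix(d)) {
    miss <- setdiff(order, rownames(d))
    if (length(miss)) stop(sprintf("annotation id '%s' absent from track '%s'",
                                   miss[1L], track@title))
    d[order, , drop = FALSE]
  } else if (is.list(d)) {
    miss <- setdiff(order, names(d))
    if (length(miss)) stop(sprintf("annotation id '%s' absent from track '%s'",
                                   miss[1L], track@title))
    d[order]
  } else {
    miss <- setdiff(order, names(d))
    if (length(miss)) stop(sprintf("annotation id '%s' absent from track '%s'",
                                   miss[1L], track@title))
    d[order]
  }
}

.default_spec <- function(track, vals) {
  if (!is.null(track@color)) return(track@color)
  if (is.character(vals) || is.factor(vals))
    colorSpecCategorical(title = track@title)
  else colorSpecContinuous(title = track@title)
}

# ---- renderers ----------------------------------------------------------

#' Render a simple (color bar) annotation track
#'
#' One filled rect per position, aligned with the heatmap cells (split gaps
#' mirrored). With add_text, one text per contiguous same-category block at
#' the block center, black or white for contrast against the block fill.
#'
#' @param track a simple \linkS4class{Track}.
#' @param order character ids in final display order.
#' @param rect allocated track rectangle c(x, y, w, h).
#' @param cells per-position intervals from \code{\link{cellIntervals}}.
#' @param side which side of the heatmap the track sits on.
#' @return list(primitives, spec): scene fragment plus the resolved ColorSpec
#' @export
renderSimple <- function(track, order, rect, cells, side = "top") {
  fr <- .track_frame(side, rect)
  vals <- .track_values(track, order)
  spec <- resolveColorSpec(.default_spec(track, vals), vals)
  cols <- mapColors(vals, spec)
  prims <- lapply(seq_along(vals), function(p) {
    tags <- list(track = track@title, id = order[p])
    if (spec@mode == "categorical" && !is.na(vals[p]))
      tags$category <- as.character(vals[p])
    fr$rect(cells$lo[p], cells$hi[p], 0, 1, fill = cols[p], tags = tags)
  })
  if (isTRUE(track@options$add_text) && spec@mode == "categorical") {
    v <- as.character(vals)
    i <- 1L; n <- length(v)
    while (i <= n) {
      j <- i
      while (j < n && !is.na(v[j + 1L]) && !is.na(v[i]) && v[j + 1L] == v[i]) j <- j + 1L
      if (!is.na(v[i])) {
        center <- (cells$lo[i] + cells$hi[j]) / 2
        mid <- fr$pt(center, 0.5)
        prims[[length(prims) + 1L]] <- sceneText(
          mid$x, mid$y, v[i], size = min(rect[4L], rect[3L], 0.02) * 0.7,
          color = textContrastColor(cols[i]),
          rotation = if (fr$horizontal) 0 else 90,
          tags = list(track = track@title, block = v[i]))
      }
      i <- j + 1L
    }
  }
  list(primitives = prims, spec = spec)
}

#' Render a bar / stacked-bar annotation track
#'
#' A single series gives plain bars on a value axis starting at 0 and
#' reaching the data maximum at the track's outer edge; two or more series
#' switch to stacked mode (all values must be nonnegative), bar height equal
#' to the row sum and segments stacked in column order from the baseline at
#' the heatmap-adjacent edge. One shared value axis across split panels.
#'
#' @inheritParams renderSimple
#' @return list(primitives, spec, stacked)
#' @export
renderBar <- function(track, order, rect, cells, side = "top") {
  fr <- .track_frame(side, rect)
  d <- track@data
  if (!is.matrix(d)) d <- matrix(d, ncol = 1L, dimnames = list(names(d), track@title))
  m <- .track_values(new("Track", kind = "bar", data = d, color = track@color,
                         extent = track@extent, title = track@title,
                         options = list()), order)
  stacked <- ncol(m) > 1L
  if (stacked) {
    bad <- which(m < 0, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("negative value in stacked bar at position '%s', column '%s'",
                   order[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
    vmax <- max(rowSums(m), na.rm = TRUE)
    vmin <- 0
  } else {
    vmax <- max(0, m, na.rm = TRUE)
    vmin <- min(0, m, na.rm = TRUE)
  }
  if (vmax == vmin) vmax <- vmin + 1
  cfrac <- function(v) (v - vmin) / (vmax - vmin)
  spec <- if (stacked) {
    resolveColorSpec(if (!is.null(track@color)) track@color
                     else colorSpecCategorical(title = track@title), colnames(m))
  } else NULL
  series_cols <- if (stacked) mapColors(colnames(m), spec) else
    if (!is.null(track@color) && track@color@mode == "categorical")
      mapColors(track@title, resolveColorSpec(track@color, track@title))
    else defaultPalette()[1L]
  prims <- list()
  for (p in seq_len(nrow(m))) {
    pad <- 0.1 * (cells$hi[p] - cells$lo[p])
    a0 <- cells$lo[p] + pad; a1 <- cells$hi[p] - pad
    base <- cfrac(0)
    for (s in seq_len(ncol(m))) {
      v <- m[p, s]
      if (is.na(v) || v == 0) next
      nxt <- base + v / (vmax - vmin)
      prims[[length(prims) + 1L]] <-
        fr$rect(a0, a1, base, nxt, fill = series_cols[s],
                tags = list(track = track@title, id = order[p],
                            series = colnames(m)[s]))
      if (stacked) base <- nxt
    }
  }
  list(primitives = prims, spec = spec, stacked = stacked)
}

#' Five-number boxplot statistics
#'
#' Quartiles use linear interpolation between order statistics (quantile
#' type 7); whiskers reach the most extreme samples within 1.5 IQR of the
#' box; samples beyond are outliers.
#'
#' @param samples numeric vector with at least one finite value.
#' @return list(q1, median, q3, whisker_lo, whisker_hi, outliers)
#' @export
boxStats <- function(samples) {
  s <- samples[is.finite(samples)]
  if (!length(s)) stop("boxStats needs at least one finite sample")
  q <- stats::quantile(s, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3L] - q[1L]
  inside <- s[s >= q[1L] - 1.5 * iqr & s <= q[3L] + 1.5 * iqr]
  list(q1 = q[1L], median = q[2L], q3 = q[3L],
       whisker_lo = min(inside), whisker_hi = max(inside),
       outliers = sort(s[s < q[1L] - 1.5 * iqr | s > q[3L] + 1.5 * iqr]))
}

.value_axis <- function(vals) {
  vmin <- min(vals, na.rm = TRUE); vmax <- max(vals, na.rm = TRUE)
  if (vmin == vmax) { vmin <- vmin - 0.5; vmax <- vmax + 0.5 }
  pad <- 0.05 * (vmax - vmin)
  c(vmin - pad, vmax + pad)
}

#' Render a boxplot annotation track
#'
#' Per position: box from q1 to q3, median line, whisker polylines and
#' outlier markers, on one value axis shared across positions (and split
#' panels) spanning the data range with 5% padding.
#'
#' @inheritParams renderSimple
#' @return list(primitives, spec)
#' @export
renderBox <- function(track, order, rect, cells, side = "top") {
  fr <- .track_frame(side, rect)
  d <- track@data
  if (is.matrix(d)) d <- stats::setNames(lapply(seq_len(nrow(d)), function(i) d[i, ]),
                                         rownames(d))
  sets <- .track_values(new("Track", kind = "box", data = d, color = NULL,
                            extent = track@extent, title = track@title,
                            options = list()), order)
  ax <- .value_axis(unlist(sets))
  cfrac <- function(v) (v - ax[1L]) / (ax[2L] - ax[1L])
  prims <- list()
  for (p in seq_along(sets)) {
    st <- boxStats(sets[[p]])
    span <- cells$hi[p] - cells$lo[p]
    a0 <- cells$lo[p] + 0.2 * span; a1 <- cells$hi[p] - 0.2 * span
    ac <- (cells$lo[p] + cells$hi[p]) / 2
    prims[[length(prims) + 1L]] <-
      fr$rect(a0, a1, cfrac(st$q1), cfrac(st$q3), fill = "#d9d9d9ff",
              stroke = "#000000ff", stroke_width = 0.0008,
              tags = list(track = track@title, id = order[p], part = "box"))
    med0 <- fr$pt(a0, cfrac(st$median)); med1 <- fr$pt(a1, cfrac(st$median))
    prims[[length(prims) + 1L]] <-
      sceneLine(med0$x, med0$y, med1$x, med1$y, stroke = "#000000ff",
                stroke_width = 0.0012)
    for (wpair in list(c(st$whisker_lo, st$q1), c(st$q3, st$whisker_hi))) {
      w0 <- fr$pt(ac, cfrac(wpair[1L])); w1 <- fr$pt(ac, cfrac(wpair[2L]))
      prims[[length(prims) + 1L]] <-
        scenePolyline(c(w0$x, w1$x), c(w0$y, w1$y), stroke = "#000000ff",
                      stroke_width = 0.0008,
                      tags = list(track = track@title, id = order[p], part = "whisker"))
    }
    for (o in st$outliers) {
      op <- fr$pt(ac, cfrac(o))
      prims[[length(prims) + 1L]] <-
        sceneMarker(op$x, op$y, 0.003, shape = "circle", fill = "#000000ff",
                    tags = list(track = track@title, id = order[p], part = "outlier"))
    }
  }
  list(primitives = prims, spec = NULL)
}

#' Render a scatter annotation track
#'
#' One marker per position at its value on the shared value axis (data
#' range with 5% padding; the track's inner edge is the axis minimum).
#'
#' @inheritParams renderSimple
#' @return list(primitives, spec)
#' @export
renderScatter <- function(track, order, rect, cells, side = "top") {
  fr <- .track_frame(side, rect)
  vals <- as.numeric(.track_values(track, order))
  ax <- .value_axis(vals)
  spec <- if (!is.null(track@color)) resolveColorSpec(track@color, vals) else NULL
  cols <- if (!is.null(spec)) mapColors(vals, spec) else
    rep(defaultPalette()[1L], length(vals))
  prims <- list()
  for (p in seq_along(vals)) {
    if (is.na(vals[p])) next
    pp <- fr$pt((cells$lo[p] + cells$hi[p]) / 2,
                (vals[p] - ax[1L]) / (ax[2L] - ax[1L]))
    prims[[length(prims) + 1L]] <-
      sceneMarker(pp$x, pp$y, min(0.004, abs(cells$hi[p] - cells$lo[p]) * 0.3),
                  shape = "circle", fill = cols[p],
                  tags = list(track = track@title, id = order[p]))
  }
  list(primitives = prims, spec = spec)
}

#' Render a label annotation track
#'
#' Optionally merges runs of equal adjacent labels, then distributes slots
#' evenly (see \code{\link{distributeLabels}}); emits rotated texts plus
#' 3-segment leader polylines. Anchors use panel-adjusted coordinates, so
#' labels follow their cells across split gaps.
#'
#' @inheritParams renderSimple
#' @return list(primitives, spec)
#' @export
renderLabel <- function(track, order, rect, cells, side = "top") {
  fr <- .track_frame(side, rect)
  vals <- as.character(.track_values(track, order))
  opt <- track@options
  if (isTRUE(opt$merge)) {
    runs <- mergeLabelRuns(vals)
    anchors_d <- runs$anchors; labs <- runs$labels
    widths_f <- vapply(seq_along(labs), function(i) {
      lo_i <- anchors_d[i] - runs$widths[i] / 2
      abs(.data_to_figure(cells, lo_i + runs$widths[i] - 1e-9) -
            .data_to_figure(cells, lo_i))
    }, numeric(1))
  } else {
    keep <- which(!is.na(vals) & nzchar(vals))
    anchors_d <- keep - 0.5; labs <- vals[keep]
    widths_f <- abs(cells$hi[keep] - cells$lo[keep])
  }
  if (!length(labs)) return(list(primitives = list(), spec = NULL))
  # to along-axis figure coordinates, local to the track span
  horiz <- fr$horizontal
  a0 <- if (horiz) rect[1L] else rect[2L] + rect[4L]
  L <- if (horiz) rect[3L] else rect[4L]
  anchors_f <- .data_to_figure(cells, anchors_d)
  local <- if (horiz) anchors_f - a0 else a0 - anchors_f   # rows walk down
  pl <- distributeLabels(local, labs, L, extend = isTRUE(opt$extend),
                         min_slot = opt$min_slot %||% 0,
                         run_widths = widths_f,
                         rotation = opt$rotation %||% 0)
  back <- function(a) if (horiz) a0 + a else a0 - a
  prims <- list()
  for (i in seq_along(pl@texts)) {
    ld <- pl@leaders[[i]]
    ptc <- lapply(seq_along(ld$xs), function(j) fr$pt(back(ld$xs[j]), ld$ys[j]))
    prims[[length(prims) + 1L]] <-
      scenePolyline(vapply(ptc, `[[`, numeric(1), "x"),
                    vapply(ptc, `[[`, numeric(1), "y"),
                    stroke = "#666666ff", stroke_width = 0.0008,
                    tags = list(track = track@title, label = pl@texts[i]))
    tp <- fr$pt(back(pl@slotPos[i]), 1)
    rot <- pl@rotation + if (horiz) 0 else 90
    prims[[length(prims) + 1L]] <-
      sceneText(tp$x, tp$y, pl@texts[i], size = min(L / max(length(pl@texts), 1), 0.018) * 0.8,
                anchor = "middle", rotation = rot,
                tags = list(track = track@title, label = pl@texts[i]))
  }
  list(primitives = prims, spec = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render any annotation track (dispatch on kind)
#' @inheritParams renderSimple
#' @return list(primitives, spec, ...)
#' @export
renderTrack <- function(track, order, rect, cells, side = "top") {
  switch(track@kind,
    simple = renderSimple(track, order, rect, cells, side),
    bar = renderBar(track, order, rect, cells, side),
    box = renderBox(track, order, rect, cells, side),
    scatter = renderScatter(track, order, rect, cells, side),
    label = renderLabel(track, order, rect, cells, side))
}
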