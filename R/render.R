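#' @include scene.R
NULL

.svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# "#rrggbbaa" -> list(color = "#rrggbb", opacity = a)
.split_rgba <- function(col) {
  if (identical(col, "none")) return(list(color = "none", opacity = 1))
  list(color = substr(col, 1, 7),
       opacity = strtoi(substr(col, 8, 9), 16L) / 255)
}

.marker_points <- function(shape, cx, cy, r) {
  switch(shape,
    square = list(x = cx + r * c(-1, 1, 1, -1), y = cy + r * c(-1, -1, 1, 1)),
    triangle = list(x = cx + r * c(0, 0.866, -0.866), y = cy + r * c(1, -0.5, -0.5)),
    diamond = list(x = cx + r * c(0, 1, 0, -1), y = cy + r * c(1, 0, -1, 0)),
    cross = {
      a <- 0.35 * r
      list(x = cx + c(-a, a, a, r, r, a, a, -a, -a, -r, -r, -a),
           y = cy + c(r, r, a, a, -a, -a, -r, -r, -a, -a, a, a))
    },
    star = {
      ang <- pi / 2 + (0:9) * pi / 5
      rad <- rep(c(1, 0.45) * r, 5)
      list(x = cx + rad * cos(ang), y = cy + rad * sin(ang))
    },
    NULL)
}

.render_svg <- function(scene, path, width_px, height_px) {
  W <- width_px; H <- height_px
  X <- function(x) x * W
  Y <- function(y) (1 - y) * H
  S <- function(s) max(s * min(W, H), 0)
  paint <- function(fill, stroke, sw) {
    f <- .split_rgba(fill); s <- .split_rgba(stroke)
    sprintf('fill="%s" fill-opacity="%.3f" stroke="%s" stroke-opacity="%.3f" stroke-width="%.3f"',
            f$color, f$opacity, s$color, s$opacity, S(sw))
  }
  out <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
                   W, H, W, H),
           sprintf('<rect x="0" y="0" width="%d" height="%d" fill="#ffffff"/>', W, H))
  for (p in scene@primitives) {
    out <- c(out, switch(p$kind,
      rect = sprintf('<rect x="%.3f" y="%.3f" width="%.3f" height="%.3f" %s/>',
                     X(p$x), Y(p$y + p$h), p$w * W, p$h * H,
                     paint(p$fill, p$stroke, p$stroke_width)),
      line = sprintf('<line x1="%.3f" y1="%.3f" x2="%.3f" y2="%.3f" %s/>',
                     X(p$x0), Y(p$y0), X(p$x1), Y(p$y1),
                     paint(NA, p$stroke, p$stroke_width)),
      polyline = sprintf('<polyline points="%s" %s/>',
                         paste(sprintf("%.3f,%.3f", X(p$xs), Y(p$ys)), collapse = " "),
                         paint(NA, p$stroke, p$stroke_width)),
      text = {
        c <- .split_rgba(p$color)
        ta <- c(start = "start", middle = "middle", end = "end")[[p$anchor]]
        sprintf('<text x="%.3f" y="%.3f" font-size="%.3f" font-family="sans-serif" fill="%s" fill-opacity="%.3f" text-anchor="%s" dominant-baseline="middle"%s>%s</text>',
                X(p$x), Y(p$y), p$size * H, c$color, c$opacity, ta,
                if (p$rotation != 0)
                  sprintf(' transform="rotate(%.3f %.3f %.3f)"',
                          -p$rotation, X(p$x), Y(p$y)) else "",
                .svg_escape(p$label))
      },
      marker = {
        pts <- .marker_points(p$shape, p$x, p$y, p$radius)
        if (is.null(pts))
          sprintf('<circle cx="%.3f" cy="%.3f" r="%.3f" %s/>',
                  X(p$x), Y(p$y), p$radius * min(W, H),
                  paint(p$fill, p$stroke, p$stroke_width))
        else
          sprintf('<polygon points="%s" %s/>',
                  paste(sprintf("%.3f,%.3f", X(pts$x), Y(pts$y)), collapse = " "),
                  paint(p$fill, p$stroke, p$stroke_width))
      },
      stop(sprintf("unknown primitive kind '%s'", p$kind))))
  }
  writeLines(c(out, "</svg>"), path, useBytes = TRUE)
  invisible(path)
}

.grid_just <- c(start = "left", middle = "centre", end = "right")

.render_grid <- function(scene) {
  grid::grid.newpage()
  for (p in scene@primitives) {
    lw <- function(sw) max(sw * 500, 0.1)
    switch(p$kind,
      rect = grid::grid.rect(
        x = p$x + p$w / 2, y = p$y + p$h / 2, width = p$w, height = p$h,
        gp = grid::gpar(fill = if (p$fill == "none") NA else p$fill,
                        col = if (p$stroke == "none") NA else p$stroke,
                        lwd = lw(p$stroke_width))),
      line = grid::grid.lines(
        x = c(p$x0, p$x1), y = c(p$y0, p$y1),
        gp = grid::gpar(col = p$stroke, lwd = lw(p$stroke_width))),
      polyline = grid::grid.lines(
        x = p$xs, y = p$ys,
        gp = grid::gpar(col = p$stroke, lwd = lw(p$stroke_width))),
      text = grid::grid.text(
        p$label, x = p$x, y = p$y, rot = p$rotation,
        just = .grid_just[[p$anchor]],
        gp = grid::gpar(col = p$color, fontsize = max(p$size * 500, 1))),
      marker = {
        pts <- .marker_points(p$shape, p$x, p$y, p$radius)
        gp <- grid::gpar(fill = if (p$fill == "none") NA else p$fill,
                         col = if (p$stroke == "none") NA else p$stroke,
                         lwd = lw(p$stroke_width))
        if (is.null(pts))
          grid::grid.circle(x = p$x, y = p$y, r = p$radius, gp = gp)
        else grid::grid.polygon(x = pts$x, y = pts$y, gp = gp)
      })
  }
  invisible(NULL)
}

#' Render a scene's legends into primitives
#'
#' Draws legend models (swatches, colorbars, marker and size references plus
#' labels) into a vertical column. The result is a scene fragment the
#' renderer appends at draw time; legend models, not these primitives, are
#' the unit of legend bookkeeping.
#'
#' @param legends list of \linkS4class{Legend}.
#' @param rect numeric c(x, y, w, h) column to fill, top-down.
#' @return list of primitives
#' @export
legendScene <- function(legends, rect = c(0.86, 0.02, 0.13, 0.94)) {
  prims <- list()
  x <- rect[1L]; w <- rect[3L]
  ytop <- rect[2L] + rect[4L]
  sw <- min(0.025, w / 3)           # swatch size
  step <- sw * 1.3
  for (lg in legends) {
    if (ytop - step * (length(lg@entries) + 2L) < rect[2L]) break
    prims[[length(prims) + 1L]] <-
      sceneText(x, ytop - step / 2, lg@title, size = sw * 0.8, anchor = "start")
    ytop <- ytop - step
    for (e in lg@entries) {
      yc <- ytop - step / 2
      sws <- e$swatch
      prims <- c(prims, switch(lg@kind,
        categorical_patches = list(sceneRect(x, yc - sw / 2, sw, sw, fill = sws$color)),
        colorbar = list(sceneRect(x, yc - sw / 2, sw, sw, fill = sws$color)),
        marker_set = list(sceneMarker(x + sw / 2, yc, sw / 2, shape = sws$shape,
                                      fill = sws$color)),
        size_set = list(sceneMarker(x + sw / 2, yc, max(sws$radius * sw, 1e-4),
                                    shape = "circle", fill = "#555555ff"))))
      prims[[length(prims) + 1L]] <-
        sceneText(x + sw * 1.4, yc, e$label, size = sw * 0.7, anchor = "start")
      ytop <- ytop - step
    }
    ytop <- ytop - step / 2
  }
  prims
}

#' Render a scene or figure to an image file
#'
#' Supported formats: SVG (hand-written, geometry mapped linearly into pixel
#' space, never altered) and PNG (grid graphics device). Rendering a
#' \linkS4class{FigureModel} also draws its legends in the right-hand legend
#' column.
#'
#' @param x a \linkS4class{Scene} or \linkS4class{FigureModel}.
#' @param path output file.
#' @param format "svg" or "png"; inferred from the path suffix when NULL.
#' @param width_px,height_px raster/viewport size in pixels.
#' @return invisibly, \code{path}
#' @export
renderScene <- function(x, path, format = NULL, width_px = 800L, height_px = 800L) {
  scene <- if (is(x, "FigureModel")) {
    Scene(c(x@scene@primitives, legendScene(x@legends)), meta = x@scene@meta)
  } else x
  stopifnot(is(scene, "Scene"))
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  if (format == "svg") return(.render_svg(scene, path, as.integer(width_px),
                                          as.integer(height_px)))
  if (format == "png") {
    grDevices::png(path, width = width_px, height = height_px)
    on.exit(grDevices::dev.off())
    .render_grid(scene)
    return(invisible(path))
  }
  stop(sprintf("unknown format '%s' (use svg or png)", format))
}
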