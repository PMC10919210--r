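# geometry helpers for layout tests

rects_overlap <- function(a, b, tol = 1e-9) {
  a[1] + a[3] > b[1] + tol && b[1] + b[3] > a[1] + tol &&
    a[2] + a[4] > b[2] + tol && b[2] + b[4] > a[2] + tol
}

# do two segments (p1-p2, q1-q2) properly intersect?
segments_cross <- function(p1, p2, q1, q2, tol = 1e-12) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  d1 * d2 < -tol && d3 * d4 < -tol
}

# count pairwise crossings among leader polylines of a LabelPlacement
leader_crossings <- function(pl) {
  segs <- list()
  for (ld in pl@leaders) {
    for (s in seq_len(length(ld$xs) - 1L))
      segs[[length(segs) + 1L]] <- list(p = c(ld$xs[s], ld$ys[s]),
                                        q = c(ld$xs[s + 1L], ld$ys[s + 1L]))
  }
  cnt <- 0L
  if (length(segs) > 1L)
    for (i in seq_len(length(segs) - 1L)) for (j in (i + 1L):length(segs))
      if (segments_cross(segs[[i]]$p, segs[[i]]$q, segs[[j]]$p, segs[[j]]$q))
        cnt <- cnt + 1L
  cnt
}

# all colors appearing as fills of tagged simple-track rects in a figure
rendered_track_categories <- function(fm, track_title) {
  prims <- scenePrimitivesOf(fm, "rect", "track", track_title)
  unique(vapply(prims, function(p) p$fill, character(1)))
}

# every category color in any legend, with multiplicity
legend_color_labels <- function(fm) {
  out <- list()
  for (lg in legends(fm)) for (e in lg@entries)
    if (!is.null(e$swatch$color))
      out[[length(out) + 1L]] <- c(title = lg@title, label = e$label,
                                   color = e$swatch$color)
  out
}
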