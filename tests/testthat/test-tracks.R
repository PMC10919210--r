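# shared scaffolding: a horizontal track rect over n unit cells
track_rect <- c(0.1, 0.8, 0.6, 0.1)
even_cells <- function(n, rect = track_rect)
  data.frame(lo = rect[1] + rect[3] * (0:(n - 1)) / n,
             hi = rect[1] + rect[3] * (1:n) / n)

prims_inside <- function(prims, rect, tol = 1e-9) {
  ok <- TRUE
  for (p in prims) {
    xs <- switch(p$kind, rect = c(p$x, p$x + p$w), line = c(p$x0, p$x1),
                 polyline = p$xs, text = p$x, marker = c(p$x - p$radius, p$x + p$radius))
    ys <- switch(p$kind, rect = c(p$y, p$y + p$h), line = c(p$y0, p$y1),
                 polyline = p$ys, text = p$y, marker = c(p$y - p$radius, p$y + p$radius))
    ok <- ok && all(xs >= rect[1] - tol) && all(xs <= rect[1] + rect[3] + tol) &&
      all(ys >= rect[2] - tol) && all(ys <= rect[2] + rect[4] + tol)
  }
  ok
}

test_that("simple tracks paint one cell per position and label category blocks", {
  ids <- c("s1", "s2", "s3")
  tr <- annoSimple(setNames(c("A", "A", "B"), ids), title = "grp", add_text = TRUE)
  out <- renderSimple(tr, ids, track_rect, even_cells(3), "top")
  rects <- Filter(function(p) p$kind == "rect", out$primitives)
  texts <- Filter(function(p) p$kind == "text", out$primitives)
  expect_identical(length(rects), 3L)
  expect_identical(length(texts), 2L)
  # block centers at data coords 1.0 and 2.5 (cells are 0.2 figure units wide)
  expect_equal(texts[[1]]$x, 0.1 + 0.2 * 1.0)
  expect_equal(texts[[2]]$x, 0.1 + 0.2 * 2.5)
  expect_identical(rects[[1]]$fill, rects[[2]]$fill)
  expect_false(rects[[1]]$fill == rects[[3]]$fill)
  # text color follows the contrast rule against the block fill
  expect_identical(texts[[1]]$color, textContrastColor(rects[[1]]$fill))
  expect_true(prims_inside(out$primitives, track_rect))

  one <- renderSimple(annoSimple(c(s1 = "A"), add_text = TRUE), "s1",
                      track_rect, even_cells(1), "top")
  expect_identical(vapply(one$primitives, `[[`, character(1), "kind"),
                   c("rect", "text"))
})

test_that("continuous simple tracks follow the color map elementwise", {
  ids <- paste0("s", 1:4)
  v <- setNames(c(0, 1, 2, 3), ids)
  tr <- annoSimple(v, color = colorSpecContinuous("greys", 0, 3))
  out <- renderSimple(tr, ids, track_rect, even_cells(4), "top")
  fills <- vapply(out$primitives, `[[`, character(1), "fill")
  expect_identical(fills, mapColors(unname(v), colorSpecContinuous("greys", 0, 3)))
})

test_that("bar tracks scale to the max and stack with conservation", {
  ids <- c("a", "b", "c")
  out <- renderBar(annoBar(setNames(c(1, 2, 4), ids)), ids, track_rect,
                   even_cells(3), "top")
  expect_false(out$stacked)
  h <- vapply(out$primitives, `[[`, numeric(1), "h")
  expect_equal(h, 0.1 * c(1, 2, 4) / 4)            # h/4, h/2, h

  m <- rbind(a = c(x = 1, y = 3), b = c(x = 1, y = 1))
  out2 <- renderBar(annoBar(m), c("a", "b"), track_rect, even_cells(2), "top")
  expect_true(out2$stacked)
  segs_a <- Filter(function(p) identical(p$tags$id, "a"), out2$primitives)
  expect_identical(length(segs_a), 2L)
  ha <- vapply(segs_a, `[[`, numeric(1), "h")
  expect_equal(ha[2] / ha[1], 3)                   # segment ratio preserved
  expect_equal(sum(ha), 0.1 * 4 / 4, tolerance = 1e-9)  # row-sum scaling
  # stacked-bar conservation at every position
  for (id in c("a", "b")) {
    segs <- Filter(function(p) identical(p$tags$id, id), out2$primitives)
    total <- sum(vapply(segs, `[[`, numeric(1), "h"))
    expect_equal(total, 0.1 * sum(m[id, ]) / 4, tolerance = 1e-9)
  }
  bad <- rbind(a = c(x = 1, y = -2), b = c(x = 1, y = 1))
  expect_error(renderBar(annoBar(bad), c("a", "b"), track_rect,
                         even_cells(2), "top"), "'a'.*'y'|position 'a'")
})

test_that("box statistics follow the type-7 / 1.5 IQR rules", {
  st <- boxStats(c(1, 2, 3, 4, 5))
  expect_equal(st$q1, 2); expect_equal(st$median, 3); expect_equal(st$q3, 4)
  expect_equal(st$whisker_lo, 1); expect_equal(st$whisker_hi, 5)
  expect_identical(length(st$outliers), 0L)

  st2 <- boxStats(c(1, 2, 3, 4, 100))
  expect_equal(st2$outliers, 100)                  # beyond q3 + 1.5 IQR
  expect_equal(st2$whisker_hi, 4)

  st3 <- boxStats(rep(7, 4))
  expect_equal(st3$q1, st3$q3)
  expect_identical(length(st3$outliers), 0L)
  expect_error(boxStats(numeric(0)), "finite")
  # invariant: whisker_lo <= q1 <= median <= q3 <= whisker_hi
  set.seed(12)
  for (i in 1:25) {
    s <- boxStats(rnorm(sample(1:40, 1)))
    expect_true(s$whisker_lo <= s$q1 && s$q1 <= s$median &&
                s$median <= s$q3 && s$q3 <= s$whisker_hi)
  }
})

test_that("box and scatter tracks share a padded value axis", {
  ids <- c("a", "b")
  out <- renderBox(annoBox(list(a = c(1, 2, 3, 4, 5), b = rep(3, 5))),
                   ids, track_rect, even_cells(2), "top")
  expect_true(prims_inside(out$primitives, track_rect))
  box_b <- Filter(function(p) p$kind == "rect" && identical(p$tags$id, "b"),
                  out$primitives)[[1]]
  expect_equal(box_b$h, 0)                         # constant data: flat box
  med_lines <- Filter(function(p) p$kind == "line", out$primitives)
  expect_true(all(vapply(med_lines, function(p) abs(p$x1 - p$x0), numeric(1)) > 0))

  vals <- setNames(c(0, 10), ids)
  sc <- renderScatter(annoScatter(vals), ids, track_rect, even_cells(2), "top")
  ys <- vapply(sc$primitives, `[[`, numeric(1), "y")
  # endpoints sit at the padded axis ends: 5% in from each track edge
  expect_equal(ys[1], track_rect[2] + track_rect[4] * (0.5 / 11), tolerance = 1e-9)
  expect_equal(ys[2], track_rect[2] + track_rect[4] * (10.5 / 11), tolerance = 1e-9)
})

test_that("track rendering is order-equivariant", {
  ids <- paste0("s", 1:5)
  v <- setNames(c(2, 5, 1, 4, 3), ids)
  out1 <- renderBar(annoBar(v), ids, track_rect, even_cells(5), "top")
  perm <- c("s3", "s1", "s5", "s2", "s4")
  out2 <- renderBar(annoBar(v), perm, track_rect, even_cells(5), "top")
  h1 <- setNames(vapply(out1$primitives, `[[`, numeric(1), "h"),
                 vapply(out1$primitives, function(p) p$tags$id, character(1)))
  h2 <- setNames(vapply(out2$primitives, `[[`, numeric(1), "h"),
                 vapply(out2$primitives, function(p) p$tags$id, character(1)))
  expect_equal(h1[ids], h2[ids])
})

test_that("label tracks compose run-merging with even distribution", {
  ids <- paste0("s", 1:5)
  tr <- annoLabel(setNames(c("A", "A", "B", "B", "B"), ids),
                  merge = TRUE, extend = TRUE, rotation = 90)
  out <- renderLabel(tr, ids, track_rect, even_cells(5), "top")
  texts <- Filter(function(p) p$kind == "text", out$primitives)
  leaders <- Filter(function(p) p$kind == "polyline", out$primitives)
  expect_identical(length(texts), 2L)
  expect_identical(length(leaders), 2L)
  expect_identical(vapply(texts, `[[`, character(1), "label"), c("A", "B"))
  # slots at 0.25 and 0.75 of the axis span
  expect_equal(texts[[1]]$x, track_rect[1] + 0.25 * track_rect[3])
  expect_equal(texts[[2]]$x, track_rect[1] + 0.75 * track_rect[3])
  expect_equal(texts[[1]]$rotation, 90)
  expect_true(prims_inside(out$primitives, track_rect))

  # one labeled row among 50: single centered slot
  ids50 <- paste0("r", 1:50)
  lab <- setNames(rep(NA_character_, 50), ids50); lab[30] <- "hit"
  out50 <- renderLabel(annoLabel(lab), ids50, track_rect, even_cells(50), "top")
  texts50 <- Filter(function(p) p$kind == "text", out50$primitives)
  expect_identical(length(texts50), 1L)
  expect_equal(texts50[[1]]$x, track_rect[1] + 0.5 * track_rect[3])

  none <- renderLabel(annoLabel(setNames(rep(NA_character_, 5), ids)),
                      ids, track_rect, even_cells(5), "top")
  expect_identical(none$primitives, list())
})

test_that("left/right tracks are the same geometry rotated", {
  ids <- c("r1", "r2", "r3")
  vrect <- c(0.02, 0.2, 0.1, 0.6)
  vcells <- data.frame(lo = c(0.6, 0.4, 0.2), hi = c(0.8, 0.6, 0.4))  # top-down
  out <- renderSimple(annoSimple(setNames(c("A", "A", "B"), ids), add_text = TRUE),
                      ids, vrect, vcells, "left")
  rects <- Filter(function(p) p$kind == "rect", out$primitives)
  expect_identical(length(rects), 3L)
  expect_true(prims_inside(out$primitives, vrect))
  texts <- Filter(function(p) p$kind == "text", out$primitives)
  expect_equal(texts[[1]]$rotation, 90)
  bar <- renderBar(annoBar(setNames(c(1, 2, 4), ids)), ids, vrect, vcells, "left")
  w <- vapply(bar$primitives, `[[`, numeric(1), "w")
  expect_equal(w, 0.1 * c(1, 2, 4) / 4)            # value axis along x now
})
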