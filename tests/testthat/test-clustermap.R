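cell_rects <- function(fm) scenePrimitivesOf(fm, "rect", "row_id")

test_that("standardization z-scores with population sd and flags constant axes", {
  m <- LabeledMatrix(rbind(c(1, 2, 3), c(5, 5, 5)), c("a", "flat"),
                     c("x", "y", "z"))
  expect_identical(values(standardizeMatrix(m, "none")), values(m))
  z <- standardizeMatrix(m, "rows")
  expect_equal(unname(values(z)[1, ]), c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  expect_equal(unname(values(z)[2, ]), c(0, 0, 0))
  expect_identical(z@metadata$constant_rows, "flat")
  zc <- standardizeMatrix(m, "cols")
  expect_equal(unname(colMeans(values(zc))), c(0, 0, 0))
})

test_that("a bare 2x2 heatmap is 4 cell rects and one colorbar legend", {
  m <- LabeledMatrix(matrix(1:4, 2, 2), c("r1", "r2"), c("c1", "c2"))
  fm <- buildClustermap(m, cluster_rows = FALSE, cluster_cols = FALSE)
  expect_identical(length(scenePrimitives(fm)), 4L)
  expect_identical(length(cell_rects(fm)), 4L)
  expect_identical(length(legends(fm)), 1L)
  expect_identical(legends(fm)[[1]]@kind, "colorbar")
  expect_identical(rowOrder(fm), c("r1", "r2"))   # clustering off: input order
  expect_identical(colOrder(fm), c("c1", "c2"))
})

test_that("integer row splits cut the global tree into proportional panels", {
  m <- LabeledMatrix(matrix(c(0, 1, 5), 3, 1) %*% t(rep(1, 3)) +
                       matrix(0, 3, 3), paste0("r", 1:3), paste0("c", 1:3))
  fm <- buildClustermap(m, row_split = 2, cluster_cols = FALSE,
                        method = "single")
  expect_identical(splitLabels(fm@rowSplit), c("1", "2"))
  expect_identical(lengths(splitMembers(fm@rowSplit)), c(`1` = 2L, `2` = 1L))
  hs <- vapply(panelGrid(fm)@panels, function(row) row[[1]][4], numeric(1))
  expect_equal(hs[1] / hs[2], 2, tolerance = 1e-9)
  expect_identical(rowOrder(fm), c("r1", "r2", "r3"))
})

test_that("categorical column splits block the axis with add_text labels", {
  set.seed(8)
  m <- LabeledMatrix(matrix(rnorm(9), 3, 3), paste0("r", 1:3), paste0("c", 1:3))
  grp <- c("A", "A", "B")
  fm <- buildClustermap(m, col_split = grp, cluster_rows = FALSE,
                        cluster_cols = FALSE,
                        top_annotation = annoSimple(
                          setNames(grp, colIds(m)), title = "grp", add_text = TRUE))
  texts <- scenePrimitivesOf(fm, "text")
  expect_identical(vapply(texts, `[[`, character(1), "label"), c("A", "B"))
  ws <- vapply(panelGrid(fm)@panels[[1]], `[`, numeric(1), 3)
  expect_equal(ws[1] / ws[2], 2, tolerance = 1e-9)
  expect_lt(texts[[1]]$x, texts[[2]]$x)
  # the simple track contributed a categorical legend after the colorbar
  expect_identical(length(legends(fm)), 2L)
  expect_identical(legends(fm)[[2]]@kind, "categorical_patches")
})

test_that("cell conservation holds, missing cells painted in the missing color", {
  set.seed(10)
  v <- matrix(rnorm(30), 5, 6)
  v[2, 3] <- NA; v[5, 1] <- NA
  m <- LabeledMatrix(v, paste0("r", 1:5), paste0("c", 1:6))
  fm <- buildClustermap(m, row_split = 2)
  expect_identical(length(cell_rects(fm)), 30L)
  na_rects <- Filter(function(p) p$fill == "#bdbdbdff", cell_rects(fm))
  expect_identical(length(na_rects), 2L)
})

test_that("scene cell tags mirror the resolved display orders", {
  set.seed(14)
  m <- LabeledMatrix(matrix(rnorm(42), 6, 7), paste0("r", 1:6), paste0("c", 1:7))
  fm <- buildClustermap(m, row_split = 2, col_split = 3)
  rects <- cell_rects(fm)
  # group cells into display rows by y, display cols by x
  ys <- vapply(rects, `[[`, numeric(1), "y")
  xs <- vapply(rects, `[[`, numeric(1), "x")
  for (j in seq_along(colOrder(fm))) {
    xcol <- sort(unique(round(xs, 9)), decreasing = FALSE)[j]
    ids <- unique(vapply(rects[round(xs, 9) == xcol],
                         function(p) p$tags$col_id, character(1)))
    expect_identical(ids, colOrder(fm)[j])
  }
  for (i in seq_along(rowOrder(fm))) {
    yrow <- sort(unique(round(ys, 9)), decreasing = TRUE)[i]
    ids <- unique(vapply(rects[round(ys, 9) == yrow],
                         function(p) p$tags$row_id, character(1)))
    expect_identical(ids, rowOrder(fm)[i])
  }
})

test_that("building the same figure twice gives byte-identical scenes", {
  fx <- makeFixtureMatrix(10, 6, n_col_groups = 2, group_shift = 2, seed = 19)
  grp <- annotationColumn(fx$annotation, "group")
  build <- function() buildClustermap(
    fx$matrix, row_split = 2, col_split = unname(grp),
    top_annotation = annoSimple(grp, title = "group", add_text = TRUE),
    right_annotation = annoBar(setNames(abs(values(fx$matrix)[, 1]),
                                        rowIds(fx$matrix))))
  expect_identical(serializeScene(build()), serializeScene(build()))
})

test_that("invalid specs fail with informative messages", {
  m <- LabeledMatrix(matrix(1:4, 2, 2), c("r1", "r2"), c("c1", "c2"))
  expect_error(buildClustermap(m, top_annotation = annoSimple(c(zz = "A"))),
               "zz")
  expect_error(buildClustermap(m, row_split = c("A", "B", "C")), "length 2")
  expect_error(buildClustermap(m, method = "median"), "arg")
})

test_that("categorical split with clustering draws one dendrogram per group", {
  set.seed(23)
  m <- LabeledMatrix(matrix(rnorm(60), 10, 6), paste0("r", 1:10), paste0("c", 1:6))
  fm <- buildClustermap(m, row_split = rep(c("A", "B"), each = 5),
                        cluster_cols = FALSE)
  polys <- scenePrimitivesOf(fm, "polyline")
  expect_identical(length(polys), 8L)   # (5-1) brackets per group, two groups
  # integer split: one global tree spanning the gaps
  fm2 <- buildClustermap(m, row_split = 2, cluster_cols = FALSE)
  expect_identical(length(scenePrimitivesOf(fm2, "polyline")), 9L)
})

test_that("annotation-only figures lay out tracks without a heatmap", {
  ids <- c("s1", "s2", "s3")
  one <- annotationOnly(annoSimple(setNames(c("A", "B", "B"), ids), title = "g"),
                        "cols", ids)
  rects <- scenePrimitivesOf(one, "rect")
  expect_identical(length(rects), 3L)
  expect_identical(length(legends(one)), 1L)
  expect_null(panelGrid(one))

  two <- annotationOnly(list(
    annoSimple(setNames(c("A", "B", "B"), ids), title = "g"),
    annoBar(setNames(c(1, 2, 3), ids))), "cols", ids)
  g_rects <- scenePrimitivesOf(two, "rect", "track", "g")
  b_rects <- scenePrimitivesOf(two, "rect", "track", "bar")
  for (a in g_rects) for (b in b_rects)
    expect_false(rects_overlap(c(a$x, a$y, a$w, a$h), c(b$x, b$y, b$w, b$h)))

  lab <- annotationOnly(annoLabel(setNames(c("A", "A", NA), ids)), "cols", ids)
  kinds <- vapply(scenePrimitives(lab), `[[`, character(1), "kind")
  expect_setequal(kinds, c("text", "polyline"))
  expect_error(annotationOnly(list(), "cols", ids), "at least one")
})
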