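test_that("panel grids are proportional and tile the plot rectangle", {
  pr <- c(0, 0, 1, 1)
  g1 <- computeGrid(4, 4, pr, 0, 0)
  expect_equal(g1@panels[[1]][[1]], c(0, 0, 1, 1))      # single panel = plot_rect

  g2 <- computeGrid(3, c(2, 2), c(0, 0, 1, 0.5), col_gap = 0.1)
  expect_equal(g2@panels[[1]][[1]][3], 0.45)            # (W - g)/2 each
  expect_equal(g2@panels[[1]][[2]][3], 0.45)

  g3 <- computeGrid(2, c(2, 1), c(0.05, 0, 0.9, 0.6), col_gap = 0)
  expect_equal(g3@panels[[1]][[1]][3], 0.6)             # widths 0.6 and 0.3
  expect_equal(g3@panels[[1]][[2]][3], 0.3)
  expect_error(computeGrid(c(1, 1), 1, c(0, 0, 1, 0.01), row_gap = 0.5), "gaps")
  expect_error(computeGrid(c(1, 0), 1, pr), "positive")
})

test_that("panels plus gaps tile exactly and stay disjoint (property)", {
  set.seed(31)
  for (i in 1:50) {
    nr <- sample(1:4, 1); nc <- sample(1:4, 1)
    rs <- sample(1:9, nr, replace = TRUE); cs <- sample(1:9, nc, replace = TRUE)
    pr <- c(runif(1, 0, 0.2), runif(1, 0, 0.2), runif(1, 0.4, 0.7), runif(1, 0.4, 0.7))
    g <- computeGrid(rs, cs, pr, row_gap = 0.008, col_gap = 0.012)
    widths <- vapply(g@panels[[1]], `[`, numeric(1), 3)
    heights <- vapply(g@panels, function(row) row[[1]][4], numeric(1))
    expect_lt(abs(sum(widths) + 0.012 * (nc - 1) - pr[3]), 1e-9)
    expect_lt(abs(sum(heights) + 0.008 * (nr - 1) - pr[4]), 1e-9)
    expect_equal(widths / sum(widths), cs / sum(cs), tolerance = 1e-12)
    all_panels <- do.call(c, g@panels)
    if (length(all_panels) > 1)
      for (a in 1:(length(all_panels) - 1)) for (b in (a + 1):length(all_panels))
        expect_false(rects_overlap(all_panels[[a]], all_panels[[b]]))
    # cell intervals concatenate panels in display order
    cc <- cellIntervals(g, "cols")
    expect_identical(nrow(cc), sum(cs))
    expect_true(all(cc$hi > cc$lo))
    rr <- cellIntervals(g, "rows")
    expect_true(all(diff(rr$hi) < 0))   # rows walk down from the top
  }
})

test_that("track stacks grow outward without overlap and respect the page", {
  pr <- c(0.2, 0.2, 0.6, 0.6)
  one <- allocateTracks("top", 0.05, pr, pad = 0)
  expect_equal(one[[1]], c(0.2, 0.8, 0.6, 0.05))
  two <- allocateTracks("top", c(0.05, 0.08), pr, pad = 0.01)
  expect_gt(two[[2]][2], two[[1]][2] + two[[1]][4])     # second strictly above
  expect_false(rects_overlap(two[[1]], two[[2]]))
  expect_identical(allocateTracks("left", numeric(0), pr), list())
  for (side in c("top", "bottom", "left", "right")) {
    rects <- allocateTracks(side, c(0.03, 0.04, 0.02), pr, pad = 0.005)
    for (r in rects) expect_false(rects_overlap(r, pr))
    for (a in 1:2) for (b in (a + 1):3)
      expect_false(rects_overlap(rects[[a]], rects[[b]]))
  }
  expect_error(allocateTracks("top", 0.5, pr), "leaves the figure")
})

test_that("dendrogram geometry draws one bracket per merge at proportional depth", {
  two <- linkageTree(structure(1, Size = 2L, class = "dist"), "single")
  br <- dendrogramGeometry(two, "top", c(0, 0.9, 1, 0.1))
  expect_identical(length(br), 1L)
  expect_equal(br[[1]]$xs, c(0.25, 0.25, 0.75, 0.75))   # both cell centers

  m <- matrix(c(0, 1, 5), ncol = 1)
  link <- linkageTree(pairwiseDistance(m, "rows"), "single")
  brs <- dendrogramGeometry(link, "top", c(0, 0.8, 0.6, 0.2))
  expect_identical(length(brs), nLeaves(link) - 1L)
  # the (0,1) bracket is strictly shallower than the root bracket
  expect_lt(max(brs[[1]]$ys), max(brs[[2]]$ys))
  # scaling all heights leaves normalized geometry unchanged
  link2 <- new("LinkageResult", merges = merges(link) %*% diag(c(1, 1, 2)),
               nLeaves = 3L, method = "single", metric = "euclidean")
  brs2 <- dendrogramGeometry(link2, "top", c(0, 0.8, 0.6, 0.2))
  for (t in 1:2) {
    expect_equal(brs[[t]]$xs, brs2[[t]]$xs)
    expect_equal(brs[[t]]$ys, brs2[[t]]$ys)
  }
})

test_that("label runs merge by adjacency only", {
  r <- mergeLabelRuns(c("A", "A", "B", "B", "B"))
  expect_equal(r$anchors, c(1.0, 3.5))
  expect_identical(r$labels, c("A", "B"))
  r2 <- mergeLabelRuns(c("A", "B", "A"))
  expect_identical(length(r2$anchors), 3L)              # non-adjacent not merged
  r3 <- mergeLabelRuns(c(NA, NA, "X", NA))
  expect_equal(r3$anchors, 2.5)
  expect_identical(r3$labels, "X")
  expect_identical(length(mergeLabelRuns(c(NA, NA))$anchors), 0L)
})

test_that("label slots are even, ordered and never cross their leaders", {
  pl <- distributeLabels(c(0.2, 0.6), c("a", "b"), 1, extend = TRUE)
  expect_equal(pl@slotPos, c(0.25, 0.75))
  pl5 <- distributeLabels(sort(runif(5)), letters[1:5], 1, extend = TRUE)
  expect_equal(diff(pl5@slotPos), rep(0.2, 4))          # constant spacing L/m
  pl3 <- distributeLabels(c(0.1, 0.12, 0.9), c("a", "b", "c"), 1, extend = TRUE)
  expect_equal(pl3@slotPos, c(1, 3, 5) / 6)
  expect_identical(leader_crossings(pl3), 0L)
  expect_error(distributeLabels(c(0.1, 0.5), c("a", "b"), 1, min_slot = 0.6),
               "fewer labels")
  expect_error(distributeLabels(c(0.5, 0.2), c("a", "b"), 1), "increasing")
  # extend = FALSE confines slots near the anchors
  plc <- distributeLabels(c(0.4, 0.45), c("a", "b"), 1, extend = FALSE,
                          run_widths = c(0.1, 0.1))
  expect_gt(plc@slotPos[1], 0.3)
  expect_lt(plc@slotPos[2], 0.55)
})

test_that("random anchor sets keep slots disjoint, ordered and crossing-free", {
  set.seed(77)
  for (i in 1:200) {
    m <- sample(1:12, 1)
    anchors <- sort(runif(m))
    anchors <- anchors[c(TRUE, diff(anchors) > 1e-6)]
    pl <- distributeLabels(anchors, paste0("l", seq_along(anchors)), 1,
                           extend = TRUE)
    gaps <- diff(pl@slotPos)
    if (length(gaps)) {
      expect_true(all(gaps > 0))
      expect_lt(max(gaps) - min(gaps), 1e-9)            # strictly even
    }
    expect_identical(leader_crossings(pl), 0L)
  }
})
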