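toy_table <- function() AlterationTable(
  sample = c("s1", "s2", "s2", "s3"),
  gene = c("g1", "g1", "g2", "g2"),
  category = c("SNV", "SNV", "AMP", "AMP"))

test_that("alteration grids collect category sets per cell", {
  at <- AlterationTable(c("s1", "s1", "s2"), c("g1", "g1", "g2"),
                        c("SNV", "AMP", "SNV"))
  g <- alterationGrid(at)
  expect_identical(dim(g$cells), c(2L, 2L))
  expect_setequal(g$cells[["g1", "s1"]], c("SNV", "AMP"))
  expect_null(g$cells[["g2", "s1"]])
  # record order does not matter
  at2 <- AlterationTable(c("s2", "s1", "s1"), c("g2", "g1", "g1"),
                         c("SNV", "AMP", "SNV"))
  g2 <- alterationGrid(at2)
  expect_setequal(g2$cells[["g1", "s1"]], g$cells[["g1", "s1"]])
  empty <- AlterationTable(character(0), character(0), character(0))
  expect_error(memoSort(alterationGrid(empty)), "empty")
})

test_that("memo sort matches the worked toy example", {
  # g1 altered in s1, s2; g2 in s2, s3: expect genes tied (stable) and
  # samples (s2, s1, s3)
  at <- toy_table()
  ms <- memoSort(alterationGrid(at))
  expect_identical(ms$gene_order, c("g1", "g2"))
  expect_identical(ms$sample_order, c("s2", "s1", "s3"))
  # gene frequency descending
  at2 <- AlterationTable(c("s1", "s2", "s3", "s2"), c("g2", "g2", "g2", "g1"),
                         rep("SNV", 4))
  expect_identical(memoSort(alterationGrid(at2))$gene_order, c("g2", "g1"))
})

test_that("memo sort equals a brute-force lexicographic maximization", {
  score <- function(B, sord) {
    # rank of the sample arrangement: concatenated binary columns read as digits
    paste(apply(B[, sord, drop = FALSE], 2, paste, collapse = ""), collapse = "")
  }
  set.seed(55)
  for (rep in 1:25) {
    ng <- sample(1:2, 1); ns <- sample(2:6, 1)
    B <- matrix(rbinom(ng * ns, 1, 0.5), ng, ns)
    recs <- which(B == 1, arr.ind = TRUE)
    if (!nrow(recs)) next
    at <- AlterationTable(paste0("s", recs[, 2]), paste0("g", recs[, 1]),
                          rep("SNV", nrow(recs)))
    g <- alterationGrid(at)
    ms <- memoSort(g)
    # brute force over all sample permutations of the grid's own ordering
    Bg <- matrix(0L, length(g$genes), length(g$samples),
                 dimnames = list(g$genes, g$samples))
    for (gi in g$genes) for (si in g$samples)
      if (length(g$cells[[gi, si]])) Bg[gi, si] <- 1L
    Bg <- Bg[ms$gene_order, , drop = FALSE]
    perms <- do.call(rbind, combinat_perms(seq_along(g$samples)))
    scores <- apply(perms, 1, function(p) score(Bg, p))
    best <- max(scores)
    expect_identical(score(Bg, match(ms$sample_order, colnames(Bg))), best)
  }
})

test_that("ties keep input order so duplicated samples stay adjacent", {
  at <- AlterationTable(c("a", "b", "c"), rep("g1", 3), rep("SNV", 3))
  ms <- memoSort(alterationGrid(at))
  expect_identical(ms$sample_order, c("a", "b", "c"))
  # a grid with genes/samples but no alterations keeps input orders
  g <- alterationGrid(at)
  g$cells[] <- list(NULL)
  ms2 <- memoSort(g)
  expect_identical(ms2$gene_order, g$genes)
  expect_identical(ms2$sample_order, g$samples)
})

test_that("oncoPrint cells draw a background plus equal category bands", {
  at <- AlterationTable(c("s1", "s1", "s2"), c("g1", "g1", "g1"),
                        c("SNV", "AMP", "SNV"))
  fm <- buildOncoprint(at, sort = "input")
  bg <- scenePrimitivesOf(fm, "rect", "part", "background")
  expect_identical(length(bg), 2L)                  # one per cell
  both <- Filter(function(p) identical(p$tags$col_id, "s1"),
                 scenePrimitivesOf(fm, "rect", "part", "band"))
  expect_identical(length(both), 2L)                # two co-occurring categories
  hs <- vapply(both, `[[`, numeric(1), "h")
  expect_equal(hs[1], hs[2])                        # equal bands
  expect_equal(sum(hs), bg[[1]]$h, tolerance = 1e-9)  # band conservation
  single <- Filter(function(p) identical(p$tags$col_id, "s2"),
                   scenePrimitivesOf(fm, "rect", "part", "band"))
  expect_equal(single[[1]]$h, bg[[1]]$h)            # one category fills the cell
})

test_that("frequency side-bars report rounded percentages from the grid", {
  at <- AlterationTable(c("s1", "s2"), c("g1", "g1"), c("SNV", "SNV"))
  # add two unaltered samples through a second gene
  at2 <- AlterationTable(c("s1", "s2", "s3", "s4"), c("g1", "g1", "g2", "g2"),
                         c("SNV", "SNV", "AMP", "AMP"))
  fm <- buildOncoprint(at2, sort = "input")
  texts <- scenePrimitivesOf(fm, "text", "track", "pct_altered")
  labels <- setNames(vapply(texts, `[[`, character(1), "label"),
                     vapply(texts, function(p) p$tags$id, character(1)))
  expect_identical(unname(labels[c("g1", "g2")]), c("50%", "50%"))
  # percentages recomputed from the scene equal those from the grid
  bars <- scenePrimitivesOf(fm, "rect", "track", "pct_altered")
  g <- alterationGrid(at2)
  for (b in bars) {
    gene <- b$tags$id
    grid_pct <- mean(lengths(g$cells[gene, ]) > 0)
    rb <- panelGrid(fm)@trackRects$right[[1]]
    expect_equal(b$w / rb[3], grid_pct, tolerance = 1e-9)
  }
  expect_identical(length(legends(fm)), 1L)
  expect_identical(legends(fm)[[1]]@kind, "categorical_patches")
})

test_that("glyph tables override the equal-band default", {
  at <- AlterationTable(c("s1", "s1"), c("g1", "g1"), c("CNV", "SNV"))
  fm <- buildOncoprint(at, sort = "input",
                       glyphs = list(CNV = c(1, 0), SNV = c(1 / 3, 1 / 3)))
  bands <- scenePrimitivesOf(fm, "rect", "part", "band")
  h <- setNames(vapply(bands, `[[`, numeric(1), "h"),
                vapply(bands, function(p) p$tags$category, character(1)))
  expect_equal(unname(h[["SNV"]] / h[["CNV"]]), 1 / 3, tolerance = 1e-9)
})

test_that("inclusion filters drop sparse genes before layout", {
  at <- AlterationTable(c("s1", "s2", "s3", "s1"),
                        c("g1", "g1", "g1", "g2"),
                        rep("SNV", 4))
  fm <- buildOncoprint(at, min_gene_count = 2L, sort = "input")
  expect_identical(rowOrder(fm), "g1")
  expect_error(buildOncoprint(at, min_gene_count = 99L), "after filtering")
})
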