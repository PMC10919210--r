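test_that("pairwise distances match hand-computed values", {
  m <- LabeledMatrix(rbind(c(0, 0), c(3, 4)), c("a", "b"), c("x", "y"))
  expect_equal(as.numeric(pairwiseDistance(m, "rows", "euclidean")), 5)
  expect_equal(as.numeric(pairwiseDistance(m, "rows", "cityblock")), 7)

  m2 <- LabeledMatrix(rbind(c(1, 2), c(1, 2)), c("a", "b"), c("x", "y"))
  expect_equal(as.numeric(pairwiseDistance(m2, "rows", "euclidean")), 0)

  m3 <- LabeledMatrix(rbind(c(1, 2, 3), c(3, 2, 1)), c("a", "b"), c("x", "y", "z"))
  expect_equal(as.numeric(pairwiseDistance(m3, "rows", "correlation")), 2)
})

test_that("pairwise distances agree with stats::dist on complete data", {
  set.seed(11)
  m <- matrix(rnorm(7 * 5), 7, 5)
  expect_equal(as.numeric(pairwiseDistance(m, "rows", "euclidean")),
               as.numeric(dist(m, "euclidean")))
  expect_equal(as.numeric(pairwiseDistance(m, "rows", "cityblock")),
               as.numeric(dist(m, "manhattan")))
})

test_that("distance edge cases fail loudly", {
  mc <- LabeledMatrix(rbind(c(1, 1, 1), c(1, 2, 3)), c("flat", "b"),
                      c("x", "y", "z"))
  expect_error(pairwiseDistance(mc, "rows", "correlation"), "flat")
  mna <- LabeledMatrix(rbind(c(NA, NA), c(1, 2)), c("gone", "b"), c("x", "y"))
  expect_error(pairwiseDistance(mna, "rows"), "gone")
  # disjoint observation patterns: no co-observed entries
  md <- LabeledMatrix(rbind(c(1, NA), c(NA, 2)), c("a", "b"), c("x", "y"))
  expect_error(pairwiseDistance(md, "rows"), "co-observed")
  # missing values use pairwise-complete entries without rescaling
  mp <- LabeledMatrix(rbind(c(0, 0, NA), c(3, 4, 10)), c("a", "b"),
                      c("x", "y", "z"))
  expect_equal(as.numeric(pairwiseDistance(mp, "rows", "euclidean")), 5)
})

test_that("linkage reproduces the worked 1-D micro-example", {
  m <- matrix(c(0, 1, 5), ncol = 1)
  d <- pairwiseDistance(m, "rows", "euclidean")
  single <- linkageTree(d, "single")
  expect_equal(unname(merges(single)[, 1]), c(0, 2))
  expect_equal(unname(merges(single)[, 2]), c(1, 3))
  expect_equal(unname(merges(single)[, 3]), c(1, 4))
  complete <- linkageTree(d, "complete")
  expect_equal(unname(merges(complete)[, 3]), c(1, 5))
  # two leaves at distance d: one merge at height d
  two <- linkageTree(structure(2.5, Size = 2L, class = "dist"), "average")
  expect_equal(unname(merges(two)), matrix(c(0, 1, 2.5), 1))
  expect_error(linkageTree(c(1, NaN, 2), "single", n_leaves = 3), "NaN")
})

test_that("leaf order is a left-first traversal and relabeling-equivariant", {
  m <- matrix(c(0, 1, 5), ncol = 1)
  link <- linkageTree(pairwiseDistance(m, "rows"), "single")
  expect_identical(leafOrder(link), c(0L, 1L, 2L))
  two <- linkageTree(structure(1, Size = 2L, class = "dist"), "single")
  expect_identical(leafOrder(two), c(0L, 1L))
  # permuting input points keeps every subtree's leaf set intact
  mp <- matrix(c(5, 1, 0), ncol = 1)   # leaf 0 is now the far point
  linkp <- linkageTree(pairwiseDistance(mp, "rows"), "single")
  expect_setequal(leafOrder(linkp), 0:2)
  expect_identical(cutTreeK(linkp, 2)[1L], 1L)          # far point alone...
  expect_identical(cutTreeK(linkp, 2)[2:3], c(2L, 2L))  # ...near pair together
})

test_that("tree cuts undo top merges with first-appearance labels", {
  m <- matrix(c(0, 1, 5), ncol = 1)
  link <- linkageTree(pairwiseDistance(m, "rows"), "single")
  expect_identical(cutTreeK(link, 1), c(1L, 1L, 1L))
  expect_identical(cutTreeK(link, 3), c(1L, 2L, 3L))
  expect_identical(cutTreeK(link, 2), c(1L, 1L, 2L))
  expect_error(cutTreeK(link, 4), "k must be")
  expect_error(cutTreeK(link, 0), "k must be")
})

test_that("linkage, leaf order and cuts agree exactly with the brute-force oracle", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(3:8, 1)
    m <- matrix(rnorm(n * 4), n, 4)
    metric <- c("euclidean", "correlation", "cityblock")[1 + rep %% 3]
    method <- c("single", "complete", "average", "ward")[1 + rep %% 4]
    d <- pairwiseDistance(m, "rows", metric)
    link <- linkageTree(d, method, metric = metric)
    om <- oracle_linkage(full_dist(d), method)
    expect_equal(unname(merges(link)), om, tolerance = 1e-9)
    expect_identical(leafOrder(link), as.integer(oracle_leaf_order(om, n)))
    for (k in c(1L, 2L, n)) if (k <= n)
      expect_identical(cutTreeK(link, k), oracle_cut(om, n, k))
  }
})

test_that("tie-breaking picks the lowest-index pair, same as the oracle", {
  # equilateral configuration: every pairwise distance ties
  d <- structure(rep(1, 6), Size = 4L, class = "dist")
  for (method in c("single", "complete", "average", "ward")) {
    link <- linkageTree(d, method)
    om <- oracle_linkage(full_dist(d), method)
    expect_equal(unname(merges(link)), om, tolerance = 1e-12)
    expect_equal(unname(merges(link)[1, 1:2]), c(0, 1))  # smallest pair first
  }
})

test_that("merge heights are monotone and match stats::hclust on tie-free data", {
  set.seed(7)
  m <- matrix(rnorm(9 * 5), 9, 5)
  d <- pairwiseDistance(m, "rows", "euclidean")
  for (method in c("single", "complete", "average", "ward")) {
    link <- linkageTree(d, method)
    expect_true(all(diff(merges(link)[, 3]) >= -1e-12))
    hc <- stats::hclust(stats::as.dist(full_dist(d)),
                        method = if (method == "ward") "ward.D2" else method)
    expect_equal(sort(merges(link)[, 3]), sort(hc$height), tolerance = 1e-9)
  }
})

test_that("clustering a permuted matrix yields the same partition of ids", {
  set.seed(9)
  m <- matrix(rnorm(7 * 4), 7, 4, dimnames = list(paste0("r", 1:7), NULL))
  link <- linkageTree(pairwiseDistance(m, "rows"), "average")
  perm <- sample(7)
  linkp <- linkageTree(pairwiseDistance(m[perm, ], "rows"), "average")
  part <- function(lab, ids) sort(vapply(split(ids, lab), function(x)
    paste(sort(x), collapse = ","), character(1)), method = "radix") |> unname()
  for (k in 2:4)
    expect_identical(part(cutTreeK(link, k), rownames(m)),
                     part(cutTreeK(linkp, k), rownames(m)[perm]))
})

test_that("cutTreeK(k) refines cutTreeK(k-1)", {
  set.seed(13)
  m <- matrix(rnorm(8 * 3), 8, 3)
  link <- linkageTree(pairwiseDistance(m, "rows"), "complete")
  for (k in 2:8) {
    fine <- cutTreeK(link, k); coarse <- cutTreeK(link, k - 1L)
    expect_true(all(vapply(split(coarse, fine), function(x)
      length(unique(x)) == 1L, logical(1))))
  }
})

test_that("split resolution covers all three flavors", {
  m <- LabeledMatrix(matrix(rnorm(16), 4, 4), paste0("r", 1:4), paste0("c", 1:4))
  none <- resolveSplit(m, "rows", NULL, cluster = FALSE)
  expect_identical(splitMembers(none), list(all = 0:3))

  cat <- resolveSplit(m, "rows", c("A", "A", "B", "A"), cluster = FALSE)
  expect_identical(splitLabels(cat), c("A", "B"))
  expect_identical(splitMembers(cat), list(A = c(0L, 1L, 3L), B = 2L))

  m3 <- LabeledMatrix(matrix(c(0, 1, 5), 3, 1), paste0("r", 1:3), "c1")
  link <- linkageTree(pairwiseDistance(m3, "rows"), "single")
  cut2 <- resolveSplit(m3, "rows", 2, link = link)
  expect_identical(splitLabels(cut2), c("1", "2"))
  expect_identical(splitMembers(cut2), list(`1` = c(0L, 1L), `2` = 2L))

  expect_error(resolveSplit(m, "rows", 2), "linkage")
  expect_error(resolveSplit(m, "rows", c("A", NA, "B", "A")), "r2")
  # concatenated groups always form a permutation
  set.seed(3)
  for (i in 1:20) {
    sp <- sample(c("x", "y", "z"), 4, replace = TRUE)
    res <- resolveSplit(m, "rows", sp, cluster = TRUE)
    expect_identical(sort(unname(unlist(splitMembers(res)))), 0:3)
  }
})

test_that("categorical splits with clustering re-order each group internally", {
  set.seed(21)
  v <- matrix(rnorm(6 * 5), 6, 5)
  m <- LabeledMatrix(v, paste0("r", 1:6), paste0("c", 1:5))
  res <- resolveSplit(m, "rows", c("A", "B", "A", "B", "A", "B"), cluster = TRUE)
  memb <- splitMembers(res)
  expect_identical(sort(memb$A), c(0L, 2L, 4L))
  # within-group order equals the leaf order of that group's own tree
  subl <- linkageTree(pairwiseDistance(v[c(1, 3, 5), ], "rows"), "average")
  expect_identical(memb$A, c(0L, 2L, 4L)[leafOrder(subl) + 1L])
})
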