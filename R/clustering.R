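#' @include AllClasses.R
NULL

.METHODS <- c("single", "complete", "average", "ward")
.METRICS <- c("euclidean", "correlation", "cityblock")

.axis_items <- function(x, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  v <- if (is(x, "LabeledMatrix")) x@values else as.matrix(x)
  if (axis == "cols") v <- t(v)
  v
}

#' Pairwise distances along one axis of a matrix
#'
#' Distances between rows (or columns) with pairwise-complete handling of
#' missing values: each pair is compared over its co-observed entries only,
#' with no rescaling. A pair with no co-observed entries is an error, never a
#' silent zero. The correlation metric is 1 - Pearson r over co-observed
#' entries; an item with zero variance there is an error naming the item.
#'
#' @param x a \linkS4class{LabeledMatrix} or numeric matrix.
#' @param axis "rows" or "cols".
#' @param metric one of euclidean, correlation, cityblock.
#' @return a condensed distance vector of class \code{dist} (length
#'   n(n-1)/2, lower-triangle column order), with item labels attached.
#' @export
pairwiseDistance <- function(x, axis = c("rows", "cols"),
                             metric = c("euclidean", "correlation", "cityblock")) {
  metric <- match.arg(metric)
  axis <- match.arg(axis)
  v <- .axis_items(x, axis)
  ids <- rownames(v)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(v)))
  n <- nrow(v)
  if (n < 2L) stop("need at least 2 items on the chosen axis")
  all_missing <- rowSums(!is.na(v)) == 0L
  if (any(all_missing))
    stop(sprintf("item '%s' has no observed values", ids[which(all_missing)[1L]]))
  d <- numeric(n * (n - 1L) / 2L)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    xi <- v[i, ]
    for (j in (i + 1L):n) {
      xj <- v[j, ]
      ok <- !is.na(xi) & !is.na(xj)
      if (!any(ok))
        stop(sprintf("items '%s' and '%s' share no co-observed entries", ids[i], ids[j]))
      a <- xi[ok]; b <- xj[ok]
      k <- k + 1L
      d[k] <- switch(metric,
        euclidean = sqrt(sum((a - b)^2)),
        cityblock = sum(abs(a - b)),
        correlation = {
          if (length(a) < 2L)
            stop(sprintf("correlation between '%s' and '%s' needs >= 2 co-observed entries",
                         ids[i], ids[j]))
          sa <- stats::sd(a); sb <- stats::sd(b)
          if (sa == 0) stop(sprintf("zero variance in item '%s' under correlation metric", ids[i]))
          if (sb == 0) stop(sprintf("zero variance in item '%s' under correlation metric", ids[j]))
          1 - stats::cor(a, b)
        })
    }
  }
  structure(d, Size = n, Labels = ids, Diag = FALSE, Upper = FALSE,
            method = metric, class = "dist")
}

# condensed-vector index of pair (i, j), 1-based, i != j
.cond_idx <- function(i, j, n) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  as.integer(n * (lo - 1L) - lo * (lo - 1L) / 2L + hi - lo)
}

#' Agglomerative linkage with deterministic tie-breaking
#'
#' Standard agglomerative clustering over a condensed distance vector using
#' Lance--Williams updates. Supported methods: single, complete, average
#' (UPGMA) and ward (on euclidean distances). Ties in the minimal distance
#' are broken by preferring the candidate pair whose (left, right) node
#' indices are lexicographically smallest — fixed so results are exact and
#' platform independent. Node indices are 0-based: leaves 0..n-1, merge t
#' creating node n+t-1.
#'
#' @param distances condensed distance vector (class \code{dist} or plain
#'   numeric with n(n-1)/2 entries).
#' @param method linkage method.
#' @param n_leaves leaf count; inferred from a \code{dist} input.
#' @param metric metric tag stored on the result (bookkeeping only).
#' @return a \linkS4class{LinkageResult}
#' @export
linkageTree <- function(distances, method = c("average", "single", "complete", "ward"),
                        n_leaves = NULL, metric = "euclidean") {
  method <- match.arg(method)
  d <- as.numeric(distances)
  if (any(is.na(d))) stop("NaN/NA in distances")
  if (is.null(n_leaves)) n_leaves <- attr(distances, "Size")
  if (is.null(n_leaves)) {
    n_leaves <- as.integer(round((1 + sqrt(1 + 8 * length(d))) / 2))
  }
  n <- as.integer(n_leaves)
  if (length(d) != n * (n - 1L) / 2L)
    stop("distance vector length does not match n_leaves")
  if (n == 1L)
    return(new("LinkageResult", merges = matrix(numeric(0), 0L, 3L),
               nLeaves = 1L, method = method, metric = metric))
  # full active distance matrix; Inf marks self/inactive
  D <- matrix(Inf, n, n)
  D[lower.tri(D)] <- NA
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- d[.cond_idx(i, j, n)]
    D[j, i] <- D[i, j]
  }
  diag(D) <- Inf
  active <- rep(TRUE, n)
  node <- 0:(n - 1L)          # 0-based node index of each active slot
  size <- rep(1L, n)
  merges <- matrix(0, n - 1L, 3L)
  colnames(merges) <- c("left", "right", "height")
  for (t in seq_len(n - 1L)) {
    act <- which(active)
    Dsub <- D[act, act, drop = FALSE]
    h <- min(Dsub)
    # candidate slot pairs attaining the minimum; break ties on node indices
    cand <- which(Dsub == h, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    ci <- act[cand[, 1L]]; cj <- act[cand[, 2L]]
    lt <- pmin(node[ci], node[cj]); rt <- pmax(node[ci], node[cj])
    pick <- order(lt, rt)[1L]
    i <- ci[pick]; j <- cj[pick]
    merges[t, ] <- c(min(node[i], node[j]), max(node[i], node[j]), h)
    ni <- size[i]; nj <- size[j]
    for (k in act) {
      if (k == i || k == j) next
      dki <- D[k, i]; dkj <- D[k, j]
      D[k, i] <- D[i, k] <- switch(method,
        single   = min(dki, dkj),
        complete = max(dki, dkj),
        average  = (ni * dki + nj * dkj) / (ni + nj),
        ward     = {
          nk <- size[k]
          sq <- ((ni + nk) * dki^2 + (nj + nk) * dkj^2 - nk * h^2) / (ni + nj + nk)
          sqrt(max(sq, 0))
        })
    }
    active[j] <- FALSE
    D[j, ] <- Inf; D[, j] <- Inf
    size[i] <- ni + nj
    node[i] <- n + t - 1L
  }
  new("LinkageResult", merges = merges, nLeaves = n,
      method = method, metric = as.character(metric))
}

# children of each internal node, 0-based; internal node n+t-1 <-> merge row t
.node_children <- function(link, node0) {
  row <- node0 - link@nLeaves + 1L
  c(link@merges[row, 1L], link@merges[row, 2L])
}

#' Display order of a linkage tree's leaves
#'
#' Left-to-right depth-first traversal from the root; at each merge the left
#' child is the subtree containing the lowest-indexed leaf (equivalently,
#' the cluster occupying the lower slot in an in-place agglomeration).
#' Returns a permutation of the 0-based leaf indices 0..n-1.
#'
#' @param link a \linkS4class{LinkageResult}
#' @return integer permutation of 0..n-1
#' @export
leafOrder <- function(link) {
  stopifnot(is(link, "LinkageResult"))
  n <- link@nLeaves
  if (n == 1L) return(0L)
  minleaf <- c(0:(n - 1L), rep(NA_integer_, n - 1L))
  for (t in seq_len(n - 1L)) {
    ch <- link@merges[t, 1:2]
    minleaf[n + t] <- min(minleaf[ch + 1L])
  }
  out <- integer(0)
  stack <- 2L * n - 2L              # root node
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v < n) out <- c(out, v)
    else {
      ch <- .node_children(link, v)
      if (minleaf[ch[1L] + 1L] > minleaf[ch[2L] + 1L]) ch <- rev(ch)
      stack <- c(stack, ch[2L], ch[1L])  # left popped first
    }
  }
  as.integer(out)
}

#' Cut a linkage tree into k flat clusters
#'
#' Undoes the last k-1 merges; each surviving subtree is one cluster.
#' Cluster labels 1..k are assigned by first appearance in the tree's leaf
#' order, so label 1 is always the leftmost display group.
#'
#' @param link a \linkS4class{LinkageResult}
#' @param k number of clusters, 1 <= k <= n.
#' @return integer vector, one label in 1..k per leaf (original leaf index
#'   order, i.e. element i+1 is the label of 0-based leaf i).
#' @export
cutTreeK <- function(link, k) {
  stopifnot(is(link, "LinkageResult"))
  n <- link@nLeaves
  if (k < 1L || k > n) stop(sprintf("k must be in 1..%d", n))
  parent <- seq_len(2L * n - 1L)    # union-find over 1-based node ids
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  n_apply <- n - k
  if (n_apply > 0L) for (t in seq_len(n_apply)) {
    newn <- n + t                                # 1-based id of node n+t-1
    for (ch in .node_children(link, n + t - 1L)) {
      r <- find(ch + 1L)
      parent[r] <- newn
    }
  }
  root_of <- vapply(seq_len(n), find, integer(1))
  labels <- integer(n)
  nxt <- 0L
  seen <- integer(0)
  for (leaf in leafOrder(link)) {
    r <- root_of[leaf + 1L]
    if (!r %in% seen) { seen <- c(seen, r); nxt <- nxt + 1L }
    labels[leaf + 1L] <- match(r, seen)
  }
  labels
}

# shared machinery for resolveSplit: returns resolution + per-group links
.resolve_split_full <- function(x, axis = c("rows", "cols"), split = NULL,
                                link = NULL, cluster = !is.null(link),
                                method = "average", metric = "euclidean",
                                levels = NULL) {
  axis <- match.arg(axis)
  v <- .axis_items(x, axis)
  n <- nrow(v)
  ids <- rownames(v)
  group_links <- list()
  if (is.null(split)) {
    ord <- if (!is.null(link)) leafOrder(link) else 0:(n - 1L)
    res <- new("SplitResolution", labels = "all", members = list(as.integer(ord)))
    if (!is.null(link)) group_links[["all"]] <- link
  } else if (is.numeric(split) && length(split) == 1L) {
    if (is.null(link)) stop("an integer split requires a linkage tree")
    k <- as.integer(split)
    lab <- cutTreeK(link, k)
    ord <- leafOrder(link)
    members <- lapply(seq_len(k), function(g) as.integer(ord[lab[ord + 1L] == g]))
    res <- new("SplitResolution", labels = as.character(seq_len(k)), members = members)
  } else {
    split <- as.character(split)
    if (length(split) != n)
      stop(sprintf("categorical split has %d entries for %d items", length(split), n))
    if (anyNA(split))
      stop(sprintf("missing split values for: %s",
                   paste(ids[is.na(split)], collapse = ", ")))
    lev <- if (!is.null(levels)) {
      if (!all(split %in% levels)) stop("split contains values outside the supplied levels")
      as.character(levels)
    } else unique(split)   # first-appearance order
    members <- vector("list", length(lev))
    for (gi in seq_along(lev)) {
      pos <- which(split == lev[gi]) - 1L          # 0-based
      if (cluster && length(pos) >= 2L) {
        sub <- v[pos + 1L, , drop = FALSE]
        gl <- linkageTree(pairwiseDistance(sub, "rows", metric), method, metric = metric)
        group_links[[lev[gi]]] <- gl
        pos <- pos[leafOrder(gl) + 1L]
      } else if (!cluster && !is.null(link)) {
        ord <- leafOrder(link)
        pos <- ord[ord %in% pos]
      }
      members[[gi]] <- as.integer(pos)
    }
    keep <- lengths(members) > 0L
    res <- new("SplitResolution", labels = lev[keep], members = members[keep])
  }
  list(resolution = res, group_links = group_links)
}

#' Resolve a row/column split into ordered display groups
#'
#' Three split flavors: \code{NULL} (one group, leaf order if a tree is
#' given), an integer k (cut the supplied linkage tree into k groups,
#' ordered and internally ordered by leaf order), or a categorical vector
#' (groups in first-appearance order, or \code{levels} order if supplied).
#' With a categorical split and \code{cluster = TRUE}, each group is
#' re-ordered by a linkage computed on that group alone, so every block is
#' internally clustered.
#'
#' @param x matrix or \linkS4class{LabeledMatrix} (supplies group data for
#'   per-group re-clustering).
#' @param axis "rows" or "cols".
#' @param split NULL, a single integer k, or a categorical vector along the
#'   axis.
#' @param link a \linkS4class{LinkageResult} over the axis (required for an
#'   integer split).
#' @param cluster re-order members by clustering (per-group for categorical
#'   splits).
#' @param method,metric linkage options used for per-group re-clustering.
#' @param levels optional explicit group order for a categorical split.
#' @return a \linkS4class{SplitResolution}; positions are 0-based.
#' @export
resolveSplit <- function(x, axis = c("rows", "cols"), split = NULL, link = NULL,
                         cluster = !is.null(link), method = "average",
                         metric = "euclidean", levels = NULL) {
  .resolve_split_full(x, axis, split, link, cluster, method, metric, levels)$resolution
}
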