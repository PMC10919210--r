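# Independent O(n^3) brute-force agglomerator used as the clustering oracle.
# Works from the full leaf-distance matrix; cluster distances are recomputed
# from scratch at every step (single = min, complete = max, average = mean
# over cross pairs; ward by its recursive definition, memoized over the
# oracle's own merge history). Ties are broken by the lexicographically
# smallest (left, right) node-index pair — the documented engine rule.

oracle_linkage <- function(D, method) {
  n <- nrow(D)
  memo <- new.env(parent = emptyenv())
  # cluster: list(id = node index, leaves = integer leaf set (1-based),
  #               kids = NULL or list(a, b))
  clus <- lapply(seq_len(n), function(i)
    list(id = i - 1L, leaves = i, kids = NULL))
  ward_d <- function(a, b) {
    key <- paste(min(a$id, b$id), max(a$id, b$id))
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (is.null(a$kids) && is.null(b$kids)) {
      D[a$leaves, b$leaves]
    } else if (!is.null(b$kids)) {
      i <- b$kids[[1]]; j <- b$kids[[2]]
      ni <- length(i$leaves); nj <- length(j$leaves); nk <- length(a$leaves)
      sqrt(max(((ni + nk) * ward_d(a, i)^2 + (nj + nk) * ward_d(a, j)^2 -
                  nk * ward_d(i, j)^2) / (ni + nj + nk), 0))
    } else ward_d(b, a)
    memo[[key]] <- val
    val
  }
  cdist <- function(a, b) {
    if (method == "ward") return(ward_d(a, b))
    cross <- D[a$leaves, b$leaves, drop = FALSE]
    switch(method, single = min(cross), complete = max(cross),
           average = mean(cross))
  }
  merges <- matrix(0, n - 1L, 3L)
  for (t in seq_len(n - 1L)) {
    best <- NULL
    for (i in seq_along(clus)) for (j in seq_along(clus)) {
      if (i >= j) next
      d <- cdist(clus[[i]], clus[[j]])
      lo <- min(clus[[i]]$id, clus[[j]]$id); hi <- max(clus[[i]]$id, clus[[j]]$id)
      cand <- list(d = d, lo = lo, hi = hi, i = i, j = j)
      if (is.null(best) || d < best$d ||
          (d == best$d && (lo < best$lo || (lo == best$lo && hi < best$hi))))
        best <- cand
    }
    merges[t, ] <- c(best$lo, best$hi, best$d)
    a <- clus[[best$i]]; b <- clus[[best$j]]
    if (a$id > b$id) { tmp <- a; a <- b; b <- tmp }
    merged <- list(id = n + t - 1L, leaves = sort(c(a$leaves, b$leaves)),
                   kids = list(a, b))
    clus <- c(clus[-c(best$i, best$j)], list(merged))
  }
  merges
}

# leaf order by traversal of an oracle merge matrix: left child is the
# subtree holding the lowest-indexed leaf (the engine's documented rule)
oracle_leaf_order <- function(merges, n) {
  minleaf <- c(0:(n - 1L), rep(NA_integer_, max(n - 1L, 0L)))
  for (t in seq_len(n - 1L))
    minleaf[n + t] <- min(minleaf[merges[t, 1:2] + 1L])
  kids <- function(node) merges[node - n + 1L, 1:2]
  out <- integer(0)
  stack <- 2L * n - 2L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v < n) out <- c(out, v)
    else {
      ch <- kids(v)
      if (minleaf[ch[1L] + 1L] > minleaf[ch[2L] + 1L]) ch <- rev(ch)
      stack <- c(stack, ch[2L], ch[1L])
    }
  }
  out
}

# flat k-clustering by undoing the top merges of an oracle merge matrix,
# labels by first appearance in oracle leaf order
oracle_cut <- function(merges, n, k) {
  parent <- seq_len(2L * n - 1L)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  if (n - k > 0L) for (t in seq_len(n - k)) {
    for (ch in merges[t, 1:2]) parent[find(ch + 1L)] <- n + t
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels <- integer(n); seen <- integer(0)
  for (leaf in oracle_leaf_order(merges, n)) {
    r <- roots[leaf + 1L]
    if (!r %in% seen) seen <- c(seen, r)
    labels[leaf + 1L] <- match(r, seen)
  }
  labels
}

# all permutations of a small vector (for brute-force ordering searches)
combinat_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in combinat_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# full distance matrix from heatscene's condensed vector
full_dist <- function(d) {
  n <- attr(d, "Size")
  M <- matrix(0, n, n)
  M[lower.tri(M)] <- as.numeric(d)
  M + t(M)
}
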