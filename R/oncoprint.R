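#' @include clustermap.R
NULL

#' Pivot an alteration table to a genes-by-samples grid of category sets
#'
#' Cell (gene, sample) holds the set of alteration categories recorded for
#' that pair (possibly several — co-occurring alterations). Genes and
#' samples appear in first-appearance order, ready for sorting.
#'
#' @param table an \linkS4class{AlterationTable}.
#' @return list(genes, samples, categories, cells) where cells is a
#'   genes x samples list-matrix of character vectors
#' @export
alterationGrid <- function(table) {
  stopifnot(is(table, "AlterationTable"))
  r <- table@records
  genes <- unique(r$gene); samples <- unique(r$sample)
  categories <- unique(r$category)
  cells <- matrix(vector("list", length(genes) * length(samples)),
                  length(genes), length(samples),
                  dimnames = list(genes, samples))
  for (k in seq_len(nrow(r))) {
    g <- r$gene[k]; s <- r$sample[k]
    cells[[g, s]] <- unique(c(cells[[g, s]], r$category[k]))
  }
  list(genes = genes, samples = samples, categories = categories, cells = cells)
}

#' Mutual-exclusivity ("memo") sort of an alteration grid
#'
#' Genes are ordered by alteration frequency, descending (ties keep input
#' order). Samples are ordered by descending lexicographic comparison of
#' their binary altered/not vectors read in the sorted gene order (ties keep
#' input order) — the classic oncoPrint waterfall that exposes mutual
#' exclusivity.
#'
#' @param grid output of \code{\link{alterationGrid}}.
#' @return list(gene_order, sample_order), character ids
#' @export
memoSort <- function(grid) {
  ng <- length(grid$genes); ns <- length(grid$samples)
  if (ng < 1L || ns < 1L) stop("empty alteration grid")
  altered <- matrix(0L, ng, ns)
  for (g in seq_len(ng)) for (s in seq_len(ns))
    if (length(grid$cells[[g, s]])) altered[g, s] <- 1L
  freq <- rowSums(altered)
  gene_ord <- order(-freq)                       # stable: ties keep input order
  B <- altered[gene_ord, , drop = FALSE]
  keys <- lapply(seq_len(ng), function(g) -B[g, ])
  sample_ord <- do.call(order, c(keys, list(seq_len(ns))))
  list(gene_order = grid$genes[gene_ord], sample_order = grid$samples[sample_ord])
}

#' Build an oncoPrint figure
#'
#' Genes-by-samples alteration glyphs on the cluster-heatmap chassis: each
#' cell draws a neutral-gray background rect (90% of the cell) and one
#' horizontal band per alteration category present, equal bands in global
#' category order (or per-category fraction/offset via \code{glyphs}). A
#' stacked top bar counts alterations per sample by category; a right bar
#' shows each gene's percent of altered samples with the rounded percentage
#' as text. Samples are ordered by mutual-exclusivity sorting by default.
#'
#' @param alterations an \linkS4class{AlterationTable}.
#' @param color categorical \linkS4class{ColorSpec} over the alteration
#'   categories; defaults to the standard palette in first-appearance order.
#' @param sort "memo", "frequency" (genes only) or "input".
#' @param min_gene_count,min_sample_count drop genes/samples with fewer
#'   altered cells before layout.
#' @param glyphs optional named list: category -> c(fraction, offset) of the
#'   inner cell height (e.g. full-height copy-number, middle-third SNV).
#' @param top_annotation,bottom_annotation,left_annotation,right_annotation
#'   extra annotation tracks, as in \code{\link{buildClustermap}}.
#' @param bar_extent thickness of the built-in frequency bars.
#' @param plot_rect,track_pad geometry options.
#' @return a \linkS4class{FigureModel}
#' @export
buildOncoprint <- function(alterations, color = NULL,
                           sort = c("memo", "frequency", "input"),
                           min_gene_count = 0L, min_sample_count = 0L,
                           glyphs = NULL,
                           top_annotation = list(), bottom_annotation = list(),
                           left_annotation = list(), right_annotation = list(),
                           bar_extent = 0.07,
                           plot_rect = c(0.15, 0.02, 0.70, 0.75),
                           track_pad = 0.005) {
  sort <- match.arg(sort)
  grid0 <- alterationGrid(alterations)
  if (!length(grid0$genes) || !length(grid0$samples))
    stop("empty alteration grid")
  altered_count <- function(cells) apply(cells, 1L, function(row) sum(lengths(row) > 0))
  keep_g <- altered_count(grid0$cells) >= min_gene_count
  keep_s <- apply(grid0$cells, 2L, function(col) sum(lengths(col) > 0)) >= min_sample_count
  grid0$genes <- grid0$genes[keep_g]; grid0$samples <- grid0$samples[keep_s]
  grid0$cells <- grid0$cells[keep_g, keep_s, drop = FALSE]
  if (!length(grid0$genes) || !length(grid0$samples))
    stop("no genes/samples left after filtering")

  ord <- switch(sort,
    memo = memoSort(grid0),
    frequency = list(gene_order = memoSort(grid0)$gene_order,
                     sample_order = grid0$samples),
    input = list(gene_order = grid0$genes, sample_order = grid0$samples))
  genes <- ord$gene_order; samples <- ord$sample_order
  cells <- grid0$cells[genes, samples, drop = FALSE]
  ng <- length(genes); ns <- length(samples)
  cat_order <- grid0$categories
  spec <- resolveColorSpec(
    if (!is.null(color)) color else colorSpecCategorical(title = "alteration"),
    cat_order)

  side_ext0 <- list(
    top = c(bar_extent, vapply(.track_list(top_annotation), function(t) t@extent, numeric(1))),
    bottom = vapply(.track_list(bottom_annotation), function(t) t@extent, numeric(1)),
    left = vapply(.track_list(left_annotation), function(t) t@extent, numeric(1)),
    right = c(vapply(.track_list(right_annotation), function(t) t@extent, numeric(1)), bar_extent))
  body_rect <- .shrink_plot_rect(plot_rect, side_ext0, track_pad)
  pg <- computeGrid(ng, ns, body_rect, 0, 0)
  rcells <- cellIntervals(pg, "rows")
  ccells <- cellIntervals(pg, "cols")
  prims <- list()
  for (i in seq_len(ng)) for (j in seq_len(ns)) {
    w <- ccells$hi[j] - ccells$lo[j]; h <- rcells$hi[i] - rcells$lo[i]
    x0 <- ccells$lo[j] + 0.05 * w; y0 <- rcells$lo[i] + 0.05 * h
    iw <- 0.9 * w; ih <- 0.9 * h
    prims[[length(prims) + 1L]] <-
      sceneRect(x0, y0, iw, ih, fill = "#ebebebff",
                tags = list(row_id = genes[i], col_id = samples[j], part = "background"))
    present <- cat_order[cat_order %in% cells[[i, j]]]
    if (!length(present)) next
    if (is.null(glyphs)) {
      bh <- ih / length(present)
      for (b in seq_along(present))
        prims[[length(prims) + 1L]] <-
          sceneRect(x0, y0 + ih - b * bh, iw, bh,
                    fill = mapColors(present[b], spec),
                    tags = list(row_id = genes[i], col_id = samples[j],
                                category = present[b], part = "band"))
    } else {
      for (ct in present) {
        fo <- glyphs[[ct]] %||% c(1, 0)
        prims[[length(prims) + 1L]] <-
          sceneRect(x0, y0 + fo[2L] * ih, iw, fo[1L] * ih,
                    fill = mapColors(ct, spec),
                    tags = list(row_id = genes[i], col_id = samples[j],
                                category = ct, part = "band"))
      }
    }
  }

  # built-in frequency bars: stacked per-sample counts (top), % altered (right)
  counts <- matrix(0, ns, length(cat_order), dimnames = list(samples, cat_order))
  for (i in seq_len(ng)) for (j in seq_len(ns))
    for (ct in cells[[i, j]]) counts[j, ct] <- counts[j, ct] + 1
  top_bar <- annoBar(counts, color = spec, extent = bar_extent, title = "alterations")
  pct <- vapply(seq_len(ng), function(i) mean(lengths(cells[i, ]) > 0), numeric(1))

  tr_top <- c(list(top_bar), .track_list(top_annotation))
  tr_bot <- .track_list(bottom_annotation)
  tr_left <- .track_list(left_annotation)
  tr_right <- .track_list(right_annotation)
  .check_track_ids(c(tr_top, tr_bot), samples, "samples")
  .check_track_ids(c(tr_left, tr_right), genes, "genes")

  legend_items <- list(legendFromColorSpec(spec, cat_order))
  sides <- list(top = tr_top, bottom = tr_bot, left = tr_left, right = tr_right)
  for (side in names(sides)) {
    tracks <- sides[[side]]
    extents <- vapply(tracks, function(t) t@extent, numeric(1))
    right_bar_here <- side == "right"
    if (right_bar_here) extents <- c(extents, bar_extent)
    if (!length(extents)) next
    rects <- allocateTracks(side, extents, body_rect, pad = track_pad)
    pg@trackRects[[side]] <- rects
    axis_cells <- if (side %in% c("top", "bottom")) ccells else rcells
    order_ids <- if (side %in% c("top", "bottom")) samples else genes
    for (ti in seq_along(tracks)) {
      out <- renderTrack(tracks[[ti]], order_ids, rects[[ti]], axis_cells, side)
      prims <- c(prims, out$primitives)
      if (!is.null(out$spec))
        legend_items[[length(legend_items) + 1L]] <-
          legendFromColorSpec(out$spec, if (tracks[[ti]]@kind == "simple")
            .track_values(tracks[[ti]], order_ids) else NULL)
    }
    if (right_bar_here) {
      rb <- rects[[length(rects)]]
      fr <- .track_frame("right", rb)
      for (i in seq_len(ng)) {
        span <- rcells$hi[i] - rcells$lo[i]
        a0 <- rcells$lo[i] + 0.1 * span; a1 <- rcells$hi[i] - 0.1 * span
        prims[[length(prims) + 1L]] <-
          fr$rect(a0, a1, 0, pct[i], fill = "#4d4d4dff",
                  tags = list(track = "pct_altered", id = genes[i]))
        tp <- fr$pt((a0 + a1) / 2, min(pct[i] + 0.12, 0.97))
        prims[[length(prims) + 1L]] <-
          sceneText(tp$x, tp$y, sprintf("%d%%", round(100 * pct[i])),
                    size = min(span * 0.5, 0.012), anchor = "start",
                    tags = list(track = "pct_altered", id = genes[i]))
      }
    }
  }

  scene <- Scene(prims, meta = list(figure = "oncoprint", sort = sort,
                                    n_genes = ng, n_samples = ns))
  new("FigureModel", grid = pg, scene = scene,
      legends = buildLegends(legend_items),
      rowOrder = genes, colOrder = samples,
      rowSplit = NULL, colSplit = NULL)
}
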