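#' @include AllClasses.R
NULL

# All fixture generators draw from one named generator — Mersenne-Twister
# with Inversion normals and Rejection sampling — seeded per call, so equal
# seeds give bitwise-equal fixtures across platforms and releases. The
# caller's RNG state is left untouched.
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || seed != floor(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  suppressWarnings(set.seed(as.integer(seed),
                            kind = "Mersenne-Twister", normal.kind = "Inversion",
                            sample.kind = "Rejection"))
  expr
}

#' Generate a random normal fixture matrix with grouped columns
#'
#' Emulates the simulated inputs of the worked examples: standard-normal
#' entries, with the columns of group g (g = 0, 1, ...) shifted upward by
#' \code{g * group_shift}. Groups are contiguous, as equal-sized as possible.
#' The companion annotation table carries the group labels plus one uniform
#' numeric column.
#'
#' @param n_rows,n_cols positive dimensions.
#' @param n_col_groups number of column groups, <= n_cols.
#' @param group_shift mean shift between consecutive groups.
#' @param seed integer; identical seeds give identical fixtures.
#' @return list with elements \code{matrix} (\linkS4class{LabeledMatrix}) and
#'   \code{annotation} (\linkS4class{AnnotationTable} over the columns).
#' @examples
#' fx <- makeFixtureMatrix(10, 6, n_col_groups = 2, group_shift = 3, seed = 1)
#' dim(fx$matrix)
#' annotationColumn(fx$annotation, "group")
#' @export
makeFixtureMatrix <- function(n_rows, n_cols, n_col_groups = 2L,
                              group_shift = 1, seed = 1L) {
  if (n_rows < 1L || n_cols < 1L) stop("dimensions must be positive")
  if (n_col_groups < 1L || n_col_groups > n_cols)
    stop("n_col_groups must be in 1..n_cols")
  .with_seed(seed, {
    vals <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
    # contiguous, near-equal groups; 0-based shift multiplier
    grp <- sort(rep_len(seq_len(n_col_groups), n_cols))
    vals <- sweep(vals, 2L, (grp - 1L) * group_shift, `+`)
    score <- stats::runif(n_cols)
    row_ids <- paste0("F", seq_len(n_rows))
    col_ids <- paste0("S", seq_len(n_cols))
    ann <- AnnotationTable(col_ids,
                           list(group = paste0("G", grp), score = score))
    list(matrix = LabeledMatrix(vals, row_ids, col_ids), annotation = ann)
  })
}

.FIXTURE_CATEGORIES <- c("SNV", "AMP", "DEL")

#' Generate a random alteration table
#'
#' Each (sample, gene) pair is altered independently with the gene's rate;
#' the alteration category is drawn uniformly from a fixed three-category
#' set (SNV, AMP, DEL). A synthetic stand-in for a real variants profile.
#'
#' @param n_samples,n_genes positive counts.
#' @param per_gene_rates numeric vector of length n_genes, rates in [0, 1].
#' @param seed integer.
#' @return an \linkS4class{AlterationTable}
#' @export
makeFixtureAlterations <- function(n_samples, n_genes, per_gene_rates, seed = 1L) {
  if (n_samples < 1L || n_genes < 1L) stop("dimensions must be positive")
  if (length(per_gene_rates) != n_genes)
    stop("per_gene_rates must have one rate per gene")
  if (any(per_gene_rates < 0 | per_gene_rates > 1))
    stop("rates must lie in [0, 1]")
  .with_seed(seed, {
    samples <- paste0("P", seq_len(n_samples))
    genes <- paste0("gene", seq_len(n_genes))
    recs <- list()
    for (g in seq_len(n_genes)) {
      hit <- stats::runif(n_samples) < per_gene_rates[g]
      if (!any(hit)) next
      cat_idx <- sample.int(length(.FIXTURE_CATEGORIES), sum(hit), replace = TRUE)
      recs[[length(recs) + 1L]] <- data.frame(
        sample = samples[hit], gene = genes[g],
        category = .FIXTURE_CATEGORIES[cat_idx], stringsAsFactors = FALSE)
    }
    recs <- if (length(recs)) do.call(rbind, recs)
    else data.frame(sample = character(0), gene = character(0),
                    category = character(0), stringsAsFactors = FALSE)
    new("AlterationTable", records = recs, dropped = 0L)
  })
}

#' Generate a dot-table fixture binding five channels to distinct variables
#'
#' Rows and columns are positional keys; \code{value} (size channel) is
#' uniform on [0, 1], \code{color_value} an independent standard normal, and
#' \code{hue} cycles over \code{n_hues} categories — five distinct variables
#' for row, column, size, color and marker.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param n_hues number of hue categories (marker shapes).
#' @param seed integer.
#' @return a \linkS4class{DotTable}
#' @export
makeFixtureDotTable <- function(n_rows, n_cols, n_hues = 3L, seed = 1L) {
  if (n_rows < 1L || n_cols < 1L) stop("dimensions must be positive")
  .with_seed(seed, {
    grid <- expand.grid(r = seq_len(n_rows), c = seq_len(n_cols))
    DotTable(row_key = paste0("M", grid$r),
             col_key = paste0("C", grid$c),
             value = stats::runif(nrow(grid)),
             color_value = stats::rnorm(nrow(grid)),
             hue = paste0("H", ((grid$r + grid$c) %% n_hues) + 1L))
  })
}
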