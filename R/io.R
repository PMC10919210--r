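#' @include AllClasses.R
NULL

# Missing-value tokens accepted on read: empty string, NA, NaN (case folded).
.MISSING_TOKENS <- c("", "na", "nan")

.is_missing_token <- function(x) tolower(trimws(x)) %in% .MISSING_TOKENS

.parse_numeric <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  out[.is_missing_token(x)] <- NA_real_
  out
}

# Split a delimited file into a list of character vectors, one per line;
# enforces a rectangular table and reports ragged lines by number.
.read_table_lines <- function(path, delimiter) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop(sprintf("empty file: %s", path))
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  # a trailing delimiter yields a silent last empty field; pad explicitly
  n_delim <- lengths(regmatches(lines, gregexpr(delimiter, lines, fixed = TRUE)))
  fields <- Map(function(f, k) c(f, rep("", k + 1L - length(f))), fields, n_delim)
  width <- length(fields[[1L]])
  bad <- which(lengths(fields) != width)
  if (length(bad))
    stop(sprintf("ragged row at line %d: %d fields, expected %d",
                 bad[1L], length(fields[[bad[1L]]]), width))
  fields
}

.check_unique <- function(ids, what) {
  d <- ids[duplicated(ids)]
  if (length(d)) stop(sprintf("duplicate %s id '%s'", what, d[1L]))
  ids
}

#' Read a labeled numeric matrix from TSV/CSV
#'
#' First row is a header of column ids (its first field, the id-column name,
#' is ignored); the first field of each subsequent row is the row id. Cells
#' that do not parse as numbers (including the missing tokens "", "NA",
#' "NaN", case-insensitive) become missing. Ids are kept in file order and
#' never coerced to numbers.
#'
#' @param path file path.
#' @param delimiter field separator, default tab.
#' @return a \linkS4class{LabeledMatrix}
#' @export
readMatrix <- function(path, delimiter = "\t") {
  f <- .read_table_lines(path, delimiter)
  col_ids <- .check_unique(as.character(f[[1L]][-1L]), "column")
  if (length(f) < 2L) stop(sprintf("no data rows in %s", path))
  body <- f[-1L]
  row_ids <- .check_unique(vapply(body, `[`, character(1), 1L), "row")
  vals <- t(vapply(body, function(r) .parse_numeric(r[-1L]),
                   numeric(length(col_ids))))
  if (length(col_ids) == 1L) vals <- matrix(vals, ncol = 1L)
  LabeledMatrix(vals, rowIds = row_ids, colIds = col_ids)
}

#' Write a LabeledMatrix to TSV/CSV
#'
#' Missing cells are written as "NA"; reading the file back reproduces ids,
#' shape, and values within text float precision.
#'
#' @param x a LabeledMatrix.
#' @param path output path.
#' @param delimiter field separator.
#' @param digits significant digits written, default 15 (round-trip safe).
#' @return invisibly, \code{path}
#' @export
writeMatrix <- function(x, path, delimiter = "\t", digits = 15L) {
  stopifnot(is(x, "LabeledMatrix"))
  v <- x@values
  fmt <- function(row) {
    s <- formatC(row, digits = digits, format = "g")
    s[is.na(row)] <- "NA"
    s
  }
  lines <- c(paste(c("id", x@colIds), collapse = delimiter),
             vapply(seq_len(nrow(v)), function(i)
               paste(c(x@rowIds[i], fmt(v[i, ])), collapse = delimiter),
               character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an annotation table from TSV/CSV
#'
#' Columns are auto-tagged: numeric when every non-missing cell parses as a
#' real number, categorical otherwise (a mixed column like "1"/"x" stays
#' categorical). Categorical level order is first appearance in the file.
#'
#' @inheritParams readMatrix
#' @return an \linkS4class{AnnotationTable}
#' @export
readAnnotation <- function(path, delimiter = "\t") {
  f <- .read_table_lines(path, delimiter)
  if (length(f) < 2L) stop(sprintf("no data rows in %s", path))
  col_names <- .check_unique(as.character(f[[1L]][-1L]), "annotation column")
  body <- f[-1L]
  idx <- .check_unique(vapply(body, `[`, character(1), 1L), "index")
  columns <- list()
  types <- character(0)
  for (j in seq_along(col_names)) {
    raw <- vapply(body, `[`, character(1), j + 1L)
    missing <- .is_missing_token(raw)
    num <- suppressWarnings(as.numeric(raw))
    if (all(missing | !is.na(num))) {
      col <- num
      col[missing] <- NA_real_
      types[col_names[j]] <- "numeric"
    } else {
      col <- as.character(raw)
      col[missing] <- NA_character_
      types[col_names[j]] <- "categorical"
    }
    columns[[col_names[j]]] <- col
  }
  new("AnnotationTable", indexIds = idx, columns = columns, types = types)
}

#' Read a MAF-like alteration table
#'
#' Long-form records of (sample, gene, alteration category). Column names
#' are configurable and default to the common MAF headers. Rows whose
#' category is empty/missing are dropped; the count of dropped rows is
#' recorded on the returned object and reported via a message.
#'
#' @inheritParams readMatrix
#' @param sample_col,gene_col,category_col header names of the three fields.
#' @return an \linkS4class{AlterationTable}
#' @export
readAlterations <- function(path, delimiter = "\t",
                            sample_col = "Tumor_Sample_Barcode",
                            gene_col = "Hugo_Symbol",
                            category_col = "Variant_Classification") {
  f <- .read_table_lines(path, delimiter)
  header <- as.character(f[[1L]])
  for (nm in c(sample_col, gene_col, category_col))
    if (!nm %in% header) stop(sprintf("column '%s' not found in %s", nm, path))
  body <- f[-1L]
  get <- function(nm) vapply(body, `[`, character(1), match(nm, header))
  sample <- get(sample_col); gene <- get(gene_col); category <- get(category_col)
  keep <- !.is_missing_token(category)
  dropped <- sum(!keep)
  if (dropped) message(sprintf("readAlterations: dropped %d record(s) with empty category", dropped))
  if (any(.is_missing_token(sample[keep])) || any(.is_missing_token(gene[keep])))
    stop("alteration records with empty sample or gene fields")
  AlterationTable(sample[keep], gene[keep], category[keep], dropped = dropped)
}

#' Read a long-form dot table
#'
#' One record per (row key, column key, optional hue): the input grammar of
#' the dot heatmap. Column bindings are configurable.
#'
#' @inheritParams readMatrix
#' @param row_col,col_col,value_col header names of the row key, column key
#'   and size-driving value fields.
#' @param color_col optional header of the color-driving field (numeric or
#'   categorical); defaults to the value field.
#' @param hue_col optional header of the hue (marker) field.
#' @return a \linkS4class{DotTable}
#' @export
readDotTable <- function(path, delimiter = "\t",
                         row_col = "row", col_col = "col", value_col = "value",
                         color_col = NULL, hue_col = NULL) {
  f <- .read_table_lines(path, delimiter)
  header <- as.character(f[[1L]])
  need <- c(row_col, col_col, value_col, color_col, hue_col)
  for (nm in need)
    if (!nm %in% header) stop(sprintf("column '%s' not found in %s", nm, path))
  body <- f[-1L]
  get <- function(nm) vapply(body, `[`, character(1), match(nm, header))
  value <- .parse_numeric(get(value_col))
  if (any(!is.finite(value))) stop("dot values must be finite numbers")
  color_raw <- if (is.null(color_col)) value else get(color_col)
  color_num <- if (is.character(color_raw)) .parse_numeric(color_raw) else color_raw
  color_value <- if (is.character(color_raw) && any(is.na(color_num) & !.is_missing_token(color_raw)))
    as.character(color_raw) else as.numeric(color_num)
  hue <- if (is.null(hue_col)) NA_character_ else get(hue_col)
  DotTable(get(row_col), get(col_col), value, color_value, hue)
}
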