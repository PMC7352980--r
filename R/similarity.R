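#' Construct a class-annotated similarity matrix
#'
#' A `similarity_matrix` holds a rectangular array of Jaccard-Tanimoto
#' coefficients between ligand conformers, together with ligand identifiers
#' and target-class labels for rows and columns. Combined shape+colour
#' scores live on \[0, 2\]; single-feature scores on \[0, 1\]. The matrix is
#' not assumed symmetric: a 3D overlay of the pair (A, B) is close to, but
#' not identical with, the overlay of (B, A).
#'
#' Duplicate identifiers are permitted (multiple conformers of one
#' compound) and are treated as distinct rows/columns.
#'
#' @param values numeric matrix of similarity coefficients.
#' @param row_ids,col_ids character vectors of ligand/conformer identifiers.
#' @param row_class,col_class class label per row/column (character or
#'   factor; coerced to character).
#' @param score_range closed interval the entries must lie in; default
#'   `c(0, 2)` for combined shape+colour scores, use `c(0, 1)` for a
#'   single-feature matrix.
#' @return An object of class `similarity_matrix`: the numeric matrix with
#'   `ids` and `class` attributes for both margins and a `score_range`
#'   attribute.
#' @examples
#' v <- matrix(runif(9), 3, 3, dimnames = list(letters[1:3], letters[1:3]))
#' sm <- similarity_matrix(v, letters[1:3], letters[1:3],
#'                         c("A", "A", "B"), c("A", "A", "B"),
#'                         score_range = c(0, 1))
#' class_numbers(sm)
#' @seealso [read_similarity_matrix()], [class_block()],
#'   [extract_query_vector()]
#' @export
similarity_matrix <- function(values, row_ids, col_ids, row_class, col_class,
                              score_range = c(0, 2)) {
  score_range <- check_score_range(score_range)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != length(row_ids) || ncol(values) != length(col_ids)) {
    stop("dimensions of `values` do not match the id vectors", call. = FALSE)
  }
  if (length(row_class) != length(row_ids) ||
      length(col_class) != length(col_ids)) {
    stop("class labels must match the id vectors in length", call. = FALSE)
  }
  check_values_in_range(values, score_range, "similarity entries")
  dimnames(values) <- list(as.character(row_ids), as.character(col_ids))
  structure(values,
            row_class = as.character(row_class),
            col_class = as.character(col_class),
            score_range = score_range,
            class = c("similarity_matrix", "matrix", "array"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  rng <- attr(x, "score_range")
  cat(sprintf("similarity_matrix: %d x %d, score range [%g, %g]\n",
              nrow(x), ncol(x), rng[1], rng[2]))
  cls <- class_numbers(x)
  cat("classes:", paste(sprintf("%s (n=%d)", names(cls),
                                tabulate(match(attr(x, "col_class"),
                                               names(cls)),
                                         nbins = length(cls))),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Class labels mapped to 1-based class numbers
#'
#' Target classes are referred to either by label or by an integer class
#' number `m` in `1..M`. The numbering is the order of first appearance
#' among the column classes (then any row-only classes).
#'
#' @param x a `similarity_matrix`.
#' @return Named integer vector: names are class labels, values 1..M.
#' @export
class_numbers <- function(x) {
  labs <- unique(c(attr(x, "col_class"), attr(x, "row_class")))
  stats::setNames(seq_along(labs), labs)
}

resolve_class <- function(x, m) {
  cls <- class_numbers(x)
  if (is.numeric(m)) {
    if (!(m %in% cls)) {
      stop(sprintf("unknown class number %s (have 1..%d)", m, length(cls)),
           call. = FALSE)
    }
    names(cls)[match(m, cls)]
  } else {
    if (!(m %in% names(cls))) {
      stop(sprintf("unknown class label '%s'", m), call. = FALSE)
    }
    as.character(m)
  }
}

#' Read a similarity matrix from delimited text
#'
#' The file must carry ligand identifiers in the first row and first
#' column. Class labels come either from a two-column annotation file
#' (`ligand_id<sep>class_label`) or an `annotations` data frame.
#'
#' @param path path to a comma- or tab-delimited matrix file.
#' @param annotations either a path to a two-column annotation file or a
#'   data frame with columns `ligand_id` and `class_label`.
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @param score_range entry bounds, see [similarity_matrix()].
#' @return A [similarity_matrix()].
#' @export
read_similarity_matrix <- function(path, annotations, sep = NULL,
                                   score_range = c(0, 2)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          row.names = 1L, stringsAsFactors = FALSE,
                          comment.char = "")
  values <- as.matrix(df)
  if (!is.numeric(values)) {
    bad <- which(!vapply(df, is.numeric, logical(1)))[1]
    stop(sprintf("non-numeric cell(s) in column '%s' of %s",
                 colnames(df)[bad], path), call. = FALSE)
  }
  ann <- read_class_annotation(annotations)
  lookup <- function(ids) {
    idx <- match(ids, ann$ligand_id)
    if (anyNA(idx)) {
      stop(sprintf("ligand '%s' missing from the class annotation",
                   ids[which(is.na(idx))[1]]), call. = FALSE)
    }
    ann$class_label[idx]
  }
  similarity_matrix(values, rownames(values), colnames(values),
                    lookup(rownames(values)), lookup(colnames(values)),
                    score_range = score_range)
}

#' Read (or pass through) a ligand-to-class annotation table
#'
#' @param annotations path to a delimited two-column file
#'   (`ligand_id`, `class_label`; header optional) or a data frame with
#'   those columns.
#' @return Data frame with character columns `ligand_id` and `class_label`.
#' @export
read_class_annotation <- function(annotations) {
  if (is.data.frame(annotations)) {
    if (!all(c("ligand_id", "class_label") %in% names(annotations))) {
      stop("annotation data frame needs columns 'ligand_id' and 'class_label'",
           call. = FALSE)
    }
    ann <- annotations[c("ligand_id", "class_label")]
  } else {
    header <- readLines(annotations, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
    has_header <- grepl("ligand_id", header, fixed = TRUE)
    ann <- utils::read.table(annotations, sep = sep, header = has_header,
                             stringsAsFactors = FALSE, comment.char = "")
    if (!has_header) names(ann)[1:2] <- c("ligand_id", "class_label")
  }
  ann$ligand_id <- as.character(ann$ligand_id)
  ann$class_label <- as.character(ann$class_label)
  if (anyDuplicated(ann$ligand_id)) {
    dup <- ann$ligand_id[duplicated(ann$ligand_id)][1]
    stop(sprintf("ligand '%s' is annotated more than once", dup),
         call. = FALSE)
  }
  ann
}

#' Write a similarity matrix (and its annotation) to delimited text
#'
#' Entries are rendered with a fixed number of decimal places so that a
#' write/read round trip reproduces the values to the printed precision.
#'
#' @param x a `similarity_matrix`.
#' @param path output path for the matrix.
#' @param annotations_path optional path for a two-column annotation file
#'   covering all row and column ligands.
#' @param sep field separator (`","` or `"\t"`).
#' @param digits decimal places on write (default 6).
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(x, path, annotations_path = NULL,
                                    sep = ",", digits = 6) {
  fmt <- formatC(unclass(x), format = "f", digits = digits)
  out <- cbind(id = rownames(x), fmt)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = c("id", colnames(x)))
  if (!is.null(annotations_path)) {
    ann <- unique(data.frame(
      ligand_id = c(rownames(x), colnames(x)),
      class_label = c(attr(x, "row_class"), attr(x, "col_class")),
      stringsAsFactors = FALSE))
    utils::write.table(ann, annotations_path, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' Extract the intra-class block of a similarity matrix
#'
#' Restricts the matrix to rows and columns annotated with class `m`
#' (Tanimoto matrix with equal class indices). By default the diagonal
#' self-pairs are dropped from the retained entries: a conformer overlaid
#' on itself scores at the range maximum and would distort the fitted
#' class distribution.
#'
#' @param x a `similarity_matrix`.
#' @param m class label or 1-based class number.
#' @param include_diagonal keep self-pairs? Default `FALSE`.
#' @return A `similarity_matrix` restricted to class `m`, with attribute
#'   `include_diagonal`; use [intra_class_values()] to obtain the retained
#'   entries as a vector.
#' @export
class_block <- function(x, m, include_diagonal = FALSE) {
  lab <- resolve_class(x, m)
  ri <- which(attr(x, "row_class") == lab)
  ci <- which(attr(x, "col_class") == lab)
  if (length(ri) == 0L || length(ci) == 0L) {
    stop(sprintf("class '%s' has no members", lab), call. = FALSE)
  }
  if (!include_diagonal && (length(ri) < 2L || length(ci) < 2L)) {
    stop(sprintf(
      "class '%s' has fewer than 2 members; no off-diagonal pairs remain",
      lab), call. = FALSE)
  }
  blk <- similarity_matrix(unclass(x)[ri, ci, drop = FALSE],
                           rownames(x)[ri], colnames(x)[ci],
                           attr(x, "row_class")[ri], attr(x, "col_class")[ci],
                           score_range = attr(x, "score_range"))
  attr(blk, "row_index") <- ri
  attr(blk, "col_index") <- ci
  attr(blk, "include_diagonal") <- include_diagonal
  blk
}

#' Retained entries of an intra-class block as a vector
#'
#' @param block result of [class_block()].
#' @return Numeric vector of similarity values; self-pairs (same original
#'   row and column position) are omitted unless the block was built with
#'   `include_diagonal = TRUE`.
#' @export
intra_class_values <- function(block) {
  v <- unclass(block)
  if (isTRUE(attr(block, "include_diagonal"))) return(as.vector(v))
  ri <- attr(block, "row_index")
  ci <- attr(block, "col_index")
  keep <- outer(ri, ci, `!=`)
  as.vector(v[keep])
}

#' Extract a query's similarity vector against one target class
#'
#' Returns the column of similarities between the query conformer (a
#' column of the matrix) and all ligands of class `n`. When the query
#' itself belongs to class `n`, its self-pair is excluded.
#'
#' @param x a `similarity_matrix`.
#' @param query query column identifier, or a 1-based column index (needed
#'   when identifiers are duplicated across conformers).
#' @param n target class label or number.
#' @return An object of class `query_vector`: numeric values with
#'   attributes `query_id`, `query_class`, `target_class` and
#'   `score_range`.
#' @export
extract_query_vector <- function(x, query, n) {
  if (is.numeric(query)) {
    j <- as.integer(query)
    if (j < 1L || j > ncol(x)) stop("query column index out of range",
                                    call. = FALSE)
  } else {
    j <- which(colnames(x) == query)
    if (length(j) == 0L) {
      stop(sprintf("unknown query id '%s'", query), call. = FALSE)
    }
    if (length(j) > 1L) {
      stop(sprintf(
        "query id '%s' matches %d columns; pass a column index instead",
        query, length(j)), call. = FALSE)
    }
  }
  lab <- resolve_class(x, n)
  ri <- which(attr(x, "row_class") == lab)
  if (length(ri) == 0L) {
    stop(sprintf("class '%s' has no members", lab), call. = FALSE)
  }
  # self-pair: the row with the same original position as the query column,
  # only meaningful for square matrices over one conformer set
  if (attr(x, "col_class")[j] == lab && nrow(x) == ncol(x)) {
    ri <- setdiff(ri, j)
  }
  structure(unclass(x)[ri, j],
            names = rownames(x)[ri],
            query_id = colnames(x)[j],
            query_class = attr(x, "col_class")[j],
            target_class = lab,
            score_range = attr(x, "score_range"),
            class = "query_vector")
}

#' @export
print.query_vector <- function(x, ...) {
  cat(sprintf("query_vector: '%s' (class %s) vs class %s, n = %d\n",
              attr(x, "query_id"), attr(x, "query_class"),
              attr(x, "target_class"), length(x)))
  cat(sprintf("  mean %.4f, sd %.4f\n", mean(x), stats::sd(x)))
  invisible(x)
}

#' Average a square similarity matrix with its transpose
#'
#' 3D overlays are direction-dependent, so the raw matrix is asymmetric;
#' this optional step replaces each pair of entries (A,B) and (B,A) by
#' their mean.
#'
#' @param x a square `similarity_matrix` with matching row/column ids.
#' @return A symmetric `similarity_matrix`.
#' @export
symmetrize <- function(x) {
  if (nrow(x) != ncol(x) || !identical(rownames(x), colnames(x))) {
    stop("symmetrize() needs a square matrix over one conformer set",
         call. = FALSE)
  }
  similarity_matrix((unclass(x) + t(unclass(x))) / 2,
                    rownames(x), colnames(x),
                    attr(x, "row_class"), attr(x, "col_class"),
                    score_range = attr(x, "score_range"))
}
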