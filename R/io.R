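#' Read a gene expression matrix from delimited text
#'
#' Expects genes as rows (first column gene identifiers) and samples as
#' columns (header row of sample identifiers), values being normalized
#' expression such as RPKM. Duplicate gene identifiers are rejected;
#' zero-variance genes (uninformative for correlation networks) are dropped
#' with a message reporting how many.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator, `"\t"` (default) or `","`.
#' @param drop_zero_variance Drop constant gene rows instead of erroring.
#' @return A numeric matrix, genes x samples, with gene ids as rownames and
#'   sample ids as colnames.
#' @export
read_expression <- function(path, sep = "\t", drop_zero_variance = TRUE) {
  if (!file.exists(path)) stop_gmcnet("expression file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2) stop_gmcnet("expression file needs a gene-id column plus samples")
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop_gmcnet("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  vals <- df[, -1, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad))
    stop_gmcnet("non-numeric expression column(s): ",
                paste(names(vals)[bad], collapse = ", "))
  x <- as.matrix(vals)
  rownames(x) <- ids
  if (anyNA(x)) stop_gmcnet("missing values in expression matrix")
  validate_expression(x, drop_zero_variance = drop_zero_variance)
}

#' Validate an expression matrix
#'
#' @param x Numeric genes x samples matrix with row and column names.
#' @param drop_zero_variance Drop constant gene rows (with a message) rather
#'   than raising an error naming them.
#' @return The validated (possibly reduced) matrix.
#' @export
validate_expression <- function(x, drop_zero_variance = FALSE) {
  if (!is.matrix(x) || !is.numeric(x)) stop_gmcnet("expression must be a numeric matrix")
  if (nrow(x) < 2) stop_gmcnet("need at least 2 genes")
  if (ncol(x) < 3) stop_gmcnet("need at least 3 samples for Pearson correlation")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop_gmcnet("expression matrix must carry gene and sample identifiers")
  if (anyDuplicated(rownames(x))) stop_gmcnet("duplicate gene identifiers")
  if (anyNA(x)) stop_gmcnet("missing values in expression matrix")
  v <- row_vars(x)
  if (any(v == 0)) {
    if (drop_zero_variance) {
      message("dropping ", sum(v == 0), " zero-variance gene(s)")
      x <- x[v > 0, , drop = FALSE]
      if (nrow(x) < 2) stop_gmcnet("fewer than 2 genes left after dropping constants")
    } else {
      stop_gmcnet("zero-variance gene row(s): ",
                  paste(utils::head(rownames(x)[v == 0], 5), collapse = ", "))
    }
  }
  x
}

#' Read a sample x trait table
#'
#' First column sample identifiers, header row of trait names. Sample order
#' must match the expression matrix it will be used with; `align_traits()`
#' reorders and checks.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator.
#' @return Numeric samples x traits matrix with sample ids as rownames.
#' @export
read_traits <- function(path, sep = "\t") {
  if (!file.exists(path)) stop_gmcnet("trait file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop_gmcnet("duplicate sample id(s) in trait table")
  y <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(y)) stop_gmcnet("trait columns must be numeric")
  rownames(y) <- ids
  if (anyNA(y)) stop_gmcnet("missing values in trait table")
  y
}

#' Align a trait table to an expression matrix's samples
#' @param traits samples x traits matrix.
#' @param expr genes x samples expression matrix.
#' @return traits reordered to `colnames(expr)`.
#' @export
align_traits <- function(traits, expr) {
  missing <- setdiff(colnames(expr), rownames(traits))
  if (length(missing))
    stop_gmcnet("trait table lacks sample(s): ", paste(missing, collapse = ", "))
  traits <- traits[colnames(expr), , drop = FALSE]
  v <- apply(traits, 2, stats::var)
  if (any(v == 0))
    stop_gmcnet("constant trait column(s): ",
                paste(colnames(traits)[v == 0], collapse = ", "))
  traits
}

#' Write a labelled numeric matrix as TSV
#' @param x Matrix with rownames.
#' @param path Output path.
#' @param id_col Name for the identifier column.
#' @export
write_matrix_tsv <- function(x, path, id_col = "id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
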