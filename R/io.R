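#' Read a genes-by-samples expression table
#'
#' Reads a delimited text file whose first column holds gene identifiers
#' and whose header row holds sample identifiers. The delimiter (tab or
#' comma) is auto-detected from the header line. Orientation is fixed as
#' genes-in-rows; a transposed file is the caller's responsibility, since
#' gene and sample counts cannot be disambiguated reliably.
#'
#' Any per-sample monotone normalization is acceptable: downstream
#' enrichment scoring is rank-based within each sample.
#'
#' Rows with missing values are handled per `policy`: `"drop"` removes
#' them with a message, `"reject"` errors. Duplicate gene rows (multiple
#' probes mapping to one identifier) are collapsed by keeping the row with
#' the highest mean expression — a deterministic microarray convention;
#' average-collapse is a reasonable alternative not offered here.
#'
#' @param path Path to a TSV/CSV file.
#' @param policy Missing-value policy: `"drop"` (default) or `"reject"`.
#' @return A numeric matrix, genes x samples, with unique rownames and
#'   colnames.
#' @export
read_expression_table <- function(path, policy = c("drop", "reject")) {
  policy <- match.arg(policy)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty expression file: ", path, call. = FALSE)
  delim <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
               lengths(regmatches(header, gregexpr(",", header, fixed = TRUE)))) {
    "\t"
  } else {
    ","
  }
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                          progress = FALSE, show_col_types = FALSE)
  if (ncol(df) < 2L) stop("expression table needs >= 1 sample column", call. = FALSE)
  genes <- as.character(df[[1L]])
  vals <- df[-1L]
  numeric_ok <- purrr::map_lgl(vals, is.numeric)
  if (!all(numeric_ok)) {
    if (policy == "reject") {
      stop("non-numeric expression values in column(s): ",
           paste(names(vals)[!numeric_ok], collapse = ", "), call. = FALSE)
    }
    vals[!numeric_ok] <- purrr::map(vals[!numeric_ok],
                                    function(x) suppressWarnings(as.numeric(x)))
  }
  mat <- as.matrix(as.data.frame(vals))
  rownames(mat) <- genes
  storage.mode(mat) <- "double"

  incomplete <- !stats::complete.cases(mat)
  if (any(incomplete)) {
    if (policy == "reject") {
      stop(sum(incomplete), " gene row(s) with missing values under 'reject' policy",
           call. = FALSE)
    }
    message("read_expression_table: dropped ", sum(incomplete),
            " row(s) with missing values")
    mat <- mat[!incomplete, , drop = FALSE]
  }
  if (nrow(mat) == 0L) stop("no complete gene rows in ", path, call. = FALSE)
  mat <- collapse_duplicate_rows(mat)
  validate_expression_matrix(mat)
}

collapse_duplicate_rows <- function(mat) {
  ids <- rownames(mat)
  if (!anyDuplicated(ids)) return(mat)
  dup <- unique(ids[duplicated(ids)])
  warning("collapsing ", length(dup), " duplicated gene identifier(s) ",
          "by keeping the row with highest mean expression",
          call. = FALSE)
  means <- rowMeans(mat)
  # stable: among equal-mean duplicates the first row wins
  keep <- !logical(nrow(mat))
  for (g in dup) {
    rows <- which(ids == g)
    keep[rows] <- FALSE
    keep[rows[which.max(means[rows])]] <- TRUE
  }
  mat[keep, , drop = FALSE]
}

#' Coerce to a genes-by-samples expression matrix
#'
#' Analysis functions accept either a numeric matrix with gene rownames or
#' a data frame whose first column holds gene identifiers (the shape
#' produced by reading a delimited expression file into a tibble). This
#' helper normalizes both to the internal matrix representation.
#'
#' @param x Numeric matrix (rownames = genes) or data frame (first column
#'   = gene identifiers, remaining columns numeric).
#' @return Validated numeric matrix, genes x samples.
#' @export
as_expression_matrix <- function(x) {
  if (is.matrix(x)) return(validate_expression_matrix(x))
  if (is.data.frame(x)) {
    if (ncol(x) < 2L) stop("data frame needs a gene column plus >= 1 sample", call. = FALSE)
    mat <- as.matrix(x[-1L])
    rownames(mat) <- as.character(x[[1L]])
    storage.mode(mat) <- "double"
    return(validate_expression_matrix(mat))
  }
  stop("cannot interpret a ", class(x)[1L], " as an expression matrix", call. = FALSE)
}

validate_expression_matrix <- function(mat) {
  if (!is.numeric(mat)) stop("expression values must be numeric", call. = FALSE)
  if (nrow(mat) < 1L || ncol(mat) < 1L) {
    stop("expression matrix needs >= 1 gene and >= 1 sample", call. = FALSE)
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("expression matrix must carry gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(mat))) {
    stop("duplicate gene identifiers in expression matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(mat))) {
    stop("duplicate sample identifiers in expression matrix", call. = FALSE)
  }
  if (anyNA(mat)) stop("expression matrix contains missing values", call. = FALSE)
  mat
}

#' Write an expression matrix as tab-delimited text
#'
#' @param mat Genes x samples numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(mat, path) {
  mat <- as_expression_matrix(mat)
  df <- tibble::as_tibble(mat, rownames = "gene")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
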