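#' Gene-by-sample count matrix container
#'
#' A \code{count_matrix} is a light container (in the spirit of edgeR's
#' \code{DGEList}) holding a genes x samples matrix of non-negative integer
#' counts together with per-sample library sizes (column sums).  Gene and
#' sample identifiers are the row and column names of the matrix and must be
#' unique.
#'
#' @param counts numeric matrix of non-negative integral counts with unique
#'   row names (gene identifiers) and column names (sample identifiers).
#'   Missing dimnames are filled in with \code{gene1..} / \code{sample1..}.
#' @return An object of class \code{"count_matrix"}: a list with elements
#'   \code{counts} (integer-valued matrix), \code{gene_ids},
#'   \code{sample_ids} and \code{lib_sizes} (named column sums).
#' @examples
#' cm <- count_matrix(matrix(c(1, 3, 2, 4), 2, 2))
#' lib_sizes(cm)
#' @export
count_matrix <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) && nrow(counts) > 0)
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(colnames(counts)) && ncol(counts) > 0)
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  validate_counts(counts)
  storage.mode(counts) <- "double"   # counts can exceed .Machine$integer.max in sums
  obj <- list(
    counts = counts,
    gene_ids = rownames(counts),
    sample_ids = colnames(counts),
    lib_sizes = colSums(counts)
  )
  class(obj) <- "count_matrix"
  obj
}

validate_counts <- function(counts) {
  if (nrow(counts) > 0 && ncol(counts) > 0) {
    bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
                 arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf(
        "counts must be non-negative integers; offending cell: gene '%s', sample '%s' (value %s)",
        rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
        format(counts[bad[1, , drop = FALSE]])), call. = FALSE)
    }
  }
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "),
         call. = FALSE)
  invisible(counts)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              length(x$gene_ids), length(x$sample_ids)))
  if (length(x$sample_ids)) {
    cat("library sizes:\n")
    print(x$lib_sizes)
  }
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Extract counts or library sizes
#'
#' @param x a \code{count_matrix}.
#' @return \code{counts()} returns the numeric matrix; \code{lib_sizes()} the
#'   named vector of column sums (recomputed, so always consistent with the
#'   matrix).
#' @export
counts <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  x$counts
}

#' @rdname counts
#' @export
lib_sizes <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  colSums(x$counts)
}

#' Subset a count matrix
#'
#' Subsetting by genes (rows) and/or samples (columns) returns a new
#' \code{count_matrix} with library sizes recomputed from the retained genes.
#'
#' @param x a \code{count_matrix}.
#' @param i,j gene and sample indices (numeric, logical or character).
#' @param ... ignored.
#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  m <- x$counts
  if (missing(i)) i <- seq_len(nrow(m))
  if (missing(j)) j <- seq_len(ncol(m))
  count_matrix(m[i, j, drop = FALSE])
}

#' Read a tab-separated count matrix
#'
#' Expects a plain TSV: header row of sample identifiers, first column of
#' gene identifiers (the first header cell is ignored), body of non-negative
#' integers.  Comment lines starting with \code{#} are skipped.  All-zero
#' genes are retained; filtering is an explicit downstream step.
#'
#' @param path path to a TSV file.
#' @return a validated \code{count_matrix} preserving input row/column order.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = NA)
  if (ncol(df) < 1) stop("count file has no columns: ", path, call. = FALSE)
  ids <- as.character(df[[1]])
  if (nrow(df) == 0) {
    m <- matrix(numeric(0), 0, ncol(df) - 1,
                dimnames = list(NULL, colnames(df)[-1]))
    return(count_matrix(m))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    # locate first non-numeric cell for the error message
    num <- suppressWarnings(apply(df[, -1, drop = FALSE], 2,
                                  function(col) as.numeric(as.character(col))))
    num <- matrix(num, nrow = nrow(df))
    bad <- which(is.na(num), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-numeric count in gene '%s', sample '%s'",
                   ids[bad[1, 1]], colnames(df)[-1][bad[1, 2]]), call. = FALSE)
    m <- num
  }
  rownames(m) <- ids
  count_matrix(m)
}

#' Write a count matrix as TSV
#'
#' Inverse of \code{\link{read_counts}}: plain UTF-8 TSV, no quoting, first
#' column \code{gene_id}.  A matrix with zero genes yields a header-only file.
#'
#' @param cm a \code{count_matrix}.
#' @param path output path.
#' @export
write_counts <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  m <- cm$counts
  header <- paste(c("gene_id", colnames(m)), collapse = "\t")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(m) > 0) {
    body <- cbind(rownames(m),
                  matrix(format(m, scientific = FALSE, trim = TRUE), nrow = nrow(m)))
    writeLines(apply(body, 1, paste, collapse = "\t"), con)
  }
  invisible(NULL)
}

#' Read a sample sheet
#'
#' A sample sheet is a TSV with columns \code{sample_id}, \code{experiment},
#' \code{condition} and optionally \code{include} (logical; defaults to
#' \code{TRUE} when absent), assigning each sequencing sample to an
#' experiment and biological condition.
#'
#' @param path path to the TSV.
#' @return a data.frame with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  required <- c("sample_id", "experiment", "condition")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("sample sheet is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  if (is.null(df$include)) df$include <- TRUE
  df$include <- as.logical(df$include)
  df
}

#' Write a results table with a provenance header
#'
#' Writes any data.frame as TSV preceded by a single \code{#} comment line
#' recording the package version and the parameters used to produce it.
#'
#' @param df a data.frame.
#' @param path output path.
#' @param params named list of parameters (seeds, thresholds, ...) recorded
#'   in the header comment.
#' @export
write_result_table <- function(df, path, params = list()) {
  ver <- as.character(utils::packageVersion("countgof"))
  meta <- if (length(params))
    paste(names(params), vapply(params, function(p) paste(format(p), collapse = ","),
                                character(1)), sep = "=", collapse = "; ")
  else ""
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# countgof %s%s", ver,
                     if (nzchar(meta)) paste0("; ", meta) else ""), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
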