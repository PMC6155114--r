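#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor pchisq pt phyper p.adjust qchisq rnorm runif
#'   smooth.spline predict wilcox.test quantile setNames
#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-stage sub-seed; kept well inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 1000L + as.double(offset)) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_symmetric <- function(m, tol = 1e-8, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stopf("%s must be square", what)
  if (max(abs(m - t(m))) > tol)
    stopf("%s must be symmetric (max asymmetry %.3g)", what, max(abs(m - t(m))))
  invisible(TRUE)
}

#' Write a matrix as an id-keyed TSV
#'
#' Tab-separated, UTF-8, `.` decimal, no quoting; first column holds the row
#' ids, header row holds the column ids.
#'
#' @param m numeric matrix with row and column names.
#' @param path output file path.
#' @param id_name header for the id column.
#' @export
write_tsv_matrix <- function(m, path, id_name = "id") {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("'%s': expected an id column plus data columns", path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(ids))
    stopf("duplicate row id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rownames(m) <- ids
  storage.mode(m) <- "double"
  m
}
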