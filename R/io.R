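#' Read a delimited numeric table
#'
#' Reads a CSV/TSV file with a single header row into a validated numeric
#' matrix. Non-numeric cells are reported with their row and column location.
#'
#' @param path File path.
#' @param delimiter Field separator; `NULL` (default) infers comma vs tab
#'   from the header line.
#' @return Numeric matrix with named columns.
#' @export
read_data_matrix <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delimiter)) {
    header <- readLines(path, n = 1L)
    delimiter <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      suppressWarnings(conv <- as.numeric(df[[j]]))
      bad <- which(is.na(conv) & !is.na(df[[j]]))
      if (length(bad)) {
        stop("non-numeric cell at row ", bad[1L], ", column '",
             names(df)[j], "' in ", path, call. = FALSE)
      }
      df[[j]] <- conv
    }
  }
  as_data_matrix(as.matrix(df))
}

#' Split an embedding table into coordinates and dependent variables
#'
#' Embedding tables carry manifold coordinates in columns named `eta1`,
#' `eta2`, ... and dependent variables in the remaining named columns.
#'
#' @param x Numeric matrix as read by [read_data_matrix()].
#' @param vars Optional character vector naming the dependent-variable
#'   columns; by default every non-`eta*` column.
#' @return List with `eta` (`"manifold_params"`) and `phi` (matrix).
#' @export
split_embedding_table <- function(x, vars = NULL) {
  x <- as_data_matrix(x)
  eta_cols <- grep("^eta[0-9]+$", colnames(x), value = TRUE)
  if (!length(eta_cols)) {
    stop("no eta1..etaq coordinate columns found in the table", call. = FALSE)
  }
  if (is.null(vars)) vars <- setdiff(colnames(x), eta_cols)
  missing <- setdiff(vars, colnames(x))
  if (length(missing)) {
    stop("dependent variable column(s) not found: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!length(vars)) stop("no dependent-variable columns found", call. = FALSE)
  list(eta = manifold_params(x[, eta_cols, drop = FALSE]),
       phi = x[, vars, drop = FALSE])
}
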