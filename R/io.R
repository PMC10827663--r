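#' Read and write dense numeric matrices
#'
#' Per-subject connectivity and time-series matrices are stored as plain
#' delimited text (`.tsv`, `.csv`, `.txt`; tab, comma or whitespace
#' separated, no header). Values round-trip at full double precision
#' (`%.17g`).
#'
#' @param path file path; the extension selects the delimiter.
#' @param expected_dim optional `c(nrow, ncol)`; a mismatch raises a
#'   dimension error.
#' @return `read_matrix` returns a numeric matrix; `write_matrix` returns
#'   `path` invisibly.
#' @export
read_matrix <- function(path, expected_dim = NULL) {
  sep <- matrix_sep(path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  split_re <- if (sep == "") "\\s+" else sep
  rows <- strsplit(trimws(lines), split_re)
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L)
    stop("ragged matrix file: rows have differing column counts in ", path,
         call. = FALSE)
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    bad_row <- (bad - 1) %/% ncols[1] + 1
    bad_col <- (bad - 1) %% ncols[1] + 1
    stop(sprintf("non-numeric cell at row %d, column %d of %s",
                 bad_row, bad_col, path),
         call. = FALSE)
  }
  m <- matrix(vals, nrow = length(rows), ncol = ncols[1], byrow = TRUE)
  if (!is.null(expected_dim) && !all(dim(m) == expected_dim))
    stop(sprintf("matrix in %s is %d x %d, expected %d x %d", path,
                 nrow(m), ncol(m), expected_dim[1], expected_dim[2]),
         call. = FALSE)
  m
}

#' @rdname read_matrix
#' @param m a numeric matrix.
#' @export
write_matrix <- function(m, path) {
  stopifnot(is.matrix(m), is.numeric(m))
  sep <- matrix_sep(path)
  if (sep == "") sep <- " "
  lines <- apply(m, 1, function(row)
    paste(sprintf("%.17g", row), collapse = sep))
  writeLines(lines, path)
  invisible(path)
}

matrix_sep <- function(path) {
  switch(tolower(tools::file_ext(path)),
         csv = ",", tsv = "\t", "")
}
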