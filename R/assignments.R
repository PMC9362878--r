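#' Cell-by-resolution assignment matrix
#'
#' Container for integer cluster assignments of `n` cells at each value of a
#' strictly increasing grid of clustering resolution parameters. This is the
#' first of the two required inputs of the cluster-flow workflow; it is
#' agnostic to the clustering method that produced it.
#'
#' The original header strings of the resolution columns are retained in
#' `res_labels` so that node identifiers (`"<resolution>_<label>"`) are
#' formatted with the user's own precision rather than a re-rendered float.
#'
#' @param cell_ids Character vector of unique cell identifiers.
#' @param labels Integer matrix, cells x resolutions, of non-negative cluster
#'   labels. Column order must follow `resolutions`.
#' @param resolutions Strictly increasing numeric vector of resolution
#'   parameter values, one per column of `labels`.
#' @param res_labels Optional character rendering of `resolutions` used in
#'   node identifiers; defaults to `format(resolutions)` trimmed.
#'
#' @return An object of class `cell_assignments`: a list with elements
#'   `cell_ids`, `resolutions`, `res_labels` and `labels` (dimnamed integer
#'   matrix).
#' @export
cell_assignments <- function(cell_ids, labels, resolutions,
                             res_labels = NULL) {
  cell_ids <- as.character(cell_ids)
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  resolutions <- as.numeric(resolutions)
  if (is.null(res_labels)) {
    res_labels <- trimws(format(resolutions, trim = TRUE, scientific = FALSE))
  }
  res_labels <- as.character(res_labels)

  if (anyDuplicated(cell_ids)) {
    stop("duplicate cell ids: ",
         paste(utils::head(unique(cell_ids[duplicated(cell_ids)]), 5),
               collapse = ", "))
  }
  if (nrow(labels) != length(cell_ids)) {
    stop("labels has ", nrow(labels), " rows but there are ",
         length(cell_ids), " cell ids")
  }
  if (ncol(labels) != length(resolutions)) {
    stop("labels has ", ncol(labels), " columns but there are ",
         length(resolutions), " resolutions")
  }
  if (length(resolutions) < 1L) stop("at least one resolution is required")
  if (length(res_labels) != length(resolutions)) {
    stop("res_labels length does not match resolutions")
  }
  if (anyNA(resolutions)) stop("resolutions must be numeric and non-missing")
  if (length(resolutions) > 1L && any(diff(resolutions) <= 0)) {
    stop("resolutions must be strictly increasing")
  }
  if (anyNA(labels)) {
    bad <- which(is.na(labels), arr.ind = TRUE)[1L, ]
    stop("missing cluster assignment for cell '", cell_ids[bad[1L]],
         "' at resolution ", res_labels[bad[2L]])
  }
  if (any(labels < 0L)) {
    bad <- which(labels < 0L, arr.ind = TRUE)[1L, ]
    stop("negative cluster label for cell '", cell_ids[bad[1L]],
         "' at resolution ", res_labels[bad[2L]])
  }
  dimnames(labels) <- list(cell_ids, res_labels)
  structure(
    list(cell_ids = cell_ids, resolutions = resolutions,
         res_labels = res_labels, labels = labels),
    class = "cell_assignments"
  )
}

#' @export
print.cell_assignments <- function(x, ...) {
  cat("<cell_assignments> ", length(x$cell_ids), " cells x ",
      length(x$resolutions), " resolutions [",
      paste(x$res_labels, collapse = ", "), "]\n", sep = "")
  k <- apply(x$labels, 2L, function(v) length(unique(v)))
  cat("  clusters per resolution: ", paste(k, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of clusters observed at each resolution
#' @param assign A `cell_assignments` object.
#' @return Named integer vector, one entry per resolution column.
#' @export
n_clusters <- function(assign) {
  stopifnot(inherits(assign, "cell_assignments"))
  vapply(seq_along(assign$resolutions), function(j) {
    length(unique(assign$labels[, j]))
  }, integer(1L), USE.NAMES = FALSE) |>
    stats::setNames(assign$res_labels)
}

guess_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
}

#' Read a cell-by-resolution assignment matrix from delimited text
#'
#' The first column holds cell identifiers; every remaining column header must
#' parse as a numeric resolution value. Columns are reordered to ascending
#' resolution if needed. Comma-separated by default; tab is auto-detected from
#' a `.tsv` extension.
#'
#' @param path Path to a CSV/TSV file with a mandatory header row.
#' @param sep Field separator; `NULL` (default) auto-detects from extension.
#' @return A [cell_assignments] object.
#' @export
read_assignments <- function(path, sep = NULL) {
  sep <- guess_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("assignment file needs a cell id column plus at ",
                          "least one resolution column")
  res_labels <- colnames(df)[-1L]
  resolutions <- suppressWarnings(as.numeric(res_labels))
  if (anyNA(resolutions)) {
    stop("non-numeric resolution header(s): ",
         paste(res_labels[is.na(resolutions)], collapse = ", "))
  }
  cell_ids <- df[[1L]]
  lab <- as.matrix(df[, -1L, drop = FALSE])
  blank <- which(is.na(lab) | trimws(lab) == "", arr.ind = TRUE)
  if (nrow(blank) > 0L) {
    stop("missing cluster assignment for cell '", cell_ids[blank[1L, 1L]],
         "' at resolution ", res_labels[blank[1L, 2L]])
  }
  num <- suppressWarnings(matrix(as.numeric(lab), nrow = nrow(lab)))
  if (anyNA(num) || any(num != floor(num))) {
    bad <- which(is.na(num) | num != floor(num), arr.ind = TRUE)[1L, ]
    stop("non-integer cluster label '", lab[bad[1L], bad[2L]],
         "' for cell '", cell_ids[bad[1L]], "' at resolution ",
         res_labels[bad[2L]])
  }
  ord <- order(resolutions)
  cell_assignments(cell_ids, num[, ord, drop = FALSE], resolutions[ord],
                   res_labels[ord])
}

#' Write a cell-by-resolution assignment matrix to delimited text
#'
#' Inverse of [read_assignments()]; the written file round-trips identically.
#'
#' @param assign A [cell_assignments] object.
#' @param path Output path; `.tsv` extension selects tab separation.
#' @param sep Field separator override.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assign, path, sep = NULL) {
  stopifnot(inherits(assign, "cell_assignments"))
  sep <- guess_sep(path, sep)
  df <- data.frame(cell_id = assign$cell_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_along(assign$res_labels)) {
    df[[assign$res_labels[j]]] <- assign$labels[, j]
  }
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
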