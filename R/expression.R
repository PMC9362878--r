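#' Read a cell-by-gene expression matrix
#'
#' Accepts either delimited text (rows = cells, columns = genes, header row of
#' gene ids, first column of cell ids) or MatrixMarket triplet format with
#' plain-text row/column sidecar files. Values are expected to be
#' library-normalised already (log or linear); no normalisation is applied
#' here. Negative values are rejected.
#'
#' MatrixMarket files conventionally store genes x cells; they are transposed
#' on load so the in-memory orientation is always cells x genes. Set
#' `transpose` to override either format's assumed orientation.
#'
#' @param path Path to a `.csv`/`.tsv` file or a `.mtx` MatrixMarket file.
#' @param features,barcodes For MTX input: paths to the gene-id and cell-id
#'   sidecar files (one id per line; for multi-column sidecars the first
#'   column is used). Default to `features.tsv`/`genes.tsv` and
#'   `barcodes.tsv` next to `path`.
#' @param transpose If `TRUE`, swap the assumed cell/gene orientation.
#' @param sep Field separator for delimited input; auto-detected by default.
#' @return A cells x genes matrix (dense `matrix` for delimited input,
#'   `dgCMatrix` for MTX) with cell ids as rownames and gene ids as colnames.
#' @export
read_expression <- function(path, features = NULL, barcodes = NULL,
                            transpose = FALSE, sep = NULL) {
  if (tolower(tools::file_ext(path)) == "mtx") {
    m <- Matrix::readMM(path)
    if (is.null(features)) {
      for (cand in c("features.tsv", "genes.tsv", "features.txt")) {
        f <- file.path(dirname(path), cand)
        if (file.exists(f)) { features <- f; break }
      }
    }
    if (is.null(barcodes)) {
      for (cand in c("barcodes.tsv", "barcodes.txt")) {
        f <- file.path(dirname(path), cand)
        if (file.exists(f)) { barcodes <- f; break }
      }
    }
    if (is.null(features) || is.null(barcodes)) {
      stop("MTX input needs 'features' and 'barcodes' sidecar files")
    }
    gene_ids <- read_id_column(features)
    cell_ids <- read_id_column(barcodes)
    # on-disk convention: genes x cells
    if (nrow(m) != length(gene_ids) || ncol(m) != length(cell_ids)) {
      stop("MTX dimensions (", nrow(m), " x ", ncol(m), ") do not match ",
           "sidecars (", length(gene_ids), " features, ",
           length(cell_ids), " barcodes)")
    }
    dimnames(m) <- list(gene_ids, cell_ids)
    m <- Matrix::t(m)
    if (transpose) m <- Matrix::t(m)
    m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
    if (any(m@x < 0)) stop("expression values must be non-negative")
  } else {
    sep <- guess_sep(path, sep)
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                            check.names = FALSE, comment.char = "",
                            stringsAsFactors = FALSE)
    m <- as.matrix(df)
    if (!is.numeric(m)) stop("non-numeric expression values in ", path)
    if (transpose) m <- t(m)
    if (anyNA(m)) stop("missing expression values in ", path)
    if (any(m < 0)) stop("expression values must be non-negative")
  }
  validate_expression(m)
  m
}

read_id_column <- function(path) {
  x <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "",
                         quote = "")
  as.character(x[[1L]])
}

validate_expression <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix must carry cell ids (rownames) and gene ids ",
         "(colnames)")
  }
  if (anyDuplicated(rownames(m))) stop("duplicate cell ids in expression")
  if (anyDuplicated(colnames(m))) stop("duplicate gene ids in expression")
  invisible(m)
}

#' Write a cell-by-gene expression matrix
#'
#' Delimited output (cells x genes, header row) for `.csv`/`.tsv` paths, or
#' MatrixMarket triplet plus `features.tsv`/`barcodes.tsv` sidecars (written
#' next to the `.mtx` path, genes x cells on disk) for `.mtx` paths.
#'
#' @param m Cells x genes matrix with dimnames.
#' @param path Output path; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  validate_expression(m)
  if (tolower(tools::file_ext(path)) == "mtx") {
    Matrix::writeMM(methods::as(Matrix::t(Matrix::Matrix(m, sparse = TRUE)),
                                "CsparseMatrix"), path)
    writeLines(colnames(m), file.path(dirname(path), "features.tsv"))
    writeLines(rownames(m), file.path(dirname(path), "barcodes.tsv"))
  } else {
    sep <- guess_sep(path)
    df <- data.frame(cell_id = rownames(m), as.matrix(m),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a cell embedding (e.g. PCA scores) from delimited text
#'
#' Rows are cells (first column = cell id), remaining numeric columns are
#' embedding components. Used for kNN construction and silhouette metrics.
#'
#' @param path CSV/TSV path with header.
#' @param sep Separator override.
#' @return Numeric matrix, cells x components, rownames = cell ids.
#' @export
read_embedding <- function(path, sep = NULL) {
  sep <- guess_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m) || any(!is.finite(m))) {
    stop("embedding must be finite numeric")
  }
  if (ncol(m) < 2L) stop("embedding needs at least 2 components")
  m
}

#' Write a cell embedding to delimited text
#' @param emb Cells x components numeric matrix with rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(emb, path) {
  df <- data.frame(cell_id = rownames(emb), emb, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = guess_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-cluster annotation table
#'
#' A TSV/CSV with columns `resolution` and `cluster` followed by arbitrary
#' named numeric or text fields (for example an externally computed enrichment
#' score and its term title). Rows key into graph nodes as
#' `"<resolution>_<cluster>"`; see [ingest_annotations()].
#'
#' @param path Path to the table.
#' @param sep Separator override.
#' @return A data.frame with at least `resolution` and `cluster` columns.
#' @export
read_annotations <- function(path, sep = NULL) {
  sep <- guess_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("resolution", "cluster")
  if (!all(need %in% colnames(df))) {
    stop("annotation table must have 'resolution' and 'cluster' columns")
  }
  num <- vapply(df, is.numeric, logical(1L))
  bad <- num & vapply(df, function(v) any(!is.finite(v)), logical(1L))
  if (any(bad)) {
    stop("non-finite values in annotation column(s): ",
         paste(colnames(df)[bad], collapse = ", "))
  }
  df
}

#' Align assignments, expression and embedding to one canonical cell order
#'
#' All downstream operations assume the same cells in the same order across
#' structures. In `strict` mode any mismatch between cell id sets is an
#' error; in `permissive` mode the intersection is kept (ordered as in the
#' assignment matrix) and the number of dropped cells is reported via
#' `message()`.
#'
#' @param assign A [cell_assignments] object.
#' @param expr Cells x genes expression matrix with cell rownames.
#' @param emb Optional cells x components embedding with cell rownames.
#' @param mode `"strict"` (default) or `"permissive"`.
#' @return A list with elements `assignments`, `expression` and (possibly
#'   `NULL`) `embedding`, all reporting identical cell id sequences.
#' @export
align_cells <- function(assign, expr, emb = NULL,
                        mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  stopifnot(inherits(assign, "cell_assignments"))
  validate_expression(expr)
  sets <- list(assignments = assign$cell_ids, expression = rownames(expr))
  if (!is.null(emb)) sets$embedding <- rownames(emb)
  common <- Reduce(intersect, sets)
  if (length(common) == 0L) stop("no cell ids shared across inputs")
  if (mode == "strict") {
    for (nm in names(sets)) {
      extra <- setdiff(sets[[nm]], common)
      if (length(extra) > 0L) {
        stop("strict alignment: ", length(extra), " cell id(s) in ", nm,
             " not shared by all inputs (e.g. '", extra[1L], "')")
      }
    }
  } else {
    dropped <- sum(vapply(sets, function(s) length(setdiff(s, common)),
                          integer(1L)))
    if (dropped > 0L) {
      message("align_cells: dropped ", dropped,
              " unmatched cell id(s) across inputs; keeping ",
              length(common), " cells")
    }
  }
  keep <- assign$cell_ids[assign$cell_ids %in% common]
  out_assign <- cell_assignments(
    keep, assign$labels[keep, , drop = FALSE],
    assign$resolutions, assign$res_labels
  )
  list(
    assignments = out_assign,
    expression = expr[keep, , drop = FALSE],
    embedding = if (is.null(emb)) NULL else emb[keep, , drop = FALSE]
  )
}
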