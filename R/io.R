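#' Write a sparse count matrix in MatrixMarket format with sidecars
#'
#' Writes `matrix.mtx` (coordinate format, 1-based indices, integer general
#' header), `genes.tsv` (one gene id per line) and `barcodes.tsv` (one cell
#' id per line) into `dir`. Round-trips losslessly for integer counts.
#'
#' @param counts gene x cell sparse matrix of integer counts with dimnames.
#' @param dir output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_mtx <- function(counts, dir) {
  counts <- as_count_matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and cell colnames")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tm <- methods::as(counts, "TsparseMatrix")
  con <- file(file.path(dir, "matrix.mtx"), "w")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix coordinate integer general", con)
  writeLines(paste(nrow(counts), ncol(counts), length(tm@x)), con)
  if (length(tm@x) > 0) {
    writeLines(paste(tm@i + 1L, tm@j + 1L, format(tm@x, scientific = FALSE,
                                                  trim = TRUE)), con)
  }
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a MatrixMarket count matrix with gene/barcode sidecars
#'
#' Expects the layout written by [write_mtx()]: `matrix.mtx` in 1-based
#' coordinate format plus `genes.tsv` and `barcodes.tsv` whose lengths match
#' the declared matrix dimensions. Zero-based indices and sidecar/dimension
#' mismatches are rejected with explicit counts.
#'
#' @param dir directory containing the three files.
#' @return gene x cell `dgCMatrix` with dimnames from the sidecars.
#' @export
read_mtx <- function(dir) {
  path <- file.path(dir, "matrix.mtx")
  lines <- readLines(path)
  if (length(lines) == 0 || !grepl("^%%MatrixMarket matrix coordinate", lines[1]))
    stop("not a MatrixMarket coordinate file: ", path)
  body <- lines[!grepl("^%", lines)]
  dims <- as.numeric(strsplit(trimws(body[1]), "\\s+")[[1]])
  if (length(dims) != 3 || anyNA(dims))
    stop("malformed MatrixMarket size line: '", body[1], "'")
  nr <- dims[1]; nc <- dims[2]; nnz <- dims[3]
  entries <- body[-1]
  if (length(entries) != nnz)
    stop("MatrixMarket header declares ", nnz, " entries but file has ",
         length(entries))
  if (nnz > 0) {
    trip <- matrix(as.numeric(unlist(strsplit(trimws(entries), "\\s+"))),
                   ncol = 3, byrow = TRUE)
    if (any(trip[, 1] < 1) || any(trip[, 2] < 1))
      stop("MatrixMarket indices must be 1-based; found index < 1")
    if (any(trip[, 1] > nr) || any(trip[, 2] > nc))
      stop("MatrixMarket index exceeds declared dimensions ", nr, " x ", nc)
    m <- Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = trip[, 3],
                              dims = c(nr, nc))
  } else {
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(nr, nc))
  }
  genes <- readLines(file.path(dir, "genes.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  if (length(genes) != nr)
    stop("genes.tsv has ", length(genes), " entries but matrix declares ",
         nr, " rows")
  if (length(barcodes) != nc)
    stop("barcodes.tsv has ", length(barcodes), " entries but matrix declares ",
         nc, " columns")
  dimnames(m) <- list(genes, barcodes)
  methods::as(m, "CsparseMatrix")
}

#' Write / read an embedding as TSV
#'
#' Column layout: `cell_id`, `dim_1` ... `dim_d`.
#'
#' @param embedding an embedding (see [as_embedding()]).
#' @param path TSV file path.
#' @return `path` invisibly / the embedding object.
#' @export
write_embedding_tsv <- function(embedding, path) {
  emb <- as_embedding(embedding)
  df <- data.frame(cell_id = emb$cell_ids, emb$coords, check.names = FALSE)
  colnames(df) <- c("cell_id", paste0("dim_", seq_len(ncol(emb$coords))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embedding_tsv
#' @export
read_embedding_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  coords <- as.matrix(df[, -1, drop = FALSE])
  rownames(coords) <- df$cell_id
  as_embedding(coords, provenance = basename(path))
}

#' Write / read per-cell labels as TSV
#'
#' Column layout: `cell_id`, `label`, plus any extra columns present
#' (`confidence`, `refined_from`, ...).
#'
#' @param labels an `fh_labels` data.frame or named character vector.
#' @param path TSV file path.
#' @export
write_labels_tsv <- function(labels, path) {
  if (!is.data.frame(labels))
    labels <- data.frame(cell_id = names(labels), label = as.character(labels))
  utils::write.table(labels, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels_tsv
#' @export
read_labels_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
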