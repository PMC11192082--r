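#' @importFrom Matrix Matrix sparseMatrix Diagonal colSums rowSums rowMeans colMeans t
#' @importFrom methods as is
#' @importFrom stats rnbinom rnorm runif quantile cor phyper dhyper
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Library-size normalize and log-transform a count matrix
#'
#' Counts-per-`scale_factor` followed by `log1p`, the standard normalization
#' applied before marker testing, module scoring, and signature weighting.
#' Columns (cells or spots) with zero total counts are left at zero.
#'
#' @param counts gene x cell matrix of non-negative counts (dense or sparse).
#' @param scale_factor library-size target; default 1e4 (counts per 10k).
#' @return matrix of the same shape, log1p-normalized.
#' @export
normalize_log <- function(counts, scale_factor = 1e4) {
  counts <- as_count_matrix(counts)
  lib <- Matrix::colSums(counts)
  lib[lib == 0] <- 1
  norm <- counts %*% Matrix::Diagonal(x = scale_factor / lib)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  norm
}

# Coerce to dgCMatrix with dimnames preserved; error if negative entries.
as_count_matrix <- function(x) {
  if (is.matrix(x)) x <- Matrix::Matrix(x, sparse = TRUE)
  x <- methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix")
  if (any(x@x < 0)) stop("count matrix has negative entries")
  x
}

# Align a label vector to a set of ids. Accepts a named vector, an
# fh_labels data.frame, or an unnamed vector of matching length.
align_labels <- function(labels, ids, what = "labels") {
  if (is.data.frame(labels)) {
    if (!all(c("cell_id", "label") %in% names(labels)))
      stop(what, " data.frame needs 'cell_id' and 'label' columns")
    lab <- as.character(labels$label)
    names(lab) <- labels$cell_id
    labels <- lab
  }
  labels <- if (is.factor(labels)) {
    structure(as.character(labels), names = names(labels))
  } else labels
  if (!is.null(names(labels))) {
    missing <- setdiff(ids, names(labels))
    if (length(missing) > 0)
      stop(length(missing), " ids have no entry in ", what,
           " (first: ", missing[1], ")")
    labels <- labels[ids]
  } else if (length(labels) != length(ids)) {
    stop(what, " length (", length(labels), ") does not match number of ids (",
         length(ids), ")")
  }
  unname_to <- as.character(labels)
  names(unname_to) <- ids
  unname_to
}

# Deterministic derived seed streams, kept below 2^31.
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 1009L + (stream %% 1009L)
}
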