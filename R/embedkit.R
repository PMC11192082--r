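#' Coerce to an embedding object
#'
#' An embedding is the integrated low-dimensional coordinate matrix produced
#' by a batch-correction method (or by the simulator): one row per cell,
#' `d >= 2` finite columns, unique cell ids.
#'
#' @param x a numeric matrix with cell-id rownames, or an `fh_embedding`.
#' @param provenance free-text tag recording where the coordinates came from.
#' @return list of class `fh_embedding` with `cell_ids`, `coords`,
#'   `provenance`.
#' @export
as_embedding <- function(x, provenance = "unspecified") {
  if (inherits(x, "fh_embedding")) return(x)
  coords <- as.matrix(x)
  if (is.null(rownames(coords)))
    rownames(coords) <- sprintf("c%05d", seq_len(nrow(coords)))
  if (ncol(coords) < 2) stop("embedding must have at least 2 dimensions")
  if (anyDuplicated(rownames(coords)))
    stop("duplicate cell ids in embedding")
  if (any(!is.finite(coords))) stop("non-finite coordinates in embedding")
  structure(list(cell_ids = rownames(coords), coords = coords,
                 provenance = provenance), class = "fh_embedding")
}

#' Exact k-nearest-neighbor index on an embedding
#'
#' For each cell, the k nearest OTHER cells by Euclidean distance, self
#' excluded, deterministically ordered by (distance, cell id). Exact search;
#' intended for the dataset sizes at which the downstream metrics are used.
#'
#' @param embedding an embedding (see [as_embedding()]).
#' @param k neighbors per cell; must be `< n`.
#' @return list of class `fh_knn` with `idx` (n x k integer matrix of
#'   neighbor row indices), `dist` (n x k distances), `cell_ids`, `k`.
#' @export
knn_index <- function(embedding, k) {
  emb <- as_embedding(embedding)
  n <- nrow(emb$coords)
  if (k >= n) stop("k (", k, ") must be smaller than the number of cells (",
                   n, ")")
  if (k < 1) stop("k must be >= 1")
  d2 <- pairwise_sqdist(emb$coords)
  ids <- emb$cell_ids
  idx <- matrix(0L, n, k)
  dmat <- matrix(0, n, k)
  for (i in seq_len(n)) {
    di <- d2[, i]
    di[i] <- Inf                        # exclude self
    ord <- order(di, ids)[seq_len(k)]
    idx[i, ] <- ord
    dmat[i, ] <- sqrt(pmax(di[ord], 0))
  }
  rownames(idx) <- ids
  structure(list(idx = idx, dist = dmat, cell_ids = ids, k = k),
            class = "fh_knn")
}

# Squared Euclidean distances via the Gram-matrix identity.
pairwise_sqdist <- function(x) {
  sq <- rowSums(x^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  d2
}

#' Refine cluster labels by k-nearest-neighbor majority vote
#'
#' Each cell's label is replaced by the modal label among its k nearest
#' neighbors on the integrated embedding (self excluded). Ties are broken in
#' favor of the cell's original label when it is among the tied modes, else
#' by the lexicographically smallest tied label, so refinement is
#' conservative. Confidence is the modal vote fraction.
#'
#' @param embedding an embedding (see [as_embedding()]).
#' @param labels per-cell labels: named character vector or data.frame with
#'   `cell_id`/`label` columns, aligned to the embedding.
#' @param k neighbors to vote; default 25, the published refinement setting.
#' @param allow_missing if `TRUE`, cells with `NA` labels are excluded from
#'   voting and returned unrefined; otherwise `NA` labels are an error.
#' @param nn optional precomputed [knn_index()] (must have `k >= k` votes).
#' @return data.frame of class `fh_labels`: `cell_id`, `label` (refined),
#'   `refined_from` (input label), `confidence` (modal fraction).
#' @export
refine_labels <- function(embedding, labels, k = 25, allow_missing = FALSE,
                          nn = NULL) {
  emb <- as_embedding(embedding)
  lab <- align_labels(labels, emb$cell_ids)
  if (anyNA(lab) && !allow_missing)
    stop("unlabeled cells present; set allow_missing = TRUE to exclude ",
         "them from voting")
  if (is.null(nn)) nn <- knn_index(emb, k)
  if (nn$k < k) stop("precomputed knn index has fewer than k neighbors")
  n <- length(lab)
  out_label <- lab
  conf <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(lab[i])) next             # unrefined by policy
    votes <- lab[nn$idx[i, seq_len(k)]]
    votes <- votes[!is.na(votes)]
    if (length(votes) == 0) { conf[i] <- NA_real_; next }
    tab <- table(votes)
    modes <- names(tab)[tab == max(tab)]
    out_label[i] <- if (lab[i] %in% modes) lab[i] else sort(modes)[1]
    conf[i] <- max(tab) / length(votes)
  }
  structure(data.frame(cell_id = emb$cell_ids, label = unname(out_label),
                       refined_from = unname(lab), confidence = conf,
                       stringsAsFactors = FALSE),
            class = c("fh_labels", "data.frame"))
}

#' Neighbor-purity matrix of an embedding
#'
#' Diagnoses batch mixing versus state retention: entry (A, B) is the mean,
#' over cells labeled A, of the percentage of their k nearest neighbors
#' labeled B. Rows sum to 100. A block-diagonal matrix indicates separated
#' groups; rows matching the global label proportions indicate full mixing.
#'
#' @param embedding an embedding (see [as_embedding()]).
#' @param labels per-cell labels aligned to the embedding.
#' @param k neighbors per cell; default 200, the published comparison
#'   setting.
#' @param nn optional precomputed [knn_index()].
#' @return matrix of class `purity_matrix` (percentages; attribute `k_used`).
#'   Label classes with zero cells are dropped with a warning.
#' @export
neighbor_purity <- function(embedding, labels, k = 200, nn = NULL) {
  emb <- as_embedding(embedding)
  lab <- align_labels(labels, emb$cell_ids)
  if (anyNA(lab)) stop("neighbor_purity requires fully labeled cells")
  if (is.null(nn)) nn <- knn_index(emb, k)
  if (nn$k < k) stop("precomputed knn index has fewer than k neighbors")
  vocab <- sort(unique(lab))
  if (is.factor(labels)) {
    declared <- levels(labels)
    empty <- setdiff(declared, vocab)
    if (length(empty) > 0)
      warning("dropping label class(es) with 0 cells: ",
              paste(empty, collapse = ", "))
  }
  L <- length(vocab)
  lab_int <- match(lab, vocab)
  neigh_lab <- matrix(lab_int[nn$idx[, seq_len(k)]], nrow = length(lab))
  # per-cell composition of neighbor labels, then average within own class
  comp <- matrix(0, length(lab), L)
  for (b in seq_len(L)) comp[, b] <- rowSums(neigh_lab == b) / k * 100
  purity <- matrix(0, L, L, dimnames = list(vocab, vocab))
  for (a in seq_len(L)) {
    purity[a, ] <- colMeans(comp[lab_int == a, , drop = FALSE])
  }
  structure(purity, class = c("purity_matrix", "matrix"), k_used = k)
}

#' @export
print.purity_matrix <- function(x, digits = 1, ...) {
  cat("Neighbor-purity matrix (row = cell class, % of k =",
      attr(x, "k_used"), "nearest neighbors)\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Batch-mixing versus state-retention report
#'
#' Computes neighbor-purity matrices by batch and by biological state on the
#' same embedding and summarizes them: a well-integrated embedding mixes
#' batches (high off-diagonal batch purity) while retaining states (high
#' diagonal state purity).
#'
#' @param embedding an embedding (see [as_embedding()]).
#' @param batch_labels,state_labels per-cell labels aligned to the embedding.
#' @param k neighbors per cell (default 200).
#' @return list of class `fh_mixing_report`: `batch_purity`, `state_purity`
#'   (purity matrices), `batch_mixing_score` (mean off-diagonal batch
#'   purity), `state_retention_score` (mean diagonal state purity).
#' @export
batch_mixing_report <- function(embedding, batch_labels, state_labels,
                                k = 200) {
  emb <- as_embedding(embedding)
  nn <- knn_index(emb, k)
  bp <- neighbor_purity(emb, batch_labels, k, nn = nn)
  sp <- neighbor_purity(emb, state_labels, k, nn = nn)
  off <- unclass(bp); diag(off) <- NA
  structure(list(
    batch_purity = bp,
    state_purity = sp,
    batch_mixing_score = mean(off, na.rm = TRUE),
    state_retention_score = mean(diag(unclass(sp)))
  ), class = "fh_mixing_report")
}

#' @export
print.fh_mixing_report <- function(x, ...) {
  cat("Batch-mixing report (k =", attr(x$batch_purity, "k_used"), ")\n")
  cat("  batch mixing score (mean off-diagonal batch purity): ",
      round(x$batch_mixing_score, 2), "\n")
  cat("  state retention score (mean diagonal state purity): ",
      round(x$state_retention_score, 2), "\n")
  invisible(x)
}
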