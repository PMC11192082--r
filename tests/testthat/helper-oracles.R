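# Independent brute-force oracles, written against the documented
# behavior, not the package internals: plain double loops over stats::dist.

oracle_knn <- function(coords, k) {
  n <- nrow(coords)
  ids <- rownames(coords)
  dm <- as.matrix(stats::dist(coords))
  res <- vapply(seq_len(n), function(i) {
    cand <- setdiff(seq_len(n), i)
    ord <- cand[order(dm[i, cand], ids[cand])]
    ord[seq_len(k)]
  }, integer(k))
  if (k == 1) matrix(res, ncol = 1) else t(res)
}

# Majority vote with the conservative tie rule: keep the original label if
# tied, else the alphabetically first tied label.
oracle_refine <- function(coords, labels, k) {
  nn <- oracle_knn(coords, k)
  vapply(seq_len(nrow(coords)), function(i) {
    tab <- table(labels[nn[i, ]])
    modes <- names(tab)[tab == max(tab)]
    if (labels[i] %in% modes) labels[i] else sort(modes)[1]
  }, character(1))
}

oracle_purity <- function(coords, labels, k) {
  nn <- oracle_knn(coords, k)
  vocab <- sort(unique(labels))
  out <- matrix(0, length(vocab), length(vocab),
                dimnames = list(vocab, vocab))
  for (a in vocab) {
    rows <- which(labels == a)
    comp <- sapply(vocab, function(b) {
      mean(vapply(rows, function(i) sum(labels[nn[i, ]] == b) / k,
                  numeric(1)))
    })
    out[a, ] <- comp * 100
  }
  out
}

# Gaussian blobs with labeled rows, for classifier and refinement fixtures.
make_blobs <- function(n_per, centers, sd = 1, seed = 1,
                       labels = paste0("blob", seq_len(nrow(centers)))) {
  set.seed(seed)
  coords <- do.call(rbind, lapply(seq_len(nrow(centers)), function(j) {
    matrix(rnorm(n_per * ncol(centers), mean = rep(centers[j, ],
                                                   each = n_per),
                 sd = sd), n_per, ncol(centers))
  }))
  rownames(coords) <- sprintf("c%05d", seq_len(nrow(coords)))
  list(coords = coords,
       labels = structure(rep(labels, each = n_per),
                          names = rownames(coords)))
}

# Small null count matrix: negative binomial, exchangeable across cells.
# Gene means are log-normal by default so average-expression bins are
# meaningful; pass a scalar mu for a flat profile.
null_counts <- function(n_genes, n_cells, mu = NULL, size = 2, seed = 1) {
  set.seed(seed)
  if (is.null(mu)) mu <- exp(rnorm(n_genes, log(2), 1))
  matrix(rnbinom(n_genes * n_cells, mu = mu, size = size), n_genes, n_cells,
         dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                         sprintf("c%05d", seq_len(n_cells))))
}
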