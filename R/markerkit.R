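#' Row-wise Wilcoxon rank-sum test
#'
#' Tie-corrected normal approximation with continuity correction, applied to
#' every row of an expression matrix at once; agrees with
#' `stats::wilcox.test(exact = FALSE, correct = TRUE)`. Constant rows (zero
#' rank-sum variance) get p = 1.
#'
#' @param x gene x cell numeric matrix.
#' @param idx_a,idx_b column indices of the two groups.
#' @return numeric vector of two-sided p-values, one per row.
#' @export
row_wilcoxon <- function(x, idx_a, idx_b) {
  x <- as.matrix(x)[, c(idx_a, idx_b), drop = FALSE]
  na <- length(idx_a); nb <- length(idx_b); n <- na + nb
  stats_row <- apply(x, 1, function(v) {
    r <- rank(v)
    t <- tabulate(match(v, unique(v)))
    c(sum(r[seq_len(na)]), sum(t^3 - t))
  })
  u <- stats_row[1, ] - na * (na + 1) / 2
  tie <- stats_row[2, ]
  z <- u - na * nb / 2
  sigma <- sqrt((na * nb / 12) * ((n + 1) - tie / (n * (n - 1))))
  z <- (z - sign(z) * 0.5) / sigma
  p <- 2 * stats::pnorm(-abs(z))
  p[!is.finite(z)] <- 1                 # constant rows
  pmin(p, 1)
}

#' Detect population marker genes
#'
#' Two-group test of a target population against the rest (or a named
#' reference group), Bonferroni-adjusted over all tested genes and filtered
#' at the published thresholds: adjusted p < 1e-5 and log2 fold change
#' > 0.5. The per-gene test is pluggable; the default is a Wilcoxon
#' rank-sum test on log-normalized expression.
#'
#' @param expr gene x cell counts (or log-normalized values with
#'   `normalized = TRUE`).
#' @param labels per-cell labels.
#' @param target population whose markers are sought.
#' @param reference population(s) to test against; default: all other cells.
#' @param min_frac minimum fraction of target cells expressing the gene.
#' @param alpha_adj Bonferroni-adjusted p-value cutoff (default 1e-5).
#' @param lfc_min log2 fold-change cutoff (default 0.5).
#' @param pseudocount added to both group means (on the normalized scale)
#'   before the fold-change ratio.
#' @param test_fun `function(matrix, idx_a, idx_b) -> p-values`; default
#'   [row_wilcoxon()].
#' @param normalized set `TRUE` when `expr` is already log-normalized.
#' @param filter if `FALSE`, return all tested genes with a `significant`
#'   column instead of only the passing rows.
#' @return data.frame (MarkerTable): `population`, `gene`,
#'   `log2_fold_change`, `p_raw`, `p_adj`, `frac_expr_in`, `frac_expr_out`,
#'   sorted by adjusted p.
#' @export
find_markers <- function(expr, labels, target, reference = NULL,
                         min_frac = 0, alpha_adj = 1e-5, lfc_min = 0.5,
                         pseudocount = 1, test_fun = row_wilcoxon,
                         normalized = FALSE, filter = TRUE) {
  norm <- if (normalized) as_count_matrix(expr) else normalize_log(expr)
  lab <- align_labels(labels, colnames(norm))
  idx_a <- which(lab == target)
  idx_b <- if (is.null(reference)) which(lab != target)
           else which(lab %in% reference)
  if (length(idx_a) < 3 || length(idx_b) < 3)
    stop("need at least 3 cells in each group (target has ", length(idx_a),
         ", reference has ", length(idx_b), ")")
  dense <- as.matrix(norm[, c(idx_a, idx_b), drop = FALSE])
  a <- seq_along(idx_a); b <- length(idx_a) + seq_along(idx_b)
  mean_a <- rowMeans(expm1(dense[, a, drop = FALSE]))
  mean_b <- rowMeans(expm1(dense[, b, drop = FALSE]))
  lfc <- log2((mean_a + pseudocount) / (mean_b + pseudocount))
  p_raw <- test_fun(dense, a, b)
  p_adj <- pmin(1, p_raw * nrow(dense))  # Bonferroni over tested genes
  out <- data.frame(
    population = target, gene = rownames(dense),
    log2_fold_change = lfc, p_raw = p_raw, p_adj = p_adj,
    frac_expr_in = rowMeans(dense[, a, drop = FALSE] > 0),
    frac_expr_out = rowMeans(dense[, b, drop = FALSE] > 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
  keep <- out$p_adj < alpha_adj & out$log2_fold_change > lfc_min &
    out$frac_expr_in >= min_frac
  if (filter) out <- out[keep, , drop = FALSE] else out$significant <- keep
  out[order(out$p_adj, -out$log2_fold_change), , drop = FALSE]
}

#' One-sided Fisher overlap (hypergeometric enrichment) test
#'
#' Probability of observing at least `n_intersect` shared genes when two
#' sets of sizes `n_a` and `n_b` are drawn from a universe of `n_universe`
#' genes: `P(X >= n_intersect)` under
#' `Hypergeometric(n_universe, n_a, n_b)`.
#'
#' @param n_intersect,n_a,n_b,n_universe overlap counts (vectorized).
#' @return p-value(s) in (0, 1].
#' @export
fisher_overlap_test <- function(n_intersect, n_a, n_b, n_universe) {
  args <- cbind(n_intersect, n_a, n_b, n_universe)
  if (any(args < 0)) stop("counts must be non-negative")
  if (any(args[, 2] > args[, 4]) || any(args[, 3] > args[, 4]))
    stop("set sizes cannot exceed the universe")
  if (any(args[, 1] > pmin(args[, 2], args[, 3])))
    stop("n_intersect cannot exceed min(n_a, n_b)")
  if (any(args[, 1] < pmax(0, args[, 2] + args[, 3] - args[, 4])))
    stop("n_intersect below the minimum forced by the set sizes")
  unname(stats::phyper(args[, 1] - 1, args[, 2], args[, 4] - args[, 2],
                       args[, 3], lower.tail = FALSE))
}

#' Match populations across datasets by marker-set overlap
#'
#' For every pair of populations from two marker tables, computes the
#' Jaccard coefficient of the (ortholog-mapped) marker gene sets together
#' with a one-sided Fisher exact enrichment p-value over the shared tested
#' universe — the statistic used to match fibroblast states across species
#' and diseases.
#'
#' Default ortholog mapping is case-normalized symbol matching (mouse
#' Title-case to human UPPER-case); an explicit two-column mapping table
#' (`from`, `to`) can be supplied for dataset A instead.
#'
#' @param markers_a,markers_b MarkerTables (see [find_markers()]) with
#'   `population` and `gene` columns.
#' @param universe_a,universe_b character vectors of all genes tested in
#'   each dataset (the Fisher universe is their mapped intersection).
#' @param ortholog_map optional data.frame with columns `from`, `to` mapping
#'   dataset-A symbols into dataset-B symbol space.
#' @return list of class `fh_overlap`: `jaccard` and `fisher_p` matrices
#'   (populations of A x populations of B), `pairs` data.frame with all
#'   counts, `n_universe`.
#' @export
jaccard_match <- function(markers_a, markers_b, universe_a, universe_b,
                          ortholog_map = NULL) {
  map_a <- if (is.null(ortholog_map)) {
    function(g) toupper(g)
  } else {
    if (!all(c("from", "to") %in% names(ortholog_map)))
      stop("ortholog_map needs 'from' and 'to' columns")
    lut <- structure(as.character(ortholog_map$to),
                     names = as.character(ortholog_map$from))
    function(g) unname(lut[g])
  }
  map_b <- if (is.null(ortholog_map)) function(g) toupper(g) else identity
  uni <- intersect(unique(stats::na.omit(map_a(universe_a))),
                   unique(map_b(universe_b)))
  if (length(uni) == 0)
    stop("empty shared universe after ortholog mapping")
  pops_a <- sort(unique(markers_a$population))
  pops_b <- sort(unique(markers_b$population))
  if (length(pops_a) == 0 || length(pops_b) == 0)
    stop("marker tables must be non-empty")
  sets_a <- lapply(pops_a, function(p) {
    intersect(unique(stats::na.omit(
      map_a(markers_a$gene[markers_a$population == p]))), uni)
  })
  sets_b <- lapply(pops_b, function(p) {
    intersect(unique(map_b(markers_b$gene[markers_b$population == p])), uni)
  })
  pairs <- expand.grid(population_a = pops_a, population_b = pops_b,
                       stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    A <- sets_a[[match(pairs$population_a[i], pops_a)]]
    B <- sets_b[[match(pairs$population_b[i], pops_b)]]
    ni <- length(intersect(A, B))
    un <- length(union(A, B))
    data.frame(
      n_intersect = ni, n_a = length(A), n_b = length(B),
      n_universe = length(uni),
      jaccard = if (un == 0) 0 else ni / un,
      fisher_p = fisher_overlap_test(ni, length(A), length(B), length(uni)))
  }))
  pairs <- cbind(pairs, res)
  jac <- matrix(pairs$jaccard, length(pops_a), length(pops_b),
                dimnames = list(pops_a, pops_b))
  fis <- matrix(pairs$fisher_p, length(pops_a), length(pops_b),
                dimnames = list(pops_a, pops_b))
  structure(list(jaccard = jac, fisher_p = fis, pairs = pairs,
                 n_universe = length(uni)),
            class = "fh_overlap")
}

#' @export
print.fh_overlap <- function(x, ...) {
  cat("Marker-set overlap over a shared universe of", x$n_universe,
      "genes\nJaccard coefficients:\n")
  print(round(x$jaccard, 3))
  invisible(x)
}

#' Gene-set module score with binned control genes
#'
#' Per-cell score of a gene set: mean log-normalized expression over the set
#' minus the mean over control genes sampled (once per run, seeded) from
#' average-expression bins matched to the set genes. Positive scores mean
#' the set is expressed above expression-matched background in that cell.
#'
#' @param expr gene x cell counts (or log-normalized with
#'   `normalized = TRUE`).
#' @param gene_set character vector of gene ids.
#' @param n_bins number of average-expression bins (default 24).
#' @param n_ctrl control genes sampled per set gene (default 100; sampled
#'   with replacement when a bin is smaller).
#' @param seed integer seed for control sampling.
#' @param normalized set `TRUE` when `expr` is already log-normalized.
#' @return named numeric vector of per-cell scores.
#' @export
module_score <- function(expr, gene_set, n_bins = 24, n_ctrl = 100, seed = 1,
                         normalized = FALSE) {
  norm <- if (normalized) as_count_matrix(expr) else normalize_log(expr)
  if (length(gene_set) == 0) stop("gene_set is empty")
  present <- intersect(gene_set, rownames(norm))
  if (length(present) == 0)
    stop("none of the gene_set genes are present in the matrix")
  if (length(present) < length(gene_set))
    warning(length(gene_set) - length(present),
            " gene_set gene(s) absent from the matrix; dropped")
  avg <- Matrix::rowMeans(norm)
  n_bins <- min(n_bins, nrow(norm))
  bin <- cut(rank(avg, ties.method = "first"), breaks = n_bins,
             labels = FALSE)
  names(bin) <- rownames(norm)
  bin_members <- split(rownames(norm), bin)
  set.seed(seed)
  ctrl <- unlist(lapply(present, function(g) {
    pool <- bin_members[[as.character(bin[g])]]
    pool[sample.int(length(pool), n_ctrl, replace = length(pool) < n_ctrl)]
  }), use.names = FALSE)
  set_mean <- Matrix::colMeans(norm[present, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(norm[ctrl, , drop = FALSE])
  structure(as.numeric(set_mean - ctrl_mean), names = colnames(norm))
}

#' Permutation-normalized weighted-mean regulon activity
#'
#' For each transcription-factor regulon, the raw per-cell statistic is the
#' weighted sum of its target genes' expression. The statistic is normalized
#' against `times` permutations of the gene labels: activity =
#' (raw - permutation mean) / permutation sd, so null regulons score around
#' zero with unit spread. Regulons with fewer than `minsize` targets present
#' in the matrix are dropped with a warning.
#'
#' @param expr gene x cell counts (or log-normalized with
#'   `normalized = TRUE`).
#' @param regulons data.frame with columns `tf`, `target`, `weight`.
#' @param times number of permutations (default 100).
#' @param minsize minimum targets present per regulon (default 5).
#' @param seed integer seed for the permutations.
#' @param normalized set `TRUE` when `expr` is already log-normalized.
#' @return tf x cell matrix of normalized activities; attribute `dropped`
#'   lists regulons below `minsize`.
#' @export
regulon_activity <- function(expr, regulons, times = 100, minsize = 5,
                             seed = 1, normalized = FALSE) {
  stopifnot(all(c("tf", "target", "weight") %in% names(regulons)))
  norm <- if (normalized) as_count_matrix(expr) else normalize_log(expr)
  reg <- regulons[regulons$target %in% rownames(norm), , drop = FALSE]
  if (anyDuplicated(reg[, c("tf", "target")]))
    stop("duplicate (tf, target) pairs in regulons")
  sizes <- table(reg$tf)
  dropped <- names(sizes)[sizes < minsize]
  dropped <- union(dropped, setdiff(unique(regulons$tf), unique(reg$tf)))
  if (length(dropped) > 0)
    warning("dropping regulon(s) with fewer than ", minsize,
            " targets present: ", paste(sort(dropped), collapse = ", "))
  reg <- reg[!reg$tf %in% dropped, , drop = FALSE]
  if (nrow(reg) == 0) stop("no regulon has >= minsize targets present")
  tfs <- sort(unique(reg$tf))
  G <- nrow(norm)
  w <- Matrix::sparseMatrix(i = match(reg$tf, tfs),
                            j = match(reg$target, rownames(norm)),
                            x = reg$weight, dims = c(length(tfs), G))
  x <- as.matrix(norm)
  raw <- as.matrix(w %*% x)
  set.seed(seed)
  s1 <- matrix(0, nrow(raw), ncol(raw))
  s2 <- matrix(0, nrow(raw), ncol(raw))
  for (t in seq_len(times)) {
    p <- as.matrix(w %*% x[sample.int(G), , drop = FALSE])
    s1 <- s1 + p
    s2 <- s2 + p^2
  }
  mu <- s1 / times
  sdev <- sqrt(pmax((s2 - times * mu^2) / (times - 1), 0))
  act <- (raw - mu) / sdev
  bad <- !is.finite(act)
  if (any(bad)) {
    warning(sum(bad), " activity value(s) had zero permutation sd; set to 0")
    act[bad] <- 0
  }
  dimnames(act) <- list(tfs, colnames(norm))
  attr(act, "dropped") <- sort(dropped)
  act
}

#' Average regulon activity per population
#'
#' @param activity tf x cell matrix from [regulon_activity()].
#' @param labels per-cell labels.
#' @return tf x population matrix of mean normalized activities.
#' @export
summarize_activity <- function(activity, labels) {
  lab <- align_labels(labels, colnames(activity))
  pops <- sort(unique(lab))
  out <- vapply(pops, function(p) {
    rowMeans(activity[, lab == p, drop = FALSE])
  }, numeric(nrow(activity)))
  matrix(out, nrow(activity), length(pops),
         dimnames = list(rownames(activity), pops))
}

#' Correlation of fold changes between two marker tables
#'
#' Pearson correlation of log2 fold changes over the union of genes
#' significant in either table — the comparison used to relate a state's
#' response across disease models. Supply full (unfiltered) tables from
#' `find_markers(..., filter = FALSE)` so genes significant in only one
#' dataset contribute their actually computed fold change in the other.
#'
#' @param markers_a,markers_b MarkerTables with `gene` and
#'   `log2_fold_change`; a logical `significant` column marks passing genes
#'   (absent: all rows treated as significant).
#' @param method correlation method (default `"pearson"`).
#' @return correlation coefficient.
#' @export
fold_change_correlation <- function(markers_a, markers_b,
                                    method = "pearson") {
  sig <- function(m) {
    if ("significant" %in% names(m)) m$gene[m$significant] else m$gene
  }
  genes <- union(sig(markers_a), sig(markers_b))
  fa <- markers_a$log2_fold_change[match(genes, markers_a$gene)]
  fb <- markers_b$log2_fold_change[match(genes, markers_b$gene)]
  ok <- !is.na(fa) & !is.na(fb)
  if (any(!ok))
    warning(sum(!ok), " significant gene(s) missing a fold change in one ",
            "table; dropped (supply full tables to avoid this)")
  if (sum(ok) < 3)
    stop("fewer than 3 genes with fold changes in both tables")
  stats::cor(fa[ok], fb[ok], method = method)
}
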