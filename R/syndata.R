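#' Configuration for the multi-batch single-cell simulator
#'
#' Bundles the generative parameters for [simulate_multibatch_counts()]:
#' UMI-like counts are drawn as negative binomial around
#' `exp(gene baseline + planted marker offset + low-rank factor term +
#' per-batch gene scaling)`. The factor term acts on within-population factor
#' scores, so population structure enters the counts only through the planted
#' marker offsets while the returned embedding (the factor-score matrix)
#' carries the population centroids. Batch effects are multiplicative
#' per-gene log-normal scalings.
#'
#' @param n_genes number of genes.
#' @param n_cells_per_batch integer vector, cells in each batch.
#' @param n_populations number of planted populations.
#' @param factor_rank rank of the shared factor model; the embedding has this
#'   many columns. Default 15, the expected biological heterogeneity used for
#'   the cardiac-fibroblast integrations this simulator emulates.
#' @param population_proportions batch x population matrix of proportions,
#'   each row summing to 1. Default: equal proportions in every batch.
#' @param batch_scale_sd sd of the per-batch per-gene log-normal scaling
#'   (natural-log scale); 0 disables batch effects.
#' @param marker_spec data.frame with columns `population`, `n_markers`,
#'   `log2fc`. Default: 10 markers per population at log2FC 2.
#' @param dispersion negative-binomial dispersion (1/size); 0 gives Poisson.
#' @param separation distance between population centroids in factor space.
#' @param factor_sd total sd of the factor contribution to log-mean expression.
#' @param base_logmean_mean,base_logmean_sd log-normal gene baseline.
#' @param marker_base_mean baseline mean count of planted marker genes in
#'   non-target populations (kept well expressed so fold changes are
#'   estimable).
#' @param seed integer seed; identical seeds give identical outputs.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_genes = 2000,
                       n_cells_per_batch = c(300, 300),
                       n_populations = 3,
                       factor_rank = 15,
                       population_proportions = NULL,
                       batch_scale_sd = 0.1,
                       marker_spec = NULL,
                       dispersion = 0.5,
                       separation = 6,
                       factor_sd = 0.2,
                       base_logmean_mean = log(0.5),
                       base_logmean_sd = 1,
                       marker_base_mean = 2,
                       seed = 1) {
  pops <- paste0("pop", seq_len(n_populations))
  if (is.null(population_proportions)) {
    population_proportions <- matrix(1 / n_populations,
                                     nrow = length(n_cells_per_batch),
                                     ncol = n_populations)
  }
  population_proportions <- as.matrix(population_proportions)
  if (nrow(population_proportions) != length(n_cells_per_batch) ||
      ncol(population_proportions) != n_populations)
    stop("population_proportions must be n_batches x n_populations")
  if (any(abs(rowSums(population_proportions) - 1) > 1e-9))
    stop("each population_proportions row must sum to 1")
  if (is.null(marker_spec)) {
    marker_spec <- data.frame(population = pops, n_markers = 10, log2fc = 2)
  }
  if (!all(marker_spec$population %in% pops))
    stop("marker_spec names unknown populations")
  if (sum(marker_spec$n_markers) > n_genes)
    stop("more markers requested than genes available")
  if (factor_rank >= min(n_genes, sum(n_cells_per_batch)))
    stop("factor_rank must be < min(n_genes, total cells)")
  if (dispersion < 0) stop("dispersion must be >= 0")
  # cell allocation by largest-remainder apportionment, so a population's
  # planted size is a deterministic function of the config
  alloc <- t(vapply(seq_along(n_cells_per_batch), function(b) {
    apportion(n_cells_per_batch[b], population_proportions[b, ])
  }, numeric(n_populations)))
  colnames(alloc) <- pops
  empty <- pops[colSums(alloc) == 0]
  if (length(empty) > 0)
    stop("population(s) with 0 cells in every batch: ",
         paste(empty, collapse = ", "))
  structure(list(
    n_genes = n_genes, n_cells_per_batch = n_cells_per_batch,
    n_populations = n_populations, populations = pops,
    factor_rank = factor_rank,
    population_proportions = population_proportions,
    batch_scale_sd = batch_scale_sd, marker_spec = marker_spec,
    dispersion = dispersion, separation = separation, factor_sd = factor_sd,
    base_logmean_mean = base_logmean_mean, base_logmean_sd = base_logmean_sd,
    marker_base_mean = marker_base_mean, seed = as.integer(seed),
    allocation = alloc
  ), class = "sim_config")
}

# Largest-remainder rounding of n * proportions to integers summing to n.
apportion <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Simulate multi-batch single-cell counts with planted structure
#'
#' Draws negative-binomial counts from a shared low-rank factor model with
#' planted population markers and per-batch multiplicative gene scalings, and
#' returns the noise-free factor-score matrix as the "ideal integration"
#' embedding, together with a full ground-truth record.
#'
#' @param config a [sim_config()].
#' @return list of class `fh_sim` with elements `counts` (gene x cell sparse
#'   matrix), `embedding` (see [as_embedding()]; `factor_rank` columns), and
#'   `truth` (cell labels, batch of each cell, marker truth, batch scaling
#'   parameters, config).
#' @export
simulate_multibatch_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes
  r <- config$factor_rank
  P <- config$n_populations
  pops <- config$populations
  alloc <- config$allocation
  n_cells <- sum(alloc)

  genes <- sprintf("g%04d", seq_len(G))
  cells <- sprintf("c%05d", seq_len(n_cells))

  # disjoint marker gene blocks, then baselines
  ms <- config$marker_spec
  marker_genes <- vector("list", nrow(ms))
  pool <- sample.int(G)                 # random but seeded gene order
  used <- 0
  for (i in seq_len(nrow(ms))) {
    marker_genes[[i]] <- sort(pool[used + seq_len(ms$n_markers[i])])
    used <- used + ms$n_markers[i]
  }
  base <- rnorm(G, config$base_logmean_mean, config$base_logmean_sd)
  base[unlist(marker_genes)] <- rnorm(length(unlist(marker_genes)),
                                      log(config$marker_base_mean), 0.25)

  lambda <- matrix(rnorm(G * r, 0, config$factor_sd / sqrt(r)), G, r)
  centroids <- qr.Q(qr(matrix(rnorm(r * P), r, P))) * config$separation

  batch <- rep(seq_along(config$n_cells_per_batch),
               times = rowSums(alloc))
  pop_idx <- unlist(lapply(seq_len(nrow(alloc)), function(b) {
    rep(seq_len(P), times = alloc[b, ])
  }))

  eps <- matrix(rnorm(n_cells * r), n_cells, r)
  scores <- t(centroids)[pop_idx, , drop = FALSE] + eps

  batch_log_scale <- matrix(rnorm(G * length(config$n_cells_per_batch), 0,
                                  config$batch_scale_sd),
                            G, length(config$n_cells_per_batch))

  marker_offset <- matrix(0, G, P)
  for (i in seq_len(nrow(ms))) {
    p <- match(ms$population[i], pops)
    marker_offset[marker_genes[[i]], p] <- ms$log2fc[i] * log(2)
  }

  # counts carry population structure only through the marker offsets; the
  # factor term uses within-population scores so planted log2FCs stay clean
  log_mu <- base +
    marker_offset[, pop_idx, drop = FALSE] +
    lambda %*% t(eps) +
    batch_log_scale[, batch, drop = FALSE]
  mu <- exp(as.matrix(log_mu))
  counts <- if (config$dispersion > 0) {
    rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
  } else {
    stats::rpois(length(mu), mu)
  }
  counts <- Matrix::Matrix(matrix(counts, G, n_cells,
                                  dimnames = list(genes, cells)),
                           sparse = TRUE)

  rownames(scores) <- cells
  marker_truth <- do.call(rbind, lapply(seq_len(nrow(ms)), function(i) {
    data.frame(population = ms$population[i], gene = genes[marker_genes[[i]]],
               log2fc = ms$log2fc[i])
  }))
  dimnames(batch_log_scale) <- list(genes,
                                    paste0("batch", seq_len(ncol(batch_log_scale))))
  truth <- list(
    cell_labels = structure(pops[pop_idx], names = cells),
    batch = structure(paste0("batch", batch), names = cells),
    marker_truth = marker_truth,
    batch_params = batch_log_scale,
    config = config
  )
  structure(list(
    counts = counts,
    embedding = as_embedding(scores, provenance = "simulated-factor-scores"),
    truth = truth
  ), class = "fh_sim")
}

#' Add batch-specific distortion to an embedding
#'
#' Applies a random rotation and translation per batch, producing a
#' "badly integrated" embedding for exercising mixing metrics.
#'
#' @param embedding an embedding (see [as_embedding()]).
#' @param batch per-cell batch labels aligned to the embedding.
#' @param shift sd of the per-batch translation.
#' @param rotate apply a random orthogonal rotation per batch.
#' @param seed integer seed.
#' @return a distorted embedding with provenance `"batch-corrupted"`.
#' @export
corrupt_embedding <- function(embedding, batch, shift = 3, rotate = TRUE,
                              seed = 1) {
  emb <- as_embedding(embedding)
  batch <- align_labels(batch, emb$cell_ids, "batch")
  set.seed(seed)
  coords <- emb$coords
  d <- ncol(coords)
  for (b in sort(unique(batch))) {
    idx <- which(batch == b)
    if (rotate) {
      q <- qr.Q(qr(matrix(rnorm(d * d), d, d)))
      coords[idx, ] <- coords[idx, , drop = FALSE] %*% q
    }
    coords[idx, ] <- sweep(coords[idx, , drop = FALSE], 2, rnorm(d, 0, shift),
                           "+")
  }
  as_embedding(coords, provenance = "batch-corrupted")
}

#' Aggregate simulated cells into spatial spots
#'
#' Mimics spot-based spatial transcriptomics: each spot's counts are the sum
#' of `cells_per_spot` sampled cells' counts (sampled without replacement
#' across the dataset), with the spot's majority cell-type annotation derived
#' from the sampled cells' planted labels and the full composition recorded.
#'
#' @param sim an `fh_sim` from [simulate_multibatch_counts()], or a list with
#'   `counts` and `truth$cell_labels`.
#' @param cells_per_spot cells aggregated per spot; default 4, the average
#'   nuclei-per-spot scale of the spatial platform being emulated.
#' @param n_spots number of spots; default uses as many whole spots as the
#'   cells allow.
#' @param seed integer seed.
#' @return list of class `fh_spots`: `counts` (gene x spot), `coords`
#'   (data.frame spot_id, x, y), `majority_celltype`, `composition` (list of
#'   member cell ids per spot, equal weights summing to 1), `truth`.
#' @export
simulate_spot_data <- function(sim, cells_per_spot = 4, n_spots = NULL,
                               seed = 1) {
  if (cells_per_spot < 1) stop("cells_per_spot must be >= 1")
  counts <- as_count_matrix(sim$counts)
  labels <- sim$truth$cell_labels
  n_cells <- ncol(counts)
  if (n_cells < cells_per_spot)
    stop("need at least cells_per_spot cells")
  if (is.null(n_spots)) n_spots <- floor(n_cells / cells_per_spot)
  if (n_spots * cells_per_spot > n_cells)
    stop("n_spots * cells_per_spot exceeds available cells")
  set.seed(seed)
  picked <- sample.int(n_cells, n_spots * cells_per_spot)
  members <- split(picked, rep(seq_len(n_spots), each = cells_per_spot))
  spot_ids <- sprintf("spot%04d", seq_len(n_spots))

  agg <- Matrix::sparseMatrix(
    i = rep(seq_len(n_spots), each = cells_per_spot),
    j = picked, x = 1, dims = c(n_spots, n_cells))
  spot_counts <- counts %*% Matrix::t(agg)
  colnames(spot_counts) <- spot_ids

  majority <- vapply(members, function(idx) {
    tab <- table(labels[colnames(counts)[idx]])
    modes <- names(tab)[tab == max(tab)]
    sort(modes)[1]                       # deterministic tie-break
  }, character(1))
  composition <- lapply(members, function(idx) {
    structure(rep(1 / length(idx), length(idx)),
              names = colnames(counts)[idx])
  })
  names(composition) <- spot_ids
  coords <- data.frame(spot_id = spot_ids,
                       x = runif(n_spots, 0, 100),
                       y = runif(n_spots, 0, 100))
  structure(list(
    counts = methods::as(spot_counts, "CsparseMatrix"),
    coords = coords,
    majority_celltype = structure(unname(majority), names = spot_ids),
    composition = composition,
    truth = list(spot_composition = composition,
                 majority_celltype = structure(unname(majority),
                                               names = spot_ids))
  ), class = "fh_spots")
}

#' Simulate a mixed single-cell / single-nucleus capture
#'
#' Emulates a dataset in which whole cells and nuclei were profiled together.
#' Cells carry a large share of their counts on a flagged ribosomal gene
#' panel; nuclei carry an elevated (but more modest) share on a flagged
#' lncRNA panel, mirroring the composition asymmetry of real sc/snRNA-seq
#' mixtures (ribosomal transcripts dominate cytoplasm; Malat1-like lncRNAs
#' are nucleus-enriched). Nuclei dominate the default mixture (80%), as in
#' preps from frozen tissue; because module scores are measured against
#' controls matched on pooled average expression, the dominant class sits
#' close to its expression-matched background and scores near zero while
#' the minority whole cells deviate strongly — the asymmetry that makes the
#' ribosomal-by-lncRNA score product split cells from nuclei at a fixed
#' threshold.
#'
#' @param config a [sim_config()]; supplies `n_genes`, cell numbers,
#'   `dispersion`, and `seed`.
#' @param ribo_fraction_cell expected ribosomal-panel share of a cell's
#'   counts (default 0.40).
#' @param lnc_fraction_nucleus expected lncRNA-panel share of a nucleus's
#'   counts (default 0.15).
#' @param ribo_fraction_nucleus,lnc_fraction_cell off-class panel shares
#'   (defaults 0.05 and 0.02).
#' @param n_ribo,n_lnc panel sizes (genes flagged in `gene_meta`).
#' @param nucleus_fraction fraction of droplets that are nuclei
#'   (default 0.8).
#' @param total_counts expected library size per cell.
#' @param seed overrides `config$seed` when given.
#' @return list of class `fh_cn_sim`: `counts`, `gene_meta` (data.frame
#'   gene, panel in ribosomal/lncRNA/none), `truth$capture_type`.
#' @export
simulate_cell_nucleus_mixture <- function(config,
                                          ribo_fraction_cell = 0.40,
                                          lnc_fraction_nucleus = 0.15,
                                          ribo_fraction_nucleus = 0.05,
                                          lnc_fraction_cell = 0.02,
                                          n_ribo = 50, n_lnc = 50,
                                          nucleus_fraction = 0.8,
                                          total_counts = 2500,
                                          seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  fr <- c(ribo_fraction_cell, lnc_fraction_nucleus,
          ribo_fraction_nucleus, lnc_fraction_cell)
  if (any(fr <= 0) || any(fr >= 1))
    stop("panel fractions must lie in (0, 1)")
  if (n_ribo < 1 || n_lnc < 1)
    stop("ribosomal and lncRNA panels must be non-empty")
  if (ribo_fraction_cell + lnc_fraction_cell >= 1 ||
      ribo_fraction_nucleus + lnc_fraction_nucleus >= 1)
    stop("panel shares within a class must sum to < 1")
  G <- config$n_genes
  if (n_ribo + n_lnc > G) stop("panels exceed n_genes")
  n_total <- sum(config$n_cells_per_batch)
  set.seed(seed %||% config$seed)

  genes <- sprintf("g%04d", seq_len(G))
  panel <- rep("none", G)
  flagged <- sample.int(G, n_ribo + n_lnc)
  panel[flagged[seq_len(n_ribo)]] <- "ribosomal"
  panel[flagged[n_ribo + seq_len(n_lnc)]] <- "lncRNA"

  capture <- rep("cell", n_total)
  capture[sample.int(n_total, round(n_total * nucleus_fraction))] <- "nucleus"
  cells <- sprintf("c%05d", seq_len(n_total))

  # within-panel gene weights (log-normal, normalized to keep shares exact
  # in expectation); identical weight law in each panel keeps the symmetric
  # design exchangeable under a panel swap
  w <- exp(rnorm(G, 0, 0.5))
  share_of <- function(is_nucleus) {
    s_ribo <- if (is_nucleus) ribo_fraction_nucleus else ribo_fraction_cell
    s_lnc <- if (is_nucleus) lnc_fraction_nucleus else lnc_fraction_cell
    s <- numeric(G)
    for (p in c("ribosomal", "lncRNA", "none")) {
      idx <- panel == p
      tot <- switch(p, ribosomal = s_ribo, lncRNA = s_lnc,
                    none = 1 - s_ribo - s_lnc)
      s[idx] <- tot * w[idx] / sum(w[idx])
    }
    s
  }
  mu <- matrix(0, G, n_total)
  mu[, capture == "cell"] <- share_of(FALSE) * total_counts
  mu[, capture == "nucleus"] <- share_of(TRUE) * total_counts
  counts <- if (config$dispersion > 0) {
    rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
  } else stats::rpois(length(mu), mu)
  counts <- Matrix::Matrix(matrix(counts, G, n_total,
                                  dimnames = list(genes, cells)),
                           sparse = TRUE)
  structure(list(
    counts = counts,
    gene_meta = data.frame(gene = genes, panel = panel),
    truth = list(capture_type = structure(capture, names = cells),
                 config = config)
  ), class = "fh_cn_sim")
}
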