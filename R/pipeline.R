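#' Default analysis parameters with provenance
#'
#' The single bundle of thresholds the pipeline runs on. Parameters tagged
#' `"published"` are the printed settings of the harmonization workflow this
#' package implements (kNN refinement and purity neighborhood sizes, forest
#' size, fold count, marker thresholds, regulon permutation settings, the
#' cell/nucleus split threshold, and the factor rank); parameters tagged
#' `"package"` are this package's own documented choices.
#'
#' @return data.frame with columns `parameter`, `value`, `provenance`.
#' @export
fibro_defaults <- function() {
  data.frame(
    parameter = c("k_refine", "k_purity", "n_trees", "n_folds", "alpha_adj",
                  "lfc_min", "wmean_times", "wmean_minsize",
                  "split_threshold", "factor_rank", "cells_per_spot",
                  "module_n_bins", "module_n_ctrl", "pseudocount",
                  "signature_n_top"),
    value = c(25, 200, 500, 10, 1e-5,
              0.5, 100, 5,
              -0.5, 15, 4,
              24, 100, 1,
              50),
    provenance = c(rep("published", 11), rep("package", 4)),
    stringsAsFactors = FALSE
  )
}

# stage registry: allowed parameter names per stage, in dependency order
pipeline_stages <- function() {
  list(
    simulate = c("n_genes", "n_cells_per_batch", "n_populations",
                 "factor_rank", "population_proportions", "batch_scale_sd",
                 "marker_spec", "dispersion", "separation", "factor_sd"),
    refine = c("k"),
    purity = c("k", "by"),
    markers = c("alpha_adj", "lfc_min", "min_frac"),
    match = character(0),
    cv = c("n_folds", "n_trees")
  )
}

#' Run the harmonization pipeline end to end
#'
#' Executes the requested stages in dependency order on a synthetic dataset
#' (`simulate` is always first), writing every stage's outputs in standard
#' text formats under `out_dir` together with a JSON manifest (stage
#' parameters, output files with MD5 checksums, timings) sufficient to
#' verify byte-identical re-runs. A JSON-lines log accompanies the manifest;
#' a one-line summary per stage goes to stderr.
#'
#' @param config list with `seed` (integer) and `stages`, a named list of
#'   per-stage parameter lists (see `names(fibroharmony:::pipeline_stages())`).
#'   Unknown stage names or parameter keys are a validation error naming the
#'   key. Stage parameters default to [fibro_defaults()].
#' @param out_dir output directory.
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  registry <- pipeline_stages()
  extra <- setdiff(names(config), c("seed", "stages"))
  if (length(extra) > 0)
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  if (is.null(config$stages) || length(config$stages) == 0)
    stop("config$stages must name at least one stage")
  unknown <- setdiff(names(config$stages), names(registry))
  if (length(unknown) > 0)
    stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  for (st in names(config$stages)) {
    bad <- setdiff(names(config$stages[[st]]), registry[[st]])
    if (length(bad) > 0)
      stop("unknown parameter key(s) for stage '", st, "': ",
           paste(bad, collapse = ", "))
  }
  if (!"simulate" %in% names(config$stages))
    stop("the 'simulate' stage is required: downstream stages run on its ",
         "outputs")
  seed <- as.integer(config$seed %||% 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log.jsonl")
  cat(NULL, file = log_path)
  log_line <- function(...) {
    rec <- list(...)
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE)
  }
  defaults <- fibro_defaults()
  dflt <- structure(defaults$value, names = defaults$parameter)

  order_run <- intersect(names(registry), names(config$stages))
  state <- list()
  manifest_stages <- list()
  for (si in seq_along(order_run)) {
    st <- order_run[si]
    p <- config$stages[[st]] %||% list()
    stage_seed <- derive_seed(seed, match(st, names(registry)))
    t0 <- proc.time()[["elapsed"]]
    outputs <- character(0)
    warnings_seen <- character(0)
    res <- withCallingHandlers(
      switch(st,
        simulate = {
          cfg <- do.call(sim_config, c(p, list(seed = stage_seed)))
          sim <- simulate_multibatch_counts(cfg)
          state$sim <- sim
          write_mtx(sim$counts, file.path(out_dir, "counts"))
          write_embedding_tsv(sim$embedding,
                              file.path(out_dir, "embedding.tsv"))
          write_labels_tsv(sim$truth$cell_labels,
                           file.path(out_dir, "labels.tsv"))
          jsonlite::write_json(
            list(marker_truth = sim$truth$marker_truth,
                 populations = cfg$populations),
            file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
          outputs <- c(file.path("counts", c("matrix.mtx", "genes.tsv",
                                             "barcodes.tsv")),
                       "embedding.tsv", "labels.tsv", "truth.json")
          sim
        },
        refine = {
          ref <- refine_labels(state$sim$embedding,
                               state$sim$truth$cell_labels,
                               k = p$k %||% dflt[["k_refine"]])
          state$refined <- ref
          write_labels_tsv(ref, file.path(out_dir, "labels_refined.tsv"))
          outputs <- "labels_refined.tsv"
          ref
        },
        purity = {
          pm <- neighbor_purity(state$sim$embedding,
                                if (identical(p$by, "batch"))
                                  state$sim$truth$batch
                                else state$sim$truth$cell_labels,
                                k = p$k %||% dflt[["k_purity"]])
          utils::write.table(as.data.frame(unclass(pm)),
                             file.path(out_dir, "purity.tsv"), sep = "\t",
                             quote = FALSE)
          outputs <- "purity.tsv"
          pm
        },
        markers = {
          labs <- state$sim$truth$cell_labels
          mk <- do.call(rbind, lapply(sort(unique(labs)), function(pop) {
            find_markers(state$sim$counts, labs, pop,
                         alpha_adj = p$alpha_adj %||% dflt[["alpha_adj"]],
                         lfc_min = p$lfc_min %||% dflt[["lfc_min"]],
                         min_frac = p$min_frac %||% 0)
          }))
          state$markers <- mk
          utils::write.table(mk, file.path(out_dir, "markers.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE)
          outputs <- "markers.tsv"
          mk
        },
        match = {
          uni <- rownames(state$sim$counts)
          ov <- jaccard_match(state$markers, state$markers, uni, uni)
          utils::write.table(ov$pairs, file.path(out_dir, "overlap.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE)
          outputs <- "overlap.tsv"
          ov
        },
        cv = {
          rep <- crossvalidate_states(
            state$sim$embedding$coords, state$sim$truth$cell_labels,
            n_folds = p$n_folds %||% dflt[["n_folds"]],
            n_trees = p$n_trees %||% dflt[["n_trees"]],
            seed = stage_seed)
          utils::write.table(as.data.frame.matrix(rep$confusion),
                             file.path(out_dir, "cv_confusion.tsv"),
                             sep = "\t", quote = FALSE)
          jsonlite::write_json(
            list(macro_balanced_accuracy = rep$macro_balanced_accuracy,
                 per_class = rep$per_class),
            file.path(out_dir, "cv_report.json"), auto_unbox = TRUE,
            digits = NA)
          outputs <- c("cv_confusion.tsv", "cv_report.json")
          rep
        }),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      error = function(e) {
        log_line(stage = st, status = "failed",
                 error = conditionMessage(e))
        stop("stage '", st, "' failed: ", conditionMessage(e),
             " (partial outputs retained in ", out_dir, ")", call. = FALSE)
      })
    elapsed <- proc.time()[["elapsed"]] - t0
    sums <- tools::md5sum(file.path(out_dir, outputs))
    manifest_stages[[st]] <- list(
      stage = st, seed = stage_seed,
      parameters = if (length(p) > 0) p else NULL,
      outputs = as.list(structure(unname(sums), names = outputs)),
      elapsed_s = round(elapsed, 3),
      warnings = as.list(warnings_seen))
    log_line(stage = st, status = "ok", elapsed_s = round(elapsed, 3),
             n_warnings = length(warnings_seen))
    message(sprintf("[%s] done in %.2fs (%d warning%s)", st, elapsed,
                    length(warnings_seen),
                    if (length(warnings_seen) == 1) "" else "s"))
  }
  manifest <- list(
    package = "fibroharmony",
    version = as.character(utils::packageVersion("fibroharmony")),
    seed = seed,
    defaults = fibro_defaults(),
    stages = unname(manifest_stages))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
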