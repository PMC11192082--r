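#' Build a weighted signature from a marker table
#'
#' Takes the top markers of one population (by adjusted p) and uses their
#' log2 fold changes as positive weights, giving a reproducible
#' marker-weighted signature that is monotone in marker strength.
#'
#' @param markers a MarkerTable (see [find_markers()]).
#' @param population population whose markers to use.
#' @param n_top number of top markers kept (default 50).
#' @param weight_col column used as the weight (default
#'   `"log2_fold_change"`).
#' @param name signature name; defaults to the population.
#' @return list of class `fh_signature`: `name`, `weights` (named numeric,
#'   all > 0).
#' @export
signature_from_markers <- function(markers, population, n_top = 50,
                                   weight_col = "log2_fold_change",
                                   name = population) {
  m <- markers[markers$population == population, , drop = FALSE]
  if (nrow(m) == 0) stop("no markers for population ", population)
  m <- m[order(m$p_adj, -m$log2_fold_change), , drop = FALSE]
  m <- m[seq_len(min(n_top, nrow(m))), , drop = FALSE]
  w <- m[[weight_col]]
  if (any(w <= 0)) stop("signature weights must be positive")
  structure(list(name = name, weights = structure(w, names = m$gene)),
            class = "fh_signature")
}

#' Marker-weighted score of spatial spots
#'
#' Scores each spot as the weighted sum of its (library-size-normalized,
#' log-transformed) expression over the signature genes — the construction
#' used to place myofibroblast and matrifibrocyte states on tissue sections.
#' Signature genes absent from the matrix are ignored; the score is linear
#' in the weight vector at fixed normalized expression.
#'
#' @param spots an `fh_spots` object (see [simulate_spot_data()]) or a
#'   gene x spot count matrix.
#' @param signature an `fh_signature`, or a named numeric weight vector.
#' @param normalize library-size-normalize + log1p before weighting
#'   (default `TRUE`); `FALSE` scores raw counts.
#' @return named numeric vector of per-spot scores.
#' @export
spot_score <- function(spots, signature, normalize = TRUE) {
  counts <- if (inherits(spots, "fh_spots")) spots$counts else spots
  counts <- as_count_matrix(counts)
  w <- if (inherits(signature, "fh_signature")) signature$weights
       else signature
  if (length(w) == 0) stop("signature has no genes")
  present <- intersect(names(w), rownames(counts))
  if (length(present) == 0)
    stop("no signature genes present in the spot matrix")
  x <- if (normalize) normalize_log(counts) else counts
  score <- as.numeric(w[present] %*% x[present, , drop = FALSE])
  structure(score, names = colnames(counts))
}

#' Keep spots whose majority cell type matches
#'
#' Restricts a spot table to spots annotated with the given majority cell
#' type (e.g. only fibroblast-majority spots before state scoring).
#'
#' @param spots an `fh_spots` object with `majority_celltype` populated.
#' @param celltype annotation to keep (default `"Fibroblast"`).
#' @return the filtered `fh_spots`; empty result is a warning, not an error.
#' @export
filter_majority <- function(spots, celltype = "Fibroblast") {
  if (is.null(spots$majority_celltype))
    stop("spot table has no majority_celltype annotation")
  keep <- which(spots$majority_celltype == celltype)
  if (length(keep) == 0)
    warning("no spots with majority cell type '", celltype, "'")
  out <- spots
  out$counts <- spots$counts[, keep, drop = FALSE]
  out$coords <- spots$coords[keep, , drop = FALSE]
  out$majority_celltype <- spots$majority_celltype[keep]
  if (!is.null(spots$composition)) out$composition <- spots$composition[keep]
  out
}

#' Bivariate quantile classes for two spot scores
#'
#' Discretizes each score into `n_levels` equal-frequency (quantile)
#' classes and assigns every spot a cell of the n x n bivariate palette,
#' the data behind a two-color spatial map of two state scores. Quantile
#' classes make the map robust to scale differences between scores.
#'
#' @param scores_a,scores_b aligned named score vectors.
#' @param coords optional data.frame with `x`, `y` (carried through for
#'   plotting).
#' @param n_levels classes per score (default 3).
#' @return data.frame of class `fh_bivariate`: `spot_id`, `class_a`,
#'   `class_b` (1 = low), `class` ("a:b"), plus coordinates when given.
#'   A constant score vector puts all spots in its lowest class, with a
#'   warning.
#' @export
bivariate_map <- function(scores_a, scores_b, coords = NULL, n_levels = 3) {
  if (length(scores_a) != length(scores_b))
    stop("score vectors must be aligned")
  classify <- function(s, tag) {
    if (diff(range(s)) == 0) {
      warning("constant ", tag, " score vector; all spots in lowest class")
      return(rep(1L, length(s)))
    }
    as.integer(ceiling(rank(s, ties.method = "first") * n_levels /
                         length(s)))
  }
  ca <- classify(scores_a, "first")
  cb <- classify(scores_b, "second")
  ids <- names(scores_a) %||% sprintf("spot%04d", seq_along(scores_a))
  out <- data.frame(spot_id = ids, class_a = ca, class_b = cb,
                    class = paste(ca, cb, sep = ":"),
                    stringsAsFactors = FALSE)
  if (!is.null(coords)) {
    out$x <- coords$x
    out$y <- coords$y
  }
  structure(out, class = c("fh_bivariate", "data.frame"),
            n_levels = n_levels)
}

#' Plot a bivariate spot map
#'
#' Renders the class assignments from [bivariate_map()] on spot
#' coordinates with an n x n two-hue palette (first score drives red,
#' second drives blue).
#'
#' @param x an `fh_bivariate` with coordinates.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fh_bivariate <- function(x, ...) {
  if (is.null(x$x)) stop("bivariate map was built without coordinates")
  n <- attr(x, "n_levels")
  pal <- grDevices::rgb((x$class_a - 1) / max(n - 1, 1), 0.2,
                        (x$class_b - 1) / max(n - 1, 1))
  graphics::plot(x$x, x$y, col = pal, pch = 16, asp = 1,
                 xlab = "x", ylab = "y", ...)
  invisible(x)
}
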