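#' Train a probabilistic cell-state classifier
#'
#' Trains a random forest (500 trees by default) on integrated
#' low-dimensional coordinates to project reference state labels onto new
#' datasets. The backend is pluggable behind a score-matrix contract: any
#' function that returns a cells x classes score matrix for new data can be
#' substituted, and all downstream metrics are backend-independent.
#'
#' @param features cells x d numeric matrix (integrated coordinates).
#' @param labels per-cell state labels (named vector or `fh_labels`).
#' @param n_trees number of trees; default 500, the published setting.
#' @param seed integer seed; training is seed-deterministic.
#' @param backend `"ranger"` (default) or a function
#'   `function(features, labels, seed)` returning an object with a
#'   `score(features)` function.
#' @return list of class `state_classifier` with `classes`, `d`, `score`
#'   (function returning a cells x classes probability matrix).
#' @export
train_state_classifier <- function(features, labels, n_trees = 500, seed = 1,
                                   backend = "ranger") {
  features <- as.matrix(features)
  if (is.null(rownames(features)))
    rownames(features) <- sprintf("c%05d", seq_len(nrow(features)))
  lab <- align_labels(labels, rownames(features))
  classes <- sort(unique(lab))
  if (length(classes) < 2)
    stop("need at least 2 label classes to train a classifier")
  small <- classes[table(factor(lab, classes)) < 2]
  if (length(small) > 0)
    stop("class(es) with fewer than 2 cells: ", paste(small, collapse = ", "))
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  if (is.function(backend)) {
    fit <- backend(features, lab, seed)
    score_fun <- fit$score
  } else if (identical(backend, "ranger")) {
    df <- data.frame(.label = factor(lab, classes), features,
                     check.names = FALSE)
    fit <- ranger::ranger(dependent.variable.name = ".label", data = df,
                          num.trees = n_trees, probability = TRUE,
                          seed = seed, num.threads = 1)
    score_fun <- function(newx) {
      colnames(newx) <- paste0("f", seq_len(ncol(newx)))
      p <- stats::predict(fit, data = as.data.frame(newx),
                          num.threads = 1)$predictions
      p[, classes, drop = FALSE]
    }
  } else stop("unknown backend")
  structure(list(classes = classes, d = ncol(features), score = score_fun,
                 n_trees = n_trees, seed = seed),
            class = "state_classifier")
}

#' Predict states with a trained classifier
#'
#' Assigns each cell the highest-scoring class (ties broken
#' lexicographically, with a message) and reports that score as the
#' prediction confidence.
#'
#' @param model a [train_state_classifier()] model.
#' @param features cells x d matrix; `d` must match training.
#' @return `fh_labels` data.frame: `cell_id`, `label`, `confidence`.
#' @export
predict_states <- function(model, features) {
  stopifnot(inherits(model, "state_classifier"))
  features <- as.matrix(features)
  if (ncol(features) != model$d)
    stop("feature dimensionality (", ncol(features),
         ") does not match training (", model$d, ")")
  if (is.null(rownames(features)))
    rownames(features) <- sprintf("q%05d", seq_len(nrow(features)))
  scores <- model$score(features)
  scores <- scores[, sort(colnames(scores)), drop = FALSE]
  best <- max.col(scores, ties.method = "first")  # columns sorted => lexicographic
  tied <- rowSums(scores == scores[cbind(seq_len(nrow(scores)), best)]) > 1
  if (any(tied))
    message(sum(tied), " prediction(s) had tied top scores; ",
            "lexicographically smallest class assigned")
  structure(data.frame(
    cell_id = rownames(features),
    label = colnames(scores)[best],
    confidence = scores[cbind(seq_len(nrow(scores)), best)],
    stringsAsFactors = FALSE
  ), class = c("fh_labels", "data.frame"))
}

#' Stratified k-fold cross-validation of state projection
#'
#' Splits cells into stratified folds, pools the out-of-fold predictions,
#' and reports per-class sensitivity, specificity, and balanced accuracy
#' (their mean), plus the confusion matrix and macro averages.
#'
#' @param features cells x d matrix.
#' @param labels per-cell labels.
#' @param n_folds number of folds; default 10, the published setting.
#'   Every class must have at least `n_folds` members.
#' @param n_trees trees per fold model (default 500).
#' @param seed integer seed controlling fold assignment and training.
#' @param backend passed to [train_state_classifier()].
#' @return list of class `cv_report`: `confusion` (truth x predicted),
#'   `per_class` (data.frame class, n, sensitivity, specificity,
#'   balanced_accuracy), `macro_balanced_accuracy`, `fold` assignment,
#'   `seed`.
#' @export
crossvalidate_states <- function(features, labels, n_folds = 10,
                                 n_trees = 500, seed = 1, backend = "ranger") {
  features <- as.matrix(features)
  if (is.null(rownames(features)))
    rownames(features) <- sprintf("c%05d", seq_len(nrow(features)))
  lab <- align_labels(labels, rownames(features))
  classes <- sort(unique(lab))
  counts <- table(factor(lab, classes))
  small <- classes[counts < n_folds]
  if (length(small) > 0)
    stop("class(es) smaller than the fold count (", n_folds, "): ",
         paste(small, collapse = ", "))
  set.seed(seed)
  fold <- integer(length(lab))
  for (cl in classes) {                  # stratified assignment
    idx <- sample(which(lab == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  pred <- character(length(lab))
  for (f in seq_len(n_folds)) {
    test <- fold == f
    model <- train_state_classifier(features[!test, , drop = FALSE],
                                    lab[!test], n_trees = n_trees,
                                    seed = derive_seed(seed, f),
                                    backend = backend)
    pred[test] <- predict_states(model, features[test, , drop = FALSE])$label
  }
  confusion <- table(truth = factor(lab, classes),
                     predicted = factor(pred, classes))
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    tp <- confusion[cl, cl]
    fn <- sum(confusion[cl, ]) - tp
    fp <- sum(confusion[, cl]) - tp
    tn <- sum(confusion) - tp - fn - fp
    sens <- tp / (tp + fn)
    spec <- tn / (tn + fp)
    data.frame(class = cl, n = tp + fn, sensitivity = sens,
               specificity = spec, balanced_accuracy = (sens + spec) / 2)
  }))
  structure(list(confusion = confusion, per_class = per_class,
                 macro_balanced_accuracy = mean(per_class$balanced_accuracy),
                 fold = structure(fold, names = rownames(features)),
                 seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Stratified cross-validation report\n")
  cat("  macro balanced accuracy:", round(x$macro_balanced_accuracy, 4), "\n")
  print(x$per_class, row.names = FALSE, digits = 4)
  invisible(x)
}
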