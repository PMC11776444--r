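# Gait / individual classification from adjacent-interval triplets: a seeded
# two-dimensional UMAP embedding of the raw (t_k, t_k+1, t_k+2) durations,
# followed by a 1000-tree random forest on the embedding coordinates.

#' Embed interval triplets in two dimensions
#'
#' Runs UMAP (uniform manifold approximation and projection) on the raw
#' triplet durations, producing the coordinates V1, V2 used for plotting and
#' classification. Single-threaded and seeded, so the embedding is
#' deterministic for a fixed input order.
#'
#' @param triplets A `triplet_table` from [make_triplets()] (raw durations;
#'   tempo differences are diagnostic of gait, so triplets are deliberately
#'   not normalized here).
#' @param n_neighbors UMAP neighborhood size (default 15).
#' @param min_dist UMAP minimum embedding distance (default 0.1).
#' @param seed Integer seed.
#' @param metric Distance metric (default `"euclidean"`).
#' @return An object of class `gait_embedding`: data frame with columns
#'   `V1`, `V2`, `individual_id`, `gait`, with the parameters and seed stored
#'   as attributes.
#' @export
embed_triplets <- function(triplets, n_neighbors = 15, min_dist = 0.1,
                           seed = 1, metric = "euclidean") {
  stopifnot(inherits(triplets, "triplet_table"))
  X <- as.matrix(triplets[, c("t1", "t2", "t3")])
  if (nrow(X) < n_neighbors + 1) {
    stop_gr("need at least n_neighbors + 1 = ", n_neighbors + 1, " triplets",
            class = "gaitrhythm_invalid_parameter")
  }
  emb <- with_seed(seed,
    uwot::umap(X, n_neighbors = n_neighbors, min_dist = min_dist,
               metric = metric, n_threads = 1, n_sgd_threads = 1,
               verbose = FALSE))
  out <- data.frame(V1 = emb[, 1], V2 = emb[, 2],
                    individual_id = triplets$individual_id,
                    gait = triplets$gait, stringsAsFactors = FALSE)
  structure(out, class = c("gait_embedding", "data.frame"),
            n_neighbors = n_neighbors, min_dist = min_dist, metric = metric,
            seed = seed)
}

#' Train a random-forest classifier on embedding coordinates
#'
#' Stratified 70/30 train/test split by the supervising label, then a
#' 1000-tree random forest on (V1, V2). Reports the out-of-bag error, the
#' OOB-based training confusion matrix, per-class one-vs-rest AUC from class
#' vote fractions, variable importance, an error-vs-trees trace, and two
#' accuracies: the pooled train+test accuracy (resubstitution on the training
#' rows, honest predictions on the test rows) and the test-only accuracy (the
#' defensible generalization metric), side by side.
#'
#' @param embedding A [embed_triplets()] result.
#' @param label `"gait"` or `"individual"` — which labelling supervises the
#'   forest.
#' @param n_trees Number of trees (default 1000).
#' @param train_fraction Fraction of rows in the training split (default 0.7,
#'   stratified by class).
#' @param seed Integer seed for the split and the forest.
#' @return An object of class `classifier_report`; see Details.
#' @export
train_classifier <- function(embedding, label = c("gait", "individual"),
                             n_trees = 1000, train_fraction = 0.7, seed = 1) {
  label <- match.arg(label)
  stopifnot(inherits(embedding, "gait_embedding"))
  y <- factor(if (label == "gait") embedding$gait else embedding$individual_id)
  if (nlevels(y) < 2L) stop_gr("need >= 2 classes",
                               class = "gaitrhythm_invalid_parameter")
  X <- as.matrix(embedding[, c("V1", "V2")])
  with_seed(seed, {
    train_idx <- sort(unlist(lapply(split(seq_along(y), y), function(idx) {
      n_tr <- max(1L, round(train_fraction * length(idx)))
      sample(idx, n_tr)
    }), use.names = FALSE))
    test_idx <- setdiff(seq_along(y), train_idx)
    if (length(test_idx) && !all(levels(y) %in% y[train_idx])) {
      stop_gr("a class is absent from the training split",
              class = "gaitrhythm_stratification")
    }
    rf <- randomForest::randomForest(X[train_idx, , drop = FALSE],
                                     y[train_idx], ntree = n_trees,
                                     importance = TRUE)
    pred_train <- predict(rf, X[train_idx, , drop = FALSE])
    votes <- matrix(NA_real_, length(y), nlevels(y),
                    dimnames = list(NULL, levels(y)))
    votes[train_idx, ] <- rf$votes[, levels(y)]  # OOB vote fractions
    pred_all <- factor(rep(NA, length(y)), levels = levels(y))
    pred_all[train_idx] <- pred_train
    if (length(test_idx)) {
      v_test <- predict(rf, X[test_idx, , drop = FALSE], type = "vote")
      votes[test_idx, ] <- v_test[, levels(y)]
      pred_all[test_idx] <- predict(rf, X[test_idx, , drop = FALSE])
    }
    accuracy <- 100 * mean(pred_all == y)
    accuracy_test <- if (length(test_idx)) {
      100 * mean(pred_all[test_idx] == y[test_idx])
    } else NA_real_
    oob <- 100 * rf$err.rate[n_trees, "OOB"]
    auc <- vapply(levels(y), function(cl) {
      auc_trapezoid(votes[, cl], y == cl)
    }, 0)
    structure(
      list(label_type = label, oob_error = unname(oob),
           confusion = rf$confusion, accuracy = accuracy,
           accuracy_test = accuracy_test, auc = auc,
           importance = rf$importance, err_trace = rf$err.rate[, "OOB"],
           votes = votes, truth = y, predicted = pred_all,
           train_idx = train_idx, test_idx = test_idx, seed = seed,
           n_trees = n_trees),
      class = "classifier_report"
    )
  })
}

# AUC of scores for a binary truth by the trapezoid rule on the ROC step
# curve; equals the Mann-Whitney statistic with tie correction
auc_trapezoid <- function(scores, positive) {
  roc <- roc_points(scores, positive)
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
}

roc_points <- function(scores, positive) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- positive[ord]
  # step at each distinct threshold
  keep <- c(diff(s) != 0, TRUE)
  tp <- cumsum(p)[keep]; fp <- cumsum(!p)[keep]
  data.frame(fpr = c(0, fp / max(1, sum(!positive))),
             tpr = c(0, tp / max(1, sum(positive))))
}

#' One-vs-rest ROC curves of a classifier report
#'
#' Builds per-class ROC curves from the report's class vote fractions (OOB
#' votes on the training rows, predicted votes on the test rows) and
#' trapezoid-rule AUCs.
#'
#' @param report A [train_classifier()] result.
#' @return Named list with one element per class, each a list with `curve`
#'   (data frame of `fpr`, `tpr`) and `auc`.
#' @export
roc_curves <- function(report) {
  stopifnot(inherits(report, "classifier_report"))
  y <- report$truth
  if (nlevels(droplevels(y)) < 2L) {
    stop_gr("AUC undefined for single-class input",
            class = "gaitrhythm_invalid_parameter")
  }
  out <- lapply(levels(y), function(cl) {
    pos <- y == cl
    list(curve = roc_points(report$votes[, cl], pos),
         auc = auc_trapezoid(report$votes[, cl], pos))
  })
  names(out) <- levels(y)
  out
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> supervised on %s (%d classes, %d trees)\n",
              x$label_type, nlevels(x$truth), x$n_trees))
  cat(sprintf("  OOB error: %.2f%%  overall accuracy (train+test): %.2f%%  test-only: %.2f%%\n",
              x$oob_error, x$accuracy, x$accuracy_test))
  cat(sprintf("  mean one-vs-rest AUC: %.3f\n", mean(x$auc)))
  invisible(x)
}
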