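#' Build a feature table from descriptor recipes
#'
#' One row per sequence, columns from a list of descriptor recipes; a
#' recipe is a list with a `representation` (passed to
#' [descriptor_vector()]) plus optional `scheme`, `property`, `k_max`,
#' `matrix_kind`. Column order is deterministic (recipes in order, each
#' recipe's features in its own order).
#'
#' @param records List of [seq_record()]s.
#' @param recipe List of recipes; the default computes edge-adjacency
#'   spectral moments of the 2D-Cartesian map up to k = 15.
#' @param labels Optional class label per record.
#' @return A `feature_table`: data.frame of features with rownames = ids,
#'   attribute `labels`.
#' @export
build_feature_table <- function(records,
                                recipe = list(list(representation = "cartesian",
                                                   k_max = 15L)),
                                labels = NULL) {
  rows <- lapply(records, function(r) {
    feats <- unlist(lapply(recipe, function(rc) {
      tryCatch(
        do.call(descriptor_vector, c(list(seq = r), rc)),
        error = function(e)
          stop(sprintf("descriptor '%s' failed for sequence '%s': %s",
                       rc$representation, r$id, conditionMessage(e))))
    }))
    feats
  })
  tab <- as.data.frame(do.call(rbind, rows))
  ids <- vapply(records, function(r) r$id, "")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sequence ids in feature table: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  rownames(tab) <- ids
  if (anyDuplicated(names(tab))) stop("duplicate feature names in recipe")
  if (any(!is.finite(as.matrix(tab)))) stop("non-finite feature values")
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(records))
    attr(tab, "labels") <- labels
  }
  class(tab) <- c("feature_table", "data.frame")
  tab
}

#' Train a simple classifier on a feature table
#'
#' `decision_tree` fits an rpart classification tree; `linear` fits a
#' logistic regression (binomial glm, ridge-free). Both are deterministic
#' given the seed.
#'
#' @param table A [build_feature_table()] result (or data.frame) with a
#'   `labels` attribute, or `labels` supplied directly.
#' @param model `"decision_tree"` or `"linear"`.
#' @param labels Class labels (two or more classes, >= 5 rows per class).
#' @param seed RNG seed for reproducibility of any internal randomness.
#' @return A `seqtopo_classifier`.
#' @export
train_classifier <- function(table, model = c("decision_tree", "linear"),
                             labels = attr(table, "labels"), seed = 1L) {
  model <- match.arg(model)
  if (is.null(labels)) stop("labels are required to train a classifier")
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("training set must contain >= 2 classes")
  if (min(table(labels)) < 5) stop("need >= 5 rows per class")
  df <- as.data.frame(table)
  feat_names <- names(df)
  df$.label <- labels
  fit <- with_seed(seed, {
    if (model == "decision_tree") {
      rpart::rpart(.label ~ ., data = df, method = "class",
                   control = rpart::rpart.control(minsplit = 5, cp = 0.01))
    } else {
      if (nlevels(labels) != 2)
        stop("linear model supports two classes")
      stats::glm(.label ~ ., data = df, family = stats::binomial())
    }
  })
  structure(list(model = model, fit = fit, classes = levels(labels),
                 features = feat_names, seed = seed),
            class = "seqtopo_classifier")
}

#' Predict classes and scores from a fitted classifier
#'
#' @param object A [train_classifier()] fit.
#' @param newdata Feature table with the training columns.
#' @param ... Unused.
#' @return data.frame with `class` and `score` (continuous score for the
#'   second class level, i.e. the positive class when labels are
#'   negative/positive).
#' @export
predict.seqtopo_classifier <- function(object, newdata, ...) {
  df <- as.data.frame(newdata)[, object$features, drop = FALSE]
  if (object$model == "decision_tree") {
    prob <- predict(object$fit, df, type = "prob")
    score <- prob[, object$classes[length(object$classes)]]
    cls <- as.character(predict(object$fit, df, type = "class"))
  } else {
    score <- predict(object$fit, df, type = "response")
    cls <- object$classes[(score >= 0.5) + 1L]
  }
  data.frame(class = cls, score = as.numeric(score),
             row.names = rownames(df))
}

#' AUROC as the Mann-Whitney rank statistic
#'
#' P(score of a random positive > score of a random negative), ties
#' counted 1/2; computed from ranks.
#'
#' @param scores Numeric scores.
#' @param labels Logical or two-level labels; `positive` names the
#'   positive level (default: second factor level, or `TRUE`).
#' @param positive Positive class value.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels, positive = NULL) {
  if (is.logical(labels)) pos <- labels
  else {
    f <- factor(labels)
    if (is.null(positive)) positive <- levels(f)[nlevels(f)]
    pos <- f == positive
  }
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("need both classes to compute AUROC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a classifier: accuracy, sensitivity, specificity, AUROC
#'
#' @param predictions Output of [predict.seqtopo_classifier()].
#' @param labels True labels; the positive class is the second level.
#' @param positive Positive class value.
#' @return Named numeric vector.
#' @export
evaluate_predictions <- function(predictions, labels, positive = NULL) {
  f <- factor(labels)
  if (is.null(positive)) positive <- levels(f)[nlevels(f)]
  truth <- f == positive
  call_pos <- predictions$class == positive
  c(accuracy = mean(call_pos == truth),
    sensitivity = if (any(truth)) mean(call_pos[truth]) else NA_real_,
    specificity = if (any(!truth)) mean(!call_pos[!truth]) else NA_real_,
    auroc = auroc(predictions$score, truth))
}

#' Cross-validated AUROC of a classifier recipe
#'
#' Stratified k-fold cross-validation; folds are drawn once from the
#' given seed, the model is refitted on each training split and scored on
#' the held-out split, and the AUROC is computed over the pooled
#' out-of-fold scores.
#'
#' @param table Feature table.
#' @param labels Class labels.
#' @param model Classifier type, see [train_classifier()].
#' @param folds Number of folds.
#' @param seed RNG seed for the fold assignment.
#' @return List with `auroc` and the out-of-fold `scores`.
#' @export
cv_auroc <- function(table, labels, model = "decision_tree", folds = 5L,
                     seed = 1L) {
  labels <- factor(labels)
  n <- nrow(table)
  fold_of <- integer(n)
  with_seed(seed, {
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      fold_of[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  scores <- numeric(n)
  for (f in seq_len(folds)) {
    test <- fold_of == f
    fit <- train_classifier(table[!test, , drop = FALSE], model,
                            labels = labels[!test], seed = seed + f)
    scores[test] <- predict(fit, table[test, , drop = FALSE])$score
  }
  list(auroc = auroc(scores, labels), scores = scores, folds = fold_of)
}

# ---- combined AB + AF scoring -----------------------------------------

#' Fit a weighted combined similarity scorer
#'
#' Combines several pairwise similarity measures into one score: each
#' measure is min-max normalized to [0, 1] using its training range, and
#' the weights reflect the discriminatory ability of each measure on the
#' training pairs: alpha_j proportional to max(AUC_j - 0.5, 0), where
#' AUC_j is the AUROC of measure j for separating homolog from
#' non-homolog pairs (uniform weights as fallback when no measure beats
#' chance). Degenerate (constant) measures get weight 0 with a warning.
#'
#' @param measures data.frame or matrix, one column per similarity
#'   measure, one row per training pair.
#' @param labels Logical (TRUE = homolog) or two-level labels per pair.
#' @return A `combined_scorer`: `weights`, `ranges` (min/max per measure),
#'   `auc` per measure.
#' @export
fit_combined_scorer <- function(measures, labels) {
  measures <- as.data.frame(measures)
  if (ncol(measures) < 2) stop("need at least two measures to combine")
  if (is.logical(labels)) pos <- labels
  else { f <- factor(labels); pos <- f == levels(f)[nlevels(f)] }
  ranges <- lapply(measures, range)
  auc <- vapply(measures, function(m) auroc(m, pos), numeric(1))
  degenerate <- vapply(ranges, function(r) diff(r) == 0, logical(1))
  raw_w <- pmax(auc - 0.5, 0)
  if (any(degenerate)) {
    warning(sprintf("degenerate constant measure(s) given weight 0: %s",
                    paste(names(measures)[degenerate], collapse = ", ")))
    raw_w[degenerate] <- 0
  }
  weights <- if (sum(raw_w) > 0) raw_w / sum(raw_w)
             else rep(1 / sum(!degenerate), ncol(measures)) * !degenerate
  structure(list(weights = weights, ranges = ranges, auc = auc,
                 measures = names(measures)),
            class = "combined_scorer")
}

#' Combined similarity score of new measure values
#'
#' @param scorer A [fit_combined_scorer()] fit.
#' @param measures data.frame/matrix with the scorer's measure columns
#'   (or a single named numeric vector for one pair).
#' @return Numeric combined scores in [0, 1] (training-range clamped).
#' @export
combined_score <- function(scorer, measures) {
  if (is.null(dim(measures))) measures <- as.data.frame(as.list(measures))
  measures <- as.data.frame(measures)[, scorer$measures, drop = FALSE]
  norm <- mapply(function(col, r) {
    if (diff(r) == 0) rep(0, length(col))
    else pmin(1, pmax(0, (col - r[1]) / (r[2] - r[1])))
  }, measures, scorer$ranges)
  if (is.null(dim(norm))) norm <- matrix(norm, nrow = 1)
  as.numeric(norm %*% scorer$weights)
}

#' k-NN classification over a combined similarity
#'
#' Convenience classifier: a query is labeled by majority vote of its k
#' most similar references under the combined score (distance =
#' 1 - combined similarity).
#'
#' @param scorer A [fit_combined_scorer()] fit.
#' @param ref_measures Measures for the query-vs-reference pairs: a matrix
#'   with one row per reference, columns = scorer measures.
#' @param ref_labels Label of each reference.
#' @param k Neighborhood size (default 5).
#' @return List with `label` (majority vote) and `mean_similarity` of the
#'   k neighbors.
#' @export
knn_combined <- function(scorer, ref_measures, ref_labels, k = 5L) {
  sim <- combined_score(scorer, ref_measures)
  k <- min(k, length(sim))
  top <- order(sim, decreasing = TRUE)[seq_len(k)]
  votes <- table(ref_labels[top])
  list(label = names(votes)[which.max(votes)],
       mean_similarity = mean(sim[top]))
}

# ---- ensemble voting ---------------------------------------------------

#' Consensus over several predictors' calls
#'
#' Combines per-sequence positive/negative calls from multiple predictors
#' under a voting rule, and reports the Venn-style agreement structure
#' between predictors (per-subset intersection counts).
#'
#' @param votes data.frame or matrix of logicals (or "positive"/"negative"
#'   strings), rows = sequences, columns = predictors (>= 2); all
#'   predictors must cover the same sequences (no NA).
#' @param rule `"unanimous"` (all positive), `"majority"` (strict
#'   majority) or `"weighted"` (sum of positive predictors' weights
#'   > 0.5).
#' @param weights Predictor weights for the weighted rule (normalized to
#'   sum 1).
#' @return List with `consensus` (logical per sequence) and `agreement`
#'   (data.frame: predictor-set pattern, count), plus `per_predictor`
#'   positive counts.
#' @export
ensemble_vote <- function(votes, rule = c("unanimous", "majority",
                                          "weighted"), weights = NULL) {
  rule <- match.arg(rule)
  votes <- as.data.frame(votes)
  if (ncol(votes) < 2) stop("ensemble voting needs >= 2 predictors")
  v <- as.matrix(as.data.frame(lapply(votes, function(col) {
    if (is.logical(col)) col
    else col == "positive"
  })))
  if (any(is.na(v))) stop("predictors must cover the same sequence set")
  consensus <- switch(rule,
    unanimous = rowSums(v) == ncol(v),
    majority = rowSums(v) > ncol(v) / 2,
    weighted = {
      if (is.null(weights)) weights <- rep(1, ncol(v))
      weights <- weights / sum(weights)
      as.vector(v %*% weights) > 0.5
    })
  pattern <- apply(v, 1, function(r)
    paste(colnames(v)[r], collapse = "&"))
  pattern[pattern == ""] <- "(none)"
  agreement <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(agreement) <- c("predictors", "count")
  list(consensus = stats::setNames(consensus, rownames(votes)),
       agreement = agreement,
       per_predictor = colSums(v))
}
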