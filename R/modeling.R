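#' Youden-J optimal decision threshold
#'
#' Evaluates J = TPR - FPR at every distinct score treated as a candidate
#' cut (predict positive when score >= cut) and returns the cut maximizing
#' J, ties broken toward the largest cut. With constant scores J is zero
#' everywhere; the constant is returned with a warning.
#'
#' @param oof_scores out-of-fold probability scores.
#' @param labels binary 0/1 labels.
#' @return the selected threshold.
#' @export
youden_threshold <- function(oof_scores, labels) {
  stopifnot(length(oof_scores) == length(labels))
  labels <- as.integer(as.character(labels))
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  cuts <- sort(unique(oof_scores))
  if (length(cuts) == 1L) {
    warning("constant scores: J = 0 at every cut; returning the constant")
    return(cuts)
  }
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  j <- vapply(cuts, function(cut) {
    pred <- oof_scores >= cut
    sum(pred & labels == 1L) / n_pos - sum(pred & labels == 0L) / n_neg
  }, numeric(1))
  best <- max(j)
  max(cuts[j >= best - 1e-12])
}

# Rank-based AUC-ROC (equivalent to the trapezoidal area under the ROC with
# tie-averaged ranks); 0.5 for constant scores.
auc_roc_score <- function(scores, labels) {
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Average precision (step-wise area under the precision-recall curve),
# grouping tied scores. Equals prevalence exactly for a constant classifier.
auc_pr_score <- function(scores, labels) {
  n1 <- sum(labels == 1L)
  if (n1 == 0L || all(labels == 1L)) return(NA_real_)
  lev <- sort(unique(scores), decreasing = TRUE)
  tp <- 0; fp <- 0; ap <- 0
  for (s in lev) {
    sel <- scores == s
    tp_new <- tp + sum(labels[sel] == 1L)
    fp_new <- fp + sum(labels[sel] == 0L)
    prec <- tp_new / (tp_new + fp_new)
    ap <- ap + (tp_new - tp) / n1 * prec
    tp <- tp_new; fp <- fp_new
  }
  ap
}

#' Evaluate probability scores against binary labels
#'
#' Thresholded metrics (balanced accuracy, sensitivity, specificity, F1,
#' MCC; positive prediction when score >= threshold) plus the threshold-free
#' AUC-ROC and AUCPR (average precision). With one class absent the AUC
#' metrics are NA while the thresholded metrics are computed against the
#' class that is present.
#'
#' @param scores probability scores.
#' @param labels binary 0/1 labels.
#' @param threshold decision threshold (default 0.5).
#' @return list with \code{balanced_accuracy, sensitivity, specificity, f1,
#'   mcc, auc_roc, auc_pr, n_pos, n_neg, prevalence}.
#' @export
evaluate_predictions <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(as.character(labels))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L); tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L); fn <- sum(pred == 0L & labels == 1L)
  n_pos <- tp + fn; n_neg <- tn + fp
  sens <- if (n_pos > 0L) tp / n_pos else NA_real_
  spec <- if (n_neg > 0L) tn / n_neg else NA_real_
  f1 <- if (2 * tp + fp + fn > 0L) 2 * tp / (2 * tp + fp + fn) else 0
  mcc_den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den > 0) (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den else 0
  list(balanced_accuracy = mean(c(sens, spec), na.rm = TRUE),
       sensitivity = sens, specificity = spec, f1 = f1, mcc = mcc,
       auc_roc = auc_roc_score(scores, labels),
       auc_pr = auc_pr_score(scores, labels),
       n_pos = n_pos, n_neg = n_neg,
       prevalence = n_pos / (n_pos + n_neg))
}

# Stratified fold assignment: shuffles within each class under the current
# RNG state and deals fold ids round-robin.
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# Random oversampling of the minority class (with replacement) to parity,
# returning row indices into the training subset. Applied inside training
# folds only, never to validation folds.
oversample_indices <- function(labels) {
  tab <- table(labels)
  if (length(tab) < 2L) return(seq_along(labels))
  minority <- names(tab)[which.min(tab)]
  n_extra <- max(tab) - min(tab)
  extra <- sample(which(labels == minority), n_extra, replace = TRUE)
  c(seq_along(labels), extra)
}

rf_hyperparameter_grid <- function() {
  expand.grid(num_trees = c(100L, 300L, 500L),
              max_depth = c(0L, 10L, 20L),           # 0 = unlimited
              min_node_size = c(2L, 5L, 10L),
              mtry_rule = c("sqrt", "log2"),
              stringsAsFactors = FALSE)
}

rf_fit <- function(x, y, hp, seed) {
  mtry <- switch(hp$mtry_rule,
                 sqrt = max(1L, floor(sqrt(ncol(x)))),
                 log2 = max(1L, floor(log2(ncol(x)))))
  ranger::ranger(x = x, y = factor(y, levels = c(0L, 1L)),
                 num.trees = hp$num_trees, mtry = min(mtry, ncol(x)),
                 max.depth = hp$max_depth, min.node.size = hp$min_node_size,
                 probability = TRUE, seed = seed, num.threads = 1L,
                 verbose = FALSE)
}

rf_predict <- function(fit, x) {
  pr <- stats::predict(fit, data = x, num.threads = 1L)$predictions
  pr[, "1"]
}

# Mean out-of-fold AUC-ROC of one configuration under stratified CV with
# in-fold oversampling; the scoring routine of the halving search.
cv_config_score <- function(x, y, hp, n_folds, seed) {
  fold <- stratified_folds(y, n_folds)
  oof <- numeric(length(y))
  for (f in seq_len(n_folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    os <- oversample_indices(y[tr])
    fit <- rf_fit(x[tr[os], , drop = FALSE], y[tr[os]], hp, seed + f)
    oof[te] <- rf_predict(fit, x[te, , drop = FALSE])
  }
  list(auc = auc_roc_score(oof, y), oof = oof)
}

#' Train a Random-Forest model with halving search and threshold optimization
#'
#' Hyperparameters are chosen by a successive-halving random search over a
#' fixed grid (trees 100/300/500; depth unlimited/10/20; minimum node size
#' 2/5/10; mtry sqrt/log2): a seeded sample of candidate configurations is
#' scored by stratified cross-validated AUC-ROC on growing stratified
#' fractions of the training data (1/4, 1/2, full), keeping the better half
#' at each rung. The minority class is randomly oversampled with replacement
#' inside each training fold only, so validation folds never contain
#' duplicated rows. The winning configuration is refit per fold to produce
#' out-of-fold probabilities for every training compound, the decision
#' threshold is set by [youden_threshold()] on those probabilities, and the
#' final model is refit on the full (oversampled) training data.
#'
#' @param fm feature matrix (rows keyed by compound).
#' @param labels data.frame with \code{key} and binary \code{label}.
#' @param seed integer seed controlling folds, sampling and forests.
#' @param n_folds number of stratified folds (default 5).
#' @param n_candidates configurations sampled for the halving search.
#' @return object of class \code{dictox_model}: \code{space_tag},
#'   \code{estimator}, \code{threshold}, \code{hyperparameters},
#'   \code{training_keys}, \code{seed}, \code{oof_scores},
#'   \code{oof_labels}, \code{feature_names}.
#' @export
cv_train <- function(fm, labels, seed = 1L, n_folds = 5L, n_candidates = 8L) {
  stopifnot(is.matrix(fm), is.data.frame(labels),
            all(c("key", "label") %in% names(labels)))
  lab <- labels[!is.na(labels$label), ]
  keys <- intersect(rownames(fm), lab$key)
  if (length(keys) < n_folds) stop("fewer compounds than folds")
  y <- as.integer(lab$label[match(keys, lab$key)])
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  if (min(table(y)) < 2L * n_folds) {
    stop("need at least ", 2L * n_folds, " compounds per class")
  }
  x <- fm[keys, , drop = FALSE]
  set.seed(seed)
  grid <- rf_hyperparameter_grid()
  cand <- grid[sample.int(nrow(grid), min(n_candidates, nrow(grid))), , drop = FALSE]
  fractions <- c(0.25, 0.5, 1)
  for (r in seq_along(fractions)) {
    if (nrow(cand) == 1L) break
    frac <- fractions[r]
    sub <- if (frac < 1) {
      unlist(lapply(unique(y), function(cl) {
        idx <- which(y == cl)
        sort(sample(idx, max(2L * n_folds, ceiling(frac * length(idx)))))
      }))
    } else seq_along(y)
    scores <- vapply(seq_len(nrow(cand)), function(i) {
      cv_config_score(x[sub, , drop = FALSE], y[sub], cand[i, ],
                      n_folds, seed = seed + 100L * r)$auc
    }, numeric(1))
    keep <- order(scores, decreasing = TRUE)[seq_len(max(1L, ceiling(nrow(cand) / 2)))]
    cand <- cand[keep, , drop = FALSE]
    if (frac == 1) { cand <- cand[1L, , drop = FALSE]; break }
  }
  best <- cand[1L, , drop = FALSE]
  oof <- cv_config_score(x, y, best, n_folds, seed = seed + 1000L)$oof
  names(oof) <- keys
  threshold <- youden_threshold(oof, y)
  os <- oversample_indices(y)
  final <- rf_fit(x[os, , drop = FALSE], y[os], best, seed = seed)
  structure(list(space_tag = attr(fm, "space_tag") %||% "composite",
                 estimator = final, threshold = threshold,
                 hyperparameters = as.list(best),
                 training_keys = keys, seed = seed,
                 oof_scores = oof, oof_labels = y,
                 feature_names = colnames(fm)),
            class = "dictox_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dictox_model <- function(x, ...) {
  cat("dictox Random-Forest model\n",
      "  feature space: ", x$space_tag, "\n",
      "  training compounds: ", length(x$training_keys), "\n",
      "  decision threshold (Youden J): ", format(x$threshold, digits = 4), "\n",
      "  trees: ", x$hyperparameters$num_trees,
      ", max depth: ", x$hyperparameters$max_depth,
      ", min node: ", x$hyperparameters$min_node_size,
      ", mtry: ", x$hyperparameters$mtry_rule, "\n", sep = "")
  invisible(x)
}

# Probability scores of a fitted model on a feature matrix, checking the
# feature schema.
model_scores <- function(model, fm, keys = rownames(fm)) {
  stopifnot(inherits(model, "dictox_model"))
  if (!identical(colnames(fm), model$feature_names)) {
    stop("feature schema mismatch with training features for space ",
         model$space_tag)
  }
  missing <- setdiff(keys, rownames(fm))
  if (length(missing)) {
    stop("missing feature space '", model$space_tag, "' for key(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  rf_predict(model$estimator, fm[keys, , drop = FALSE])
}

#' Rescale a probability against a model's decision threshold
#'
#' Piecewise-linear map sending the threshold t to 0.5: s = p/(2t) for
#' p <= t, else 0.5 + (p - t) / (2 (1 - t)). Used by the soft-voting
#' ensemble so that each member votes relative to its own operating point.
#'
#' @param p probability in \[0, 1\].
#' @param t decision threshold in (0, 1).
#' @return rescaled score in \[0, 1\].
#' @export
threshold_rescale <- function(p, t) {
  t <- min(max(t, 1e-9), 1 - 1e-9)
  ifelse(p <= t, 0.5 * p / t, 0.5 + 0.5 * (p - t) / (1 - t))
}

#' Soft-voting ensemble prediction
#'
#' Each member model scores the compounds in its own feature space; scores
#' are rescaled with [threshold_rescale()] (so each model's threshold maps
#' to 0.5) and averaged. A compound is predicted toxic when the ensemble
#' score is at least 0.5.
#'
#' @param models list of \code{dictox_model} objects.
#' @param features_by_space named list of feature matrices, one per member
#'   space tag, each covering all \code{keys}.
#' @param keys compounds to score.
#' @return data.frame \code{key, score, label}.
#' @export
ensemble_predict <- function(models, features_by_space, keys) {
  stopifnot(length(models) >= 1L)
  scaled <- vapply(models, function(m) {
    fm <- features_by_space[[m$space_tag]]
    if (is.null(fm)) stop("missing feature space '", m$space_tag, "'")
    threshold_rescale(model_scores(m, fm, keys), m$threshold)
  }, numeric(length(keys)))
  if (length(keys) == 1L) scaled <- matrix(scaled, nrow = 1)
  score <- rowMeans(scaled)
  data.frame(key = keys, score = score, label = as.integer(score >= 0.5),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Applicability-domain report by nearest-neighbor similarity binning
#'
#' For each test compound, computes the maximum Tanimoto similarity to a
#' training compound of the same true label, then groups the test set into
#' five similarity bins ([0,0.2), [0.2,0.4), [0.4,0.6), [0.6,0.8),
#' [0.8,1.0]) and reports per-bin n, balanced accuracy (at the model's
#' threshold) and AUCPR (NA for single-class bins).
#'
#' @param test_keys held-out compound identifiers.
#' @param model a \code{dictox_model}.
#' @param fingerprints structure-space feature matrix covering test and
#'   training compounds (used for similarity).
#' @param labels data.frame with \code{key} and binary \code{label}.
#' @param fm feature matrix used to score the test compounds (defaults to
#'   \code{fingerprints}, i.e. a structure-space model).
#' @return list with \code{bins} (edge vector) and \code{per_bin}
#'   data.frame (\code{bin, lo, hi, n, balanced_accuracy, auc_pr}), plus the
#'   per-compound \code{similarity} vector.
#' @export
ad_report <- function(test_keys, model, fingerprints, labels, fm = fingerprints) {
  stopifnot(all(test_keys %in% rownames(fingerprints)))
  lab <- labels[!is.na(labels$label), ]
  y <- as.integer(lab$label[match(test_keys, lab$key)])
  train_keys <- intersect(model$training_keys, rownames(fingerprints))
  train_y <- as.integer(lab$label[match(train_keys, lab$key)])
  sims <- vapply(seq_along(test_keys), function(i) {
    pool <- train_keys[train_y == y[i]]
    if (length(pool) == 0L) {
      stop("no training compounds with label ", y[i], " for similarity")
    }
    max(tanimoto_matrix(fingerprints[test_keys[i], , drop = FALSE],
                        fingerprints[pool, , drop = FALSE]))
  }, numeric(1))
  scores <- model_scores(model, fm, test_keys)
  edges <- seq(0, 1, by = 0.2)
  bin <- pmin(findInterval(sims, edges, rightmost.closed = TRUE), 5L)
  per_bin <- do.call(rbind, lapply(1:5, function(b) {
    sel <- bin == b
    if (!any(sel)) {
      return(data.frame(bin = b, lo = edges[b], hi = edges[b + 1], n = 0L,
                        balanced_accuracy = NA_real_, auc_pr = NA_real_))
    }
    ev <- evaluate_predictions(scores[sel], y[sel], model$threshold)
    data.frame(bin = b, lo = edges[b], hi = edges[b + 1], n = sum(sel),
               balanced_accuracy = ev$balanced_accuracy,
               auc_pr = if (is.na(ev$auc_pr)) NA_real_ else ev$auc_pr)
  }))
  list(bins = edges, per_bin = per_bin,
       similarity = stats::setNames(sims, test_keys))
}

#' Score unlabeled compounds
#'
#' Emits probability scores and thresholded labels for compounds without
#' ground truth (e.g. ambiguous-concern compounds). Overlap with the
#' training set is flagged with a message but predictions are still emitted.
#'
#' @param model a \code{dictox_model}.
#' @param fm feature matrix for the compounds to score.
#' @return data.frame \code{key, score, label}.
#' @export
predict_unlabeled <- function(model, fm) {
  keys <- rownames(fm)
  if (length(keys) == 0L) {
    return(data.frame(key = character(), score = numeric(), label = integer()))
  }
  overlap <- intersect(keys, model$training_keys)
  if (length(overlap)) {
    message("predict_unlabeled: ", length(overlap),
            " compound(s) overlap the training set")
  }
  score <- model_scores(model, fm, keys)
  data.frame(key = keys, score = score,
             label = as.integer(score >= model$threshold),
             stringsAsFactors = FALSE, row.names = NULL)
}
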