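# PCA with scree-based component retention, class-weighted SVM training,
# projection of held-out sequences, and evaluation (ROC/AUC, length bins).

#' Mean-centred PCA of an RSCU feature matrix
#'
#' Principal component analysis of per-sequence (or per-species) RSCU
#' vectors, mean-centred but not scaled (RSCU values already share a common
#' scale). Component signs are fixed so that each component's
#' largest-magnitude loading is positive, making results deterministic.
#'
#' @param matrix Numeric matrix, rows = sequences/species, feature columns
#'   (typically the 59 canonical codons).
#' @param max_k Maximum number of components the scree rule may retain.
#' @return An object of class `rscu_pca`: `loadings` (orthonormal columns),
#'   `center`, `scores` (training projections), `explained_variance`
#'   (fractions, non-increasing), `k_retained`.
#' @export
fit_pca <- function(matrix, max_k = 10L) {
  stopifnot(nrow(matrix) >= 2L)
  if (all(abs(sweep(matrix, 2, colMeans(matrix))) < 1e-12)) {
    stop("no variance: constant feature matrix")
  }
  pc <- stats::prcomp(matrix, center = TRUE, scale. = FALSE)
  # sign convention: largest-|loading| entry positive per component
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(loadings = rot,
         center = pc$center,
         scores = scores,
         explained_variance = ev,
         k_retained = scree_retain(ev, max_k = max_k)),
    class = "rscu_pca"
  )
}

#' @export
print.rscu_pca <- function(x, ...) {
  cat(sprintf("rscu_pca: %d components, %d retained (%.1f%% variance)\n",
              ncol(x$loadings), x$k_retained,
              100 * sum(x$explained_variance[seq_len(x$k_retained)])))
  invisible(x)
}

#' Project new vectors onto a fitted PCA
#'
#' Applies the training-set centring and loadings to new RSCU vectors.
#'
#' @param pca An `rscu_pca`.
#' @param matrix Numeric matrix with the same feature columns as training.
#' @param k Number of components (default: the retained set).
#' @return Score matrix, rows matching `matrix`.
#' @export
project_pca <- function(pca, matrix, k = pca$k_retained) {
  if (ncol(matrix) != length(pca$center)) {
    stop("dimension mismatch: ", ncol(matrix), " features vs ",
         length(pca$center), " in the PCA")
  }
  sweep(matrix, 2, pca$center) %*% pca$loadings[, seq_len(k), drop = FALSE]
}

#' Scree-rule component retention
#'
#' Operationalises the scree elbow as the point of maximal curvature of the
#' explained-variance profile: the elbow index is the interior component at
#' which the second difference (acceleration) of the profile is maximal,
#' and all components before the elbow are retained. A flat profile has no
#' elbow and retains one component with a warning.
#'
#' @param explained_variance Non-increasing variance fractions.
#' @param max_k Upper bound on the retained count (default 10).
#' @return Integer `k_retained` (at least 1).
#' @examples
#' scree_retain(c(0.9, 0.05, 0.03, 0.02))        # 1
#' scree_retain(c(0.4, 0.3, 0.2, 0.05, 0.05))    # 3
#' @export
scree_retain <- function(explained_variance, max_k = 10L) {
  ev <- explained_variance
  m <- length(ev)
  if (m < 3L) return(1L)
  interior <- 2:(m - 1L)
  accel <- ev[interior - 1L] - 2 * ev[interior] + ev[interior + 1L]
  if (max(accel) < 1e-12) {
    warning("no elbow in the variance profile; retaining 1 component")
    return(1L)
  }
  k <- interior[which.max(accel)] - 1L
  max(1L, min(k, as.integer(max_k)))
}

#' Train a class-weighted SVM on PCA scores
#'
#' Fits a C-classification support vector machine (radial kernel by
#' default) on PCA scores with class weights inversely proportional to
#' class frequency, tuning cost and kernel width by grid search under
#' k-fold cross-validation, and reports the fold-wise accuracy of the
#' selected model.
#'
#' @param scores Numeric matrix of PCA scores (rows = sequences).
#' @param labels Factor or character vector of class labels.
#' @param folds Cross-validation folds (default 5).
#' @param seed Integer seed; training is deterministic given the seed.
#' @param cost_grid,gamma_grid Tuning grids; defaults
#'   `c(0.1, 1, 10, 100)` and `c(0.001, 0.01, 0.1, 1)`.
#' @param kernel Kernel for [e1071::svm()]; default `"radial"`.
#' @return An object of class `domain_model`: the fitted `svm` (with
#'   probability model), `classes`, `class_weights`, `tuned` (cost, gamma),
#'   `cv_accuracy` (fold-wise) and `cv_accuracy_mean`, plus `pca` if
#'   supplied via [train_domain_classifier()].
#' @export
train_classifier <- function(scores, labels, folds = 5L, seed = 1L,
                             cost_grid = c(0.1, 1, 10, 100),
                             gamma_grid = c(0.001, 0.01, 0.1, 1),
                             kernel = "radial") {
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 classes to train")
  stopifnot(nrow(scores) >= folds)
  tab <- table(labels)
  weights <- as.numeric(sum(tab) / (nlevels(labels) * tab))
  names(weights) <- names(tab)
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  set.seed(as.integer(seed))
  cv_acc <- vapply(seq_len(nrow(grid)), function(i) {
    fit <- e1071::svm(scores, labels, type = "C-classification",
                      kernel = kernel, cost = grid$cost[i],
                      gamma = grid$gamma[i], class.weights = weights,
                      cross = folds, scale = FALSE)
    mean(fit$accuracies) / 100
  }, 0)
  best <- which.max(cv_acc)  # ties: first (smallest cost, then gamma)
  set.seed(as.integer(seed))
  final <- e1071::svm(scores, labels, type = "C-classification",
                      kernel = kernel, cost = grid$cost[best],
                      gamma = grid$gamma[best], class.weights = weights,
                      probability = TRUE, cross = folds, scale = FALSE)
  structure(
    list(svm = final,
         classes = levels(labels),
         class_weights = weights,
         kernel = kernel,
         tuned = list(cost = grid$cost[best], gamma = grid$gamma[best]),
         tuning = cbind(grid, cv_accuracy = cv_acc),
         cv_accuracy = final$accuracies / 100,
         cv_accuracy_mean = mean(final$accuracies) / 100,
         pca = NULL,
         seed = as.integer(seed)),
    class = "domain_model"
  )
}

#' @export
print.domain_model <- function(x, ...) {
  cat(sprintf(
    "domain_model (%s SVM): classes %s; cost %g, gamma %g; CV accuracy %.3f\n",
    x$kernel, paste(x$classes, collapse = "/"),
    x$tuned$cost, x$tuned$gamma, x$cv_accuracy_mean))
  invisible(x)
}

#' Fit PCA and SVM from an RSCU matrix in one step
#'
#' Convenience wrapper: fits the PCA on the training RSCU matrix, retains
#' `k` components (scree rule by default), and trains the class-weighted
#' SVM on the scores. The returned model carries its paired PCA, so
#' held-out sequences are projected with the training loadings.
#'
#' @param rscu Numeric training matrix (rows = sequences, canonical codon
#'   columns, or any fixed feature set such as the six arginine codons).
#' @param labels Class labels, one per row.
#' @param k Components to retain; `NULL` (default) uses the scree rule,
#'   floored at `k_min`.
#' @param k_min Minimum retention when `k` is `NULL`; default 3. The first
#'   component of an RSCU matrix tracks GC content, and the taxonomic
#'   signal sits in the next components, so per-sequence domain
#'   classification keeps at least the first three.
#' @param ... Passed to [train_classifier()].
#' @return A `domain_model` with `pca` attached.
#' @export
train_domain_classifier <- function(rscu, labels, k = NULL, k_min = 3L, ...) {
  pca <- fit_pca(rscu)
  pca$k_retained <- if (!is.null(k)) as.integer(k)
                    else min(max(pca$k_retained, as.integer(k_min)),
                             ncol(pca$loadings))
  model <- train_classifier(
    project_pca(pca, rscu, k = pca$k_retained), labels, ...)
  model$pca <- pca
  model
}

#' Predict domains for new RSCU vectors
#'
#' Projects the vectors with the model's training PCA and applies the SVM.
#' Class probabilities sum to 1 per sequence; the reported label is the
#' probability argmax with alphabetical tie-break.
#'
#' @param object A `domain_model` with `pca` attached (see
#'   [train_domain_classifier()]), or pass `pca` explicitly.
#' @param rscu Numeric matrix in the model's feature order, or a
#'   pre-projected score matrix when `projected = TRUE`.
#' @param pca Optional `rscu_pca` overriding `object$pca`.
#' @param projected Set `TRUE` if `rscu` already contains PCA scores.
#' @param ... Unused.
#' @return A list: `labels` (factor), `probabilities` (matrix, columns in
#'   alphabetical class order), `scores` (the projected coordinates).
#' @export
predict.domain_model <- function(object, rscu, pca = object$pca,
                                 projected = FALSE, ...) {
  scores <- if (projected) rscu else {
    if (is.null(pca)) stop("no PCA attached to the model; supply `pca`")
    project_pca(pca, rscu)
  }
  pred <- stats::predict(object$svm, scores, probability = TRUE)
  prob <- attr(pred, "probabilities")
  prob <- prob[, sort(colnames(prob)), drop = FALSE]
  lab <- factor(colnames(prob)[max.col(prob, ties.method = "first")],
                levels = object$classes)
  list(labels = lab, probabilities = prob, scores = scores)
}

#' Evaluate a trained classifier on held-out sequences
#'
#' Computes overall accuracy, the confusion matrix, one-vs-rest ROC curves
#' and AUC per class from the SVM class probabilities, and accuracy per
#' sequence-length bin.
#'
#' @param model A `domain_model`.
#' @param rscu Held-out RSCU matrix (test set, disjoint from training).
#' @param labels True class labels.
#' @param lengths_nt Optional sequence lengths (nt) for length-binned
#'   accuracy.
#' @param length_bins Bin edges in nt; default
#'   `c(100, 200, 500, 1000, Inf)`.
#' @param pca Optional `rscu_pca` overriding `model$pca`.
#' @return An object of class `eval_report`: `accuracy`, `confusion`
#'   (rows = true class), `auc` (named per class), `roc` (list of
#'   `pROC::roc` objects), `length_accuracy` (data frame or `NULL`),
#'   `n_test`.
#' @export
evaluate_classifier <- function(model, rscu, labels, lengths_nt = NULL,
                                length_bins = c(100, 200, 500, 1000, Inf),
                                pca = model$pca) {
  labels <- factor(labels, levels = model$classes)
  pred <- stats::predict(model, rscu, pca = pca)
  acc <- mean(pred$labels == labels)
  confusion <- table(truth = labels, predicted = pred$labels)
  roc <- list(); auc <- numeric(0)
  for (cls in model$classes) {
    if (!any(labels == cls)) {
      warning("class absent from test set, ROC omitted: ", cls)
      next
    }
    r <- pROC::roc(response = labels == cls,
                   predictor = pred$probabilities[, cls],
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    roc[[cls]] <- r
    auc[cls] <- as.numeric(pROC::auc(r))
  }
  length_accuracy <- NULL
  if (!is.null(lengths_nt)) {
    bin <- cut(lengths_nt, breaks = length_bins, right = FALSE,
               include.lowest = TRUE)
    ok <- !is.na(bin)
    length_accuracy <- stats::aggregate(
      correct ~ bin,
      data = data.frame(bin = bin[ok],
                        correct = (pred$labels == labels)[ok]),
      FUN = mean)
    names(length_accuracy) <- c("length_bin", "accuracy")
  }
  structure(
    list(accuracy = acc, confusion = confusion, auc = auc, roc = roc,
         length_accuracy = length_accuracy, n_test = length(labels)),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: accuracy %.3f on %d sequences\n",
              x$accuracy, x$n_test))
  if (length(x$auc)) {
    cat("  AUC:", paste(sprintf("%s %.3f", names(x$auc), x$auc),
                        collapse = ", "), "\n")
  }
  invisible(x)
}
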