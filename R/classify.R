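#' Labeled image dataset container
#'
#' @param images list of `connectivity_image` objects (or plain H x W x 3
#'   numeric arrays).
#' @param labels class label per image (coerced to factor; level order is
#'   kept if already a factor).
#' @param subjects optional subject id per image (needed for subject-mode
#'   folds).
#' @return object of class `image_dataset`.
#' @export
image_dataset <- function(images, labels, subjects = NULL) {
  if (!is.factor(labels)) labels <- factor(labels)
  if (length(images) != length(labels))
    stop("images and labels differ in length")
  if (!is.null(subjects) && length(subjects) != length(images))
    stop("subjects and images differ in length")
  structure(list(images = images, labels = labels, subjects = subjects),
            class = "image_dataset")
}

#' @export
print.image_dataset <- function(x, ...) {
  cat("<image_dataset>", length(x$images), "images;",
      paste(sprintf("%s=%d", levels(x$labels), tabulate(x$labels)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Build k-fold assignments
#'
#' Window mode: stratified by class with a rotating offset so overall fold
#' sizes differ by at most one. Subject mode: whole subjects are assigned to
#' folds so no subject spans a fold boundary (guards against subject-identity
#' leakage across folds). Deterministic for a fixed seed.
#'
#' @param labels class label per image.
#' @param k number of folds (default 5).
#' @param mode `"window"` or `"subject"`.
#' @param subjects subject id per image (subject mode).
#' @param seed RNG seed.
#' @return object of class `fold_split` with `assignments` (fold index per
#'   image), `k`, `mode`, `seed`.
#' @export
make_folds <- function(labels, k = 5, mode = c("window", "subject"),
                       subjects = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (!is.factor(labels)) labels <- factor(labels)
  n <- length(labels)
  assignments <- integer(n)
  set.seed(seed)
  if (mode == "window") {
    counts <- tabulate(labels, nbins = nlevels(labels))
    if (any(counts < k))
      stop("need at least k=", k, " images per class; got minimum ",
           min(counts))
    offset <- 0L
    for (lv in levels(labels)) {
      idx <- sample(which(labels == lv))
      assignments[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  } else {
    if (is.null(subjects)) stop("subject mode needs subjects")
    subj <- unique(subjects)
    if (length(subj) < k)
      stop("need at least k=", k, " subjects; got ", length(subj))
    subj <- sample(subj)
    fold_of <- setNames(((seq_along(subj) - 1L) %% k) + 1L, subj)
    assignments <- unname(fold_of[as.character(subjects)])
  }
  structure(list(k = as.integer(k), assignments = assignments, mode = mode,
                 seed = as.integer(seed)),
            class = "fold_split")
}

#' Confusion matrix of a trained backend on a test set
#'
#' Hard argmax of the predicted class probabilities against the true labels.
#'
#' @param handle a trained backend (from [fit_backend()]).
#' @param images list of test images.
#' @param labels true labels (factor on the training levels).
#' @return L x L integer confusion matrix, rows = true class.
#' @export
evaluate <- function(handle, images, labels) {
  if (!length(images)) stop("empty test set")
  probs <- predict_proba(handle, images)
  lv <- colnames(probs)
  pred <- factor(lv[max.col(probs, ties.method = "first")], levels = lv)
  truth <- factor(as.character(labels), levels = lv)
  confusion_table(truth, pred)
}

confusion_table <- function(truth, pred) {
  tab <- table(true = truth, predicted = pred)
  matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
}

ovr_counts <- function(confusion, i) {
  total <- sum(confusion)
  tp <- confusion[i, i]
  fn <- sum(confusion[i, ]) - tp
  fp <- sum(confusion[, i]) - tp
  tn <- total - tp - fn - fp
  c(tp = tp, fn = fn, fp = fp, tn = tn)
}

#' Average one-vs-rest accuracy of a multiclass confusion matrix
#'
#' Mean over classes of `(tp_i + tn_i) / (tp_i + tn_i + fp_i + fn_i)` with
#' one-vs-rest counts. Note the chance level of this metric on balanced
#' 4-class data is 0.625 (not 0.25): a uniformly random predictor gets most
#' "rest" decisions right.
#'
#' @param confusion square confusion matrix, rows = true class.
#' @return value in `[0, 1]`.
#' @export
average_accuracy <- function(confusion) {
  stopifnot(nrow(confusion) == ncol(confusion), sum(confusion) > 0)
  mean(vapply(seq_len(nrow(confusion)), function(i) {
    ct <- ovr_counts(confusion, i)
    (ct["tp"] + ct["tn"]) / sum(ct)
  }, numeric(1)))
}

#' One-vs-rest AUC of the hard classifier
#'
#' `AUC_i = 1/2 (TP/(TP+FN) + TN/(TN+FP))` from one-vs-rest counts -
#' algebraically the balanced accuracy of the hard decision for class i, not
#' a probability-ranking ROC area (see [roc_auc_ovr()] for that).
#'
#' @param confusion square confusion matrix, rows = true class.
#' @param i positive class index.
#' @return value in `[0, 1]`.
#' @export
auc_ovr <- function(confusion, i) {
  ct <- ovr_counts(confusion, i)
  if (ct["tp"] + ct["fn"] == 0 || ct["tn"] + ct["fp"] == 0)
    stop("undefined one-vs-rest AUC: class ", i,
         " has no positives or no negatives")
  unname(0.5 * (ct["tp"] / (ct["tp"] + ct["fn"]) +
                ct["tn"] / (ct["tn"] + ct["fp"])))
}

#' Conventional ranking ROC-AUC, one class vs rest
#'
#' Probability-ranking area under the ROC curve (Mann-Whitney form) for one
#' class against the rest; reported alongside [auc_ovr()] for comparability
#' with studies that plot ROC curves.
#'
#' @param probs n x L matrix of predicted class probabilities.
#' @param labels true labels.
#' @param class positive class (name or index).
#' @return value in `[0, 1]`.
#' @export
roc_auc_ovr <- function(probs, labels, class) {
  s <- probs[, class]
  pos <- as.character(labels) == (if (is.numeric(class))
    colnames(probs)[class] else class)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("undefined ROC-AUC: need both classes present")
  r <- rank(s)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated image classification
#'
#' k-fold cross-validation of a pluggable classifier backend: for each fold
#' the backend is trained on the remaining k-1 folds and evaluated on the
#' held-out fold, so every image is tested exactly once. Reports per-fold
#' confusion matrices, average one-vs-rest accuracy (mean and sd across
#' folds), per-class one-vs-rest AUC of the hard classifier, and per-class
#' ranking ROC-AUC.
#'
#' @param dataset an [image_dataset()].
#' @param k number of folds (default 5).
#' @param backend a backend configuration (default [small_cnn()]).
#' @param mode fold mode, see [make_folds()].
#' @param seed seed for the fold assignment.
#' @return object of class `classification_result`.
#' @export
cross_validate <- function(dataset, k = 5, backend = small_cnn(),
                           mode = c("window", "subject"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "image_dataset"))
  if (mode == "window" && !is.null(dataset$subjects))
    message("window-mode folds: images of one subject may appear in both ",
            "training and test folds (use mode='subject' to prevent leakage)")
  folds <- make_folds(dataset$labels, k = k, mode = mode,
                      subjects = dataset$subjects, seed = seed)
  lv <- levels(dataset$labels)
  confusions <- vector("list", k)
  acc <- numeric(k)
  auc <- matrix(NA_real_, k, length(lv), dimnames = list(NULL, lv))
  rauc <- matrix(NA_real_, k, length(lv), dimnames = list(NULL, lv))
  for (f in seq_len(k)) {
    tr <- which(folds$assignments != f)
    te <- which(folds$assignments == f)
    if (length(unique(dataset$labels[tr])) < length(lv))
      stop("fold ", f, ": not all classes present in training data")
    handle <- fit_backend(backend, dataset$images[tr], dataset$labels[tr])
    probs <- predict_proba(handle, dataset$images[te])
    pred <- factor(lv[max.col(probs, ties.method = "first")], levels = lv)
    truth <- factor(as.character(dataset$labels[te]), levels = lv)
    cm <- confusion_table(truth, pred)
    confusions[[f]] <- cm
    acc[f] <- average_accuracy(cm)
    for (ci in seq_along(lv)) {
      auc[f, ci] <- tryCatch(auc_ovr(cm, ci), error = function(e) NA_real_)
      rauc[f, ci] <- tryCatch(roc_auc_ovr(probs, truth, lv[ci]),
                              error = function(e) NA_real_)
    }
  }
  structure(list(confusions = confusions, average_accuracy = acc,
                 accuracy_mean = mean(acc), accuracy_sd = stats::sd(acc),
                 auc_per_class = auc, roc_auc_per_class = rauc,
                 folds = folds, levels = lv,
                 config = backend_config(backend), seed = seed),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %d-fold CV, %d classes\n",
              x$folds$k, length(x$levels)))
  cat(sprintf("  average accuracy (one-vs-rest): %.4f +/- %.4f\n",
              x$accuracy_mean, x$accuracy_sd))
  cat("  per-class AUC (balanced-accuracy form):",
      paste(sprintf("%s=%.3f", x$levels, colMeans(x$auc_per_class)),
            collapse = ", "), "\n")
  cat("  per-class ROC-AUC (ranking):",
      paste(sprintf("%s=%.3f", x$levels,
                    colMeans(x$roc_auc_per_class, na.rm = TRUE)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a classification result to JSON
#'
#' @param result a `classification_result`.
#' @param path destination file.
#' @return `path` invisibly.
#' @export
write_cv_report <- function(result, path) {
  out <- list(
    k = result$folds$k, mode = result$folds$mode, seed = result$seed,
    levels = result$levels,
    confusions = lapply(result$confusions, function(m)
      `dimnames<-`(m, NULL)),
    average_accuracy = result$average_accuracy,
    accuracy_mean = result$accuracy_mean, accuracy_sd = result$accuracy_sd,
    auc_per_class = result$auc_per_class,
    roc_auc_per_class = result$roc_auc_per_class,
    config = result$config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
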