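# Evaluation: confusion matrices, one-vs-rest per-class metrics
# (precision, recall, specificity, F1, accuracy), macro averaging,
# multi-class ROC/AUC and gradient-weighted class activation maps.

#' Confusion matrix from actual and predicted labels
#'
#' @param actual,predicted equal-length vectors of 0-based class ids.
#' @param n_classes number of classes.
#' @return `n_classes x n_classes` integer matrix, rows = actual,
#'   columns = predicted.
#' @export
confusion <- function(actual, predicted, n_classes) {
  if (length(actual) == 0) stop("empty label vectors", call. = FALSE)
  if (length(actual) != length(predicted))
    stop("label vectors differ in length", call. = FALSE)
  if (any(actual < 0 | actual >= n_classes | predicted < 0 |
          predicted >= n_classes))
    stop("labels out of range [0, n_classes)", call. = FALSE)
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(actual)) {
    cm[actual[i] + 1L, predicted[i] + 1L] <- cm[actual[i] + 1L, predicted[i] + 1L] + 1L
  }
  dimnames(cm) <- list(actual = 0:(n_classes - 1), predicted = 0:(n_classes - 1))
  cm
}

#' One-vs-rest metrics for a single class
#'
#' Computes precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, the F1 score `2*precision*recall/(precision+recall)` and
#' one-vs-rest accuracy `(TP+TN)/total` from the confusion matrix. Degenerate
#' 0/0 ratios return 0 and raise the `degenerate` flag.
#'
#' @param cm a [confusion()] matrix.
#' @param class_id 0-based class index.
#' @return list with fields `precision`, `recall`, `specificity`, `f1`,
#'   `accuracy`, `degenerate`.
#' @export
class_metrics <- function(cm, class_id) {
  k <- class_id + 1L
  if (k < 1 || k > nrow(cm)) stop("invalid class id", call. = FALSE)
  tp <- cm[k, k]
  fn <- sum(cm[k, ]) - tp
  fp <- sum(cm[, k]) - tp
  tn <- sum(cm) - tp - fn - fp
  degenerate <- FALSE
  ratio <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; return(0) }
    num / den
  }
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  specificity <- ratio(tn, tn + fp)
  f1 <- if (precision + recall == 0) { degenerate <- TRUE; 0 } else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, specificity = specificity,
       f1 = f1, accuracy = (tp + tn) / sum(cm), degenerate = degenerate)
}

#' Unweighted macro average of per-class metrics
#'
#' @param per_class non-empty list of [class_metrics()] results.
#' @return list with the same numeric fields, each the arithmetic mean.
#' @export
macro_average <- function(per_class) {
  if (length(per_class) == 0) stop("no per-class metrics to average", call. = FALSE)
  fields <- c("precision", "recall", "specificity", "f1", "accuracy")
  out <- lapply(fields, function(f) mean(vapply(per_class, `[[`, numeric(1), f)))
  stats::setNames(out, fields)
}

#' Full metrics report
#'
#' @param actual 0-based labels.
#' @param predicted 0-based predictions.
#' @param scores optional `n x n_classes` score matrix for AUC.
#' @param n_classes number of classes.
#' @return list with `confusion`, `per_class`, `macro`, `accuracy` and, when
#'   scores are given, `auc`.
#' @export
metrics_report <- function(actual, predicted, n_classes, scores = NULL) {
  cm <- confusion(actual, predicted, n_classes)
  per_class <- lapply(0:(n_classes - 1), function(k) class_metrics(cm, k))
  rep <- list(confusion = cm, per_class = per_class,
              macro = macro_average(per_class),
              accuracy = sum(diag(cm)) / sum(cm))
  if (!is.null(scores)) rep$auc <- roc_auc(scores, actual)
  rep
}

#' Macro-averaged one-vs-rest ROC AUC
#'
#' For each class, the class-score column is scored against the one-vs-rest
#' response with trapezoidal integration of the ROC curve (via pROC), and the
#' class AUCs are averaged without weighting.
#'
#' @param scores `n x n_classes` matrix of class scores (higher = more likely).
#' @param actual 0-based labels; at least two classes must be present.
#' @return scalar AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, actual) {
  scores <- as.matrix(scores)
  assert_finite(scores, "score matrix")
  if (length(unique(actual)) < 2)
    stop("AUC needs at least two classes present", call. = FALSE)
  aucs <- vapply(sort(unique(actual)), function(k) {
    resp <- factor(actual == k, levels = c(FALSE, TRUE))
    as.numeric(pROC::auc(pROC::roc(resp, scores[, k + 1L],
                                   levels = c(FALSE, TRUE), direction = "<",
                                   quiet = TRUE)))
  }, numeric(1))
  mean(aucs)
}

#' Gradient-weighted class activation map
#'
#' Backpropagates the chosen class logit through the network head to the
#' backbone's final convolutional map, weights each channel by its spatially
#' averaged gradient, rectifies the weighted sum, min-max normalizes it
#' (constant maps become all-zeros) and upsamples to the input resolution.
#'
#' @param model a trained [build_model()] result.
#' @param image numeric intensity matrix in `[0, 255]`.
#' @param class_id 0-based class of interest.
#' @return `input_size x input_size` matrix with values in `[0, 1]`.
#' @export
cam <- function(model, image, class_id) {
  if (class_id < 0 || class_id >= model$cfg$n_classes)
    stop("invalid class id", call. = FALSE)
  x <- preprocess_images(model, list(image))
  fw <- model_forward(model, x, training = FALSE, keep_cache = TRUE)
  dlogits <- matrix(0, 1, model$cfg$n_classes)
  dlogits[1, class_id + 1L] <- 1
  bw <- model_backward(model, fw, dlogits, through_backbone = FALSE)
  fm <- fw$featmap[, , , 1, drop = TRUE]        # h x w x c
  g <- bw$dfeat[, , , 1, drop = TRUE]
  wts <- apply(g, 3, mean)
  d <- dim(fm)
  heat <- matrix(matrix(fm, d[1] * d[2], d[3]) %*% wts, d[1], d[2])
  heat <- pmax(heat, 0)
  rng <- range(heat)
  heat <- if (diff(rng) < 1e-12) heat * 0 else (heat - rng[1]) / diff(rng)
  resize_bilinear(heat, model$cfg$input_size, model$cfg$input_size)
}
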