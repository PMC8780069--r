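# Confusion-matrix metrics, macro averaging, multi-class AUC, activation maps.

test_that("confusion matrices count actual-by-predicted pairs", {
  cm <- confusion(c(0, 1, 2, 2), c(0, 1, 2, 2), 3)
  expect_equal(unname(diag(cm)), c(1L, 1L, 2L))
  expect_equal(sum(cm) - sum(diag(cm)), 0)
  # binary matrix reconstructing TP=9, FN=1, FP=2, TN=8 for class 1
  cm2 <- confusion(c(rep(1, 10), rep(0, 10)),
                   c(rep(1, 9), 0, rep(1, 2), rep(0, 8)), 2)
  expect_equal(unname(cm2), matrix(c(8L, 1L, 2L, 9L), 2, 2))
  expect_error(confusion(integer(0), integer(0), 2), "empty")
  expect_error(confusion(c(0, 3), c(0, 1), 2), "range")
  expect_error(confusion(c(0, 1), c(0), 2), "length")
})

test_that("per-class metrics apply the one-vs-rest definitions exactly", {
  cm <- confusion(c(rep(1, 10), rep(0, 10)),
                  c(rep(1, 9), 0, rep(1, 2), rep(0, 8)), 2)
  mt <- class_metrics(cm, 1)
  expect_equal(mt$precision, 9 / 11, tolerance = 1e-12)
  expect_equal(mt$recall, 0.9)
  expect_equal(mt$specificity, 0.8)
  expect_equal(mt$f1, 2 * (9 / 11) * 0.9 / (9 / 11 + 0.9), tolerance = 1e-12)
  expect_equal(mt$accuracy, 0.85)
  expect_false(mt$degenerate)

  # perfect classifier
  pc <- class_metrics(confusion(c(0, 1, 1), c(0, 1, 1), 2), 1)
  expect_equal(unlist(pc[c("precision", "recall", "specificity", "f1")]),
               c(precision = 1, recall = 1, specificity = 1, f1 = 1))
  # all-wrong binary classifier
  aw <- metrics_report(c(0, 1), c(1, 0), 2)
  expect_equal(aw$accuracy, 0)
  # degenerate 0/0 cases flag instead of propagating NaN
  dg <- class_metrics(confusion(c(0, 0), c(0, 0), 2), 1)
  expect_true(dg$degenerate)
  expect_equal(dg$precision, 0)
  expect_error(class_metrics(cm, 5), "class id")
})

test_that("macro averages are unweighted means, invariant to relabeling", {
  a <- list(precision = 0.6, recall = 1, specificity = 0.5, f1 = 0.7,
            accuracy = 0.8, degenerate = FALSE)
  b <- list(precision = 1.0, recall = 0.4, specificity = 0.9, f1 = 0.5,
            accuracy = 0.6, degenerate = FALSE)
  mac <- macro_average(list(a, b))
  expect_equal(mac$precision, 0.8)
  expect_equal(mac$recall, 0.7)
  expect_identical(macro_average(list(a, a)), macro_average(list(a, a)))
  expect_error(macro_average(list()), "average")

  # permutation invariance on a real report
  set.seed(88)
  actual <- sample(0:2, 60, replace = TRUE)
  pred <- ifelse(runif(60) < 0.7, actual, sample(0:2, 60, replace = TRUE))
  r1 <- metrics_report(actual, pred, 3)
  perm <- c(2L, 0L, 1L)
  r2 <- metrics_report(perm[actual + 1], perm[pred + 1], 3)
  expect_equal(r1$macro, r2$macro, tolerance = 1e-12)
  expect_equal(r1$accuracy, sum(diag(r1$confusion)) / sum(r1$confusion))
  # in a binary problem, recall of class 1 equals specificity of class 0
  rb <- metrics_report(c(0, 0, 1, 1, 1), c(0, 1, 1, 1, 0), 2)
  expect_equal(rb$per_class[[2]]$recall, rb$per_class[[1]]$specificity)
})

test_that("macro AUC agrees with the pairwise-concordance oracle", {
  # one-hot scores: perfect separation
  actual <- c(0, 1, 2, 1, 0)
  onehot <- diag(3)[actual + 1, ]
  expect_equal(roc_auc(onehot, actual), 1)
  # label-independent scores: chance level
  expect_equal(roc_auc(matrix(0.4, 5, 3), actual), 0.5)
  expect_error(roc_auc(matrix(1, 3, 2), c(1, 1, 1)), "two classes")

  # 20-sample binary case against exhaustive pairwise concordance
  set.seed(44)
  lab <- rep(0:1, each = 10)
  s <- runif(20) + 0.3 * lab
  expect_equal(roc_auc(cbind(1 - s, s), lab),
               concordance_auc(lab == 1, s), tolerance = 1e-12)

  # random multi-class problems up to 30 samples
  for (i in 1:20) {
    n <- sample(6:30, 1)
    actual <- c(0:2, sample(0:2, n - 3, replace = TRUE))
    sc <- matrix(runif(3 * n), n, 3)
    expected <- mean(sapply(0:2, function(k)
      concordance_auc(actual == k, sc[, k + 1])))
    expect_equal(roc_auc(sc, actual), expected, tolerance = 1e-10)
  }
})

test_that("activation heatmaps satisfy the normalization contract", {
  m <- tiny_model(seed = 19, n_classes = 2)
  set.seed(61)
  img <- matrix(runif(80 * 80, 0, 255), 80, 80)
  h <- cam(m, img, 1)
  expect_equal(dim(h), c(56L, 56L))
  expect_gte(min(h), 0)
  expect_lte(max(h), 1)
  expect_error(cam(m, img, 5), "class id")
  # a constant feature response maps to the all-zero heatmap
  hz <- cam(m, matrix(0, 64, 64), 0)
  expect_true(all(hz >= 0 & hz <= 1))
})

test_that("heatmaps of a trained model localize the class-discriminative lesion", {
  # use the benchmark-trained model; the bright posterior lesion (class 3) is
  # the most sharply localized class signature
  bm <- get_benchmark()
  labs <- dataset_labels(bm$dataset)[bm$split$test]
  imgs <- dataset_images(bm$dataset, bm$split$test)
  ids <- which(labs == 3)
  hits <- 0
  for (i in ids) {
    h <- cam(bm$model, imgs[[i]], 3)
    pk <- which(h == max(h), arr.ind = TRUE)[1, ]
    # lesion prior: center 0.63 of the side +/- jitter and radius, widened by
    # one 8-pixel backbone cell for the 7x7-map upsampling blur
    if (all(pk / 56 >= 0.40) && all(pk / 56 <= 0.90)) hits <- hits + 1
  }
  expect_gt(hits / length(ids), 0.5)
})
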