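test_that("window-mode folds are stratified with balanced sizes", {
  labels <- factor(rep(emotion_classes(), each = 25))
  fs <- make_folds(labels, k = 5, seed = 3)
  expect_identical(as.integer(table(fs$assignments)), rep(20L, 5))
  for (f in 1:5)
    expect_identical(as.integer(table(labels[fs$assignments == f])), rep(5L, 4))
  # determinism
  fs2 <- make_folds(labels, k = 5, seed = 3)
  expect_identical(fs$assignments, fs2$assignments)
  expect_false(identical(make_folds(labels, k = 5, seed = 4)$assignments,
                         fs$assignments))
  expect_error(make_folds(factor(rep("a", 3)), k = 5), "at least k")
})

test_that("subject-mode folds never split a subject", {
  set.seed(1)
  subjects <- sprintf("S%02d", sample(1:24, 240, replace = TRUE))
  labels <- factor(sample(emotion_classes(), 240, replace = TRUE))
  fs <- make_folds(labels, k = 5, mode = "subject", subjects = subjects,
                   seed = 8)
  per_subj <- tapply(fs$assignments, subjects, function(a)
    length(unique(a)))
  expect_true(all(per_subj == 1L))
  expect_error(make_folds(labels[1:4], k = 5, mode = "subject",
                          subjects = rep("S01", 4)), "subjects")
})

test_that("average accuracy and one-vs-rest AUC match hand computations", {
  perfect <- diag(c(10, 20, 30, 40))
  expect_identical(average_accuracy(perfect), 1)
  conf <- matrix(c(40, 10, 0, 0,
                   10, 40, 0, 0,
                   0, 0, 50, 0,
                   0, 0, 0, 50), 4, 4, byrow = TRUE)
  expect_equal(average_accuracy(conf), 0.95, tolerance = 1e-12)
  for (i in 1:4) expect_equal(auc_ovr(perfect, i), 1, tolerance = 1e-12)
  # TP=40 FN=10 TN=140 FP=10 -> 0.5*(0.8 + 140/150)
  conf2 <- matrix(0, 4, 4)
  conf2[1, 1] <- 40; conf2[1, 2] <- 10
  conf2[2, 1] <- 10; conf2[2, 2] <- 40
  conf2[3, 3] <- 50; conf2[4, 4] <- 50
  expect_equal(auc_ovr(conf2, 1), 0.5 * (0.8 + 140 / 150),
               tolerance = 1e-12)
  expect_equal(round(auc_ovr(conf2, 1), 4), 0.8667)
  # degenerate: no positives
  conf3 <- diag(c(0, 10, 10, 10))
  expect_error(auc_ovr(conf3, 1), "no positives")
})

test_that("evaluate builds confusion matrices from argmax predictions", {
  labels <- factor(rep(c("a", "b", "c", "d"), each = 5))
  n <- length(labels)
  perfect <- matrix(0.01, n, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  perfect[cbind(seq_len(n), as.integer(labels))] <- 0.97
  cm <- evaluate(mock_handle(perfect), as.list(seq_len(n)), labels)
  expect_equal(unname(diag(cm)), rep(5, 4))
  expect_equal(sum(cm), n)
  constant <- matrix(rep(c(0.7, 0.1, 0.1, 0.1), each = n), n, 4,
                     dimnames = list(NULL, c("a", "b", "c", "d")))
  cm2 <- evaluate(mock_handle(constant), as.list(seq_len(n)), labels)
  expect_equal(unname(colSums(cm2)), c(n, 0, 0, 0))
  expect_error(evaluate(mock_handle(perfect), list(), labels), "empty")
})

test_that("small_cnn separates solid-colour classes within 5 epochs", {
  fx <- solid_image_set(n_per_class = 40, seed = 1)
  h <- fit_backend(small_cnn(input_size = 16, epochs = 5, seed = 3),
                   fx$images, fx$labels)
  probs <- predict_proba(h, fx$images)
  expect_lt(max(abs(rowSums(probs) - 1)), 1e-6)
  acc <- mean(colnames(probs)[max.col(probs)] == as.character(fx$labels))
  expect_identical(acc, 1)
})

test_that("transfer adapter trains a replacement head and validates input", {
  fx <- solid_image_set(n_per_class = 15, seed = 2)
  be <- transfer_backend(mock_network(), epochs = 30)
  h <- fit_backend(be, fx$images, fx$labels)
  probs <- predict_proba(h, fx$images)
  expect_lt(max(abs(rowSums(probs) - 1)), 1e-6)
  acc <- mean(colnames(probs)[max.col(probs)] == as.character(fx$labels))
  expect_gte(acc, 0.95)
  # a network without a final fully connected layer is a config error
  bad <- mock_network(); bad$final_fc <- NULL
  expect_error(transfer_backend(bad), "fully connected")
  expect_error(transfer_backend(list(final_fc = 1)), "features")
})

test_that("cross_validate partitions every image into exactly one test fold", {
  fx <- solid_image_set(n_per_class = 10, seed = 5)
  res <- cross_validate(image_dataset(fx$images, fx$labels), k = 5,
                        backend = small_cnn(input_size = 8, epochs = 2,
                                            seed = 1), seed = 2)
  expect_equal(sum(vapply(res$confusions, sum, 1)), 40)
  expect_identical(as.integer(table(res$folds$assignments)), rep(8L, 5))
  expect_length(res$average_accuracy, 5L)
  expect_true(all(res$auc_per_class >= 0 & res$auc_per_class <= 1,
                  na.rm = TRUE))
  # report serialization
  path <- withr::local_tempfile(fileext = ".json")
  write_cv_report(res, path)
  rep_ <- jsonlite::read_json(path)
  expect_identical(rep_$k, 5L)
  expect_length(rep_$confusions, 5L)
})
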