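test_that("dLDA matches hand-evaluated discriminants and breaks ties negatively", {
  # one feature: class LB mean 0, class NP mean 10, pooled variance 2
  X <- toy_matrix(matrix(c(-1, 1, 9, 11), nrow = 1), scale = "log2")
  y <- toy_labels(2, 2)
  m <- train_dlda(X, y)
  expect_equal(unname(m$params$m_pos), 0)
  expect_equal(unname(m$params$m_neg), 10)
  expect_equal(unname(m$params$s2), 2)
  # query x = 1: d_LB = 0.5, d_NP = 40.5 -> LB
  expect_identical(unname(predict_class(m, matrix(1, 1, 1))), "LB")
  # query at the NP centroid -> NP
  expect_identical(unname(predict_class(m, matrix(10, 1, 1))), "NP")
  # equidistant query (x = 5) -> tie resolved to the negative class
  expect_equal(decision_value(m, matrix(5, 1, 1)), 0)
  expect_identical(unname(predict_class(m, matrix(5, 1, 1))), "NP")
})

test_that("dLDA equals a brute-force discriminant evaluation on random instances", {
  set.seed(11)
  for (rep in 1:15) {
    nf <- sample(1:10, 1); n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    v <- matrix(rnorm(nf * (n1 + n2)), nrow = nf,
                dimnames = list(sprintf("f%02d", 1:nf),
                                sprintf("s%02d", 1:(n1 + n2))))
    y <- toy_labels(n1, n2)
    m <- train_dlda(expression_matrix(v, scale = "log2"), y)
    q <- matrix(rnorm(nf * 3), nrow = nf)
    # independent oracle: explicit per-class discriminant sums
    mu1 <- rowMeans(v[, 1:n1, drop = FALSE])
    mu2 <- rowMeans(v[, n1 + 1:n2, drop = FALSE])
    va <- function(block, mu) rowSums((block - mu)^2)
    s2 <- (va(v[, 1:n1, drop = FALSE], mu1) +
             va(v[, n1 + 1:n2, drop = FALSE], mu2)) / (n1 + n2 - 2)
    for (j in 1:3) {
      d1 <- sum((q[, j] - mu1)^2 / s2); d2 <- sum((q[, j] - mu2)^2 / s2)
      want <- if (d1 < d2) "LB" else "NP"
      expect_identical(unname(predict_class(m, q[, j, drop = FALSE])), want)
    }
  }
})

test_that("kNN votes by the nearest neighbours with deterministic tie-breaks", {
  v <- matrix(c(0, 1, 4, 5, 6), nrow = 1,
              dimnames = list("f1", sprintf("s%02d", 1:5)))
  y <- toy_labels(2, 3, positive = "A", negative = "B")
  # k=1, query equals a training sample -> that sample's class
  expect_identical(predict_knn(v, y, 4, k = 1), "B")
  expect_identical(predict_knn(v, y, 1, k = 1), "A")
  # k=3 around x=2: neighbours s02 (A), s01 (A), s03 (B) -> A
  expect_identical(predict_knn(v, y, 2, k = 3), "A")
  expect_error(predict_knn(v, y, 2, k = 2), "odd")
  expect_error(predict_knn(v, y, 2, k = 7), "training samples")

  # distance ties at the k-th rank keep the earlier-indexed sample,
  # verified against an exhaustive stable sort of all distances
  v2 <- matrix(c(-1, 1, 3, -3), nrow = 1,
               dimnames = list("f1", sprintf("s%02d", 1:4)))
  y2 <- label_vector(sprintf("s%02d", 1:4), c("A", "B", "A", "B"),
                     positive = "A", negative = "B")
  d <- abs(as.numeric(v2))          # query at 0; s01/s02 tie, s03/s04 tie
  nn <- order(d, seq_along(d))[1:3] # oracle: 1, 2, 3 -> A,B,A -> A
  expect_identical(nn, c(1L, 2L, 3L))
  expect_identical(predict_knn(v2, y2, 0, k = 3), "A")

  # invariance under a joint order-preserving rescaling of all features
  set.seed(2)
  v3 <- matrix(rnorm(3 * 8), nrow = 3,
               dimnames = list(sprintf("f%d", 1:3), sprintf("s%02d", 1:8)))
  y3 <- toy_labels(4, 4)
  q <- rnorm(3)
  for (k in c(1, 3, 5)) {
    a <- predict_knn(v3, y3, q, k)
    b <- predict_knn(3 * v3 + 7, y3, 3 * q + 7, k)
    expect_identical(a, b)
  }
})

test_that("linear SVM separates, tolerates inseparable data, and scales sanely", {
  # two separable points: boundary midway
  v <- matrix(c(0, 4), nrow = 1, dimnames = list("f1", c("s01", "s02")))
  y <- toy_labels(1, 1)
  for (cost in c(1, 2, 10)) {
    m <- train_linear_svm(v, y, cost = cost)
    expect_identical(unname(predict_class(m, matrix(c(0, 4), 1))), c("LB", "NP"))
    expect_equal(unname(decision_value(m, matrix(2, 1, 1))), 0,
                 tolerance = 1e-6)
  }
  # interleaved one-feature classes: training succeeds with >=1 error
  v2 <- matrix(c(0, 4, 2, 6), nrow = 1,
               dimnames = list("f1", sprintf("s%02d", 1:4)))
  y2 <- label_vector(sprintf("s%02d", 1:4), c("LB", "LB", "NP", "NP"))
  m2 <- train_linear_svm(v2, y2, cost = 1)
  train_pred <- predict_class(m2, v2)
  expect_gte(sum(train_pred != unclass(y2)), 1)
  # degenerate identical samples refuse to train
  v3 <- matrix(5, nrow = 2, ncol = 4,
               dimnames = list(c("f1", "f2"), sprintf("s%02d", 1:4)))
  expect_error(train_linear_svm(v3, y2, cost = 1), "identical")

  # duplicating every training sample leaves the separable boundary unchanged
  sep <- separated_data(n_pos = 4, n_neg = 4, n_features = 3, shift = 10)
  vd <- cbind(unclass(sep$X), unclass(sep$X))
  colnames(vd) <- sprintf("s%02d", 1:16)
  yd <- label_vector(colnames(vd), rep(unclass(sep$y), 2))
  m_a <- train_linear_svm(unclass(sep$X), sep$y, cost = 5)
  m_b <- train_linear_svm(vd, yd, cost = 5)
  q <- matrix(rnorm(3 * 20, 5, 6), nrow = 3)
  expect_identical(predict_class(m_a, q), predict_class(m_b, q))
})

test_that("all three families are perfect on well-separated training data", {
  sep <- separated_data(n_pos = 6, n_neg = 6, n_features = 5, shift = 20)
  for (spec in list(classifier_spec("svm", cost = 1),
                    classifier_spec("knn", k = 3),
                    classifier_spec("dlda"))) {
    m <- train_classifier(sep$X, sep$y, spec)
    expect_identical(unname(predict_class(m, unclass(sep$X))),
                     as.character(sep$y))
  }
})

test_that("logit calibration is monotone, symmetric, and guarded", {
  # direct fit on symmetric decision values: probabilities mirror to 1
  for (d in c(0.5, 1, 3)) {
    cal <- ooclassify:::fit_platt(c(d, -d), c(TRUE, FALSE))
    expect_lt(cal$A, 0)
    p <- function(f) 1 / (1 + exp(cal$A * f + cal$B))
    expect_equal(p(d) + p(-d), 1, tolerance = 1e-6)
    # decision value at the logistic midpoint -> probability one half
    expect_equal(p(-cal$B / cal$A), 0.5, tolerance = 1e-12)
  }
  # perfect separation stays finite thanks to the L2 guard
  cal <- ooclassify:::fit_platt(c(5, 4, 3, -3, -4, -5),
                                c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_true(is.finite(cal$A) && is.finite(cal$B))
  expect_lt(cal$A, 0)

  # end-to-end: calibrated SVM probabilities increase with decision value
  sep <- separated_data(n_pos = 5, n_neg = 5, n_features = 4, shift = 6,
                        seed = 9)
  m <- train_linear_svm(sep$X, sep$y, cost = 1)
  expect_error(predict_proba(m, unclass(sep$X)), "calibrate_logit")
  mc <- calibrate_logit(m, sep$X, sep$y, seed = 4)
  f <- decision_value(mc, unclass(sep$X))
  p <- predict_proba(mc, unclass(sep$X))
  expect_identical(order(f), order(p))
  expect_true(all(p >= 0 & p <= 1))
  # calibration is reproducible under the same seed
  mc2 <- calibrate_logit(m, sep$X, sep$y, seed = 4)
  expect_equal(mc2$calibration, mc$calibration)
})

test_that("predictive probabilities follow the stated decision rule", {
  # 3-NN with neighbour classes (A, A, B) -> p = 2/3
  v <- matrix(c(0, 1, 2, 10), nrow = 1,
              dimnames = list("f1", sprintf("s%02d", 1:4)))
  y <- label_vector(sprintf("s%02d", 1:4), c("A", "A", "B", "B"),
                    positive = "A", negative = "B")
  m <- train_classifier(v, y, classifier_spec("knn", k = 3))
  expect_equal(unname(predict_proba(m, matrix(0.5, 1, 1))), 2 / 3)
  # p exactly 0.5 classifies negative: dLDA tie point
  X <- toy_matrix(matrix(c(-1, 1, 9, 11), nrow = 1), scale = "log2")
  md <- train_dlda(X, toy_labels(2, 2))
  expect_equal(unname(predict_proba(md, matrix(5, 1, 1))), 0.5)
  expect_identical(unname(predict_class(md, matrix(5, 1, 1))), "NP")
})

test_that("classifier specifications validate their hyperparameters", {
  expect_error(classifier_spec("knn"), "odd")
  expect_error(classifier_spec("knn", k = 2), "odd")
  expect_error(classifier_spec("dlda", k = 3), "knn")
  expect_error(classifier_spec("svm", cost = -1), "positive")
  expect_error(classifier_spec("svm", p_cutoff = 1.5), "0, 1")
})
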