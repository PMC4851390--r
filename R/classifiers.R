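#' Classifier specification
#'
#' Describes one candidate model of the selection grid: an algorithm
#' family, its hyperparameter, and the p-value cutoff used for in-fold
#' univariate feature selection.
#'
#' @param algorithm `"svm"` (linear soft-margin support vector machine),
#'   `"knn"` (k-nearest neighbours) or `"dlda"` (diagonal linear
#'   discriminant analysis).
#' @param k Positive odd neighbour count, kNN only (1 and 3 are the usual
#'   choices for cohorts of this size).
#' @param cost Positive soft-margin penalty, SVM only.
#' @param p_cutoff Feature-selection p-value cutoff in (0, 1).
#' @return A list of class `classifier_spec`.
#' @examples
#' classifier_spec("svm", cost = 2, p_cutoff = 0.01)
#' classifier_spec("knn", k = 3, p_cutoff = 0.01)
#' @export
classifier_spec <- function(algorithm = c("svm", "knn", "dlda"), k = NULL,
                            cost = NULL, p_cutoff = 0.01) {
  algorithm <- match.arg(algorithm)
  if (!is.numeric(p_cutoff) || length(p_cutoff) != 1 ||
      p_cutoff <= 0 || p_cutoff >= 1) {
    stop("`p_cutoff` must be a single number in (0, 1)", call. = FALSE)
  }
  if (algorithm == "knn") {
    if (is.null(k) || k < 1 || k %% 2 == 0) {
      stop("kNN requires a positive odd `k` (even k can leave the two-class ",
           "vote undecided)", call. = FALSE)
    }
    k <- as.integer(k)
  } else if (!is.null(k)) {
    stop("`k` is only meaningful for algorithm = \"knn\"", call. = FALSE)
  }
  if (algorithm == "svm") {
    if (is.null(cost)) cost <- 1
    if (!is.numeric(cost) || cost <= 0) {
      stop("`cost` must be a positive number", call. = FALSE)
    }
  } else if (!is.null(cost)) {
    stop("`cost` is only meaningful for algorithm = \"svm\"", call. = FALSE)
  }
  structure(list(algorithm = algorithm, k = k, cost = cost,
                 p_cutoff = p_cutoff),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat("<classifier_spec>", spec_label(x), "\n")
  invisible(x)
}

# Human-readable one-line label, e.g. "svm (cost 2) @ p<0.01".
spec_label <- function(spec) {
  hp <- switch(spec$algorithm,
               svm = sprintf(" (cost %g)", spec$cost),
               knn = sprintf(" (k=%d)", spec$k),
               dlda = "")
  sprintf("%s%s @ p<%g", spec$algorithm, hp, spec$p_cutoff)
}

# Coerce X to a plain features-x-samples matrix.
as_feature_matrix <- function(X) {
  if (inherits(X, "expr_matrix")) unclass(X) else as.matrix(X)
}

new_cc_model <- function(spec, feature_ids, family, params, y) {
  structure(list(spec = spec, feature_ids = feature_ids, family = family,
                 params = params, positive = positive_name(y),
                 negative = negative_name(y), calibration = NULL),
            class = "cc_model")
}

#' @export
print.cc_model <- function(x, ...) {
  cat(sprintf("<cc_model> %s: %d feature(s), classes %s (+) / %s (-)%s\n",
              x$family, length(x$feature_ids), x$positive, x$negative,
              if (!is.null(x$calibration)) ", logit-calibrated" else ""))
  invisible(x)
}

# Align a query matrix (features x samples) to a model's feature set.
align_query <- function(model, query) {
  q <- as_feature_matrix(query)
  if (is.null(dim(q))) q <- matrix(q, ncol = 1)
  if (!is.null(rownames(q))) {
    idx <- match(model$feature_ids, rownames(q))
    if (anyNA(idx)) {
      stop("query is missing model feature(s): ",
           paste(head(model$feature_ids[is.na(idx)], 5), collapse = ", "),
           call. = FALSE)
    }
    q <- q[idx, , drop = FALSE]
  } else if (nrow(q) != length(model$feature_ids)) {
    stop("unnamed query must have exactly the model's ",
         length(model$feature_ids), " feature rows", call. = FALSE)
  }
  q
}

#' Train a diagonal linear discriminant analysis model
#'
#' dLDA is linear discriminant analysis with a diagonal covariance
#' estimate: per-feature class means and pooled within-class variances,
#' equal class priors. A query is assigned to the class minimizing
#' `sum_g (x_g - m_cg)^2 / s2_g`; an exact tie goes to the negative class
#' (never predict the positive outcome on zero evidence). Pooled variances
#' are floored at `1e-8` times their mean so constant background features
#' cannot produce infinite discriminants.
#'
#' @param X Features-x-samples matrix (or [expression_matrix()]) already
#'   restricted to the selected features.
#' @param y A [label_vector()] aligned to the columns of `X`.
#' @param spec Optional [classifier_spec()] recorded on the model.
#' @return A `cc_model`.
#' @export
train_dlda <- function(X, y, spec = classifier_spec("dlda")) {
  v <- as_feature_matrix(X)
  y <- check_labels(v, y, min_per_class = 2L)
  pos <- which(is_positive(y)); neg <- which(!is_positive(y))
  n1 <- length(pos); n2 <- length(neg)
  m_pos <- rowMeans(v[, pos, drop = FALSE])
  m_neg <- rowMeans(v[, neg, drop = FALSE])
  v1 <- rowSums((v[, pos, drop = FALSE] - m_pos)^2) / (n1 - 1)
  v2 <- rowSums((v[, neg, drop = FALSE] - m_neg)^2) / (n2 - 1)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  floor_ <- 1e-8 * mean(s2)
  if (floor_ <= 0) floor_ <- 1e-12  # all features constant
  s2 <- pmax(s2, floor_)
  new_cc_model(spec, rownames(v) %||% paste0("f", seq_len(nrow(v))), "dlda",
               list(m_pos = m_pos, m_neg = m_neg, s2 = s2), y)
}

#' Classify a query by k-nearest neighbours
#'
#' Majority vote among the `k` training samples closest to the query in
#' Euclidean distance. Distance ties at the k-th rank are broken in favour
#' of the earlier-indexed training sample, making the prediction
#' deterministic.
#'
#' @param train_X Features-x-samples training matrix.
#' @param train_y A [label_vector()] for the training columns.
#' @param query Numeric feature vector (or one-column matrix) in the same
#'   feature order as `train_X`.
#' @param k Positive odd neighbour count, at most the number of training
#'   samples.
#' @return The predicted class name (character scalar).
#' @export
predict_knn <- function(train_X, train_y, query, k) {
  v <- as_feature_matrix(train_X)
  train_y <- check_labels(v, train_y, min_per_class = 1L)
  if (k %% 2 == 0 || k < 1) {
    stop("`k` must be a positive odd integer", call. = FALSE)
  }
  if (k > ncol(v)) {
    stop("`k` exceeds the number of training samples", call. = FALSE)
  }
  p <- knn_vote(v, is_positive(train_y), as.numeric(query), k)
  if (p > 0.5) positive_name(train_y) else negative_name(train_y)
}

# Fraction of positive votes among the k nearest training columns.
knn_vote <- function(v, pos_flags, query, k) {
  d2 <- colSums((v - query)^2)
  nn <- order(d2, seq_along(d2))[seq_len(k)]  # stable: earlier index wins ties
  mean(pos_flags[nn])
}

train_knn_model <- function(X, y, spec) {
  v <- as_feature_matrix(X)
  y <- check_labels(v, y, min_per_class = 1L)
  if (spec$k > ncol(v)) {
    stop("`k` exceeds the number of training samples", call. = FALSE)
  }
  new_cc_model(spec, rownames(v) %||% paste0("f", seq_len(nrow(v))), "knn",
               list(train = v, pos_flags = is_positive(y), k = spec$k), y)
}

#' Train a linear soft-margin support vector machine
#'
#' Fits the standard soft-margin linear SVM (via libsvm through
#' \pkg{e1071}, without internal rescaling) and stores the explicit weight
#' vector and bias, oriented so that a positive decision value
#' `f(x) = w.x + b` predicts the positive class.
#'
#' @inheritParams train_dlda
#' @param cost Positive slack penalty; overrides `spec$cost` when given.
#' @return A `cc_model` with `params$w` and `params$b`.
#' @export
train_linear_svm <- function(X, y, cost = NULL,
                             spec = classifier_spec("svm", cost = cost %||% 1)) {
  v <- as_feature_matrix(X)
  y <- check_labels(v, y, min_per_class = 1L)
  cost <- cost %||% spec$cost
  if (all(v == v[, 1])) {
    stop("all training samples are identical; SVM training is degenerate",
         call. = FALSE)
  }
  yf <- factor(ifelse(is_positive(y), "pos", "neg"), levels = c("pos", "neg"))
  fit <- e1071::svm(x = t(v), y = yf, kernel = "linear", cost = cost,
                    scale = FALSE, type = "C-classification")
  w <- drop(crossprod(fit$coefs, fit$SV))    # decision value positive => first level
  b <- -fit$rho
  new_cc_model(spec, rownames(v) %||% paste0("f", seq_len(nrow(v))), "svm",
               list(w = w, b = b), y)
}

#' Train the classifier named by a specification
#'
#' Dispatches to [train_dlda()], the kNN trainer or [train_linear_svm()]
#' according to `spec$algorithm`.
#'
#' @inheritParams train_dlda
#' @param spec A [classifier_spec()].
#' @return A `cc_model`.
#' @export
train_classifier <- function(X, y, spec) {
  switch(spec$algorithm,
         dlda = train_dlda(X, y, spec = spec),
         knn = train_knn_model(X, y, spec = spec),
         svm = train_linear_svm(X, y, spec = spec))
}

#' Decision values of a trained model
#'
#' Continuous class score per query sample, oriented so that larger means
#' more positive-like. For the SVM this is `w.x + b`; for dLDA half the
#' difference of the two discriminant sums (negative minus positive), so
#' that the native softmax probability is `plogis(decision)`. kNN has no
#' continuous decision value.
#'
#' @param model A `cc_model`.
#' @param query Features-x-samples matrix or feature vector.
#' @return Numeric vector, one value per query sample.
#' @export
decision_value <- function(model, query) {
  q <- align_query(model, query)
  switch(model$family,
    svm = drop(crossprod(q, model$params$w)) + model$params$b,
    dlda = {
      d_pos <- colSums((q - model$params$m_pos)^2 / model$params$s2)
      d_neg <- colSums((q - model$params$m_neg)^2 / model$params$s2)
      0.5 * (d_neg - d_pos)
    },
    knn = stop("kNN has no continuous decision value; use predict_proba()",
               call. = FALSE)
  )
}

#' Calibrate a classifier's decision values to probabilities
#'
#' Platt-style logit calibration: decision values are collected from
#' seeded inner cross-validated refits (so the calibration data are not
#' resubstitution scores), then a two-parameter logistic map
#' `p(positive | x) = 1 / (1 + exp(A f(x) + B))` is fitted by maximum
#' likelihood with a tiny L2 penalty on (A, B) that keeps the slope finite
#' under perfect separation. `A < 0` is enforced, so the probability is a
#' strictly increasing function of the decision value.
#'
#' @param model A trained `cc_model` (SVM or dLDA).
#' @param X Features-x-samples training matrix used to fit `model`.
#' @param y A [label_vector()] for the columns of `X`; at least 3 samples
#'   per class.
#' @param inner_folds Number of stratified inner folds (default 3).
#' @param seed Integer seed for the inner-fold assignment.
#' @param lambda L2 penalty weight on (A, B).
#' @return `model` with a `calibration` component `(A, B)`.
#' @export
calibrate_logit <- function(model, X, y, inner_folds = 3, seed = 1,
                            lambda = 1e-6) {
  v <- as_feature_matrix(X)
  y <- check_labels(v, y, min_per_class = 3L)
  if (model$family == "knn") {
    stop("kNN probabilities are native neighbour-vote fractions; ",
         "calibration applies to SVM and dLDA models", call. = FALSE)
  }
  folds <- stratified_folds(is_positive(y), inner_folds, seed)
  f <- numeric(ncol(v))
  for (j in seq_len(inner_folds)) {
    hold <- which(folds == j)
    refit <- train_classifier(v[, -hold, drop = FALSE], y[-hold], model$spec)
    f[hold] <- decision_value(refit, v[, hold, drop = FALSE])
  }
  model$calibration <- fit_platt(f, is_positive(y), lambda = lambda)
  model
}

# Stratified fold ids: within each class, a seeded shuffle then round-robin.
stratified_folds <- function(pos_flags, n_folds, seed) {
  folds <- integer(length(pos_flags))
  rs <- local_rng(seed)
  on.exit(rs$restore())
  for (cls in c(TRUE, FALSE)) {
    idx <- which(pos_flags == cls)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

# Penalized ML fit of p = 1/(1+exp(A f + B)) with A < 0 via A = -exp(a).
fit_platt <- function(f, pos_flags, lambda = 1e-6) {
  yy <- as.numeric(pos_flags)
  nll <- function(par) {
    A <- -exp(par[1]); B <- par[2]
    eta <- -(A * f + B)                 # logit of p(positive)
    # ll = y*eta - log(1+exp(eta)), the log1p term computed stably
    ll <- yy * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))
    -sum(ll) + lambda * (A^2 + B^2)
  }
  fit <- optim(c(0, 0), nll, method = "BFGS")
  list(A = -exp(fit$par[1]), B = fit$par[2])
}

#' Predictive probability of the positive class
#'
#' Returns `p(positive)` for each query sample: the calibrated logit map of
#' the decision value for SVM, the softmax of negative discriminants for
#' dLDA, and the neighbour-vote fraction for kNN. The classification rule
#' is `p > 0.5` predicts positive; `p = 0.5` exactly is classified
#' negative (total uncertainty never predicts the positive outcome).
#'
#' @param model A `cc_model`; an SVM model must have been passed through
#'   [calibrate_logit()] first.
#' @param query Features-x-samples matrix or feature vector.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(model, query) {
  q <- align_query(model, query)
  switch(model$family,
    svm = {
      if (is.null(model$calibration)) {
        stop("SVM model is uncalibrated; run calibrate_logit() before ",
             "predict_proba()", call. = FALSE)
      }
      f <- decision_value(model, q)
      1 / (1 + exp(model$calibration$A * f + model$calibration$B))
    },
    dlda = stats::plogis(decision_value(model, q)),
    knn = apply(q, 2, function(x) {
      knn_vote(model$params$train, model$params$pos_flags, x, model$params$k)
    })
  )
}

#' Predicted class labels
#'
#' SVM and dLDA classify by the sign of the decision value (a tie at
#' exactly zero goes to the negative class); kNN by majority vote.
#'
#' @inheritParams predict_proba
#' @return Character vector of class names.
#' @export
predict_class <- function(model, query) {
  q <- align_query(model, query)
  pos <- switch(model$family,
    knn = predict_proba(model, q) > 0.5,
    decision_value(model, q) > 0
  )
  ifelse(pos, model$positive, model$negative)
}

# Seed-scoped RNG helper: sets the seed, returns a restorer for the
# caller's RNG state so library code never clobbers the user's stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  list(restore = function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
}
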