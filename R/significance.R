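#' Permutation test of the cross-validated misclassification rate
#'
#' Repeats the *entire* nested LOOCV — including in-fold feature selection
#' — on `n_perm` independent random permutations of the class labels, and
#' reports the proportion of permutations whose cross-validated error rate
#' is smaller than or equal to the observed one. This is the unsmoothed
#' permutation p-value; `smooth = TRUE` adds the +1 correction
#' `(b + 1) / (n_perm + 1)` for users who prefer the estimate that can
#' never be exactly zero.
#'
#' Each permutation draws its labels from its own counter-derived seed
#' (`seed + index`), so any individual null replicate can be reproduced in
#' isolation.
#'
#' @inheritParams loocv
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed governing the permutation stream.
#' @param smooth Use the +1-smoothed p-value estimate instead of the plain
#'   proportion.
#' @return A `cc_perm` object with `observed_error`, `null_errors`,
#'   `p_value`, `n_perm`, `seed`; see the `tidy()`/`glance()` methods.
#' @export
permutation_test <- function(X, y, spec, n_perm = 1000, seed = 1,
                             test = c("pooled", "welch"), smooth = FALSE) {
  test <- match.arg(test)
  if (!is.numeric(n_perm) || length(n_perm) != 1 || n_perm < 1) {
    stop("`n_perm` must be a positive integer", call. = FALSE)
  }
  n_perm <- as.integer(n_perm)
  v <- as_feature_matrix(X)
  y <- check_labels(v, y, min_per_class = 3L)
  observed <- 1 - loocv(v_as_expr(v, X), y, spec, seed = seed,
                        proba = FALSE, test = test)$accuracy
  ids <- names(unclass(y))
  classes <- unname(unclass(y))
  null_errors <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    rs <- local_rng(seed + b)
    perm <- sample.int(length(classes))
    rs$restore()
    y_b <- label_vector(ids, classes[perm], positive = positive_name(y),
                        negative = negative_name(y))
    null_errors[b] <- 1 - loocv(v_as_expr(v, X), y_b, spec, seed = seed,
                                proba = FALSE, test = test)$accuracy
  }
  hits <- sum(null_errors <= observed)
  p_value <- if (smooth) (hits + 1) / (n_perm + 1) else hits / n_perm
  structure(list(observed_error = observed, null_errors = null_errors,
                 p_value = p_value, n_perm = n_perm, seed = seed,
                 smooth = smooth, spec = spec),
            class = "cc_perm")
}

# Rewrap a plain matrix with the scale of the object it came from.
v_as_expr <- function(v, X) {
  sc <- if (inherits(X, "expr_matrix")) expr_scale(X) else "unlogged"
  expression_matrix(v, scale = sc)
}

#' @export
print.cc_perm <- function(x, ...) {
  cat(sprintf(
    "<cc_perm> observed error %.3f vs %d permutations: p = %.4g%s\n",
    x$observed_error, x$n_perm, x$p_value,
    if (x$smooth) " (+1 smoothed)" else ""))
  invisible(x)
}

#' @rdname permutation_test
#' @param x A `cc_perm` object.
#' @param ... Unused.
#' @method tidy cc_perm
#' @export
tidy.cc_perm <- function(x, ...) {
  tibble::tibble(permutation = seq_len(x$n_perm), null_error = x$null_errors)
}

#' @rdname permutation_test
#' @method glance cc_perm
#' @export
glance.cc_perm <- function(x, ...) {
  tibble::tibble(
    observed_error = x$observed_error,
    p_value = x$p_value,
    n_perm = x$n_perm,
    null_error_mean = mean(x$null_errors),
    seed = x$seed
  )
}

#' Receiver operating characteristic curve
#'
#' Threshold sweep over the unique score values (samples with tied scores
#' enter at a single threshold), giving the standard staircase from
#' (0, 0) to (1, 1); the AUC is the trapezoidal area under it, which
#' equals the Mann-Whitney probability that a random positive sample
#' outscores a random negative one (ties counting one half).
#'
#' @param scores Numeric score per sample (e.g. predictive probability of
#'   the positive class).
#' @param y A [label_vector()] aligned with `scores`; both classes must be
#'   present.
#' @return A `cc_roc` object: tibble of `threshold`, `tpr`, `fpr` rows
#'   (thresholds descending, starting above the maximum score) with an
#'   `auc` attribute; see [autoplot()][ggplot2::autoplot].
#' @export
roc_curve <- function(scores, y) {
  if (length(scores) != length(unclass(y))) {
    stop("`scores` and labels must have the same length", call. = FALSE)
  }
  pos <- is_positive(y)
  if (!any(pos) || all(pos)) {
    stop("ROC needs both classes present", call. = FALSE)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  tpr <- vapply(thr, function(t) sum(scores >= t & pos) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !pos) / n_neg, numeric(1))
  curve <- tibble::tibble(
    threshold = c(Inf, thr),
    tpr = c(0, tpr),
    fpr = c(0, fpr)
  )
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
  structure(curve, auc = auc, positive = positive_name(y),
            class = c("cc_roc", class(curve)))
}

#' @rdname roc_curve
#' @param x A `cc_roc` object.
#' @export
auc <- function(x) {
  attr(x, "auc")
}

#' @export
print.cc_roc <- function(x, ...) {
  cat(sprintf("<cc_roc> %d threshold(s), AUC = %.3f (positive class: %s)\n",
              nrow(x) - 1L, attr(x, "auc"), attr(x, "positive")))
  NextMethod()
}
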