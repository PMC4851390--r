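#' Confusion-matrix metrics
#'
#' Closed-form performance ratios from the four confusion counts. Ratios
#' with a zero denominator (e.g. PPV when nothing is called positive) are
#' reported as 0 and named in the `undefined` column, matching the
#' convention of reporting 0 for a degenerate classifier rather than NA.
#'
#' @param tp,fn,tn,fp Non-negative integer counts; their total must be
#'   positive.
#' @return A one-row tibble with the counts, `accuracy`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, and an `undefined` column listing any
#'   ratios that had zero denominator.
#' @examples
#' confusion_metrics(tp = 10, fn = 2, tn = 12, fp = 3)
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  total <- sum(counts)
  if (total == 0) {
    stop("all confusion counts are zero", call. = FALSE)
  }
  safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  vals <- c(
    sensitivity = safe_ratio(tp, tp + fn),
    specificity = safe_ratio(tn, tn + fp),
    ppv = safe_ratio(tp, tp + fp),
    npv = safe_ratio(tn, tn + fn)
  )
  undefined <- names(vals)[is.na(vals)]
  vals[is.na(vals)] <- 0
  tibble::tibble(
    tp = as.integer(tp), fn = as.integer(fn),
    tn = as.integer(tn), fp = as.integer(fp),
    accuracy = (tp + tn) / total,
    sensitivity = vals[["sensitivity"]],
    specificity = vals[["specificity"]],
    ppv = vals[["ppv"]],
    npv = vals[["npv"]],
    undefined = paste(undefined, collapse = ",")
  )
}

# One LOOCV fold: selection on training samples only, then train/predict.
# Returns list(predicted, prob, selected, empty).
run_fold <- function(v, y, hold, spec, annot, test, cal_seed, proba,
                     preselected = NULL) {
  train_idx <- setdiff(seq_len(ncol(v)), hold)
  y_train <- y[train_idx]
  pos <- which(is_positive(y_train)); neg <- which(!is_positive(y_train))
  vt <- v[, train_idx, drop = FALSE]
  if (is.null(preselected)) {
    tt <- row_ttest(vt, pos, neg, test = test)
    sel <- which(tt$p < spec$p_cutoff)
  } else {
    sel <- match(preselected, rownames(v))
  }
  if (length(sel) == 0) {
    maj <- if (length(pos) >= length(neg)) positive_name(y) else negative_name(y)
    return(list(predicted = maj, prob = 0.5, selected = character(0),
                empty = TRUE))
  }
  model <- train_classifier(vt[sel, , drop = FALSE], y_train, spec)
  query <- v[sel, hold, drop = FALSE]
  predicted <- predict_class(model, query)
  prob <- NA_real_
  if (proba) {
    if (model$family == "svm") {
      model <- calibrate_logit(model, vt[sel, , drop = FALSE], y_train,
                               seed = cal_seed)
    }
    prob <- unname(predict_proba(model, query))
  }
  list(predicted = unname(predicted), prob = prob,
       selected = rownames(v)[sel], empty = FALSE)
}

# Assemble a cc_cv object from per-fold results.
new_cc_cv <- function(per_fold, support, y, spec, seed) {
  truth_pos <- per_fold$true_class == positive_name(y)
  pred_pos <- per_fold$predicted_class == positive_name(y)
  metrics <- confusion_metrics(
    tp = sum(truth_pos & pred_pos), fn = sum(truth_pos & !pred_pos),
    tn = sum(!truth_pos & !pred_pos), fp = sum(!truth_pos & pred_pos)
  )
  structure(list(
    per_fold = per_fold,
    support = support,
    accuracy = metrics$accuracy,
    per_class_accuracy = c(
      setNames(mean(pred_pos[truth_pos]), positive_name(y)),
      setNames(mean(!pred_pos[!truth_pos]), negative_name(y))
    ),
    metrics = metrics,
    spec = spec,
    positive = positive_name(y),
    negative = negative_name(y),
    seed = seed
  ), class = "cc_cv")
}

#' Leave-one-out cross-validation with in-fold feature selection
#'
#' The core engine. Each sample is held out once; univariate t-test
#' feature selection at `spec$p_cutoff` is repeated on the remaining
#' samples only, the classifier is trained on those samples restricted to
#' the selected probes, and the held-out sample is predicted. The held-out
#' sample never influences selection or training — the property that makes
#' the cross-validated error rate honest.
#'
#' A fold whose selection is empty predicts the training-majority class
#' with probability 0.5 and is flagged rather than aborting the run.
#'
#' @param X An [expression_matrix()].
#' @param y A [label_vector()]; at least 3 samples per class so every
#'   training fold retains 2 per class for the t-test.
#' @param spec A [classifier_spec()].
#' @param seed Integer seed (only classifier-internal randomness — the
#'   calibration inner folds — consumes it; fold order is the sample order).
#' @param proba Whether to compute predictive probabilities (SVM folds are
#'   then logit-calibrated, which costs inner refits); disable for speed
#'   when only the error rate is needed, e.g. inside permutation tests.
#' @param test t-test variant, `"pooled"` or `"welch"`.
#' @param preselected_features Optional character vector of probe ids.
#'   When given, in-fold selection is *skipped* and these features are used
#'   in every fold. This deliberately reintroduces selection bias and
#'   exists only to demonstrate feature-selection leakage; never use it for
#'   a real analysis.
#' @return A `cc_cv` object; see [tidy()][generics::tidy] and
#'   [glance()][generics::glance] methods.
#' @export
loocv <- function(X, y, spec, seed = 1, proba = TRUE,
                  test = c("pooled", "welch"), preselected_features = NULL) {
  test <- match.arg(test)
  v <- as_feature_matrix(X)
  y <- check_labels(v, y, min_per_class = 3L)
  n <- ncol(v)
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    folds[[i]] <- run_fold(v, y, i, spec, annot = NULL, test = test,
                           cal_seed = seed + i, proba = proba,
                           preselected = preselected_features)
  }
  per_fold <- tibble::tibble(
    fold = seq_len(n),
    sample_id = colnames(v),
    true_class = unname(unclass(y)),
    predicted_class = purrr::map_chr(folds, "predicted"),
    prob_positive = purrr::map_dbl(folds, "prob"),
    n_selected = purrr::map_int(folds, ~ length(.x$selected)),
    empty_selection = purrr::map_lgl(folds, "empty"),
    selected = purrr::map(folds, "selected")
  )
  if (any(per_fold$empty_selection)) {
    warning(sum(per_fold$empty_selection),
            " fold(s) selected zero probes and fell back to the ",
            "training-majority class", call. = FALSE)
  }
  support <- cv_support_table(per_fold$selected, n)
  new_cc_cv(per_fold, support, y, spec, seed)
}

# Per-probe cross-validation support from per-fold selection lists.
cv_support_table <- function(selected_lists, n_folds) {
  all_sel <- unlist(selected_lists, use.names = FALSE)
  if (!length(all_sel)) {
    return(tibble::tibble(probe_id = character(0), n_folds_selected = integer(0),
                          cv_support = numeric(0)))
  }
  tab <- table(all_sel)
  out <- tibble::tibble(
    probe_id = names(tab),
    n_folds_selected = as.integer(tab),
    cv_support = 100 * as.integer(tab) / n_folds
  )
  dplyr::arrange(out, dplyr::desc(.data$cv_support), .data$probe_id)
}

#' @export
print.cc_cv <- function(x, ...) {
  cat(sprintf("<cc_cv> %s | LOOCV over %d samples: accuracy %.3f (%s %.0f%%, %s %.0f%%)\n",
              spec_label(x$spec), nrow(x$per_fold), x$accuracy,
              x$positive, 100 * x$per_class_accuracy[[x$positive]],
              x$negative, 100 * x$per_class_accuracy[[x$negative]]))
  invisible(x)
}

#' @rdname loocv
#' @param x A `cc_cv` object.
#' @param ... Unused.
#' @method tidy cc_cv
#' @export
tidy.cc_cv <- function(x, ...) {
  dplyr::select(x$per_fold, -"selected")
}

#' @rdname loocv
#' @method glance cc_cv
#' @export
glance.cc_cv <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      algorithm = x$spec$algorithm,
      p_cutoff = x$spec$p_cutoff,
      n_folds = nrow(x$per_fold),
      median_features = median(x$per_fold$n_selected),
      n_empty_folds = sum(x$per_fold$empty_selection)
    ),
    x$metrics
  )
}

#' Scan a grid of classifier specifications by LOOCV
#'
#' Runs [loocv()] for every combination of the supplied specifications,
#' sharing the per-fold t-tests across the grid (the selection p-values of
#' a fold do not depend on the cutoff or the classifier). Returns one row
#' per model, the material of a model-selection table.
#'
#' @inheritParams loocv
#' @param specs List of [classifier_spec()] objects, e.g. from
#'   [default_spec_grid()].
#' @return A tibble with one row per spec: `algorithm`, `hyperparameter`,
#'   `p_cutoff`, `accuracy`, per-class accuracies, `median_features`, and a
#'   `cv` list-column of `cc_cv` objects.
#' @export
loocv_grid <- function(X, y, specs, seed = 1, proba = FALSE,
                       test = c("pooled", "welch")) {
  test <- match.arg(test)
  v <- as_feature_matrix(X)
  y <- check_labels(v, y, min_per_class = 3L)
  n <- ncol(v)
  # Per-fold selection p-values, computed once and reused by every spec.
  fold_p <- vector("list", n)
  for (i in seq_len(n)) {
    train_idx <- setdiff(seq_len(n), i)
    y_train <- y[train_idx]
    fold_p[[i]] <- row_ttest(v[, train_idx, drop = FALSE],
                             which(is_positive(y_train)),
                             which(!is_positive(y_train)), test = test)$p
  }
  rows <- purrr::map(specs, function(spec) {
    folds <- vector("list", n)
    for (i in seq_len(n)) {
      sel <- which(fold_p[[i]] < spec$p_cutoff)
      folds[[i]] <- run_fold_presel(v, y, i, spec, sel, seed + i, proba)
    }
    per_fold <- tibble::tibble(
      fold = seq_len(n),
      sample_id = colnames(v),
      true_class = unname(unclass(y)),
      predicted_class = purrr::map_chr(folds, "predicted"),
      prob_positive = purrr::map_dbl(folds, "prob"),
      n_selected = purrr::map_int(folds, ~ length(.x$selected)),
      empty_selection = purrr::map_lgl(folds, "empty"),
      selected = purrr::map(folds, "selected")
    )
    cv <- new_cc_cv(per_fold, cv_support_table(per_fold$selected, n), y,
                    spec, seed)
    tibble::tibble(
      algorithm = spec$algorithm,
      hyperparameter = switch(spec$algorithm,
                              svm = sprintf("cost=%g", spec$cost),
                              knn = sprintf("k=%d", spec$k),
                              dlda = ""),
      p_cutoff = spec$p_cutoff,
      accuracy = cv$accuracy,
      accuracy_positive = cv$per_class_accuracy[[1]],
      accuracy_negative = cv$per_class_accuracy[[2]],
      median_features = median(per_fold$n_selected),
      spec = list(spec),
      cv = list(cv)
    )
  })
  dplyr::bind_rows(rows)
}

# Fold runner for loocv_grid: selection indices already known.
run_fold_presel <- function(v, y, hold, spec, sel, cal_seed, proba) {
  train_idx <- setdiff(seq_len(ncol(v)), hold)
  y_train <- y[train_idx]
  if (length(sel) == 0) {
    maj <- if (sum(is_positive(y_train)) >= sum(!is_positive(y_train))) {
      positive_name(y)
    } else {
      negative_name(y)
    }
    return(list(predicted = maj, prob = 0.5, selected = character(0),
                empty = TRUE))
  }
  vt <- v[sel, train_idx, drop = FALSE]
  model <- train_classifier(vt, y_train, spec)
  query <- v[sel, hold, drop = FALSE]
  predicted <- predict_class(model, query)
  prob <- NA_real_
  if (proba) {
    if (model$family == "svm") {
      model <- calibrate_logit(model, vt, y_train, seed = cal_seed)
    }
    prob <- unname(predict_proba(model, query))
  }
  list(predicted = unname(predicted), prob = prob,
       selected = rownames(v)[sel], empty = FALSE)
}

#' Default model-selection grid
#'
#' Three classifier families crossed with the four-cutoff p-value grid:
#' linear SVM, k-nearest neighbours, and dLDA, giving the 12-row
#' model-selection table scanned during training.
#'
#' @param p_grid P-value cutoffs (default `c(0.001, 0.005, 0.01, 0.05)`).
#' @param cost SVM cost for the training grid.
#' @param k Neighbour count for kNN.
#' @return A list of [classifier_spec()] objects.
#' @export
default_spec_grid <- function(p_grid = c(0.001, 0.005, 0.01, 0.05), cost = 1,
                              k = 3) {
  specs <- list()
  for (p in p_grid) {
    specs <- c(specs,
               list(classifier_spec("svm", cost = cost, p_cutoff = p),
                    classifier_spec("knn", k = k, p_cutoff = p),
                    classifier_spec("dlda", p_cutoff = p)))
  }
  specs
}

#' Choose the optimal model from a selection grid
#'
#' Picks the row of a [loocv_grid()] table with maximal LOOCV accuracy.
#' Ties are broken toward the model selecting fewer features (median
#' across folds) — the more parsimonious signature — and then by algorithm
#' order SVM, kNN, dLDA.
#'
#' @param results The tibble returned by [loocv_grid()].
#' @return A list with elements `spec` (the winning [classifier_spec()]),
#'   `cv` (its `cc_cv`), and `row` (the winning grid row).
#' @export
choose_optimal <- function(results) {
  if (!is.data.frame(results) || nrow(results) == 0) {
    stop("empty model-selection table", call. = FALSE)
  }
  alg_rank <- c(svm = 1L, knn = 2L, dlda = 3L)
  ord <- order(-results$accuracy, results$median_features,
               alg_rank[results$algorithm])
  best <- results[ord[1], ]
  list(spec = best$spec[[1]], cv = best$cv[[1]], row = best)
}

#' Build the final signature from the full data set
#'
#' Selects probes at `p < p_cutoff` on the complete data set (the model
#' actually deployed), then attaches each probe's cross-validation support
#' — the percentage of LOOCV training folds in which it passed selection,
#' a measure of its stability (0 for a probe never selected in any fold).
#' Rows are ordered by descending support, then ascending p-value.
#'
#' @inheritParams loocv
#' @param p_cutoff Selection cutoff; must equal the cutoff used for `cv`.
#' @param cv The `cc_cv` computed at the same cutoff on the same data.
#' @param annot Optional [probe_annotation()] for gene symbols.
#' @return A signature tibble with columns `probe_id`, `gene_symbol`,
#'   `t_statistic`, `p_value`, `fold_change`, `cv_support`.
#' @export
final_signature <- function(X, y, p_cutoff, cv, annot = NULL,
                            test = c("pooled", "welch")) {
  test <- match.arg(test)
  sig <- select_features_ttest(X, y, p_cutoff, annot = annot, test = test)
  if (nrow(sig) == 0) {
    stop("no probe passes p < ", p_cutoff,
         " on the full data set; consider a larger cutoff", call. = FALSE)
  }
  idx <- match(sig$probe_id, cv$support$probe_id)
  sig$cv_support <- ifelse(is.na(idx), 0, cv$support$cv_support[idx])
  dplyr::arrange(sig, dplyr::desc(.data$cv_support), .data$p_value,
                 .data$probe_id)
}
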