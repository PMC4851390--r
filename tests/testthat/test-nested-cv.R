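test_that("LOOCV holds each sample out exactly once", {
  sim <- small_sim(seed = 3)
  X <- filter_above_background(filter_annotated(sim$expr, sim$annot))
  cv <- loocv(X, sim$labels, classifier_spec("dlda", p_cutoff = 0.01),
              proba = FALSE)
  expect_identical(nrow(cv$per_fold), ncol(X))
  expect_identical(sort(cv$per_fold$sample_id), sort(colnames(X)))
  expect_identical(anyDuplicated(cv$per_fold$sample_id), 0L)
})

test_that("well-separated planted classes are classified perfectly", {
  sim <- small_sim(seed = 5, fold_change = 8, cv_within = 0.15)
  X <- filter_above_background(filter_annotated(sim$expr, sim$annot))
  for (spec in list(classifier_spec("svm", cost = 1, p_cutoff = 0.01),
                    classifier_spec("knn", k = 3, p_cutoff = 0.01),
                    classifier_spec("dlda", p_cutoff = 0.01))) {
    cv <- loocv(X, sim$labels, spec, proba = FALSE)
    expect_equal(cv$accuracy, 1.0)
  }
})

test_that("in-fold selection never sees the held-out sample", {
  sim <- small_sim(seed = 13, n_probes = 300, n_de = 10)
  X <- sim$expr
  spec <- classifier_spec("dlda", p_cutoff = 0.01)
  cv <- loocv(X, sim$labels, spec, proba = FALSE)
  # corrupt one held-out sample arbitrarily: its fold's selection and
  # prediction machinery must be unchanged
  for (fold in c(1L, 10L, 27L)) {
    v <- unclass(X)
    v[, fold] <- v[, fold] * 1000 + 5
    Xc <- expression_matrix(v, scale = expr_scale(X))
    cvc <- suppressWarnings(loocv(Xc, sim$labels, spec, proba = FALSE))
    expect_identical(cvc$per_fold$selected[[fold]],
                     cv$per_fold$selected[[fold]])
  }
})

test_that("cross-validation support equals a direct per-fold recount", {
  sim <- small_sim(seed = 6, n_probes = 300, n_de = 10)
  cv <- loocv(sim$expr, sim$labels, classifier_spec("dlda", p_cutoff = 0.01),
              proba = FALSE)
  n <- nrow(cv$per_fold)
  for (probe in cv$support$probe_id[c(1, nrow(cv$support))]) {
    count <- sum(vapply(cv$per_fold$selected, function(s) probe %in% s,
                        logical(1)))
    row <- cv$support[cv$support$probe_id == probe, ]
    expect_identical(row$n_folds_selected, count)
    expect_equal(row$cv_support, 100 * count / n)
  }
  expect_true(all(cv$support$cv_support >= 0 & cv$support$cv_support <= 100))
})

test_that("folds with empty selection fall back to the training majority", {
  # pure noise at a tiny cutoff: most folds select nothing
  sim <- simulate_study(simulation_config(n_pos = 5, n_neg = 7,
                                          n_probes = 50, n_de = 0,
                                          fold_change = 1, seed = 4))
  expect_warning(
    cv <- loocv(sim$expr, sim$labels, classifier_spec("dlda", p_cutoff = 0.001),
                proba = TRUE),
    "zero probes"
  )
  empty <- cv$per_fold[cv$per_fold$empty_selection, ]
  expect_gt(nrow(empty), 0)
  expect_true(all(empty$prob_positive == 0.5))
  expect_true(all(empty$predicted_class == "NP"))  # NP is the majority
})

test_that("the model-selection scan covers the grid and picks the argmax", {
  sim <- small_sim(seed = 7, n_probes = 400, n_de = 15)
  X <- filter_above_background(sim$expr)
  grid <- loocv_grid(X, sim$labels, default_spec_grid(), seed = 1)
  expect_identical(nrow(grid), 12L)  # 3 algorithms x 4 cutoffs
  expect_identical(sort(unique(grid$algorithm)), c("dlda", "knn", "svm"))
  expect_identical(sort(unique(grid$p_cutoff)), c(0.001, 0.005, 0.01, 0.05))
  best <- choose_optimal(grid)
  expect_equal(best$cv$accuracy, max(grid$accuracy))
  # grid rows agree with standalone loocv runs
  i <- which(grid$algorithm == "dlda" & grid$p_cutoff == 0.01)
  solo <- loocv(X, sim$labels, classifier_spec("dlda", p_cutoff = 0.01),
                proba = FALSE)
  expect_equal(grid$accuracy[i], solo$accuracy)
  expect_identical(grid$cv[[i]]$per_fold$selected, solo$per_fold$selected)
})

test_that("choose_optimal breaks ties toward fewer features then algorithm order", {
  mk <- function(alg, acc, feats) {
    tibble::tibble(algorithm = alg, p_cutoff = 0.01, accuracy = acc,
                   median_features = feats,
                   spec = list(classifier_spec(alg, p_cutoff = 0.01,
                                               k = if (alg == "knn") 3,
                                               cost = if (alg == "svm") 1)),
                   cv = list(NULL))
  }
  grid <- dplyr::bind_rows(mk("dlda", 0.57, 12), mk("svm", 0.81, 82),
                           mk("knn", 0.85, 40))
  expect_identical(choose_optimal(grid)$spec$algorithm, "knn")
  # equal accuracy: the 34-feature model beats the 82-feature model
  grid2 <- dplyr::bind_rows(mk("svm", 0.81, 82), mk("svm", 0.81, 34))
  expect_identical(choose_optimal(grid2)$row$median_features, 34)
  # full tie: algorithm order svm, knn, dlda
  grid3 <- dplyr::bind_rows(mk("dlda", 0.8, 10), mk("svm", 0.8, 10),
                            mk("knn", 0.8, 10))
  expect_identical(choose_optimal(grid3)$spec$algorithm, "svm")
  expect_error(choose_optimal(grid3[0, ]), "empty")
})

test_that("the final signature reflects full-data selection and fold support", {
  sim <- small_sim(seed = 8, n_probes = 400, n_de = 15)
  X <- filter_above_background(filter_annotated(sim$expr, sim$annot))
  spec <- classifier_spec("svm", cost = 1, p_cutoff = 0.01)
  cv <- loocv(X, sim$labels, spec, proba = FALSE)
  sig <- final_signature(X, sim$labels, 0.01, cv, annot = sim$annot)
  # every full-data selected probe appears
  full <- select_features_ttest(X, sim$labels, 0.01)
  expect_setequal(sig$probe_id, full$probe_id)
  # planted probes surviving the filters and passing full-data selection
  # all land in the signature
  planted_here <- intersect(sim$truth$de_probe_ids, full$probe_id)
  expect_true(all(planted_here %in% sig$probe_id))
  # probes selected in all folds get support 100
  always <- cv$support$probe_id[cv$support$n_folds_selected == nrow(cv$per_fold)]
  expect_gt(length(always), 0)
  expect_true(all(sig$cv_support[sig$probe_id %in% always] == 100))
  # ordering: support descending, then p ascending
  expect_true(all(diff(sig$cv_support) <= 0))
  # symbols came from the annotation
  expect_true(all(sig$gene_symbol[sig$probe_id %in% sim$annot$probe_id] != ""))
  expect_error(final_signature(X, sim$labels, 1e-30, cv), "cutoff")
})

test_that("confusion metrics reproduce closed-form ratios and flag undefined ones", {
  m <- confusion_metrics(tp = 10, fn = 2, tn = 12, fp = 3)
  expect_equal(m$accuracy, 22 / 27)
  expect_equal(round(m$accuracy, 2), 0.81)
  expect_equal(m$sensitivity, 10 / 12)
  expect_equal(m$specificity, 12 / 15)
  expect_equal(m$ppv, 10 / 13)
  expect_equal(m$npv, 12 / 14)
  expect_identical(m$undefined, "")

  # degenerate classifier that calls almost everything one way
  g <- confusion_metrics(tp = 2, fn = 8, tn = 0, fp = 9)
  expect_equal(g$accuracy, 2 / 19)
  expect_equal(g$sensitivity, 0.2)
  expect_equal(g$specificity, 0)
  expect_equal(g$ppv, 2 / 11)
  expect_equal(g$npv, 0)

  # perfect classifier
  p <- confusion_metrics(tp = 9, fn = 0, tn = 0, fp = 0)
  expect_equal(p$accuracy, 1)
  expect_equal(p$sensitivity, 1)
  expect_match(p$undefined, "specificity")

  expect_error(confusion_metrics(0, 0, 0, 0), "zero")
  expect_error(confusion_metrics(-1, 0, 2, 0), "non-negative")

  # identity sweep over random counts
  set.seed(3)
  for (rep in 1:25) {
    cts <- rpois(4, 6)
    if (sum(cts) == 0) next
    m <- confusion_metrics(cts[1], cts[2], cts[3], cts[4])
    expect_equal(m$accuracy, (cts[1] + cts[3]) / sum(cts))
    if (cts[1] + cts[2] > 0) expect_equal(m$sensitivity, cts[1] / (cts[1] + cts[2]))
    if (cts[3] + cts[4] > 0) expect_equal(m$specificity, cts[3] / (cts[3] + cts[4]))
    if (cts[1] + cts[4] > 0) expect_equal(m$ppv, cts[1] / (cts[1] + cts[4]))
    if (cts[3] + cts[2] > 0) expect_equal(m$npv, cts[3] / (cts[3] + cts[2]))
  }
})
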