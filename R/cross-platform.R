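#' Translate a signature to a second platform by gene symbol
#'
#' Maps each unique gene symbol of a signature onto the probes of a
#' target platform. Genes absent from the target annotation are reported
#' as unmapped; genes with several redundant target probes are resolved by
#' the intermediate-expression rule: candidates are ranked by their mean
#' expression across the target samples and the median-ranked probe is
#' chosen (for an even number of candidates, the lower median). The full
#' resolution is logged so the choice can be audited.
#'
#' @param sig Signature tibble (from [final_signature()]); gene symbols
#'   must be present.
#' @param target_annot [probe_annotation()] of the target platform; must
#'   carry gene symbols.
#' @param X_target [expression_matrix()] of the target samples on the
#'   log2 scale (the scale on which external data are validated).
#' @return A `cc_mapping` object: `pairs` (tibble `gene_symbol`,
#'   `source_probe`, `target_probe`), `unmapped_genes` (character), and
#'   `resolution_log` (tibble of every candidate with its mean expression
#'   and whether it was chosen).
#' @export
translate_signature <- function(sig, target_annot, X_target) {
  if (!is.data.frame(sig) || nrow(sig) == 0) {
    stop("empty signature", call. = FALSE)
  }
  if (expr_scale(X_target) != "log2") {
    stop("target matrix must be on the log2 scale; apply log2_transform() first",
         call. = FALSE)
  }
  if (all(target_annot$gene_symbol == "")) {
    stop("target annotation carries no gene symbols; symbol-level ",
         "translation is impossible", call. = FALSE)
  }
  with_symbol <- sig[sig$gene_symbol != "", , drop = FALSE]
  if (nrow(with_symbol) == 0) {
    stop("signature has no gene symbols to translate", call. = FALSE)
  }
  # One source probe represents each gene: the signature's top-ranked row.
  rep_rows <- with_symbol[!duplicated(with_symbol$gene_symbol), ]
  target_means <- rowMeans(unclass(X_target))

  res <- purrr::map(seq_len(nrow(rep_rows)), function(i) {
    gene <- rep_rows$gene_symbol[i]
    cand <- target_annot$probe_id[target_annot$gene_symbol == gene]
    cand <- cand[cand %in% rownames(X_target)]
    if (length(cand) == 0) {
      return(list(unmapped = gene, pair = NULL, log = NULL))
    }
    m <- target_means[cand]
    ord <- order(m, cand)       # ascending mean; id breaks exact ties
    pick <- cand[ord][ceiling(length(cand) / 2)]  # lower median when even
    list(
      unmapped = NULL,
      pair = tibble::tibble(gene_symbol = gene,
                            source_probe = rep_rows$probe_id[i],
                            target_probe = pick),
      log = tibble::tibble(gene_symbol = gene, candidate_probe = cand,
                           mean_expression = unname(m),
                           chosen = cand == pick)
    )
  })
  structure(list(
    pairs = dplyr::bind_rows(purrr::map(res, "pair")),
    unmapped_genes = unlist(purrr::map(res, "unmapped")) %||% character(0),
    resolution_log = dplyr::bind_rows(purrr::map(res, "log"))
  ), class = "cc_mapping")
}

#' @export
print.cc_mapping <- function(x, ...) {
  cat(sprintf("<cc_mapping> %d gene(s) mapped, %d unmapped\n",
              nrow(x$pairs), length(x$unmapped_genes)))
  invisible(x)
}

#' @rdname translate_signature
#' @param x A `cc_mapping` object.
#' @param ... Unused.
#' @method tidy cc_mapping
#' @export
tidy.cc_mapping <- function(x, ...) {
  x$resolution_log
}

# Per-feature z-scores within one data set; constant features become 0.
standardize_rows <- function(v) {
  mu <- rowMeans(v)
  s <- apply(v, 1, sd)
  s[s == 0] <- 1
  (v - mu) / s
}

#' Validate a signature on an external cohort
#'
#' Tests a trained signature on samples from a second platform. The
#' training matrix is restricted to the mapped source probes and the
#' external matrix to the paired target probes; each side is then
#' log2-scaled (if not already) and standardized per feature *within its
#' own data set* (gene-wise z-scores), the bridge that makes intensities
#' from two platforms commensurable. For each cost in the grid a linear
#' SVM is trained with logit calibration on the training side only and
#' applied to every external sample; external samples never refit the
#' classifier.
#'
#' @param X_train Training [expression_matrix()].
#' @param y_train Training [label_vector()].
#' @param mapping A `cc_mapping` from [translate_signature()].
#' @param X_ext External [expression_matrix()] on the log2 scale.
#' @param y_ext External [label_vector()] (e.g. classes B/EP).
#' @param cost_grid SVM cost values to sweep (default `c(1, 2, 10)`).
#' @param seed Integer seed for the calibration inner folds.
#' @return A `cc_external` object: `per_cost` metrics tibble and
#'   `probabilities` (per-cost per-sample predictions); see the
#'   `tidy()`/`glance()` methods.
#' @export
external_validate <- function(X_train, y_train, mapping, X_ext, y_ext,
                              cost_grid = c(1, 2, 10), seed = 1) {
  if (!inherits(mapping, "cc_mapping") || nrow(mapping$pairs) == 0) {
    stop("mapping is empty; nothing to validate", call. = FALSE)
  }
  if (expr_scale(X_ext) != "log2") {
    stop("external matrix must be on the log2 scale", call. = FALSE)
  }
  miss_src <- setdiff(mapping$pairs$source_probe, rownames(X_train))
  miss_tgt <- setdiff(mapping$pairs$target_probe, rownames(X_ext))
  if (length(miss_src) || length(miss_tgt)) {
    stop("mapping references absent probe(s): ",
         paste(head(c(miss_src, miss_tgt), 5), collapse = ", "), call. = FALSE)
  }
  y_train <- check_labels(as_feature_matrix(X_train), y_train,
                          min_per_class = 3L)
  y_ext <- check_labels(as_feature_matrix(X_ext), y_ext, min_per_class = 1L)

  vt <- unclass(X_train)[mapping$pairs$source_probe, , drop = FALSE]
  if (expr_scale(X_train) == "unlogged") vt <- log2(vt + 1)
  ve <- unclass(X_ext)[mapping$pairs$target_probe, , drop = FALSE]
  # Pair rows by gene under a common feature naming.
  rownames(vt) <- rownames(ve) <- mapping$pairs$gene_symbol
  vt <- standardize_rows(vt)
  ve <- standardize_rows(ve)

  res <- purrr::map(cost_grid, function(cost) {
    spec <- classifier_spec("svm", cost = cost, p_cutoff = 0.5)
    model <- train_classifier(vt, y_train, spec)
    model <- calibrate_logit(model, vt, y_train, seed = seed)
    prob <- unname(predict_proba(model, ve))
    pred_pos <- prob > 0.5
    truth_pos <- is_positive(y_ext)
    metrics <- confusion_metrics(
      tp = sum(truth_pos & pred_pos), fn = sum(truth_pos & !pred_pos),
      tn = sum(!truth_pos & !pred_pos), fp = sum(!truth_pos & pred_pos)
    )
    list(
      metrics = dplyr::bind_cols(tibble::tibble(cost = cost), metrics),
      prob = tibble::tibble(
        cost = cost,
        sample_id = names(unclass(y_ext)),
        true_class = unname(unclass(y_ext)),
        prob_positive = prob,
        predicted_class = ifelse(pred_pos, positive_name(y_ext),
                                 negative_name(y_ext))
      )
    )
  })
  structure(list(
    per_cost = dplyr::bind_rows(purrr::map(res, "metrics")),
    probabilities = dplyr::bind_rows(purrr::map(res, "prob")),
    positive = positive_name(y_ext),
    negative = negative_name(y_ext),
    seed = seed
  ), class = "cc_external")
}

#' @export
print.cc_external <- function(x, ...) {
  cat("<cc_external> per-cost accuracy:\n")
  print(as.data.frame(x$per_cost[, c("cost", "accuracy", "sensitivity",
                                     "specificity")]), row.names = FALSE)
  invisible(x)
}

#' @rdname external_validate
#' @param x A `cc_external` object.
#' @param ... Unused.
#' @method tidy cc_external
#' @export
tidy.cc_external <- function(x, ...) {
  x$probabilities
}

#' @rdname external_validate
#' @method glance cc_external
#' @export
glance.cc_external <- function(x, ...) {
  x$per_cost
}
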