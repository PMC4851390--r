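#' Plot a ROC curve
#'
#' Staircase ROC with the chance diagonal and the AUC in the subtitle.
#'
#' @param object A `cc_roc` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cc_roc
#' @export
autoplot.cc_roc <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = "Receiver operating characteristic",
      subtitle = sprintf("AUC = %.3f (positive class: %s)",
                         attr(object, "auc"), attr(object, "positive"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-sample predictive probabilities
#'
#' Scatter of the cross-validated probability of the positive class for
#' each sample, coloured by true class, with the 0.5 decision line.
#' Samples above the line are called positive.
#'
#' @param cv A `cc_cv` from [loocv()] run with `proba = TRUE`.
#' @return A ggplot object.
#' @export
plot_probabilities <- function(cv) {
  stopifnot(inherits(cv, "cc_cv"))
  df <- tidy(cv)
  if (all(is.na(df$prob_positive))) {
    stop("no probabilities recorded; rerun loocv() with proba = TRUE",
         call. = FALSE)
  }
  df$sample_id <- factor(df$sample_id, levels = df$sample_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id,
                                   y = .data$prob_positive,
                                   colour = .data$true_class)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = sprintf("p(%s)", cv$positive),
                  colour = "True class",
                  title = "Cross-validated predictive probabilities") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot cross-validation support of a signature
#'
#' Bar chart of the percentage of LOOCV training folds in which each
#' signature probe passed feature selection — the stability weight of
#' each probe in the classifier.
#'
#' @param sig A signature tibble from [final_signature()].
#' @return A ggplot object.
#' @export
plot_cv_support <- function(sig) {
  stopifnot(is.data.frame(sig), "cv_support" %in% colnames(sig))
  lab <- ifelse(sig$gene_symbol != "", sig$gene_symbol, sig$probe_id)
  df <- tibble::tibble(
    probe = factor(make.unique(lab), levels = rev(make.unique(lab))),
    cv_support = sig$cv_support
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cv_support, y = .data$probe)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_x_continuous(limits = c(0, 100)) +
    ggplot2::labs(x = "Cross-validation support (%)", y = NULL,
                  title = "Signature stability across LOOCV folds") +
    ggplot2::theme_minimal()
}
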