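#' Feature-selection configuration
#'
#' @param p_grid Strictly increasing p-value cutoffs, all in (0, 1), scanned
#'   during model selection. The default grid is 0.001, 0.005, 0.01, 0.05.
#' @param test Two-sample t-test variant used for per-probe selection:
#'   `"pooled"` (Student, equal-variance — the classic microarray default)
#'   or `"welch"`.
#' @return A list of class `fs_config`.
#' @export
fs_config <- function(p_grid = c(0.001, 0.005, 0.01, 0.05),
                      test = c("pooled", "welch")) {
  test <- match.arg(test)
  if (!is.numeric(p_grid) || !length(p_grid) || any(p_grid <= 0 | p_grid >= 1)) {
    stop("all p-grid cutoffs must lie in (0, 1)", call. = FALSE)
  }
  if (is.unsorted(p_grid, strictly = TRUE)) {
    stop("p-grid cutoffs must be strictly increasing", call. = FALSE)
  }
  structure(list(p_grid = p_grid, test = test), class = "fs_config")
}

# Vectorized two-sample t-test over the rows of a numeric matrix.
# pos/neg are column indices. Returns list(t, p, df). Probes with zero
# pooled variance get t = 0, p = 1: they carry no discriminating signal
# for a t statistic. Direction: positive-class mean minus negative-class.
row_ttest <- function(v, pos, neg, test = "pooled") {
  n1 <- length(pos); n2 <- length(neg)
  if (n1 < 2 || n2 < 2) {
    stop("t-test needs at least 2 samples per class", call. = FALSE)
  }
  m1 <- rowMeans(v[, pos, drop = FALSE])
  m2 <- rowMeans(v[, neg, drop = FALSE])
  v1 <- rowSums((v[, pos, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((v[, neg, drop = FALSE] - m2)^2) / (n2 - 1)
  if (test == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep.int(n1 + n2 - 2, length(m1))
  } else {
    se2 <- v1 / n1 + v2 / n2
    # Welch-Satterthwaite df; zero-variance probes handled below
    df <- se2^2 / (pmax(v1 / n1, 0)^2 / (n1 - 1) + pmax(v2 / n2, 0)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / sqrt(se2)
  dead <- !is.finite(t) | se2 == 0
  t[dead] <- 0
  df[dead | !is.finite(df)] <- 1
  p <- 2 * stats::pt(-abs(t), df)
  p[dead] <- 1
  list(t = unname(t), p = unname(p), df = unname(df))
}

# Signed fold change: positive-class mean over negative-class mean on the
# unlogged scale, reported as -1/ratio when the ratio is below 1.
signed_fold_change <- function(v, pos, neg, scale = "unlogged") {
  if (scale == "log2") v <- 2^v
  m1 <- rowMeans(v[, pos, drop = FALSE])
  m2 <- rowMeans(v[, neg, drop = FALSE])
  r <- m1 / m2
  unname(ifelse(r >= 1, r, -1 / r))
}

#' Select discriminating probes by univariate t-tests
#'
#' Computes, for every probe, a two-sample t statistic and two-sided
#' p-value comparing the positive and negative classes, and returns the
#' probes with p strictly below the cutoff together with their signed fold
#' change. Probes with zero within-class variance in both classes cannot
#' discriminate by t and receive p = 1.
#'
#' This is the in-fold selection step of the cross-validation engine: when
#' called inside [loocv()] it sees only the training samples of the fold.
#'
#' @param X An [expression_matrix()].
#' @param y A [label_vector()] aligned to the samples of `X`.
#' @param p_cutoff Selection threshold; a probe is kept when `p < p_cutoff`.
#' @param annot Optional [probe_annotation()] used to attach gene symbols.
#' @param test `"pooled"` (default) or `"welch"`.
#' @return A tibble with columns `probe_id`, `gene_symbol`, `t_statistic`,
#'   `p_value`, `fold_change`, ordered by ascending p-value.
#' @export
select_features_ttest <- function(X, y, p_cutoff, annot = NULL,
                                  test = c("pooled", "welch")) {
  test <- match.arg(test)
  y <- check_labels(X, y, min_per_class = 2L)
  pos <- which(is_positive(y)); neg <- which(!is_positive(y))
  v <- unclass(X)
  tt <- row_ttest(v, pos, neg, test = test)
  fc <- signed_fold_change(v, pos, neg, scale = expr_scale(X))
  keep <- which(tt$p < p_cutoff)
  symbols <- rep("", length(keep))
  if (!is.null(annot) && length(keep)) {
    idx <- match(rownames(X)[keep], annot$probe_id)
    symbols <- ifelse(is.na(idx), "", annot$gene_symbol[idx])
  }
  out <- tibble::tibble(
    probe_id = rownames(X)[keep],
    gene_symbol = symbols,
    t_statistic = tt$t[keep],
    p_value = tt$p[keep],
    fold_change = fc[keep]
  )
  dplyr::arrange(out, .data$p_value, .data$probe_id)
}
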