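#' Filtering configuration
#'
#' @param background_threshold Intensity on the unlogged scale below which a
#'   probe is considered unexpressed; a probe is kept when its mean intensity
#'   across all samples is strictly above this value. Default 10, the
#'   empirical noise floor for PLIER-normalized intensities on this platform.
#' @param require_annotation Whether probes must carry functional annotation
#'   (protein coding or non-coding) to enter the analysis.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(background_threshold = 10, require_annotation = TRUE) {
  if (!is.numeric(background_threshold) || length(background_threshold) != 1 ||
      background_threshold <= 0) {
    stop("`background_threshold` must be a single positive number", call. = FALSE)
  }
  structure(list(background_threshold = background_threshold,
                 require_annotation = isTRUE(require_annotation)),
            class = "filter_config")
}

#' Keep only functionally annotated probes
#'
#' Restricts an expression matrix to probes whose annotation status is
#' `protein_coding` or `non_coding`, discarding unannotated probes. The
#' sample set is unchanged. Every probe of the matrix must be present in
#' the annotation table.
#'
#' @param X An [expression_matrix()].
#' @param annot A [probe_annotation()] covering all probes of `X`.
#' @return The filtered [expression_matrix()].
#' @export
filter_annotated <- function(X, annot) {
  idx <- match(rownames(X), annot$probe_id)
  if (anyNA(idx)) {
    miss <- rownames(X)[is.na(idx)]
    stop("probe(s) absent from annotation: ",
         paste(head(miss, 5), collapse = ", "),
         if (length(miss) > 5) sprintf(" (and %d more)", length(miss) - 5),
         call. = FALSE)
  }
  keep <- annot$status[idx] %in% c("protein_coding", "non_coding")
  subset_expr(X, probes = which(keep))
}

#' Remove probes expressed below background level
#'
#' Retains exactly the probes whose arithmetic mean intensity across all
#' samples is strictly greater than the background threshold. Defined on
#' the unlogged scale only; the filter uses no class labels, so it can be
#' applied once before cross-validation without information leakage.
#'
#' @param X An [expression_matrix()] on the unlogged scale.
#' @param cfg A [filter_config()]; its `background_threshold` is used.
#' @return The filtered [expression_matrix()].
#' @export
filter_above_background <- function(X, cfg = filter_config()) {
  if (expr_scale(X) != "unlogged") {
    stop("background filtering is defined on the unlogged scale; ",
         "got a log2 matrix", call. = FALSE)
  }
  keep <- rowMeans(unclass(X)) > cfg$background_threshold
  subset_expr(X, probes = which(keep))
}

#' Log2-transform an expression matrix
#'
#' Replaces every intensity by `log2(value + offset)` and flags the matrix
#' as log2 scale. With the default offset 0 every value must be strictly
#' positive; set `offset = 1` for matrices containing exact zeros.
#'
#' @param X An [expression_matrix()] on the unlogged scale.
#' @param offset Non-negative pseudo-count added before taking logs.
#' @return The transformed [expression_matrix()] with scale `"log2"`.
#' @export
log2_transform <- function(X, offset = 0) {
  if (expr_scale(X) != "unlogged") {
    stop("matrix is already on the log2 scale", call. = FALSE)
  }
  v <- unclass(X) + offset
  if (any(v <= 0)) {
    stop("non-positive value encountered; use a positive `offset`", call. = FALSE)
  }
  expression_matrix(log2(v), probe_ids = rownames(X), sample_ids = colnames(X),
                    scale = "log2")
}
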