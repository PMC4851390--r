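#' Construct an expression matrix
#'
#' The central container of the package: a probe-by-sample matrix of
#' non-negative normalized intensities, together with a flag recording
#' whether the values are on the raw ("unlogged") or log2 scale.
#' Probes are rows, samples are columns — the dominant microarray
#' convention.
#'
#' @param values Numeric matrix, probes in rows, samples in columns.
#' @param probe_ids Character vector of unique probe identifiers; defaults
#'   to `rownames(values)`.
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to `colnames(values)`.
#' @param scale Either `"unlogged"` (raw intensities, all values must be
#'   non-negative) or `"log2"`.
#'
#' @return An object of class `expr_matrix`: the numeric matrix with
#'   dimnames set and a `scale` attribute.
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
#'             dimnames = list(paste0("p", 1:3), c("s1", "s2")))
#' X <- expression_matrix(m)
#' expr_scale(X)
#' @export
expression_matrix <- function(values, probe_ids = rownames(values),
                              sample_ids = colnames(values),
                              scale = c("unlogged", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (probes x samples)", call. = FALSE)
  }
  if (is.null(probe_ids) || is.null(sample_ids)) {
    stop("probe and sample identifiers are required", call. = FALSE)
  }
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (length(probe_ids) != nrow(values)) {
    stop("length(probe_ids) must equal nrow(values)", call. = FALSE)
  }
  if (length(sample_ids) != ncol(values)) {
    stop("length(sample_ids) must equal ncol(values)", call. = FALSE)
  }
  if (anyDuplicated(probe_ids)) {
    dup <- unique(probe_ids[duplicated(probe_ids)])
    stop("duplicated probe id(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    dup <- unique(sample_ids[duplicated(sample_ids)])
    stop("duplicated sample id(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(values)) {
    stop("missing values are not supported in expression matrices", call. = FALSE)
  }
  if (scale == "unlogged" && any(values < 0)) {
    stop("negative intensities are not allowed on the unlogged scale", call. = FALSE)
  }
  dimnames(values) <- list(probe_ids, sample_ids)
  structure(values, scale = scale, class = c("expr_matrix", "matrix", "array"))
}

#' @rdname expression_matrix
#' @param x An `expr_matrix`.
#' @export
expr_scale <- function(x) {
  attr(x, "scale") %||% "unlogged"
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d probes x %d samples [%s scale]\n",
              nrow(x), ncol(x), expr_scale(x)))
  n <- min(5L, nrow(x)); m <- min(5L, ncol(x))
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE])
  if (nrow(x) > n) cat(sprintf("... %d more probes\n", nrow(x) - n))
  invisible(x)
}

# Subset an expr_matrix keeping class and scale; rows/cols by id or index.
subset_expr <- function(x, probes = NULL, samples = NULL) {
  sc <- expr_scale(x)
  v <- unclass(x)
  if (!is.null(probes)) v <- v[probes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  expression_matrix(v, scale = sc)
}

#' @method as_tibble expr_matrix
#' @export
as_tibble.expr_matrix <- function(x, ...) {
  tibble::as_tibble(unclass(x), rownames = "probe_id")
}

#' Construct a label vector
#'
#' Binary class labels for the samples of an expression matrix, together
#' with the names of the positive and negative classes (for the training
#' cohort "LB" live birth vs "NP" no pregnancy; for external validation
#' "B" blastocyst vs "EP" poor-quality embryo).
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param classes Character vector, same length, each element equal to
#'   `positive` or `negative`.
#' @param positive,negative Names of the two classes.
#'
#' @return An object of class `label_vector`: a named character vector of
#'   class names with `positive` and `negative` attributes.
#' @examples
#' y <- label_vector(c("s1", "s2", "s3"), c("LB", "NP", "LB"))
#' is_positive(y)
#' @export
label_vector <- function(sample_ids, classes, positive = "LB", negative = "NP") {
  sample_ids <- as.character(sample_ids)
  classes <- as.character(classes)
  if (length(sample_ids) != length(classes)) {
    stop("sample_ids and classes must have the same length", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample id(s) in labels", call. = FALSE)
  }
  if (identical(positive, negative)) {
    stop("positive and negative class names must differ", call. = FALSE)
  }
  bad <- setdiff(unique(classes), c(positive, negative))
  if (length(bad)) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  names(classes) <- sample_ids
  structure(classes, positive = positive, negative = negative,
            class = "label_vector")
}

#' @rdname label_vector
#' @param y A `label_vector`.
#' @export
is_positive <- function(y) {
  unname(unclass(y) == attr(y, "positive"))
}

#' @rdname label_vector
#' @export
positive_name <- function(y) attr(y, "positive")

#' @rdname label_vector
#' @export
negative_name <- function(y) attr(y, "negative")

#' @export
print.label_vector <- function(x, ...) {
  cat(sprintf("<label_vector> %d samples: %d %s (positive) / %d %s (negative)\n",
              length(x), sum(is_positive(x)), positive_name(x),
              sum(!is_positive(x)), negative_name(x)))
  invisible(x)
}

#' @export
`[.label_vector` <- function(x, i) {
  label_vector(names(unclass(x))[i], unclass(x)[i],
               positive = positive_name(x), negative = negative_name(x))
}

#' @method as_tibble label_vector
#' @export
as_tibble.label_vector <- function(x, ...) {
  tibble::tibble(sample_id = names(unclass(x)), class = unname(unclass(x)))
}

# Check both classes non-empty and aligned to a matrix's samples.
check_labels <- function(X, y, min_per_class = 1L) {
  if (!identical(colnames(X), names(unclass(y)))) {
    if (!setequal(colnames(X), names(unclass(y)))) {
      stop("labels and matrix samples do not match", call. = FALSE)
    }
    y <- y[match(colnames(X), names(unclass(y)))]
  }
  npos <- sum(is_positive(y)); nneg <- sum(!is_positive(y))
  if (npos < min_per_class || nneg < min_per_class) {
    stop(sprintf("need at least %d sample(s) per class (found %d %s, %d %s)",
                 min_per_class, npos, positive_name(y), nneg, negative_name(y)),
         call. = FALSE)
  }
  y
}

#' Read an expression matrix from tab-separated text
#'
#' Expects a header row of sample identifiers, a first column of probe
#' identifiers, and a fully numeric body. Row and column order are
#' preserved. Empty cells are parse errors: the source platforms produce
#' complete matrices, so missing values are not supported.
#'
#' @param path Path to a TSV file.
#' @param scale Declared scale of the stored intensities (`"unlogged"` or
#'   `"log2"`).
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, scale = c("unlogged", "log2")) {
  scale <- match.arg(scale)
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(df) < 2) {
    stop("expression matrix file needs a probe-id column plus >=1 sample column",
         call. = FALSE)
  }
  probe_ids <- df[[1]]
  body <- as.matrix(df[-1])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) & !is.na(body) | is.na(body), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric or empty cell at data row %d, column '%s'",
                 bad[1, 1], colnames(df)[-1][bad[1, 2]]), call. = FALSE)
  }
  colnames(num) <- colnames(df)[-1]
  rownames(num) <- probe_ids
  expression_matrix(num, scale = scale)
}

#' Write an expression matrix as tab-separated text
#'
#' @param X An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(X, path) {
  df <- tibble::as_tibble(unclass(X), rownames = "probe_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

# Valid annotation status tokens.
ANNOT_STATUSES <- c("protein_coding", "non_coding", "unannotated")

#' Construct a probe annotation table
#'
#' Maps each probe to a gene symbol and a functional-annotation status.
#' A probe is `unannotated` exactly when no functional annotation exists
#' for it; an empty gene symbol is allowed only for probes that are not
#' protein coding.
#'
#' @param probe_id,gene_symbol,status Character vectors of equal length.
#'   `status` must be one of `"protein_coding"`, `"non_coding"`,
#'   `"unannotated"`.
#' @return A tibble of class `probe_annotation` with those three columns.
#' @export
probe_annotation <- function(probe_id, gene_symbol, status) {
  probe_id <- as.character(probe_id)
  gene_symbol <- as.character(gene_symbol)
  gene_symbol[is.na(gene_symbol)] <- ""
  status <- as.character(status)
  if (anyDuplicated(probe_id)) {
    stop("duplicated probe id(s) in annotation", call. = FALSE)
  }
  bad <- setdiff(unique(status), ANNOT_STATUSES)
  if (length(bad)) {
    stop("unknown annotation status token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(status == "protein_coding" & gene_symbol == "")) {
    stop("protein_coding probes must carry a gene symbol", call. = FALSE)
  }
  out <- tibble::tibble(probe_id = probe_id, gene_symbol = gene_symbol,
                        status = status)
  class(out) <- c("probe_annotation", class(out))
  out
}

#' Read a probe annotation table from tab-separated text
#'
#' Expects columns `probe_id`, `gene_symbol`, `status` (header mandatory).
#'
#' @param path Path to a TSV file.
#' @return A [probe_annotation()] tibble.
#' @export
read_annotation <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  need <- c("probe_id", "gene_symbol", "status")
  missing <- setdiff(need, colnames(df))
  if (length(missing)) {
    stop("annotation file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  probe_annotation(df$probe_id, df$gene_symbol, df$status)
}

#' @rdname read_annotation
#' @param annot A [probe_annotation()].
#' @export
write_annotation <- function(annot, path) {
  readr::write_tsv(tibble::as_tibble(annot), path, progress = FALSE)
  invisible(path)
}

#' Read sample class labels from tab-separated text
#'
#' Expects columns `sample_id` and `class`; every class value must equal
#' `positive` or `negative`.
#'
#' @inheritParams label_vector
#' @param path Path to a TSV file.
#' @return A [label_vector()].
#' @export
read_labels <- function(path, positive = "LB", negative = "NP") {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  need <- c("sample_id", "class")
  missing <- setdiff(need, colnames(df))
  if (length(missing)) {
    stop("label file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  label_vector(df$sample_id, df$class, positive = positive, negative = negative)
}

#' @rdname read_labels
#' @param y A [label_vector()].
#' @export
write_labels <- function(y, path) {
  readr::write_tsv(as_tibble.label_vector(y), path, progress = FALSE)
  invisible(path)
}

# Signature column contract shared by selection, final_signature and IO.
SIGNATURE_COLS <- c("probe_id", "gene_symbol", "t_statistic", "p_value",
                    "fold_change", "cv_support")

#' Write a gene signature to tab-separated text
#'
#' One row per signature probe; the header names all fields. `cv_support`
#' is serialized at full precision (readr writes round-trip-safe doubles),
#' so e.g. 88.9 and 100 remain distinguishable.
#'
#' @param sig A signature tibble as produced by [final_signature()] or
#'   [select_features_ttest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  if (!is.data.frame(sig) || nrow(sig) == 0) {
    stop("refusing to write an empty signature", call. = FALSE)
  }
  missing <- setdiff(setdiff(SIGNATURE_COLS, "cv_support"), colnames(sig))
  if (length(missing)) {
    stop("signature missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"cv_support" %in% colnames(sig)) sig$cv_support <- NA_real_
  readr::write_tsv(dplyr::select(sig, dplyr::all_of(SIGNATURE_COLS)), path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(),
    gene_symbol = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  missing <- setdiff(SIGNATURE_COLS, colnames(df))
  if (length(missing)) {
    stop("signature file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$probe_id)) {
    stop("duplicated probe id(s) in signature file", call. = FALSE)
  }
  df$gene_symbol[is.na(df$gene_symbol)] <- ""
  df
}
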