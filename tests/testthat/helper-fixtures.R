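# Small in-code fixtures shared across test files.

# Toy expression matrix with named probes/samples.
toy_matrix <- function(values, n_probes = NULL, n_samples = NULL,
                       scale = "unlogged") {
  if (is.matrix(values)) {
    v <- values
  } else {
    v <- matrix(values, nrow = n_probes, ncol = n_samples)
  }
  rownames(v) <- sprintf("p%02d", seq_len(nrow(v)))
  colnames(v) <- sprintf("s%02d", seq_len(ncol(v)))
  expression_matrix(v, scale = scale)
}

# Labels for the first n_pos columns positive, rest negative.
toy_labels <- function(n_pos, n_neg, positive = "LB", negative = "NP") {
  n <- n_pos + n_neg
  label_vector(sprintf("s%02d", seq_len(n)),
               c(rep(positive, n_pos), rep(negative, n_neg)),
               positive = positive, negative = negative)
}

# Two well-separated classes: feature means differ by `shift` with unit
# noise. Returns list(X, y).
separated_data <- function(n_pos = 6, n_neg = 6, n_features = 5, shift = 20,
                           seed = 42) {
  set.seed(seed)
  n <- n_pos + n_neg
  v <- matrix(rnorm(n_features * n), nrow = n_features)
  v[, seq_len(n_pos)] <- v[, seq_len(n_pos)] + shift
  v <- v - min(v) + 1    # keep non-negative for the unlogged scale
  rownames(v) <- sprintf("p%02d", seq_len(n_features))
  colnames(v) <- sprintf("s%02d", seq_len(n))
  list(X = expression_matrix(v), y = toy_labels(n_pos, n_neg))
}

# Column permutation preserving the expr_matrix class.
subset_expr_for_test <- function(X, cols) {
  expression_matrix(unclass(X)[, cols, drop = FALSE], scale = expr_scale(X))
}

# Default small simulation used by several files (fast, strong signal).
small_sim <- function(seed = 3, n_probes = 600, n_de = 20, fold_change = 4,
                      ...) {
  simulate_study(simulation_config(n_probes = n_probes, n_de = n_de,
                                   fold_change = fold_change, seed = seed,
                                   ...))
}
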