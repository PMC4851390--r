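#' Pipeline configuration
#'
#' Collects every input and tuning parameter of the orchestrated analysis.
#' Expression/annotation/label inputs may be given either as in-memory
#' objects or as TSV file paths (loaded with the package readers at run
#' start).
#'
#' @param expr Training [expression_matrix()] or TSV path (unlogged).
#' @param annot [probe_annotation()] or TSV path.
#' @param labels [label_vector()] or TSV path.
#' @param external Optional named list of external cohorts, each itself a
#'   list with `expr`, `annot`, `labels` (objects or paths; matrices on
#'   the log2 scale or unlogged — unlogged external matrices are
#'   log2-transformed at load).
#' @param filter A [filter_config()].
#' @param selection An [fs_config()].
#' @param cost,k Training-grid hyperparameters for the SVM and kNN
#'   families.
#' @param cost_grid Cost sweep used for external validation.
#' @param n_perm Label permutations for the error-rate significance test.
#' @param seed Integer master seed.
#' @param out_dir Optional output directory for artifacts; created if
#'   absent.
#' @param overwrite Allow writing into a non-empty `out_dir`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(expr, annot, labels, external = NULL,
                            filter = filter_config(),
                            selection = fs_config(),
                            cost = 1, k = 3, cost_grid = c(1, 2, 10),
                            n_perm = 1000, seed = 1, out_dir = NULL,
                            overwrite = FALSE) {
  for (p in list(expr, annot, labels)) {
    if (is_input_path(p) && !file.exists(p)) {
      stop("input path does not exist: ", p, call. = FALSE)
    }
  }
  structure(list(expr = expr, annot = annot, labels = labels,
                 external = external, filter = filter, selection = selection,
                 cost = cost, k = k, cost_grid = cost_grid,
                 n_perm = n_perm, seed = as.integer(seed),
                 out_dir = out_dir, overwrite = isTRUE(overwrite)),
            class = "pipeline_config")
}

# A bare length-1 character is a file path; classed character vectors
# (label_vector) are in-memory objects.
is_input_path <- function(x) {
  is.character(x) && length(x) == 1L && is.null(attr(x, "class"))
}

load_input <- function(x, reader, ...) {
  if (is_input_path(x)) reader(x, ...) else x
}

#' Run the full classification pipeline
#'
#' Executes, in order: annotation filter, background filter, LOOCV over
#' the full algorithm-by-cutoff grid, selection of the optimal model,
#' a probability-bearing LOOCV re-run of the winner, the final signature
#' with cross-validation support, a permutation test of the winner's
#' error rate, a ROC curve on the LOOCV predictive probabilities, and —
#' when external cohorts are configured — signature translation plus
#' per-cost external validation. All artifacts are written to
#' `cfg$out_dir` when set, together with a JSON report carrying the
#' configuration echo, seeds and input digests needed to reproduce every
#' number.
#'
#' @param cfg A [pipeline_config()].
#' @return A list of class `cc_report` with components `filtered_dims`,
#'   `model_selection`, `best_spec`, `cv`, `signature`, `permutation`,
#'   `roc`, `external`, `seed`.
#' @export
run_full_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$out_dir
  if (!is.null(out)) {
    if (dir.exists(out) && length(dir(out)) && !cfg$overwrite) {
      stop("output directory ", out, " is not empty; set overwrite = TRUE",
           call. = FALSE)
    }
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
  }
  X <- load_input(cfg$expr, read_expression_matrix)
  annot <- load_input(cfg$annot, read_annotation)
  y <- load_input(cfg$labels, read_labels)

  n_input <- nrow(X)
  if (cfg$filter$require_annotation) X <- filter_annotated(X, annot)
  n_annot <- nrow(X)
  X <- filter_above_background(X, cfg$filter)
  message(sprintf("filtering: %d probes -> %d annotated -> %d above background",
                  n_input, n_annot, nrow(X)))

  specs <- default_spec_grid(cfg$selection$p_grid, cost = cfg$cost, k = cfg$k)
  grid <- loocv_grid(X, y, specs, seed = cfg$seed, proba = FALSE,
                     test = cfg$selection$test)
  best <- choose_optimal(grid)
  message("selected model: ", spec_label(best$spec))

  cv <- loocv(X, y, best$spec, seed = cfg$seed, proba = TRUE,
              test = cfg$selection$test)
  sig <- final_signature(X, y, best$spec$p_cutoff, cv, annot = annot,
                         test = cfg$selection$test)
  perm <- permutation_test(X, y, best$spec, n_perm = cfg$n_perm,
                           seed = cfg$seed, test = cfg$selection$test)
  roc <- roc_curve(cv$per_fold$prob_positive, y)

  external <- NULL
  if (!is.null(cfg$external)) {
    external <- purrr::imap(cfg$external, function(ext, name) {
      Xe <- load_input(ext$expr, read_expression_matrix)
      if (expr_scale(Xe) == "unlogged") Xe <- log2_transform(Xe, offset = 1)
      ae <- load_input(ext$annot, read_annotation)
      ye <- load_input(ext$labels, read_labels, positive = "B",
                       negative = "EP")
      mapping <- translate_signature(sig, ae, Xe)
      val <- external_validate(X, y, mapping, Xe, ye,
                               cost_grid = cfg$cost_grid, seed = cfg$seed)
      list(mapping = mapping, validation = val)
    })
  }

  report <- structure(list(
    filtered_dims = c(input = n_input, annotated = n_annot,
                      above_background = nrow(X)),
    model_selection = grid,
    best_spec = best$spec,
    cv = cv,
    signature = sig,
    permutation = perm,
    roc = roc,
    external = external,
    seed = cfg$seed
  ), class = "cc_report")

  if (!is.null(out)) write_report_artifacts(report, cfg, out)
  report
}

# Emit the TSV artifacts plus a machine-readable JSON report.
write_report_artifacts <- function(report, cfg, out) {
  write_signature(report$signature, file.path(out, "signature.tsv"))
  readr::write_tsv(dplyr::select(report$model_selection, -"spec", -"cv"),
                   file.path(out, "model_selection.tsv"), progress = FALSE)
  readr::write_tsv(tidy(report$cv), file.path(out, "per_fold.tsv"),
                   progress = FALSE)
  readr::write_tsv(tibble::as_tibble(report$roc), file.path(out, "roc.tsv"),
                   progress = FALSE)
  readr::write_tsv(tidy(report$permutation),
                   file.path(out, "permutation_null.tsv"), progress = FALSE)
  if (!is.null(report$external)) {
    for (name in names(report$external)) {
      e <- report$external[[name]]
      readr::write_tsv(e$mapping$resolution_log,
                       file.path(out, paste0("mapping_", name, ".tsv")),
                       progress = FALSE)
      readr::write_tsv(e$validation$per_cost,
                       file.path(out, paste0("external_metrics_", name, ".tsv")),
                       progress = FALSE)
    }
  }
  digest_of <- function(x) {
    if (is.character(x)) unname(tools::md5sum(x)) else "in-memory"
  }
  json <- list(
    schema_version = "1.0",
    seed = cfg$seed,
    inputs = list(expr = digest_of(cfg$expr), annot = digest_of(cfg$annot),
                  labels = digest_of(cfg$labels)),
    config = list(
      background_threshold = cfg$filter$background_threshold,
      require_annotation = cfg$filter$require_annotation,
      p_grid = cfg$selection$p_grid,
      test = cfg$selection$test,
      cost = cfg$cost, k = cfg$k, cost_grid = cfg$cost_grid,
      n_perm = cfg$n_perm
    ),
    filtered_dims = as.list(report$filtered_dims),
    best_model = spec_label(report$best_spec),
    loocv = as.list(glance(report$cv)),
    signature_size = nrow(report$signature),
    permutation = as.list(glance(report$permutation)),
    auc = auc(report$roc),
    external = if (!is.null(report$external)) {
      purrr::map(report$external, function(e) {
        list(n_mapped = nrow(e$mapping$pairs),
             n_unmapped = length(e$mapping$unmapped_genes),
             per_cost = purrr::transpose(as.list(
               e$validation$per_cost[, c("cost", "accuracy")])))
      })
    }
  )
  jsonlite::write_json(json, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' @export
print.cc_report <- function(x, ...) {
  cat("<cc_report>\n")
  cat(sprintf("  probes: %d input, %d annotated, %d above background\n",
              x$filtered_dims[["input"]], x$filtered_dims[["annotated"]],
              x$filtered_dims[["above_background"]]))
  cat("  best model:", spec_label(x$best_spec), "\n")
  cat(sprintf("  LOOCV accuracy %.3f | signature %d probe(s) | AUC %.3f | permutation p %.4g\n",
              x$cv$accuracy, nrow(x$signature), auc(x$roc),
              x$permutation$p_value))
  if (!is.null(x$external)) {
    for (name in names(x$external)) {
      acc <- x$external[[name]]$validation$per_cost
      cat(sprintf("  external [%s]: accuracy %s at cost %s\n", name,
                  paste(sprintf("%.2f", acc$accuracy), collapse = "/"),
                  paste(acc$cost, collapse = "/")))
    }
  }
  invisible(x)
}
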