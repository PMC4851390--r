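#' Simulation configuration
#'
#' Parameters of the synthetic microarray study generator. The defaults
#' mirror the shape of a small two-class follicular-cell cohort: 12
#' positive vs 15 negative samples, 20,000 probes of which 15% lack
#' functional annotation and 10% sit below the background intensity floor,
#' with 30 planted differentially expressed probes at fold change 4 and a
#' within-group coefficient of variation of 0.3.
#'
#' @param n_pos,n_neg Samples per class.
#' @param n_probes Total probes on the simulated platform.
#' @param frac_unannotated Fraction of probes without functional annotation.
#' @param frac_background Fraction of probes whose true mean lies below
#'   `background_threshold`.
#' @param n_de Number of planted differentially expressed probes (always
#'   annotated, never background; directions balanced up/down).
#' @param fold_change Multiplicative effect of planted probes, positive
#'   class over negative class (> 0; 1 plants no effect at all).
#' @param cv_within Within-group coefficient of variation of the
#'   multiplicative log-normal noise.
#' @param baseline_log_mean,baseline_log_sd Log-scale location and spread
#'   of the log-normal baseline intensity distribution of expressed probes.
#' @param background_threshold Intensity floor separating background from
#'   expressed probes (matches [filter_config()]'s default 10).
#' @param probes_per_gene_target Integer vector of possible redundant-probe
#'   counts per gene on the simulated second platform (sampled uniformly).
#' @param frac_genes_missing_target Fraction of genes absent from the
#'   second platform.
#' @param seed Integer seed; the generator is fully determined by it.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_pos = 12, n_neg = 15, n_probes = 20000,
                              frac_unannotated = 0.15, frac_background = 0.10,
                              n_de = 30, fold_change = 4, cv_within = 0.3,
                              baseline_log_mean = log(300),
                              baseline_log_sd = 1,
                              background_threshold = 10,
                              probes_per_gene_target = 1:3,
                              frac_genes_missing_target = 1 / 6,
                              seed = 1) {
  fr <- c(frac_unannotated = frac_unannotated,
          frac_background = frac_background,
          frac_genes_missing_target = frac_genes_missing_target)
  if (any(fr < 0 | fr > 1)) {
    stop("all fractions must lie in [0, 1]", call. = FALSE)
  }
  if (fold_change <= 0) stop("`fold_change` must be positive", call. = FALSE)
  if (cv_within < 0) stop("`cv_within` must be non-negative", call. = FALSE)
  if (n_pos < 1 || n_neg < 1 || n_probes < 1) {
    stop("sample and probe counts must be positive", call. = FALSE)
  }
  n_eligible <- floor(n_probes * (1 - frac_unannotated)) -
    floor(n_probes * frac_background)
  if (n_de > n_eligible) {
    stop("`n_de` exceeds the number of annotated, above-background probes (",
         n_eligible, ")", call. = FALSE)
  }
  if (any(probes_per_gene_target < 1)) {
    stop("`probes_per_gene_target` counts must be >= 1", call. = FALSE)
  }
  structure(list(
    n_pos = n_pos, n_neg = n_neg, n_probes = n_probes,
    frac_unannotated = frac_unannotated, frac_background = frac_background,
    n_de = n_de, fold_change = fold_change, cv_within = cv_within,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    background_threshold = background_threshold,
    probes_per_gene_target = as.integer(probes_per_gene_target),
    frac_genes_missing_target = frac_genes_missing_target,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Mean-preserving multiplicative log-normal noise with coefficient of
# variation cv: E[exp(N(-s^2/2, s^2))] = 1, CV = sqrt(exp(s^2)-1) = cv.
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  exp(rnorm(n, -s^2 / 2, s))
}

#' Simulate a two-class expression study
#'
#' Generates a probe-by-sample intensity matrix with the statistical
#' structure the classification pipeline assumes: log-normal baseline
#' intensities per probe, mean-preserving multiplicative within-class
#' noise at the configured coefficient of variation, a configurable
#' fraction of probes below background and without annotation, and
#' `n_de` planted probes whose positive-class mean is shifted by
#' `fold_change` (half up, half down). Identical seeds give identical
#' output.
#'
#' @param cfg A [simulation_config()].
#' @return A list with components `expr` ([expression_matrix()], unlogged),
#'   `annot` ([probe_annotation()]), `labels` ([label_vector()], classes
#'   LB/NP), and `truth` (list: `de_probe_ids`, `de_direction`, `gene_map`,
#'   `baseline_mean`).
#' @examples
#' sim <- simulate_study(simulation_config(n_probes = 500, seed = 7))
#' sim$expr
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  rs <- local_rng(cfg$seed)
  on.exit(rs$restore())

  np <- cfg$n_probes
  probe_ids <- sprintf("PS%06d", seq_len(np))
  n_unannot <- floor(np * cfg$frac_unannotated)
  n_bg <- floor(np * cfg$frac_background)
  shuffled <- sample.int(np)
  unannot <- shuffled[seq_len(n_unannot)]
  bg <- shuffled[n_unannot + seq_len(n_bg)]

  # Baseline means: background probes strictly below the threshold,
  # expressed probes log-normal and kept clear of the floor.
  baseline <- numeric(np)
  baseline[bg] <- runif(n_bg, 0.05, 0.9) * cfg$background_threshold
  expressed <- setdiff(seq_len(np), bg)
  draw <- rlnorm(length(expressed), cfg$baseline_log_mean, cfg$baseline_log_sd)
  low <- draw <= 1.5 * cfg$background_threshold
  for (iter in 1:50) {
    if (!any(low)) break
    draw[low] <- rlnorm(sum(low), cfg$baseline_log_mean, cfg$baseline_log_sd)
    low <- draw <= 1.5 * cfg$background_threshold
  }
  draw[low] <- 1.5 * cfg$background_threshold + 1
  baseline[expressed] <- draw

  # Annotation: unique symbol per annotated probe, ~25% non-coding.
  status <- rep("protein_coding", np)
  status[unannot] <- "unannotated"
  annotated <- setdiff(seq_len(np), unannot)
  nc <- annotated[runif(length(annotated)) < 0.25]
  status[nc] <- "non_coding"
  symbol <- rep("", np)
  symbol[annotated] <- sprintf("GENE%05d", seq_along(annotated))

  # Planted effects: annotated, expressed, balanced up/down.
  eligible <- setdiff(annotated, bg)
  de <- sort(sample(eligible, cfg$n_de))
  direction <- rep(c("up", "down"), length.out = length(de))
  effect <- rep(1, np)
  effect[de[direction == "up"]] <- cfg$fold_change
  effect[de[direction == "down"]] <- 1 / cfg$fold_change

  n <- cfg$n_pos + cfg$n_neg
  sample_ids <- sprintf("S%02d", seq_len(n))
  classes <- c(rep("LB", cfg$n_pos), rep("NP", cfg$n_neg))
  mean_mat <- outer(baseline, rep(1, n))
  mean_mat[, classes == "LB"] <- mean_mat[, classes == "LB"] * effect
  values <- mean_mat * matrix(lognormal_noise(np * n, cfg$cv_within),
                              nrow = np)
  dimnames(values) <- list(probe_ids, sample_ids)

  list(
    expr = expression_matrix(values, scale = "unlogged"),
    annot = probe_annotation(probe_ids, symbol, status),
    labels = label_vector(sample_ids, classes, positive = "LB",
                          negative = "NP"),
    truth = list(
      de_probe_ids = probe_ids[de],
      de_direction = setNames(direction, probe_ids[de]),
      gene_map = setNames(symbol[annotated], probe_ids[annotated]),
      baseline_mean = setNames(baseline, probe_ids)
    )
  )
}

#' Simulate an external cohort on a second platform
#'
#' Draws a new sample cohort from the same class-effect model as a
#' [simulate_study()] result and emits it on a simulated second platform:
#' gene-symbol annotation, 1..k redundant probes per gene with
#' probe-specific affinity multipliers, a configured fraction of genes
#' missing entirely, a different global intensity scale, and a log2
#' transform — emulating a platform change between training and external
#' validation. Class names are B (blastocyst, positive) vs EP (poor
#' quality embryo).
#'
#' @param sim A [simulate_study()] result (its `truth` drives the effects).
#' @param cfg A [simulation_config()]; `n_pos`/`n_neg` size the new
#'   cohort, `probes_per_gene_target` and `frac_genes_missing_target`
#'   shape the platform. The seed is offset from `cfg$seed` so the cohort
#'   is independent of the training draw.
#' @return A list with `expr` (log2 [expression_matrix()]), `annot`
#'   ([probe_annotation()]) and `labels` ([label_vector()], B/EP).
#' @export
simulate_external_platform <- function(sim, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  truth <- sim$truth
  rs <- local_rng(cfg$seed + 104729L)
  on.exit(rs$restore())

  genes <- unname(truth$gene_map)
  src_probe <- names(truth$gene_map)
  keep <- runif(length(genes)) >= cfg$frac_genes_missing_target
  genes <- genes[keep]; src_probe <- src_probe[keep]

  ppg <- cfg$probes_per_gene_target   # explicit indexing: a scalar must not
  n_per <- ppg[sample.int(length(ppg), length(genes), replace = TRUE)]
  gene_rep <- rep(seq_along(genes), n_per)
  probe_ids <- sprintf("A_%s_%d", genes[gene_rep],
                       unlist(lapply(n_per, seq_len)))
  affinity <- exp(rnorm(length(probe_ids), 0, 0.4))

  # Class effect per target probe, inherited from the source probe's
  # planted direction.
  fc <- rep(1, length(genes))
  is_de <- src_probe %in% truth$de_probe_ids
  dirs <- truth$de_direction[src_probe[is_de]]
  fc[is_de] <- ifelse(dirs == "up", cfg$fold_change, 1 / cfg$fold_change)

  n <- cfg$n_pos + cfg$n_neg
  sample_ids <- sprintf("E%02d", seq_len(n))
  classes <- c(rep("B", cfg$n_pos), rep("EP", cfg$n_neg))

  base <- truth$baseline_mean[src_probe[gene_rep]] * affinity
  mean_mat <- outer(base, rep(1, n))
  mean_mat[, classes == "B"] <- mean_mat[, classes == "B"] * fc[gene_rep]
  platform_scale <- 0.37   # different global intensity scale than training
  values <- platform_scale * mean_mat *
    matrix(lognormal_noise(length(base) * n, cfg$cv_within), nrow = length(base))
  dimnames(values) <- list(probe_ids, sample_ids)

  expr <- log2_transform(expression_matrix(values, scale = "unlogged"))
  list(
    expr = expr,
    annot = probe_annotation(probe_ids, genes[gene_rep],
                             rep("protein_coding", length(probe_ids))),
    labels = label_vector(sample_ids, classes, positive = "B",
                          negative = "EP")
  )
}
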