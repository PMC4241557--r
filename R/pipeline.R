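#' Run the analysis pipeline from a configuration
#'
#' Chains the pipeline stages in their canonical order:
#' `generate` -> `extract` -> `classify` -> `stack` -> `cluster` -> `pca`.
#' The configuration names the input (a synthetic generation spec or an
#' existing feature table), the stages to run, the output directory and the
#' seed; identical configuration + seed gives identical outputs.
#'
#' @param config a named list, or a path to a JSON/YAML file with the same
#'   structure. Recognized fields: `stages` (character vector), `seed`,
#'   `out_dir`, `features_file` (input for runs without
#'   generate/extract), `plan` (data.frame or list of `stage`/`n`),
#'   `scale` (plan scaling), `duration_s`, `noise_sd`, `protocols`.
#' @return named list of stage results (`features`, `labels`, `stacking`,
#'   `classes`, `pca`, `trajectory`, file paths in `files`)
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stages <- config$stages
  if (is.null(stages) || !length(stages))
    abort("config must list at least one stage", "validation_error")
  known <- c("generate", "extract", "classify", "stack", "cluster", "pca")
  bad <- setdiff(stages, known)
  if (length(bad)) abort("unknown stage(s): %s", "validation_error",
                         paste(bad, collapse = ", "))
  stages <- known[known %in% stages]          # canonical order
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(files = character(0))
  t0 <- Sys.time()
  log_stage <- function(name, detail) {
    message(sprintf("[%s] %s (%.1f s elapsed)", name, detail,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  features <- NULL
  if ("generate" %in% stages || "extract" %in% stages) {
    plan <- config$plan
    if (is.null(plan))
      plan <- default_stage_plan(scale = config$scale %||% 1)
    if (!is.data.frame(plan)) plan <- as.data.frame(plan)
    sim <- simulate_feature_cohort(
      plan, seed = config$seed %||% 1L,
      duration_s = config$duration_s %||% 120,
      noise_sd = config$noise_sd %||% 0.3,
      protocols = config$protocols %||% c("spontaneous", "passive", "sag",
                                          "fi"))
    features <- sim$features
    res$ground_truth <- sim$ground_truth
    f <- file.path(out_dir, "features.csv")
    write_feature_table(features, f)
    utils::write.csv(sim$ground_truth,
                     file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
    res$files <- c(res$files, f)
    log_stage("generate/extract", sprintf("%d neurons", nrow(features)))
  } else if (!is.null(config$features_file)) {
    features <- read_feature_table(config$features_file)
  }
  res$features <- features

  need_features <- intersect(stages, c("classify", "stack", "cluster", "pca"))
  if (length(need_features) && is.null(features))
    abort("stage '%s' requested but no features generated or supplied",
          "dependency_error", need_features[1])

  if ("classify" %in% stages) {
    labels <- data.frame(neuron_id = features$neuron_id,
                         stage = features$stage,
                         cv_isi = features$cv_isi,
                         label = as.character(classify_firing(features$cv_isi)),
                         stringsAsFactors = FALSE)
    res$labels <- labels
    res$proportions <- pattern_proportions(features)
    f <- file.path(out_dir, "labels.csv")
    utils::write.csv(labels, f, row.names = FALSE)
    res$files <- c(res$files, f)
    log_stage("classify", sprintf("%d neurons", nrow(labels)))
  }
  if ("stack" %in% stages) {
    res$stacking <- build_stacking_table(features)
    f <- file.path(out_dir, "stacking.csv")
    write_stacking_table(res$stacking, f)
    res$files <- c(res$files, f)
    log_stage("stack", sprintf("%d cells", nrow(res$stacking) / 16))
  }
  if (any(c("cluster", "pca") %in% stages)) {
    snm <- spontaneous_matrix(features,
                              normalization = config$normalization %||% "mean")
    if ("cluster" %in% stages) {
      dend <- ahc_ward(snm)
      res$classes <- auto_cut(dend, snm, k = config$k)
      f <- file.path(out_dir, "dendrogram.nwk")
      write_dendrogram_newick(dend, f)
      cls <- data.frame(neuron_id = snm$neuron_id, stage = snm$stage,
                        class = res$classes$membership)
      f2 <- file.path(out_dir, "classes.csv")
      utils::write.csv(cls, f2, row.names = FALSE)
      res$files <- c(res$files, f, f2)
      log_stage("cluster", sprintf("%d classes", res$classes$k))
    }
    if ("pca" %in% stages) {
      res$pca <- pca_covariance(snm)
      res$trajectory <- stage_trajectory(res$pca)
      res$ellipses <- variability_ellipse(res$trajectory)
      sc <- data.frame(neuron_id = snm$neuron_id, stage = snm$stage,
                       res$pca$scores[, 1:2])
      f <- file.path(out_dir, "scores.csv")
      utils::write.csv(sc, f, row.names = FALSE)
      f2 <- file.path(out_dir, "trajectory.csv")
      utils::write.csv(res$trajectory, f2, row.names = FALSE)
      res$files <- c(res$files, f, f2)
      log_stage("pca", sprintf("PC1+PC2 = %.1f%% of variance",
                               100 * sum(res$pca$variance_fraction[1:2])))
    }
  }
  res
}

read_pipeline_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      abort("the 'yaml' package is needed for YAML configs", "dependency_error")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
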