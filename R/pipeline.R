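# End-to-end orchestration: normalize -> baseline-adjust -> block set ->
# MBPLSR fit -> cross-validation / jack-knife / outliers -> univariate
# result table, with every artifact written as diff-able text.

#' Run the full analysis pipeline
#'
#' Executes all stages in order on one dataset and, if `output_dir` is
#' given, writes the artifacts: the normalized concentrations
#' (`concentrations.tsv`), the result table (`result_table.tsv`), the model
#' summary (`model_summary.json`: explained variances, y-loadings, super and
#' block scores) and the validation summary (`validation_summary.json`:
#' RMSECV curve, per-block validated explained Y-variance, selected
#' components, outlier flags). Every artifact carries the seed and a hash of
#' the configuration in its header.
#'
#' @param dataset Raw-intensity [lipid_dataset()], or path to a dataset TSV.
#' @param standards [standards_table()], or path to a standards TSV.
#' @param annotations Required when `dataset` is a path: annotation data
#'   frame or TSV path.
#' @param week Analysis week (3 or 7).
#' @param A_max Largest component count assessed in cross-validation.
#' @param ncomp Fixed component count; default `NULL` selects by RMSECV.
#' @param scheme Cross-validation scheme, see [cv_folds()].
#' @param fdr_threshold Univariate q-value threshold.
#' @param fdr_method `"storey"` or `"bh"`.
#' @param sm_standard Internal standard used for SM species.
#' @param ratio_then_share Order-of-operations flag, see [build_blockset()].
#' @param exclude_subjects Character vector of subject ids excluded before
#'   analysis (e.g. after reviewing outlier flags from an earlier run).
#' @param outlier_level Confidence level for T2 outlier flagging.
#' @param seed Seed recorded in the artifacts (the pipeline itself is
#'   deterministic given the data; the seed documents data provenance).
#' @param output_dir Optional directory for artifacts.
#' @return A list with `concentrations`, `blocks`, `model`, `validation`,
#'   `jackknife`, `outliers`, `result_table`, `config`.
#' @export
run_pipeline <- function(dataset, standards, annotations = NULL,
                         week = 3, A_max = 5, ncomp = NULL, scheme = "loo",
                         fdr_threshold = 0.05, fdr_method = "storey",
                         sm_standard = "PC(17:0/17:0)",
                         ratio_then_share = FALSE,
                         exclude_subjects = character(),
                         outlier_level = 0.95,
                         seed = NA_integer_, output_dir = NULL) {
  if (is.character(dataset)) {
    if (is.null(annotations)) stop("annotations required to read a dataset TSV")
    dataset <- read_dataset_tsv(dataset, annotations, unit = "intensity")
  }
  if (is.character(standards)) standards <- read_standards_tsv(standards)
  config <- list(week = week, A_max = A_max, ncomp = ncomp, scheme = scheme,
                 fdr_threshold = fdr_threshold, fdr_method = fdr_method,
                 sm_standard = sm_standard,
                 ratio_then_share = ratio_then_share,
                 exclude_subjects = exclude_subjects,
                 outlier_level = outlier_level, seed = seed)
  config_hash <- hash_config(config)
  meta <- c(paste0("seed: ", seed), paste0("config_hash: ", config_hash))

  if (length(exclude_subjects)) {
    keep <- !(dataset$samples$subject_id %in% exclude_subjects)
    keep_std <- standards_table(standards$info,
                                standards$intensities[keep, , drop = FALSE])
    dataset <- lipid_dataset(dataset$values[keep, , drop = FALSE],
                             dataset$samples[keep, , drop = FALSE],
                             dataset$species, unit = dataset$unit)
    standards <- keep_std
    message("excluded subject(s): ", paste(exclude_subjects, collapse = ", "))
  }

  conc <- with_stage("normalize", normalize_intensities(
    dataset, standards, sm_standard = sm_standard))
  blocks <- with_stage("blockset", build_blockset(
    conc, week, ratio_then_share = ratio_then_share))
  validation <- with_stage("cross-validation",
                           cross_validate(blocks, A_max, scheme = scheme))
  A <- if (is.null(ncomp)) max(validation$selected_A, 1L) else as.integer(ncomp)
  model <- with_stage("fit", fit_mbplsr(blocks, A))
  jack <- with_stage("jack-knife",
                     jackknife_significance(blocks, A, scheme = scheme))
  outliers <- with_stage("outlier-detection",
                         detect_outliers(model, level = outlier_level))
  if (any(outliers$flagged)) {
    warning("outlier advisory: sample(s) ",
            paste(outliers$sample[outliers$flagged], collapse = ", "),
            " exceed the T2 limit; exclusion requires an explicit rerun ",
            "with 'exclude_subjects'")
  }
  result_table <- with_stage("result-table", build_result_table(
    conc, week, jackknife = jack, fdr_threshold = fdr_threshold,
    fdr_method = fdr_method))

  out <- list(concentrations = conc, blocks = blocks, model = model,
              validation = validation, jackknife = jack, outliers = outliers,
              result_table = result_table, config = config)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_dataset_tsv(conc, file.path(output_dir, "concentrations.tsv"), meta)
    write_tsv_meta(result_table, file.path(output_dir, "result_table.tsv"),
                   meta)
    write_tsv_meta(jack, file.path(output_dir, "jackknife.tsv"), meta)
    jsonlite::write_json(
      list(seed = seed, config_hash = config_hash,
           n_components = model$n_components,
           explained_Y_variance = model$explained_Y_variance,
           explained_X_block_variance = model$explained_X_block_variance,
           y_loadings = model$y_loadings,
           super_scores = model$super_scores,
           block_scores = model$block_scores),
      file.path(output_dir, "model_summary.json"),
      auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
    jsonlite::write_json(
      list(seed = seed, config_hash = config_hash,
           rmsecv = validation$rmsecv,
           selected_A = validation$selected_A,
           validated_explained_Y = validation$validated_explained_Y,
           validated_explained_Y_per_block =
             validation$validated_explained_Y_per_block,
           outlier_T2 = outliers$T2,
           outlier_flagged = outliers$flagged,
           outlier_limit = attr(outliers, "limit")),
      file.path(output_dir, "validation_summary.json"),
      auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  }
  out
}

# run a stage, prefixing any error with the stage name
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

# stable content hash of the configuration (md5 of its serialized JSON)
hash_config <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}
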