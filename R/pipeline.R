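#' Pipeline configuration
#'
#' Collects every tunable of the detection workflow, validated up front so a
#' bad setting fails before any computation. Defaults: 70/30 control split,
#' L1 penalty 1, QC gate PCC > 0.5 and p < 0.05, alteration rule ratio > 1
#' with one-sided Mann-Whitney q < 0.05, model FDR restriction q < 0.01.
#'
#' @param train_fraction control fraction used for training, in (0, 1).
#' @param seed integer seed driving the control split (and retraining splits).
#' @param penalty L1 strength of the per-target lasso.
#' @param pcc_min,p_max correlation QC thresholds (both exclusive).
#' @param q_fdr model FDR threshold (exclusive).
#' @param ratio_min,q_alt alteration rule thresholds.
#' @param rule `"ratio_test"` or `"ratio_only"`, see [detect_altered()].
#' @param mode cross-dataset confirmation mode, `"transfer"` or `"retrain"`.
#' @param standardize standardize TF features inside the lasso (opt-in).
#' @return a validated list of class `mqtrans_config`.
#' @export
mqtrans_config <- function(train_fraction = 0.7, seed = 1, penalty = 1,
                           pcc_min = 0.5, p_max = 0.05, q_fdr = 0.01,
                           ratio_min = 1, q_alt = 0.05,
                           rule = c("ratio_test", "ratio_only"),
                           mode = c("transfer", "retrain"),
                           standardize = FALSE) {
  rule <- match.arg(rule)
  mode <- match.arg(mode)
  chk_unit <- function(x, nm, lo = 0, hi = 1) {
    if (!is.numeric(x) || length(x) != 1 || x <= lo || x > hi) {
      stop(nm, " must be a single number in (", lo, ", ", hi, "]")
    }
  }
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be strictly between 0 and 1")
  }
  if (!is.numeric(penalty) || penalty < 0) stop("penalty must be non-negative")
  chk_unit(p_max, "p_max"); chk_unit(q_fdr, "q_fdr"); chk_unit(q_alt, "q_alt")
  if (!is.numeric(pcc_min) || pcc_min < -1 || pcc_min >= 1) {
    stop("pcc_min must lie in [-1, 1)")
  }
  if (!is.numeric(ratio_min) || ratio_min < 0) stop("ratio_min must be >= 0")
  structure(
    list(train_fraction = train_fraction, seed = as.integer(seed),
         penalty = penalty, pcc_min = pcc_min, p_max = p_max, q_fdr = q_fdr,
         ratio_min = ratio_min, q_alt = q_alt, rule = rule, mode = mode,
         standardize = standardize),
    class = "mqtrans_config"
  )
}

# core single-dataset pipeline: partition -> split -> fit -> QC -> mqTrans ->
# alteration -> screen. Shared by run_pipeline() and confirm_across().
run_core <- function(ds, tf_symbols, config) {
  stopifnot(inherits(ds, "ExpressionDataset"), inherits(config, "mqtrans_config"))
  partition <- partition_features(ds, tf_symbols)
  if (length(partition$mrna_features) == 0) {
    stop("no mRNA features to model after partition")
  }
  split <- split_controls(ds, config$train_fraction, config$seed)
  models <- fit_models(ds, partition, split$train_sample_ids,
                       penalty = config$penalty,
                       standardize = config$standardize)
  qc_holdout <- qc_models(models, ds, split$holdout_sample_ids,
                          eval_set = "holdout")
  qc_train <- qc_models(models, ds, split$train_sample_ids, eval_set = "train")
  # mqTrans for cases vs non-training controls: training samples are excluded
  # so the comparison is not biased by in-sample residuals
  eval_ids <- c(split$holdout_sample_ids, case_ids(ds))
  mq <- mqtrans_matrix(models, ds, eval_ids)
  alteration <- alteration_table(mq, ds$sample_labels)
  screen <- screen_cascade(models, qc_holdout, alteration,
                           pcc_min = config$pcc_min, p_max = config$p_max,
                           rule = config$rule, ratio_min = config$ratio_min,
                           q_max = config$q_alt, q_fdr = config$q_fdr)
  list(dataset_id = ds$dataset_id, partition = partition, split = split,
       models = models, qc_holdout = qc_holdout, qc_train = qc_train,
       mqtrans = mq, alteration = alteration, screen = screen)
}

#' Run the full detection workflow
#'
#' Partitions features, splits the controls, fits one sparse regulatory model
#' per mRNA feature on the training controls, quality-controls the models on
#' the hold-out controls, computes mqTrans features for hold-out controls and
#' all case samples, screens for altered regulation, and (when validation
#' datasets are supplied) confirms the altered set across datasets. With
#' `out_dir` set, all artifacts are persisted as TSV plus a run manifest; two
#' runs with identical inputs and config produce byte-identical artifacts.
#'
#' @param train_ds annotated training [expression_dataset()].
#' @param tf_symbols TF gene-symbol catalogue.
#' @param config an [mqtrans_config()].
#' @param validation_datasets optional named list of annotated datasets for
#'   cross-dataset confirmation.
#' @param out_dir optional output directory for artifacts.
#' @param input_paths optional named character vector of input file paths,
#'   checksummed into the manifest.
#' @return An object of class `mqtrans_run`: the [run_core] fields plus
#'   `confirmation` (see [confirm_across()]; `NULL` without validation
#'   datasets), `config` and `out_dir`.
#' @export
run_pipeline <- function(train_ds, tf_symbols, config = mqtrans_config(),
                         validation_datasets = list(), out_dir = NULL,
                         input_paths = NULL) {
  res <- run_core(train_ds, tf_symbols, config)
  res$confirmation <- NULL
  if (length(validation_datasets) > 0) {
    res$confirmation <- confirm_across(train_ds, validation_datasets,
                                       tf_symbols, config, mode = config$mode)
  }
  res$config <- config
  res$out_dir <- out_dir
  class(res) <- "mqtrans_run"
  if (!is.null(out_dir)) write_run_artifacts(res, out_dir, input_paths)
  res
}

#' @export
print.mqtrans_run <- function(x, ...) {
  cat(sprintf("mqtrans run on '%s'\n", x$dataset_id))
  cat(sprintf("  features: %d TF / %d mRNA / %d dropped\n",
              length(x$partition$tf_features), length(x$partition$mrna_features),
              length(x$partition$dropped_features)))
  cat(sprintf("  controls: %d train / %d holdout; cases scored: %d\n",
              length(x$split$train_sample_ids), length(x$split$holdout_sample_ids),
              x$alteration$n_case[1]))
  print(x$screen)
  if (!is.null(x$confirmation)) {
    cat(sprintf("  confirmed across %d datasets (%s mode): %d\n",
                length(x$confirmation$altered), x$confirmation$mode,
                length(x$confirmation$confirmed)))
  }
  invisible(x)
}
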