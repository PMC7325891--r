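#' Compute mqTrans features for one target
#'
#' The mqTrans feature of target F in a sample is
#' `|observed F - predicted F|`, the absolute residual of the control-trained
#' regulatory model. It is close to zero while the sample maintains the
#' TF-mRNA regulatory relationship learned from controls, and elevated where
#' that regulation is altered.
#'
#' @param model a [fit_target_model()] result.
#' @param ds an [expression_dataset()] containing the target and all TFs the
#'   model needs.
#' @param eval_ids sample ids to score; defaults to all samples.
#' @return An object of class `MqTransProfile`: list with `target_id`,
#'   `sample_ids`, `values` (named non-negative numeric) and `dataset_id`.
#' @export
compute_mqtrans <- function(model, ds, eval_ids = NULL) {
  stopifnot(inherits(model, "RegulatoryModel"), inherits(ds, "ExpressionDataset"))
  if (is.null(eval_ids)) eval_ids <- sample_ids(ds)
  if (!model$target_id %in% feature_ids(ds)) {
    stop("target feature absent from dataset: ", model$target_id)
  }
  sub <- ds$values[, eval_ids, drop = FALSE]
  vals <- abs(sub[model$target_id, ] - predict_target(model, sub))
  structure(
    list(target_id = model$target_id, sample_ids = eval_ids,
         values = vals, dataset_id = ds$dataset_id),
    class = "MqTransProfile"
  )
}

#' mqTrans matrix for a set of models
#'
#' @param models named list of models.
#' @inheritParams compute_mqtrans
#' @return numeric matrix, targets in rows and samples in columns.
#' @export
mqtrans_matrix <- function(models, ds, eval_ids = NULL) {
  if (is.null(eval_ids)) eval_ids <- sample_ids(ds)
  out <- matrix(NA_real_, nrow = length(models), ncol = length(eval_ids),
                dimnames = list(names(models), eval_ids))
  for (t in names(models)) {
    out[t, ] <- compute_mqtrans(models[[t]], ds, eval_ids)$values
  }
  out
}

#' Case/control summary of one mqTrans profile
#'
#' Group means, their ratio, and a one-sided Mann-Whitney location test of the
#' alternative that mqTrans is larger in cases. The ratio is guarded by
#' `eps = 1e-12`: a control mean below `eps` flags the ratio as infinite.
#'
#' @param profile a [compute_mqtrans()] profile, or a named numeric vector of
#'   mqTrans values.
#' @param labels named character vector of `"case"`/`"control"` covering the
#'   profile's samples (an [expression_dataset()]'s `sample_labels` works).
#' @return one-row data.frame with `target_id`, `mean_control`, `mean_case`,
#'   `ratio`, `ratio_infinite`, `test_p`, `n_case`, `n_control`.
#' @export
summarize_groups <- function(profile, labels) {
  if (inherits(profile, "MqTransProfile")) {
    vals <- profile$values
    target_id <- profile$target_id
  } else {
    vals <- profile
    target_id <- NA_character_
  }
  lab <- labels[names(vals)]
  if (anyNA(lab)) stop("labels missing for some samples")
  case_v <- vals[lab == "case"]
  ctrl_v <- vals[lab == "control"]
  if (length(case_v) == 0 || length(ctrl_v) == 0) {
    stop("both case and control groups must be non-empty")
  }
  eps <- 1e-12
  mc <- mean(case_v)
  mn <- mean(ctrl_v)
  inf_flag <- mn < eps
  test_p <- stats::wilcox.test(case_v, ctrl_v, alternative = "greater",
                               exact = FALSE, correct = TRUE)$p.value
  data.frame(target_id = target_id,
             mean_control = mn, mean_case = mc,
             ratio = mc / max(mn, eps),
             ratio_infinite = inf_flag,
             test_p = test_p,
             n_case = length(case_v), n_control = length(ctrl_v),
             stringsAsFactors = FALSE)
}

#' Case/control alteration table over an mqTrans matrix
#'
#' Applies [summarize_groups()] per target and BH-adjusts the one-sided test
#' p-values across the table's targets.
#'
#' @param mq matrix from [mqtrans_matrix()].
#' @param labels named case/control labels covering the matrix columns.
#' @return data.frame, one row per target, columns of [summarize_groups()]
#'   plus `test_q`.
#' @export
alteration_table <- function(mq, labels) {
  rows <- lapply(rownames(mq), function(t) {
    r <- summarize_groups(mq[t, ], labels)
    r$target_id <- t
    r
  })
  if (length(rows) == 0) {
    out <- data.frame(target_id = character(0), mean_control = numeric(0),
                      mean_case = numeric(0), ratio = numeric(0),
                      ratio_infinite = logical(0), test_p = numeric(0),
                      n_case = integer(0), n_control = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
  }
  out$test_q <- benjamini_hochberg(out$test_p)
  out
}

#' Detect targets with altered regulation
#'
#' Default rule (`"ratio_test"`): altered iff the case/control mqTrans mean
#' ratio exceeds `ratio_min` (or is flagged infinite) AND the BH-adjusted
#' one-sided Mann-Whitney q-value is below `q_max`. The pure-ratio rule
#' (`"ratio_only"`) drops the test condition, for sensitivity analyses.
#'
#' @param results an [alteration_table()] data.frame.
#' @param rule `"ratio_test"` (default) or `"ratio_only"`.
#' @param ratio_min ratio threshold (exclusive); default 1.
#' @param q_max q-value threshold (exclusive); default 0.05.
#' @return character vector of altered target ids.
#' @export
detect_altered <- function(results, rule = c("ratio_test", "ratio_only"),
                           ratio_min = 1, q_max = 0.05) {
  rule <- match.arg(rule)
  up <- results$ratio > ratio_min | results$ratio_infinite
  keep <- switch(rule,
                 ratio_test = up & results$test_q < q_max,
                 ratio_only = up)
  results$target_id[keep]
}

#' Multi-stage screening cascade
#'
#' Composes the screens in order, each stage intersecting the previous stage's
#' survivors: (1) a regulatory model exists (at least one non-zero TF weight);
#' (2) correlation QC, `pcc > pcc_min` and `p < p_max`; (3) altered in cases
#' per [detect_altered()]; (4) FDR restriction `q < q_fdr` on the model
#' significance. Both BH families are the QC-stage survivors: the alteration
#' q-values and the model q-values are re-adjusted within that family before
#' stages 3 and 4 apply.
#'
#' @param models named list of models (the candidate universe).
#' @param qc a [qc_models()] table for these models.
#' @param alteration an [alteration_table()] for these models.
#' @param pcc_min,p_max QC thresholds (stage 2).
#' @param rule,ratio_min,q_max alteration rule parameters (stage 3).
#' @param q_fdr model FDR threshold (stage 4, exclusive: q >= q_fdr excluded).
#' @return An object of class `ScreenReport`: list with `stages` (named list
#'   of surviving id vectors: `input`, `model`, `qc`, `altered`, `fdr`),
#'   `counts` and `thresholds`.
#' @export
screen_cascade <- function(models, qc, alteration,
                           pcc_min = 0.5, p_max = 0.05,
                           rule = "ratio_test", ratio_min = 1, q_max = 0.05,
                           q_fdr = 0.01) {
  universe <- names(models)
  has_model <- universe[vapply(models, function(m) length(m$weights) > 0, logical(1))]

  qc1 <- qc[qc$target_id %in% has_model, , drop = FALSE]
  qc_pass <- intersect(qc_screen(qc1, pcc_min, p_max), has_model)

  # alteration stage, BH within the QC-surviving family
  alt_sub <- alteration[alteration$target_id %in% qc_pass, , drop = FALSE]
  if (nrow(alt_sub)) alt_sub$test_q <- benjamini_hochberg(alt_sub$test_p)
  altered <- intersect(detect_altered(alt_sub, rule = rule,
                                      ratio_min = ratio_min, q_max = q_max),
                       qc_pass)

  # FDR stage on model significance, family = QC survivors
  fdr_sub <- qc1[qc1$target_id %in% qc_pass & !is.na(qc1$p_value), , drop = FALSE]
  fdr_pass <- character(0)
  if (nrow(fdr_sub)) {
    qv <- benjamini_hochberg(fdr_sub$p_value)
    fdr_pass <- fdr_sub$target_id[qv < q_fdr]
  }
  fdr <- intersect(fdr_pass, altered)

  stages <- list(input = universe, model = has_model, qc = qc_pass,
                 altered = altered, fdr = fdr)
  structure(
    list(stages = stages,
         counts = vapply(stages, length, integer(1)),
         thresholds = list(pcc_min = pcc_min, p_max = p_max, rule = rule,
                           ratio_min = ratio_min, q_max = q_max, q_fdr = q_fdr)),
    class = "ScreenReport"
  )
}

#' @export
print.ScreenReport <- function(x, ...) {
  cat("Screening cascade survivors:\n")
  for (s in names(x$stages)) {
    cat(sprintf("  %-8s %d\n", s, x$counts[[s]]))
  }
  invisible(x)
}

#' Rank targets by a score, descending
#'
#' Ties are broken by target id, lexicographically ascending, so rankings are
#' stable across runs. For ratio rankings, targets flagged with an infinite
#' ratio sort above every finite ratio.
#'
#' @param results data.frame with `target_id` and the key column (`ratio` with
#'   optional `ratio_infinite` flag, or `pcc`).
#' @param key `"ratio"` or `"pcc"`.
#' @param n how many top ids to return; if larger than the table, the full
#'   ranking is returned.
#' @return character vector of at most `n` target ids.
#' @export
rank_features <- function(results, key = c("ratio", "pcc"), n) {
  key <- match.arg(key)
  if (!is.numeric(n) || n <= 0) stop("n must be a positive count")
  score <- results[[key]]
  if (is.null(score)) stop("results lack a '", key, "' column")
  if (key == "ratio" && !is.null(results$ratio_infinite)) {
    score[results$ratio_infinite] <- Inf
  }
  score[is.na(score)] <- -Inf
  ord <- order(-score, results$target_id)
  utils::head(results$target_id[ord], min(n, nrow(results)))
}
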