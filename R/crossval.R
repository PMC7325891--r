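#' Transfer trained models to another dataset
#'
#' A model transfers only if its target feature and every TF with a non-zero
#' weight exist in the destination dataset (feature spaces differ across
#' exports of the same platform). Missing features are reported, never raised.
#' Correlation QC on the destination dataset's control samples is computed for
#' the transferable models.
#'
#' @param models named list of [fit_target_model()] results.
#' @param target_ds destination [expression_dataset()].
#' @return list with `reports` (data.frame: `target_id`, `transferable`,
#'   `n_missing`, `missing` list-column) and `qc` (a [qc_models()] table over
#'   the transferable models, `NULL` when the destination has no controls or
#'   nothing transfers).
#' @export
transfer_models <- function(models, target_ds) {
  stopifnot(inherits(target_ds, "ExpressionDataset"))
  feats <- feature_ids(target_ds)
  missing <- lapply(models, function(m) {
    setdiff(c(m$target_id, names(m$weights)), feats)
  })
  transferable <- vapply(missing, length, integer(1)) == 0
  reports <- data.frame(target_id = names(models),
                        transferable = unname(transferable),
                        n_missing = unname(vapply(missing, length, integer(1))),
                        stringsAsFactors = FALSE)
  reports$missing <- unname(missing)
  qc <- NULL
  ctrl <- control_ids(target_ds)
  if (any(transferable) && length(ctrl) > 0) {
    qc <- qc_models(models[transferable], target_ds, ctrl,
                    eval_set = target_ds$dataset_id)
  }
  list(reports = reports, qc = qc)
}

#' Exclusive Venn regions of 2-3 id sets
#'
#' @param sets named list of 2 or 3 character vectors.
#' @return An object of class `VennSummary`: list with `set_labels`,
#'   `region_counts` (named integer vector over every non-empty label subset,
#'   labels joined by `"&"`) and `full_intersection`.
#' @export
venn_regions <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 || length(sets) > 3) {
    stop("venn_regions needs a list of 2 or 3 sets")
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- LETTERS[seq_along(sets)]
  }
  labels <- names(sets)
  sets <- lapply(sets, unique)
  elements <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) elements %in% s, logical(length(elements)))
  if (length(elements) == 1) member <- matrix(member, nrow = 1)
  if (length(elements) == 0) {
    member <- matrix(logical(0), nrow = 0, ncol = length(sets))
  }

  subset_keys <- unlist(lapply(seq_along(labels), function(k) {
    apply(utils::combn(labels, k), 2, paste, collapse = "&")
  }))
  counts <- stats::setNames(integer(length(subset_keys)), subset_keys)
  if (length(elements)) {
    keys <- apply(member, 1, function(row) paste(labels[row], collapse = "&"))
    tab <- table(keys)
    counts[names(tab)] <- as.integer(tab)
  }
  structure(
    list(set_labels = labels, region_counts = counts,
         full_intersection = Reduce(intersect, sets)),
    class = "VennSummary"
  )
}

#' @export
print.VennSummary <- function(x, ...) {
  cat("Venn regions (exclusive):\n")
  for (k in names(x$region_counts)) {
    cat(sprintf("  %-12s %d\n", k, x$region_counts[[k]]))
  }
  cat(sprintf("  full intersection: %d\n", length(x$full_intersection)))
  invisible(x)
}

#' Confirm altered regulations across independent datasets
#'
#' Runs the detection pipeline on the training dataset, then on each
#' validation dataset either by transferring the trained models
#' (`mode = "transfer"`: QC on the destination's controls, mqTrans and
#' alteration on its samples) or by retraining from scratch on the
#' destination's own controls (`mode = "retrain"`: full split/fit/QC/detect,
#' dataset-order independent). A target is confirmed iff it is altered in
#' every dataset.
#'
#' @param train_ds training [expression_dataset()] (annotated).
#' @param validation_datasets named list of annotated datasets (>= 1).
#' @param tf_symbols TF catalogue used to partition features.
#' @param config an [mqtrans_config()].
#' @param mode `"transfer"` or `"retrain"`.
#' @return list with `mode`, `altered` (named list of per-dataset altered id
#'   sets, training dataset first), `confirmed` (their intersection), `venn`
#'   (a [venn_regions()] summary when 2-3 sets are involved, else `NULL`),
#'   `reports` (per-dataset `ScreenReport`s) and `transfer` (per-dataset
#'   transfer reports in transfer mode).
#' @export
confirm_across <- function(train_ds, validation_datasets, tf_symbols, config,
                           mode = c("transfer", "retrain")) {
  mode <- match.arg(mode)
  if (!is.list(validation_datasets) || length(validation_datasets) < 1) {
    stop("need at least one validation dataset")
  }
  if (is.null(names(validation_datasets))) {
    names(validation_datasets) <- vapply(validation_datasets,
                                         function(d) d$dataset_id, character(1))
  }
  for (d in validation_datasets) {
    if (length(control_ids(d)) == 0) {
      stop("validation dataset ", d$dataset_id, " has no control samples")
    }
  }

  train_run <- run_core(train_ds, tf_symbols, config)
  altered <- list()
  reports <- list()
  transfer <- list()
  altered[[train_ds$dataset_id]] <- train_run$screen$stages$altered
  reports[[train_ds$dataset_id]] <- train_run$screen

  for (nm in names(validation_datasets)) {
    vds <- validation_datasets[[nm]]
    if (mode == "retrain") {
      run_v <- run_core(vds, tf_symbols, config)
      altered[[nm]] <- run_v$screen$stages$altered
      reports[[nm]] <- run_v$screen
    } else {
      tr <- transfer_models(train_run$models, vds)
      transfer[[nm]] <- tr$reports
      keep <- tr$reports$target_id[tr$reports$transferable]
      models_v <- train_run$models[keep]
      if (length(models_v) == 0) {
        altered[[nm]] <- character(0)
        next
      }
      mq <- mqtrans_matrix(models_v, vds)
      alt_tab <- alteration_table(mq, vds$sample_labels)
      screen_v <- screen_cascade(models_v, tr$qc, alt_tab,
                                 pcc_min = config$pcc_min, p_max = config$p_max,
                                 rule = config$rule, ratio_min = config$ratio_min,
                                 q_max = config$q_alt, q_fdr = config$q_fdr)
      altered[[nm]] <- screen_v$stages$altered
      reports[[nm]] <- screen_v
    }
  }

  venn <- if (length(altered) %in% 2:3) venn_regions(altered) else NULL
  list(mode = mode, altered = altered,
       confirmed = Reduce(intersect, altered),
       venn = venn, reports = reports,
       transfer = if (mode == "transfer") transfer else NULL)
}
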