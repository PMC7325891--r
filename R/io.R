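# number formatting used by every artifact writer: 17 significant digits
# round-trips doubles exactly and is byte-stable across runs
fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

#' Write / read a model store
#'
#' One row per non-zero weight (`target_id, intercept, penalty, n_train,
#' tf_id, weight`); intercept-only models contribute a single row with an
#' empty `tf_id`. The store round-trips through [read_model_store()].
#'
#' @param models named list of [fit_target_model()] results.
#' @param path TSV file path.
#' @return `path` invisibly (writer); named list of `RegulatoryModel` (reader).
#' @export
write_model_store <- function(models, path) {
  rows <- lapply(models, function(m) {
    if (length(m$weights) == 0) {
      data.frame(target_id = m$target_id, intercept = fmt_num(m$intercept),
                 penalty = fmt_num(m$penalty), n_train = m$n_train,
                 tf_id = "", weight = "NA", stringsAsFactors = FALSE)
    } else {
      data.frame(target_id = m$target_id, intercept = fmt_num(m$intercept),
                 penalty = fmt_num(m$penalty), n_train = m$n_train,
                 tf_id = names(m$weights), weight = fmt_num(m$weights),
                 stringsAsFactors = FALSE)
    }
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_model_store
#' @param train_dataset_id dataset id recorded in the re-built models.
#' @export
read_model_store <- function(path, train_dataset_id = NA_character_) {
  tab <- utils::read.delim(path, colClasses = "character")
  out <- list()
  for (t in unique(tab$target_id)) {
    sub <- tab[tab$target_id == t, , drop = FALSE]
    w <- stats::setNames(as.numeric(sub$weight), sub$tf_id)
    w <- w[nzchar(names(w)) & !is.na(w)]
    out[[t]] <- structure(
      list(target_id = t, intercept = as.numeric(sub$intercept[1]),
           weights = w, penalty = as.numeric(sub$penalty[1]),
           n_train = as.integer(sub$n_train[1]),
           train_dataset_id = train_dataset_id, converged = TRUE),
      class = "RegulatoryModel"
    )
  }
  out
}

write_tsv_stable <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Persist every artifact of a pipeline run
#'
#' Writes the partition report, split, model store, QC tables, mqTrans matrix,
#' alteration table, screen report, per-dataset altered lists, confirmed list,
#' Venn summary and a run manifest (seed, thresholds, input checksums,
#' per-stage counts) into `out_dir`. All files are plain TSV/text with stable
#' numeric formatting, so reruns under the same config are byte-identical.
#'
#' @param run an [run_pipeline()] result.
#' @param out_dir output directory (created if needed).
#' @param input_paths optional named character vector of input files to
#'   checksum into the manifest.
#' @return `out_dir`, invisibly.
#' @export
write_run_artifacts <- function(run, out_dir, input_paths = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)

  part <- run$partition
  part_df <- data.frame(
    feature_id = c(part$tf_features, part$mrna_features, part$dropped_features),
    class = rep(c("tf", "mrna", "dropped"),
                c(length(part$tf_features), length(part$mrna_features),
                  length(part$dropped_features))),
    stringsAsFactors = FALSE
  )
  write_tsv_stable(part_df, fp("partition.tsv"))

  split_df <- data.frame(
    sample_id = c(run$split$train_sample_ids, run$split$holdout_sample_ids),
    role = rep(c("train", "holdout"),
               c(length(run$split$train_sample_ids),
                 length(run$split$holdout_sample_ids))),
    stringsAsFactors = FALSE
  )
  write_tsv_stable(split_df, fp("split.tsv"))

  write_model_store(run$models, fp("models.tsv"))
  write_tsv_stable(run$qc_holdout, fp("qc_holdout.tsv"))
  write_tsv_stable(run$qc_train, fp("qc_train.tsv"))

  mq_df <- data.frame(target_id = rownames(run$mqtrans),
                      stringsAsFactors = FALSE)
  for (s in colnames(run$mqtrans)) mq_df[[s]] <- fmt_num(run$mqtrans[, s])
  utils::write.table(mq_df, fp("mqtrans.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  write_tsv_stable(run$alteration, fp("alteration.tsv"))
  write_screen_report(run$screen, fp("screen_report.tsv"))

  if (!is.null(run$confirmation)) {
    conf <- run$confirmation
    for (nm in names(conf$altered)) {
      writeLines(conf$altered[[nm]], fp(sprintf("altered_%s.tsv", nm)))
    }
    writeLines(conf$confirmed, fp("confirmed.tsv"))
    if (!is.null(conf$venn)) {
      venn_df <- data.frame(region = names(conf$venn$region_counts),
                            count = as.integer(conf$venn$region_counts),
                            stringsAsFactors = FALSE)
      write_tsv_stable(venn_df, fp("venn.tsv"))
    }
  }

  write_manifest(run, fp("manifest.txt"), input_paths)
  invisible(out_dir)
}

#' Screen report as TSV
#'
#' @param report a [screen_cascade()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(report, path) {
  df <- data.frame(
    stage = names(report$stages),
    n = as.integer(report$counts),
    ids = vapply(report$stages, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_manifest <- function(run, path, input_paths = NULL) {
  cfg <- run$config
  lines <- c(
    paste0("dataset_id\t", run$dataset_id),
    paste0("seed\t", cfg$seed),
    paste0("train_fraction\t", fmt_num(cfg$train_fraction)),
    paste0("penalty\t", fmt_num(cfg$penalty)),
    paste0("pcc_min\t", fmt_num(cfg$pcc_min)),
    paste0("p_max\t", fmt_num(cfg$p_max)),
    paste0("q_fdr\t", fmt_num(cfg$q_fdr)),
    paste0("ratio_min\t", fmt_num(cfg$ratio_min)),
    paste0("q_alt\t", fmt_num(cfg$q_alt)),
    paste0("rule\t", cfg$rule),
    paste0("mode\t", cfg$mode),
    paste0("n_train\t", length(run$split$train_sample_ids)),
    paste0("n_holdout\t", length(run$split$holdout_sample_ids)),
    paste0("count_", names(run$screen$stages), "\t", run$screen$counts)
  )
  if (!is.null(run$confirmation)) {
    lines <- c(lines,
               paste0("count_confirmed\t", length(run$confirmation$confirmed)))
  }
  if (!is.null(input_paths)) {
    sums <- tools::md5sum(input_paths)
    lines <- c(lines, paste0("md5_", names(input_paths), "\t", unname(sums)))
  }
  writeLines(lines, path)
  invisible(path)
}
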