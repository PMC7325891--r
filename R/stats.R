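#' Pearson correlation with two-sided significance
#'
#' Product-moment correlation plus the p-value of the t-transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` against the t distribution with `n - 2`
#' degrees of freedom, two-sided. A constant input vector makes the
#' correlation undefined; the result is then flagged rather than raised, so QC
#' screens can simply exclude it.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `pcc`, `p_value` and `defined` (FALSE when either vector
#'   is constant; `pcc`/`p_value` are `NA` then). `p_value` is `NA` when
#'   `n < 3`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite input")
  n <- length(x)
  if (n < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(pcc = NA_real_, p_value = NA_real_, defined = FALSE))
  }
  r <- stats::cor(x, y)
  p <- NA_real_
  if (n >= 3) {
    if (abs(r) >= 1) {
      p <- 0
    } else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    }
  }
  list(pcc = r, p_value = p, defined = TRUE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1 and
#' mapped back to the input order (delegates to [stats::p.adjust()]).
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values in the input order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must all lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Quality control of fitted models on an evaluation sample set
#'
#' For each model, correlates observed target expression with the model
#' prediction over the given samples (typically the hold-out controls, or an
#' independent dataset's controls) and attaches the two-sided significance of
#' the correlation plus its BH-adjusted q-value over the models with a defined
#' p in this table.
#'
#' @param models named list of [fit_target_model()] results.
#' @param ds an [expression_dataset()] containing every target and required TF.
#' @param eval_ids sample ids to evaluate on.
#' @param eval_set label recorded in the table (e.g. `"holdout"`, `"train"` or
#'   a dataset id).
#' @return data.frame with columns `target_id`, `eval_set`, `n_eval`, `pcc`,
#'   `p_value`, `q_value`. `pcc` is `NA` (flagged undefined) when observed or
#'   predicted values are constant, e.g. for intercept-only models.
#' @export
qc_models <- function(models, ds, eval_ids, eval_set = "holdout") {
  stopifnot(inherits(ds, "ExpressionDataset"))
  miss <- setdiff(eval_ids, sample_ids(ds))
  if (length(miss)) stop("unknown evaluation sample ids: ", paste(miss, collapse = ", "))
  sub <- ds$values[, eval_ids, drop = FALSE]
  out <- data.frame(
    target_id = unname(vapply(models, function(m) m$target_id, character(1))),
    eval_set = eval_set,
    n_eval = length(eval_ids),
    pcc = NA_real_,
    p_value = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(models)) {
    m <- models[[i]]
    if (!m$target_id %in% rownames(sub)) {
      stop("target feature absent from dataset: ", m$target_id)
    }
    obs <- sub[m$target_id, ]
    pred <- predict_target(m, sub)
    r <- pearson_with_p(obs, pred)
    out$pcc[i] <- r$pcc
    out$p_value[i] <- r$p_value
  }
  out$q_value <- NA_real_
  ok <- !is.na(out$p_value)
  if (any(ok)) out$q_value[ok] <- benjamini_hochberg(out$p_value[ok])
  out
}

#' Keep models passing the correlation quality screen
#'
#' Strict inequalities on both axes: a model is kept iff `pcc > pcc_min` and
#' `p_value < p_max`. Records with an undefined correlation are always
#' excluded.
#'
#' @param qc a [qc_models()] table (or any data.frame with `target_id`, `pcc`,
#'   `p_value`).
#' @param pcc_min minimum correlation (exclusive); default 0.5.
#' @param p_max maximum p-value (exclusive); default 0.05.
#' @return character vector of surviving target ids.
#' @export
qc_screen <- function(qc, pcc_min = 0.5, p_max = 0.05) {
  keep <- !is.na(qc$pcc) & !is.na(qc$p_value) &
    qc$pcc > pcc_min & qc$p_value < p_max
  qc$target_id[keep]
}
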