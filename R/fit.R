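# evaluate code under a temporary RNG state so library calls never disturb
# the caller's random stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Split the control samples into training and hold-out sets
#'
#' Case samples never enter either side: models are trained on (a fraction of)
#' the controls only, and the remaining controls provide unbiased quality
#' control of the fitted regulatory models. The training set size is
#' `floor(train_fraction * n_controls)`, sampled without replacement;
#' the split is deterministic given the seed.
#'
#' @param ds an [expression_dataset()] with at least two control samples.
#' @param train_fraction proportion of controls used for training, in (0, 1).
#' @param seed integer seed.
#' @return An object of class `SplitSpec`: list with `train_fraction`, `seed`,
#'   `train_sample_ids`, `holdout_sample_ids`.
#' @export
split_controls <- function(ds, train_fraction = 0.7, seed = 1) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be strictly between 0 and 1")
  }
  controls <- control_ids(ds)
  if (length(controls) < 2) stop("need at least 2 control samples to split")
  n_train <- floor(train_fraction * length(controls))
  if (n_train < 1 || n_train >= length(controls)) {
    stop(sprintf("train_fraction %.3f yields an empty train or hold-out set for %d controls",
                 train_fraction, length(controls)))
  }
  train <- with_seed(seed, sample(controls, n_train))
  structure(
    list(train_fraction = train_fraction, seed = as.integer(seed),
         train_sample_ids = train,
         holdout_sample_ids = setdiff(controls, train)),
    class = "SplitSpec"
  )
}

#' Fit the sparse regulatory model of one mRNA target
#'
#' Minimizes `(1/(2n)) * sum_j (y_j - w0 - sum_k w_k x_jk)^2 + penalty * sum_k |w_k|`
#' over the intercept `w0` (unpenalized) and TF weights `w`. Only TFs with a
#' non-zero weight are stored: they are read as the target's regulators. The
#' optimization is performed by coordinate descent via \pkg{glmnet}
#' (`alpha = 1`); a constant response
#' short-circuits to the intercept-only model.
#'
#' @param target_id id of the target mRNA feature.
#' @param tf_matrix numeric matrix of TF expression, TFs in rows (rownames =
#'   TF feature ids), training samples in columns.
#' @param y numeric response: the target's expression over the same samples.
#' @param penalty non-negative L1 strength (the lasso alpha of common Python
#'   implementations; default 1).
#' @param train_dataset_id id recorded for provenance.
#' @param standardize standardize TF columns internally before fitting
#'   (coefficients are always returned on the original scale). Off by default:
#'   values are modelled on their distributed scale.
#' @param thresh coordinate-descent convergence threshold. The tight default
#'   makes near-zero penalties reproduce ordinary least squares to numerical
#'   precision at negligible cost.
#' @return An object of class `RegulatoryModel`: list with `target_id`,
#'   `intercept`, `weights` (named numeric, non-zero entries only), `penalty`,
#'   `n_train`, `train_dataset_id`, `converged`.
#' @export
fit_target_model <- function(target_id, tf_matrix, y, penalty = 1,
                             train_dataset_id = NA_character_,
                             standardize = FALSE, thresh = 1e-18) {
  if (!is.matrix(tf_matrix) || is.null(rownames(tf_matrix))) {
    stop("tf_matrix must be a matrix with TF ids as rownames")
  }
  if (ncol(tf_matrix) != length(y)) {
    stop("tf_matrix column count must equal length(y)")
  }
  if (any(!is.finite(tf_matrix)) || any(!is.finite(y))) {
    stop("non-finite values in the training data for target ", target_id)
  }
  if (length(y) < 2) stop("need at least 2 training samples")
  if (penalty < 0) stop("penalty must be non-negative")

  empty_model <- function(converged = TRUE) {
    structure(
      list(target_id = target_id, intercept = mean(y),
           weights = stats::setNames(numeric(0), character(0)),
           penalty = penalty, n_train = length(y),
           train_dataset_id = train_dataset_id, converged = converged),
      class = "RegulatoryModel"
    )
  }
  if (stats::var(y) == 0 || nrow(tf_matrix) == 0) return(empty_model())

  X <- t(tf_matrix)
  padded <- FALSE
  if (ncol(X) == 1) {              # glmnet requires >= 2 columns; a zero
    X <- cbind(X, 0)               # column provably keeps coefficient 0
    padded <- TRUE
  }
  converged <- TRUE
  fit <- withCallingHandlers(
    glmnet::glmnet(X, y, family = "gaussian", alpha = 1, lambda = penalty,
                   standardize = standardize, intercept = TRUE,
                   thresh = thresh, maxit = 1e7),
    warning = function(w) {
      if (grepl("convergence|maxit", conditionMessage(w), ignore.case = TRUE)) {
        converged <<- FALSE
      }
      invokeRestart("muffleWarning")
    }
  )
  co <- as.matrix(stats::coef(fit))[, 1]
  w <- co[-1]
  if (padded) w <- w[1]
  names(w) <- rownames(tf_matrix)
  w <- w[w != 0]
  structure(
    list(target_id = target_id, intercept = unname(co[1]), weights = w,
         penalty = penalty, n_train = length(y),
         train_dataset_id = train_dataset_id, converged = converged),
    class = "RegulatoryModel"
  )
}

#' @export
print.RegulatoryModel <- function(x, ...) {
  cat(sprintf("RegulatoryModel for %s: intercept %.4g, %d regulator(s), penalty %g, n_train %d\n",
              x$target_id, x$intercept, length(x$weights), x$penalty, x$n_train))
  invisible(x)
}

#' Predict a target's expression from its regulatory model
#'
#' Evaluates `w0 + sum_k w_k * TF_k` for every sample. All TFs carrying a
#' non-zero weight must be present in `tf_matrix` (rows); anything else is an
#' error naming the missing TF, which is how non-transferable models surface.
#'
#' @param model a [fit_target_model()] result.
#' @param tf_matrix numeric matrix, features in rows and samples in columns;
#'   may contain more rows than the model needs.
#' @return named numeric vector of predictions, one per column.
#' @export
predict_target <- function(model, tf_matrix) {
  stopifnot(inherits(model, "RegulatoryModel"))
  need <- names(model$weights)
  miss <- setdiff(need, rownames(tf_matrix))
  if (length(miss)) {
    stop("missing required TF feature(s): ", paste(miss, collapse = ", "))
  }
  pred <- rep(model$intercept, ncol(tf_matrix))
  if (length(need)) {
    pred <- pred + as.numeric(crossprod(tf_matrix[need, , drop = FALSE],
                                        model$weights))
  }
  stats::setNames(pred, colnames(tf_matrix))
}

#' Fit regulatory models for many targets
#'
#' @param ds an [expression_dataset()].
#' @param partition a [partition_features()] result.
#' @param train_ids training sample ids (control samples).
#' @param penalty L1 strength passed to [fit_target_model()].
#' @param targets which mRNA features to model; defaults to all of
#'   `partition$mrna_features`.
#' @param standardize see [fit_target_model()].
#' @return named list of `RegulatoryModel` objects, one per target. Every
#'   target gets a model; targets for which the penalty zeroes all weights get
#'   an intercept-only model (they do not count as "modelled" in the screening
#'   cascade).
#' @export
fit_models <- function(ds, partition, train_ids, penalty = 1, targets = NULL,
                       standardize = FALSE) {
  stopifnot(inherits(ds, "ExpressionDataset"),
            inherits(partition, "FeaturePartition"))
  if (is.null(targets)) targets <- partition$mrna_features
  miss <- setdiff(train_ids, sample_ids(ds))
  if (length(miss)) stop("unknown training sample ids: ", paste(miss, collapse = ", "))
  tf_mat <- ds$values[partition$tf_features, train_ids, drop = FALSE]
  models <- vector("list", length(targets))
  names(models) <- targets
  for (t in targets) {
    models[[t]] <- fit_target_model(t, tf_mat, ds$values[t, train_ids],
                                    penalty = penalty,
                                    train_dataset_id = ds$dataset_id,
                                    standardize = standardize)
  }
  models
}
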