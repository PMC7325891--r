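#' Generate a ground-truth sparse regulatory network
#'
#' Each mRNA target is regulated by `k_regulators` distinct TFs chosen
#' uniformly at random; weight magnitudes are uniform on `weight_range` with
#' random sign. Defaults (`k = 3`, magnitudes in \[0.5, 1.5\], noise sd 0.2)
#' describe a moderately sparse, clearly identifiable regulatory programme on
#' an additive (log-like) expression scale.
#'
#' @param n_tf number of transcription factors.
#' @param n_mrna number of mRNA targets.
#' @param k_regulators regulators per target (0 gives a null network where
#'   every target is pure intercept + noise).
#' @param weight_range length-2 numeric, magnitude range of true weights.
#' @param noise_sigma sd of the additive Gaussian noise on each target.
#' @param seed integer seed; networks are deterministic given the seed.
#' @return An object of class `GroundTruthNetwork`: list with `tf_ids`,
#'   `mrna_ids`, `intercepts`, `true_weights` (named list of named numeric
#'   vectors), `noise_sigma`, `seed`.
#' @export
generate_network <- function(n_tf, n_mrna, k_regulators = 3,
                             weight_range = c(0.5, 1.5),
                             noise_sigma = 0.2, seed = 1) {
  if (n_tf < 1 || n_mrna < 1) stop("network dimensions must be positive")
  if (k_regulators < 0 || k_regulators > n_tf) {
    stop("k_regulators must lie in [0, n_tf]")
  }
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  weight_range <- sort(abs(weight_range))
  tf_ids <- sprintf("TF%04d", seq_len(n_tf))
  mrna_ids <- sprintf("MRNA%05d", seq_len(n_mrna))
  net <- with_seed(seed, {
    intercepts <- stats::setNames(stats::rnorm(n_mrna), mrna_ids)
    true_weights <- lapply(mrna_ids, function(t) {
      if (k_regulators == 0) {
        return(stats::setNames(numeric(0), character(0)))
      }
      regs <- sample(tf_ids, k_regulators)
      mag <- stats::runif(k_regulators, weight_range[1], weight_range[2])
      sgn <- sample(c(-1, 1), k_regulators, replace = TRUE)
      stats::setNames(mag * sgn, regs)
    })
    names(true_weights) <- mrna_ids
    list(intercepts = intercepts, true_weights = true_weights)
  })
  structure(
    list(tf_ids = tf_ids, mrna_ids = mrna_ids,
         intercepts = net$intercepts, true_weights = net$true_weights,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "GroundTruthNetwork"
  )
}

#' Define a regulatory perturbation for the case group
#'
#' Picks the altered targets (if not given) and, per altered target, one true
#' regulator whose weight is modified in case samples. Modes:
#' `"sign_flip"` negates the chosen weight — this preserves the marginal
#' variance of the target, so altered targets are not detectable by
#' differential expression of the target alone; `"delete_regulator"` zeroes
#' it; `"weight_shift"` moves it by `magnitude` away from zero
#' (`w + magnitude * sign(w)`).
#'
#' @param net a [generate_network()] result.
#' @param n_altered number of altered targets to draw at random (ignored when
#'   `altered_targets` is given).
#' @param altered_targets explicit target ids to alter.
#' @param mode perturbation mode.
#' @param magnitude shift size for `"weight_shift"` (>= 0).
#' @param seed integer seed for the random choices.
#' @return An object of class `PerturbationSpec`: list with `altered_targets`,
#'   `mode`, `magnitude`, `regulator` (named: chosen TF per altered target)
#'   and `case_weights` (named list of full perturbed weight vectors).
#' @export
perturbation_spec <- function(net, n_altered = NULL, altered_targets = NULL,
                              mode = c("sign_flip", "delete_regulator",
                                       "weight_shift"),
                              magnitude = 0, seed = 1) {
  stopifnot(inherits(net, "GroundTruthNetwork"))
  mode <- match.arg(mode)
  if (magnitude < 0) stop("magnitude must be non-negative")
  eligible <- net$mrna_ids[vapply(net$true_weights, length, integer(1)) > 0]
  picks <- with_seed(seed, {
    if (is.null(altered_targets)) {
      if (is.null(n_altered)) stop("give either n_altered or altered_targets")
      if (n_altered > length(eligible)) {
        stop("not enough targets with at least one regulator to alter")
      }
      altered_targets <- sample(eligible, n_altered)
    }
    bad <- setdiff(altered_targets, eligible)
    if (length(bad)) {
      stop("cannot perturb targets without regulators: ",
           paste(bad, collapse = ", "))
    }
    reg <- vapply(altered_targets,
                  function(t) sample(names(net$true_weights[[t]]), 1),
                  character(1))
    list(altered = altered_targets, reg = reg)
  })
  case_weights <- lapply(picks$altered, function(t) {
    w <- net$true_weights[[t]]
    f <- picks$reg[[t]]
    w[f] <- switch(mode,
                   sign_flip = -w[f],
                   delete_regulator = 0,
                   weight_shift = w[f] + magnitude * sign(w[f]))
    w
  })
  names(case_weights) <- picks$altered
  structure(
    list(altered_targets = picks$altered, mode = mode, magnitude = magnitude,
         regulator = picks$reg, case_weights = case_weights,
         seed = as.integer(seed)),
    class = "PerturbationSpec"
  )
}

#' Simulate a labelled case/control expression dataset
#'
#' TF values are i.i.d. standard normal per sample (optionally equicorrelated
#' with coefficient `tf_rho`, to stress sparse selection under collinearity).
#' Control targets follow the network exactly:
#' `intercept + sum(true_weights * TF) + N(0, noise_sigma^2)`. Case samples
#' are generated identically except that altered targets use the
#' perturbation's case weights. The returned dataset carries identity
#' feature-symbol annotation (each simulated feature is its own gene), so
#' [partition_features()] with `tf_symbols = net$tf_ids` reproduces the truth.
#'
#' @param net a [generate_network()] result.
#' @param n_control,n_case group sizes (>= 1).
#' @param perturbation optional [perturbation_spec()]; `NULL` means the case
#'   group follows the same generative law as the controls.
#' @param seed integer seed; matrices are bit-identical given the seed.
#' @param tf_rho equicorrelation of the TF panel, in \[0, 1).
#' @param dataset_id id for the returned dataset.
#' @return list with `dataset` (an [expression_dataset()]) and `truth` (list
#'   with the network and perturbation used, plus `altered_targets`).
#' @export
simulate_dataset <- function(net, n_control, n_case, perturbation = NULL,
                             seed = 1, tf_rho = 0, dataset_id = "simulated") {
  stopifnot(inherits(net, "GroundTruthNetwork"))
  if (n_control < 1 || n_case < 1) stop("group sizes must be >= 1")
  if (tf_rho < 0 || tf_rho >= 1) stop("tf_rho must lie in [0, 1)")
  if (!is.null(perturbation)) stopifnot(inherits(perturbation, "PerturbationSpec"))

  n <- n_control + n_case
  smp <- c(sprintf("CTRL%04d", seq_len(n_control)),
           sprintf("CASE%04d", seq_len(n_case)))
  labels <- rep(c("control", "case"), c(n_control, n_case))
  is_case <- labels == "case"
  altered <- if (is.null(perturbation)) character(0) else perturbation$altered_targets

  vals <- with_seed(seed, {
    tf <- matrix(stats::rnorm(length(net$tf_ids) * n),
                 nrow = length(net$tf_ids), ncol = n,
                 dimnames = list(net$tf_ids, smp))
    if (tf_rho > 0) {
      common <- matrix(stats::rnorm(n), nrow = 1)
      tf <- sqrt(tf_rho) * common[rep(1, nrow(tf)), , drop = FALSE] +
        sqrt(1 - tf_rho) * tf
      dimnames(tf) <- list(net$tf_ids, smp)
    }
    mrna <- matrix(NA_real_, nrow = length(net$mrna_ids), ncol = n,
                   dimnames = list(net$mrna_ids, smp))
    for (t in net$mrna_ids) {
      w <- net$true_weights[[t]]
      base <- net$intercepts[[t]] + stats::rnorm(n, sd = net$noise_sigma)
      sig <- if (length(w)) as.numeric(crossprod(tf[names(w), , drop = FALSE], w)) else 0
      y <- base + sig
      if (t %in% altered) {
        wc <- perturbation$case_weights[[t]]
        sig_c <- if (length(wc)) {
          as.numeric(crossprod(tf[names(wc), is_case, drop = FALSE], wc))
        } else 0
        y[is_case] <- base[is_case] + sig_c
      }
      mrna[t, ] <- y
    }
    rbind(tf, mrna)
  })

  ids <- rownames(vals)
  ds <- expression_dataset(vals, labels, dataset_id = dataset_id,
                           feature_symbols = stats::setNames(ids, ids))
  list(dataset = ds,
       truth = list(network = net, perturbation = perturbation,
                    altered_targets = altered))
}

#' Write simulator ground truth as TSV
#'
#' One row per true regulatory weight: `target, tf, weight, altered,
#' case_weight`.
#'
#' @param truth the `truth` element returned by [simulate_dataset()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  net <- truth$network
  rows <- lapply(net$mrna_ids, function(t) {
    w <- net$true_weights[[t]]
    if (length(w) == 0) {
      return(data.frame(target = t, tf = NA_character_, weight = NA_real_,
                        altered = t %in% truth$altered_targets,
                        case_weight = NA_real_, stringsAsFactors = FALSE))
    }
    cw <- w
    if (t %in% truth$altered_targets) cw <- truth$perturbation$case_weights[[t]]
    data.frame(target = t, tf = names(w), weight = unname(w),
               altered = t %in% truth$altered_targets,
               case_weight = unname(cw[names(w)]), stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Score detection of altered targets against ground truth
#'
#' Confusion counts of a detected id set against the true altered set, plus
#' AUROC of a per-target score: the probability that a random altered target
#' outscores a random unaltered one, ties counting one half.
#'
#' @param detected character vector of detected target ids.
#' @param truth_altered character vector of truly altered target ids.
#' @param scores named numeric vector covering every target in the evaluation
#'   universe (the names define the universe).
#' @return list with `sensitivity`, `specificity`, `precision`, `auroc` and
#'   the confusion counts `tp`, `fp`, `tn`, `fn`. Undefined ratios (empty
#'   denominator) are `NA`.
#' @export
evaluate_recovery <- function(detected, truth_altered, scores) {
  if (is.null(names(scores)) || anyDuplicated(names(scores))) {
    stop("scores must be uniquely named by target id")
  }
  universe <- names(scores)
  pos <- universe %in% truth_altered
  det <- universe %in% detected
  tp <- sum(pos & det); fp <- sum(!pos & det)
  fn <- sum(pos & !det); tn <- sum(!pos & !det)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  auroc <- NA_real_
  if (any(pos) && any(!pos)) {
    r <- rank(scores)  # midranks: ties contribute 1/2 automatically
    n1 <- sum(pos)
    auroc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * sum(!pos))
  }
  list(sensitivity = safe_div(tp, tp + fn),
       specificity = safe_div(tn, tn + fp),
       precision = safe_div(tp, tp + fp),
       auroc = auroc,
       tp = tp, fp = fp, tn = tn, fn = fn)
}
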