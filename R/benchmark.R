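#' Universal-threshold lasso penalty
#'
#' The standard theory rate `sigma * sqrt(2 * log(p) / n)` for a lasso on
#' (approximately) unit-variance predictors: the smallest penalty that keeps
#' pure-noise coordinates out of the model with high probability. The L1
#' penalty is scale-dependent, so simulated data on the additive unit scale is
#' fitted at this rate rather than at the intensity-scale default of
#' [mqtrans_config()].
#'
#' @param sigma residual noise sd.
#' @param n_tf number of candidate TF predictors.
#' @param n_train training sample count.
#' @return a single non-negative penalty value.
#' @export
universal_penalty <- function(sigma, n_tf, n_train) {
  sigma * sqrt(2 * log(n_tf) / n_train)
}

#' Synthetic recovery benchmark of the full pipeline
#'
#' Simulates a ground-truth network with a fixed fraction of targets perturbed
#' in the case group, runs the default detection pipeline, and scores the
#' altered-target recovery: AUROC of the case/control mqTrans mean-ratio
#' ranking over all targets, plus sensitivity / false-positive rate of the
#' default alteration rule, averaged over seeds. The lasso penalty is the
#' [universal_penalty()] for the simulated scale unless overridden.
#'
#' @param n_tf,n_mrna,k_regulators,weight_range,noise_sigma network parameters
#'   (see [generate_network()]); defaults are the package's reference
#'   benchmark: 200 TFs, 300 targets, 3 regulators each with weight magnitudes
#'   in \[0.5, 1.5\], noise sd 0.2.
#' @param n_control,n_case group sizes (80/80).
#' @param n_altered perturbed targets (60).
#' @param mode,magnitude perturbation (sign flip by default).
#' @param seeds integer vector; one full simulate+fit+detect replicate per
#'   seed.
#' @param config an [mqtrans_config()]; its penalty is replaced by
#'   `penalty` below.
#' @param penalty lasso penalty used on the simulated scale.
#' @return list with `auroc`, `sensitivity`, `fpr` (averaged over seeds),
#'   `per_seed` (data.frame) and the settings used.
#' @export
recovery_benchmark <- function(n_tf = 200, n_mrna = 300, k_regulators = 3,
                               weight_range = c(0.5, 1.5), noise_sigma = 0.2,
                               n_control = 80, n_case = 80, n_altered = 60,
                               mode = "sign_flip", magnitude = 0,
                               seeds = 1:5, config = mqtrans_config(),
                               penalty = NULL) {
  if (is.null(penalty)) {
    n_train <- floor(config$train_fraction * n_control)
    penalty <- universal_penalty(noise_sigma, n_tf, n_train)
  }
  per_seed <- lapply(seeds, function(s) {
    net <- generate_network(n_tf, n_mrna, k_regulators, weight_range,
                            noise_sigma, seed = s)
    pert <- perturbation_spec(net, n_altered = n_altered, mode = mode,
                              magnitude = magnitude, seed = s + 1L)
    sim <- simulate_dataset(net, n_control, n_case, pert, seed = s + 2L)
    cfg <- config
    cfg$penalty <- penalty
    cfg$seed <- s + 3L
    run <- run_core(sim$dataset, net$tf_ids, cfg)
    scores <- stats::setNames(run$alteration$ratio, run$alteration$target_id)
    ev <- evaluate_recovery(run$screen$stages$altered,
                            sim$truth$altered_targets, scores)
    mean_case_mq_altered <- mean(run$mqtrans[sim$truth$altered_targets,
                                             case_ids(sim$dataset)])
    data.frame(seed = s, auroc = ev$auroc, sensitivity = ev$sensitivity,
               fpr = ev$fp / (ev$fp + ev$tn),
               n_detected = length(run$screen$stages$altered),
               mean_case_mqtrans_altered = mean_case_mq_altered)
  })
  per_seed <- do.call(rbind, per_seed)
  list(auroc = mean(per_seed$auroc),
       sensitivity = mean(per_seed$sensitivity),
       fpr = mean(per_seed$fpr),
       mean_case_mqtrans_altered = mean(per_seed$mean_case_mqtrans_altered),
       per_seed = per_seed,
       penalty = penalty, n_altered = n_altered, mode = mode,
       magnitude = magnitude)
}
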