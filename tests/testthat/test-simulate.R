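test_that("network generation is seeded and respects its preconditions", {
  a <- generate_network(50, 100, 3, seed = 5)
  b <- generate_network(50, 100, 3, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, generate_network(50, 100, 3, seed = 6)))
  expect_true(all(vapply(a$true_weights, length, integer(1)) == 3))
  mags <- abs(unlist(a$true_weights))
  expect_true(all(mags >= 0.5 & mags <= 1.5))

  null_net <- generate_network(10, 5, 0, seed = 1)
  expect_true(all(vapply(null_net$true_weights, length, integer(1)) == 0))
  dense <- generate_network(10, 5, 10, seed = 1)
  expect_true(all(vapply(dense$true_weights, length, integer(1)) == 10))

  expect_error(generate_network(0, 5), "positive")
  expect_error(generate_network(10, 5, 11), "k_regulators")
})

test_that("simulated datasets are bit-identical under a fixed seed", {
  net <- generate_network(20, 30, 3, seed = 2)
  pert <- perturbation_spec(net, n_altered = 5, seed = 3)
  a <- simulate_dataset(net, 15, 15, pert, seed = 4)
  b <- simulate_dataset(net, 15, 15, pert, seed = 4)
  expect_identical(a$dataset$values, b$dataset$values)
  expect_identical(a$truth$altered_targets, b$truth$altered_targets)
  expect_false(identical(a$dataset$values,
                         simulate_dataset(net, 15, 15, pert, seed = 5)$dataset$values))
})

test_that("controls follow the network law: near-zero penalty recovers truth", {
  net <- generate_network(20, 10, 3, noise_sigma = 0, seed = 7)
  sim <- simulate_dataset(net, 120, 1, seed = 8)
  ds <- sim$dataset
  part <- partition_features(ds, net$tf_ids)
  sp <- split_controls(ds, 0.7, seed = 9)
  models <- fit_models(ds, part, sp$train_sample_ids, penalty = 1e-9)
  for (t in net$mrna_ids) {
    w_hat <- stats::setNames(rep(0, 20), net$tf_ids)
    w_hat[names(models[[t]]$weights)] <- models[[t]]$weights
    w_true <- stats::setNames(rep(0, 20), net$tf_ids)
    w_true[names(net$true_weights[[t]])] <- net$true_weights[[t]]
    expect_equal(unname(w_hat), unname(w_true), tolerance = 1e-5)
  }
})

test_that("a sign flip inflates the case residual variance by 4w^2", {
  # single-regulator target, unit-variance TF: control residual variance is
  # sigma^2, case residual variance under the control-trained model is
  # 4 w^2 + sigma^2
  net <- generate_network(5, 1, 1, weight_range = c(1, 1), noise_sigma = 0.3,
                          seed = 11)
  t <- net$mrna_ids[1]
  w <- net$true_weights[[t]]
  pert <- perturbation_spec(net, altered_targets = t, mode = "sign_flip",
                            seed = 12)
  sim <- simulate_dataset(net, 2000, 2000, pert, seed = 13)
  ds <- sim$dataset
  part <- partition_features(ds, net$tf_ids)
  sp <- split_controls(ds, 0.7, seed = 14)
  models <- fit_models(ds, part, sp$train_sample_ids, penalty = 1e-4)
  mq <- mqtrans_matrix(models, ds)
  v_ctrl <- mean(mq[t, sp$holdout_sample_ids]^2)
  v_case <- mean(mq[t, case_ids(ds)]^2)
  expect_equal(v_ctrl, 0.3^2, tolerance = 0.1)
  expect_equal(v_case, 4 * unname(w)^2 + 0.3^2, tolerance = 0.1)
})

test_that("unaltered targets stay indistinguishable between groups", {
  net <- generate_network(20, 40, 3, noise_sigma = 0.2, seed = 21)
  pert <- perturbation_spec(net, n_altered = 10, seed = 22)
  sim <- simulate_dataset(net, 60, 60, pert, seed = 23)
  cfg <- mqtrans_config(seed = 24, penalty = universal_penalty(0.2, 20, 42))
  run <- run_pipeline(sim$dataset, net$tf_ids, cfg)
  unalt <- setdiff(net$mrna_ids, sim$truth$altered_targets)
  p_un <- run$alteration$test_p[run$alteration$target_id %in% unalt]
  # one-sided null p-values: no mass piling up near zero
  expect_lt(mean(p_un < 0.05), 0.15)
  expect_gt(median(p_un), 0.2)
})

test_that("perturbations require an existing regulator", {
  null_net <- generate_network(5, 4, 0, seed = 1)
  expect_error(perturbation_spec(null_net, n_altered = 1), "not enough targets")
  net <- generate_network(5, 4, 1, seed = 1)
  expect_error(perturbation_spec(net, n_altered = 2, mode = "weight_shift",
                                 magnitude = -1), "non-negative")
})

test_that("evaluate_recovery scores detection against the truth", {
  scores <- stats::setNames(runif(10), paste0("t", 1:10))
  truth <- paste0("t", 1:4)
  perfect <- evaluate_recovery(truth, truth, scores)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  inverted <- evaluate_recovery(setdiff(names(scores), truth), truth, scores)
  expect_equal(inverted$sensitivity, 0)

  none <- evaluate_recovery(character(0), character(0), scores)
  expect_true(is.na(none$sensitivity))   # undefined, flagged not raised
  expect_true(is.na(none$auroc))
})

test_that("AUROC matches brute-force pairwise counting, ties at one half", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 12
    scores <- stats::setNames(sample(1:6, n, replace = TRUE) / 2,
                              paste0("t", 1:n))
    truth <- sample(names(scores), 5)
    got <- evaluate_recovery(character(0), truth, scores)$auroc
    want <- auroc_bruteforce(scores[truth], scores[setdiff(names(scores), truth)])
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("random scores give chance-level AUROC", {
  set.seed(99)
  scores <- stats::setNames(runif(4000), paste0("t", 1:4000))
  truth <- sample(names(scores), 2000)
  auroc <- evaluate_recovery(character(0), truth, scores)$auroc
  expect_lt(abs(auroc - 0.5), 0.03)  # ~3 binomial sds
})

test_that("simulated data round-trips through the series-matrix dialect", {
  net <- generate_network(5, 5, 2, seed = 31)
  sim <- simulate_dataset(net, 4, 4, seed = 32)
  path <- withr::local_tempfile(fileext = ".txt")
  write_series_matrix(sim$dataset, path)
  back <- read_series_matrix(path, written_label_rule())
  expect_identical(back$values, sim$dataset$values)
  expect_identical(back$sample_labels, sim$dataset$sample_labels)
})
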