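test_that("transfer reports missing features instead of raising", {
  ds <- tiny_dataset()
  models <- list(
    ok = make_model("g1", weights = c(t1 = 1, t2 = 0.5)),
    no_tf = make_model("g2", weights = c(t1 = 1, t9 = 2)),
    no_target = make_model("g9", weights = c(t1 = 1))
  )
  tr <- transfer_models(models, ds)
  expect_equal(tr$reports$transferable, c(TRUE, FALSE, FALSE))
  expect_equal(tr$reports$missing[[2]], "t9")
  expect_equal(tr$reports$missing[[3]], "g9")
  expect_equal(tr$qc$target_id, "g1")   # QC only for transferable models
  expect_equal(tr$qc$eval_set, "tiny")
})

test_that("self-transfer QC equals in-dataset QC on the same samples", {
  ds <- tiny_dataset(seed = 8, n_control = 20, n_case = 5)
  part <- partition_features(ds, c("TFA", "TFB", "TFC"))
  sp <- split_controls(ds, 0.7, seed = 3)
  models <- fit_models(ds, part, sp$train_sample_ids, penalty = 0.05)
  tr <- transfer_models(models, ds)
  direct <- qc_models(models, ds, control_ids(ds), eval_set = ds$dataset_id)
  expect_equal(tr$qc$pcc, direct$pcc)
  expect_equal(tr$qc$p_value, direct$p_value)
})

test_that("venn_regions returns exclusive regions and the full intersection", {
  v <- venn_regions(list(A = c("1", "2"), B = c("2", "3")))
  expect_equal(unname(v$region_counts[c("A", "B", "A&B")]), c(1L, 1L, 1L))
  expect_equal(v$full_intersection, "2")

  ids <- paste0("x", 1:5)
  v3 <- venn_regions(list(A = ids, B = ids, C = ids))
  expect_equal(unname(v3$region_counts[["A&B&C"]]), 5L)
  expect_equal(sum(v3$region_counts), 5L)

  expect_error(venn_regions(list(A = "1")), "2 or 3")
})

test_that("venn region counts match exhaustive enumeration on random sets", {
  universe <- sprintf("e%02d", 1:30)
  for (seed in 1:20) {
    set.seed(seed)
    sets <- list(A = sample(universe, sample(0:20, 1)),
                 B = sample(universe, sample(0:20, 1)),
                 C = sample(universe, sample(0:20, 1)))
    v <- venn_regions(sets)
    # oracle: classify every universe element by membership pattern
    expected <- table(vapply(universe, function(e) {
      paste(names(sets)[vapply(sets, function(s) e %in% s, logical(1))],
            collapse = "&")
    }, character(1)))
    expected <- expected[nzchar(names(expected))]
    for (k in names(v$region_counts)) {
      want <- if (k %in% names(expected)) as.integer(expected[[k]]) else 0L
      expect_equal(unname(v$region_counts[[k]]), want)
    }
    expect_equal(sum(v$region_counts), length(unique(unlist(sets))))
    expect_setequal(v$full_intersection, Reduce(intersect, sets))
  }
})

sim_pair <- function(seed_ds) {
  net <- generate_network(30, 40, 3, noise_sigma = 0.2, seed = 50)
  pert <- perturbation_spec(net, n_altered = 10, seed = 51)
  simulate_dataset(net, 60, 60, pert, seed = seed_ds,
                   dataset_id = paste0("sim", seed_ds))
}

test_that("confirm_across intersects per-dataset altered sets", {
  simA <- sim_pair(60)
  simB <- sim_pair(61)
  net_tfs <- simA$truth$network$tf_ids
  cfg <- mqtrans_config(seed = 7, penalty = universal_penalty(0.2, 30, 42))

  conf <- confirm_across(simA$dataset, list(simB$dataset), net_tfs, cfg,
                         mode = "transfer")
  expect_named(conf$altered, c("sim60", "sim61"))
  expect_setequal(conf$confirmed,
                  intersect(conf$altered$sim60, conf$altered$sim61))
  expect_true(all(conf$confirmed %in% conf$altered$sim61))
  expect_equal(length(conf$venn$full_intersection), length(conf$confirmed))
  # the shared ground truth should actually be confirmed above chance
  expect_gt(length(conf$confirmed), 0)
  expect_true(mean(conf$confirmed %in% simA$truth$altered_targets) > 0.8)
})

test_that("retrain mode on an identical dataset reproduces the training set's list", {
  simA <- sim_pair(70)
  cfg <- mqtrans_config(seed = 9, penalty = universal_penalty(0.2, 30, 42))
  conf <- confirm_across(simA$dataset,
                         list(dup = simA$dataset),
                         simA$truth$network$tf_ids, cfg, mode = "retrain")
  expect_identical(sort(conf$altered[[1]]), sort(conf$altered$dup))
  expect_setequal(conf$confirmed, conf$altered[[1]])
})

test_that("a validation dataset without controls is rejected", {
  simA <- sim_pair(80)
  ds_cases <- expression_dataset(simA$dataset$values,
                                 rep("case", ncol(simA$dataset$values)))
  expect_error(
    confirm_across(simA$dataset, list(ds_cases),
                   simA$truth$network$tf_ids, mqtrans_config()),
    "no control samples")
})
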