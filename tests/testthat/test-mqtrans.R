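test_that("mqTrans is the absolute prediction residual", {
  ds <- expression_dataset(
    matrix(c(1, 5, 2, 3, 0, 5), nrow = 3,
           dimnames = list(c("t1", "gA", "gB"), c("s1", "s2"))),
    c("control", "case"))
  # prediction for gA: 1 + 2*t1 -> 3 (s1), 7 (s2); observed 5, 0
  m <- make_model("gA", weights = c(t1 = 2), intercept = 1)
  prof <- compute_mqtrans(m, ds)
  expect_equal(unname(prof$values), c(2, 7))
  expect_true(all(prof$values >= 0))

  # observed == predicted -> exactly zero; |obs - pred| symmetric otherwise
  m2 <- make_model("gB", weights = c(t1 = 1), intercept = 1)
  expect_equal(unname(compute_mqtrans(m2, ds)$values), c(0, 1))

  expect_error(compute_mqtrans(make_model("missing"), ds), "absent")
})

test_that("mqTrans values are invariant to sample and feature order", {
  ds <- tiny_dataset(seed = 3)
  part <- partition_features(ds, c("TFA", "TFB", "TFC"))
  sp <- split_controls(ds, 0.7, seed = 1)
  models <- fit_models(ds, part, sp$train_sample_ids, penalty = 0.05)
  mq <- mqtrans_matrix(models, ds)

  perm_s <- sample(sample_ids(ds))
  perm_f <- sample(feature_ids(ds))
  ds_perm <- expression_dataset(ds$values[perm_f, perm_s],
                                ds$sample_labels[perm_s],
                                feature_symbols = ds$feature_symbols[perm_f])
  mq_perm <- mqtrans_matrix(models, ds_perm)
  expect_equal(mq_perm[rownames(mq), colnames(mq)], mq)
})

test_that("summarize_groups computes means, guarded ratio and one-sided test", {
  lab <- c(a = "case", b = "case", c = "case",
           x = "control", y = "control", z = "control")
  r <- summarize_groups(c(a = 2, b = 2, c = 2, x = 1, y = 1, z = 1), lab)
  expect_equal(r$ratio, 2)
  expect_equal(r$n_case, 3)

  # exact fold is reproduced: case mean = 2.1529 * control mean
  ctrl <- c(x = 0.8, y = 1.0, z = 1.2)
  case <- c(a = 0.8, b = 1.0, c = 1.2) * 2.1529
  expect_equal(summarize_groups(c(case, ctrl), lab)$ratio, 2.1529,
               tolerance = 1e-12)

  # identical groups: null ratio and no one-sided evidence
  r0 <- summarize_groups(c(a = 1, b = 2, c = 3, x = 1, y = 2, z = 3), lab)
  expect_equal(r0$ratio, 1)
  expect_gte(r0$test_p, 0.5)

  # zero control mean flags the ratio as infinite
  rz <- summarize_groups(c(a = 1, b = 1, c = 1, x = 0, y = 0, z = 0), lab)
  expect_true(rz$ratio_infinite)

  expect_error(summarize_groups(c(a = 1, b = 1), lab[1:2]), "non-empty")
})

test_that("detect_altered applies direction, significance and rule choice", {
  res <- data.frame(
    target_id = c("up_sig", "down_sig", "up_weak"),
    ratio = c(1.8, 0.9, 1.6215),
    ratio_infinite = FALSE,
    test_q = c(0.001, 0.001, 0.2)
  )
  expect_equal(detect_altered(res), "up_sig")
  expect_setequal(detect_altered(res, rule = "ratio_only"),
                  c("up_sig", "up_weak"))
  expect_error(detect_altered(res, rule = "bogus"))

  # pure-ratio rule equals the set {ratio > 1} exactly
  for (seed in 1:5) {
    set.seed(seed)
    rnd <- data.frame(target_id = paste0("t", 1:50),
                      ratio = exp(rnorm(50, sd = 0.5)),
                      ratio_infinite = FALSE,
                      test_q = runif(50))
    expect_setequal(detect_altered(rnd, rule = "ratio_only"),
                    rnd$target_id[rnd$ratio > 1])
  }
})

test_that("screen_cascade composes stages by intersection", {
  ids <- sprintf("t%02d", 1:10)
  # 8 with models, 6 of those pass QC, 4 altered, 3 with model q < 0.01
  models <- c(
    lapply(ids[1:8], make_model, weights = c(tf1 = 1)),
    lapply(ids[9:10], make_model)
  )
  names(models) <- ids
  qc <- data.frame(
    target_id = ids,
    pcc = c(rep(0.9, 6), 0.2, 0.3, NA, NA),
    p_value = c(1e-9, 1e-8, 1e-7, 4e-2, 2e-3, 4.5e-2, 0.5, 0.6, NA, NA)
  )
  alteration <- data.frame(
    target_id = ids,
    ratio = c(2, 2, 2, 2, 0.5, 0.9, 2, 2, 2, 2),
    ratio_infinite = FALSE,
    test_p = c(1e-6, 1e-6, 1e-6, 1e-6, 1e-6, 0.9, 1e-6, 1e-6, 1e-6, 1e-6)
  )
  rep <- screen_cascade(models, qc, alteration)
  expect_equal(unname(rep$counts),
               c(10L, 8L, 6L, 4L, 3L))
  expect_equal(rep$stages$altered, ids[1:4])
  # fdr stage: BH over the 6 QC survivors' p-values, q < 0.01
  q6 <- benjamini_hochberg(qc$p_value[1:6])
  expect_equal(rep$stages$fdr, ids[1:4][q6[1:4] < 0.01])
  expect_length(rep$stages$fdr, 3)
})

test_that("screen_cascade boundaries are strict and empty input is all-zero", {
  models <- list(a = make_model("a", weights = c(t = 1)))
  qc <- data.frame(target_id = "a", pcc = 0.9, p_value = 1e-6)
  alteration <- data.frame(target_id = "a", ratio = 2, ratio_infinite = FALSE,
                           test_p = 1e-6)
  # model q exactly 0.01 is excluded ("FDR >= 0.01 are excluded")
  qc$p_value <- 0.01
  rep <- screen_cascade(models, qc, alteration, p_max = 0.05)
  expect_length(rep$stages$fdr, 0)

  rep0 <- screen_cascade(structure(list(), names = character(0)),
                         qc[0, ], alteration[0, ])
  expect_true(all(rep0$counts == 0))
})

test_that("rank_features is descending with lexicographic tie-break", {
  res <- data.frame(target_id = c("a", "b", "c"), pcc = c(0.9, 0.95, 0.8))
  expect_equal(rank_features(res, "pcc", 2), c("b", "a"))

  tie <- data.frame(target_id = c("x2", "x10"), pcc = c(0.9, 0.9))
  expect_equal(rank_features(tie, "pcc", 2), c("x10", "x2"))

  expect_equal(rank_features(res, "pcc", 99), c("b", "a", "c"))
  expect_error(rank_features(res, "pcc", 0), "positive")

  inf_res <- data.frame(target_id = c("fin", "inf"),
                        ratio = c(100, 5),
                        ratio_infinite = c(FALSE, TRUE))
  expect_equal(rank_features(inf_res, "ratio", 2), c("inf", "fin"))
})
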