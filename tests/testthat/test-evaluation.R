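fake_cases <- function(n_normal, n_acute, n_chronic) {
  labels <- rep(c("normal", "acute", "chronic"),
                c(n_normal, n_acute, n_chronic))
  lapply(seq_along(labels), function(i)
    structure(list(case_id = sprintf("case%04d", i), label = labels[i],
                   slices = list()), class = "oct_case"))
}

test_that("fold assignment partitions patients with stratified balance", {
  cases <- fake_cases(82, 109, 106)
  plan <- make_folds(cases, k = 5, seed = 3)
  ids <- vapply(cases, `[[`, character(1), "case_id")
  tests <- lapply(plan$folds, `[[`, "test")
  expect_setequal(unlist(tests), ids)                     # exhaustive
  expect_identical(anyDuplicated(unlist(tests)), 0L)      # disjoint
  labels <- vapply(cases, `[[`, character(1), "label")
  for (f in seq_len(5)) {
    fl <- plan$folds[[f]]
    expect_length(intersect(fl$test, c(fl$sip, fl$fd)), 0)  # no leakage
    expect_setequal(c(fl$sip, fl$fd), setdiff(ids, fl$test))
    for (lb in c("normal", "acute", "chronic")) {
      n_lb <- sum(labels[match(fl$test, ids)] == lb)
      expect_lte(abs(n_lb - sum(labels == lb) / 5), 1)
    }
  }
  expect_identical(make_folds(cases, k = 5, seed = 3)$assignments,
                   plan$assignments)
  expect_error(make_folds(fake_cases(2, 30, 30), k = 5), "too few cases")
  single <- make_folds(cases, k = 1, seed = 1)
  expect_length(single$folds[[1]]$test, 297)
})

test_that("the SIP/FD sub-split is an exact stratified 75/25", {
  cases <- fake_cases(40, 30, 30)
  ids <- vapply(cases, `[[`, character(1), "case_id")
  labels <- vapply(cases, `[[`, character(1), "label")
  sp <- split_sip_fd(ids, labels, ratio = 0.75, seed = 11)
  expect_length(sp$sip, 75)
  expect_length(sp$fd, 25)
  expect_length(intersect(sp$sip, sp$fd), 0)
  expect_setequal(c(sp$sip, sp$fd), ids)
  for (lb in unique(labels)) {
    n_sip <- sum(labels[match(sp$sip, ids)] == lb)
    expect_lte(abs(n_sip - 0.75 * sum(labels == lb)), 1)
  }
  # exact multiples split exactly
  cases2 <- fake_cases(40, 40, 40)
  sp2 <- split_sip_fd(vapply(cases2, `[[`, character(1), "case_id"),
                      vapply(cases2, `[[`, character(1), "label"),
                      ratio = 0.75, seed = 2)
  labels2 <- vapply(cases2, `[[`, character(1), "label")
  ids2 <- vapply(cases2, `[[`, character(1), "case_id")
  for (lb in unique(labels2))
    expect_identical(sum(labels2[match(sp2$sip, ids2)] == lb), 30L)
  expect_error(split_sip_fd(c("a", "b"), c("acute", "chronic")),
               "degenerate")
})

test_that("metrics match hand-computable confusion-matrix cases", {
  # perfect agreement
  perf <- compute_metrics(rep(c("acute", "chronic", "normal"), 5),
                          rep(c("acute", "chronic", "normal"), 5))
  expect_equal(perf$accuracy, 1)
  expect_equal(perf$kappa, 1)
  expect_equal(unname(perf$sensitivity), rep(1, 3))
  expect_equal(unname(perf$specificity), rep(1, 3))
  # cyclic shift, uniform marginals: p_o = 0, p_e = 1/3 -> kappa = -1/2
  actual <- rep(c("acute", "chronic", "normal"), each = 10)
  shifted <- rep(c("chronic", "normal", "acute"), each = 10)
  cyc <- compute_metrics(actual, shifted)
  expect_equal(cyc$accuracy, 0)
  expect_equal(cyc$kappa, -0.5)
  # the best-fold worked example: 60 cases, one normal case misclassified
  actual4 <- rep(c("normal", "acute", "chronic"), c(18, 22, 20))
  pred4 <- actual4; pred4[1] <- "acute"
  m4 <- compute_metrics(actual4, pred4)
  expect_equal(round(100 * m4$accuracy, 2), 98.33)
  expect_identical(unname(m4$confusion["normal", "acute"]), 1L)
  expect_identical(sum(m4$confusion), 60L)
  expect_error(compute_metrics(c("acute", "odd"), c("acute", "acute")),
               "outside the class set")
  expect_error(compute_metrics(character(0), character(0)), "non-empty")
})

test_that("kappa agrees with a first-principles computation on random data", {
  set.seed(314)
  for (i in 1:300) {
    n <- sample(5:40, 1)
    actual <- sample(c("acute", "chronic", "normal"), n, replace = TRUE)
    predicted <- sample(c("acute", "chronic", "normal"), n, replace = TRUE)
    if (length(unique(c(actual, predicted))) == 1) next
    m <- compute_metrics(actual, predicted)
    expect_equal(m$kappa, kappa_brute(actual, predicted), tolerance = 1e-12)
    expect_true(m$accuracy >= 0 && m$accuracy <= 1)
    expect_true(m$kappa >= -1 && m$kappa <= 1 + 1e-12)
  }
})

test_that("a fold trains without leakage and the comparison table is sound", {
  cases <- tiny_cases(4, seed = 555)
  cfg <- csc_config(sip = quick_sip(), hyper = train_hyper(epochs = 8),
                    p = tiny_pp(), a = augment_params(enabled = FALSE))
  plan <- make_folds(cases, k = 2, seed = 1)
  r <- run_fold(plan, 1, cases, cfg, seed = 4)
  expect_s3_class(r$metrics, "metrics_report")
  expect_identical(r$metrics$n_cases, length(plan$folds[[1]]$test))
  expect_setequal(r$predictions$case_id, plan$folds[[1]]$test)
  expect_length(intersect(r$predictions$case_id,
                          c(r$model$sip_ids, r$model$fd_ids)), 0)
  # comparison table: one row per model, Average = mean of fold columns
  models <- list(
    proposed = list(type = "proposed", config = cfg),
    cnn3d = list(type = "cnn3d", spec = baseline_3dcnn_spec(c(4, 6, 8)),
                 hyper = train_hyper(epochs = 2, batch_size = 4),
                 p = tiny_pp(), a = augment_params(enabled = FALSE)))
  tab <- compare_models(cases, models, k = 2, seed = 6)
  expect_identical(rownames(tab), c("proposed", "cnn3d"))
  expect_identical(ncol(tab), 3L)
  expect_equal(tab$Average, unname(rowMeans(tab[, 1:2])), tolerance = 1e-12)
})
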