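test_that("sip_spec enforces the four-layer, 3-class head contract", {
  expect_error(sip_spec(head_widths = c(64, 3)), "four head layers")
  expect_error(sip_spec(head_widths = c(64, 32, 16, 4)), "3")
  expect_error(sip_spec(backbone = "vgg99"), "unknown backbone")
  expect_error(build_sip(sip_spec(backbone = "resnet50")), "pretrained")
})

test_that("an untrained SIP emits valid, deterministic softmax vectors", {
  m1 <- build_sip(quick_sip(), input_shape = c(18L, 26L), seed = 4)
  m2 <- build_sip(quick_sip(), input_shape = c(18L, 26L), seed = 4)
  img <- array(runif(18 * 26 * 3, 0, 255), c(18, 26, 3))
  p1 <- predict_slice(m1, img)
  expect_equal(sum(p1), 1, tolerance = 1e-9)
  expect_true(all(p1 >= 0))
  expect_identical(names(p1), c("acute", "chronic", "normal"))
  expect_identical(p1, predict_slice(m2, img))      # same spec + seed
  expect_identical(p1, predict_slice(m1, img))      # inference determinism
  expect_error(predict_slice(m1, array(0, c(10, 10, 3))), "dimensions")
  # zeroed final layer -> uniform probabilities (equal logits)
  m1$head[[10]]$W[] <- 0; m1$head[[10]]$b[] <- 0
  expect_equal(unname(predict_slice(m1, img)), rep(1 / 3, 3),
               tolerance = 1e-12)
})

test_that("freezing the backbone restricts the trainable parameter set", {
  frozen <- build_sip(quick_sip(freeze_backbone = TRUE),
                      input_shape = c(18L, 26L), seed = 1)
  free <- build_sip(quick_sip(freeze_backbone = FALSE),
                    input_shape = c(18L, 26L), seed = 1)
  head_params <- octcsc:::nn_count_params(frozen$head)
  backbone_params <- octcsc:::nn_count_params(frozen$backbone)
  expect_identical(sip_n_params(frozen, trainable_only = TRUE), head_params)
  expect_identical(sip_n_params(free, trainable_only = TRUE),
                   head_params + backbone_params)
  expect_identical(sip_n_params(frozen), head_params + backbone_params)
})

test_that("the training pool keeps only lesion cuts from CSC cases", {
  cases <- tiny_cases(2)
  pool <- select_sip_training_slices(cases)
  expected <- sum(vapply(cases, function(cs) {
    if (cs$label == "normal") length(cs$slices)
    else sum(vapply(cs$slices, `[[`, logical(1), "is_lesion_cut"))
  }, numeric(1)))
  expect_length(pool$slices, expected)
  csc <- pool$labels != "normal"
  expect_true(all(vapply(pool$slices[csc], `[[`, logical(1),
                         "is_lesion_cut")))
  # normal cases contribute all 25 slices under the all-slices policy
  expect_identical(sum(pool$labels == "normal"), 2L * 25L)
  # a CSC case with its lesion flags stripped is rejected
  broken <- cases[[3]]
  for (i in seq_along(broken$slices)) broken$slices[[i]]$is_lesion_cut <- FALSE
  expect_error(select_sip_training_slices(list(broken)), "zero lesion cuts")
})

test_that("training separates a clean pool and never touches frozen weights", {
  sp <- tiny_sp(noise_sd = 0)
  cases <- generate_dataset(2, 3, 3, sp, seed = 21)
  pool <- select_sip_training_slices(cases)
  m <- build_sip(quick_sip(), input_shape = c(18L, 26L), seed = 2)
  sum_before <- octcsc:::nn_weight_checksum(m$backbone)
  tr <- train_sip(m, pool, train_hyper(epochs = 40, seed = 3,
                                       learning_rate = 3e-3),
                  p = tiny_pp(), a = augment_params(enabled = FALSE))
  base <- lapply(pool$slices, function(s)
    downsample_slice(crop_slice(s, tiny_pp()), tiny_pp()))
  pred <- vapply(base, function(s)
    names(which.max(predict_slice(tr, s))), character(1))
  expect_gte(mean(pred == pool$labels), 0.99)
  expect_identical(octcsc:::nn_weight_checksum(tr$backbone), sum_before)
  # identical seeds and data give identical training trajectories
  tr2 <- train_sip(m, pool, train_hyper(epochs = 40, seed = 3,
                                        learning_rate = 3e-3),
                   p = tiny_pp(), a = augment_params(enabled = FALSE))
  expect_identical(tr$log, tr2$log)
  expect_error(train_sip(m, list(slices = pool$slices[1:3],
                                 labels = rep("acute", 3)),
                         train_hyper(epochs = 1), tiny_pp()),
               "2 distinct labels")
})

test_that("volume scoring is row-stochastic and ordered by slice index", {
  cases <- tiny_cases(2)
  m <- build_sip(quick_sip(), input_shape = c(18L, 26L), seed = 5)
  sm <- predict_volume(m, cases[[1]], tiny_pp())
  expect_identical(dim(sm), c(25L, 3L))
  expect_true(max(abs(rowSums(sm) - 1)) < 1e-6)
  expect_identical(attr(sm, "case_id"), cases[[1]]$case_id)
  # shuffling the stored slice list must not change the matrix (ordering
  # is by slice_index metadata, not storage order)
  shuffled <- cases[[1]]
  set.seed(8)
  shuffled$slices <- shuffled$slices[sample(25)]
  expect_identical(unclass(predict_volume(m, shuffled, tiny_pp())),
                   unclass(sm))
})

test_that("lesion-cut-only training is at least as good on lesion cuts as
           all-slice training", {
  sp <- tiny_sp()
  train <- generate_dataset(4, 5, 5, sp, seed = 31)
  val <- generate_dataset(3, 4, 4, sp, seed = 32)
  pool_lc <- select_sip_training_slices(train, lesion_cuts_only = TRUE)
  pool_all <- select_sip_training_slices(train, lesion_cuts_only = FALSE)
  a_off <- augment_params(enabled = FALSE)
  vpool <- select_sip_training_slices(val, lesion_cuts_only = TRUE)
  pre <- lapply(vpool$slices, function(s)
    downsample_slice(crop_slice(s, tiny_pp()), tiny_pp()))
  acc_on_lesion_cuts <- function(m) {
    pred <- vapply(pre, function(s)
      names(which.max(predict_slice(m, s))), character(1))
    mean(pred == vpool$labels)
  }
  accs <- sapply(7:8, function(sd) {
    hy <- train_hyper(epochs = 35, seed = sd, learning_rate = 3e-3)
    m0 <- build_sip(quick_sip(), input_shape = c(18L, 26L), seed = sd)
    c(lc = acc_on_lesion_cuts(train_sip(m0, pool_lc, hy, tiny_pp(), a_off)),
      all = acc_on_lesion_cuts(train_sip(m0, pool_all, hy, tiny_pp(),
                                         a_off)))
  })
  expect_gte(mean(accs["lc", ]), mean(accs["all", ]))
})
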