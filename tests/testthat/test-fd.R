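onehot_matrix <- function(label, slices = 25) {
  m <- matrix(0, slices, 3)
  m[, match(label, c("acute", "chronic", "normal"))] <- 1
  colnames(m) <- c("acute", "chronic", "normal")
  m
}

uniform_matrix <- function(slices = 25) {
  matrix(1 / 3, slices, 3,
         dimnames = list(NULL, c("acute", "chronic", "normal")))
}

test_that("featurize flattens row-major, invertibly, with validation", {
  u <- featurize(uniform_matrix())
  expect_length(u$values, 75)
  expect_true(all(abs(u$values - 1 / 3) < 1e-12))
  m <- uniform_matrix()
  m[7, ] <- c(1, 0, 0)
  f <- featurize(m)
  expect_identical(f$values[(7 - 1) * 3 + 1:3], c(1, 0, 0))
  expect_identical(matrix(f$values, ncol = 3, byrow = TRUE), unname(m))
  bad <- uniform_matrix(); bad[3, ] <- c(0.5, 0.2, 0.2)
  expect_error(featurize(bad), "row 3")
  expect_error(featurize(matrix(1, 25, 2)), "3 softmax")
})

test_that("every FD kind reaches 100% on oracle one-hot features", {
  labels <- rep(c("acute", "chronic", "normal"), each = 8)
  feats <- lapply(labels, function(l) featurize(onehot_matrix(l)))
  for (kind in c("logistic_regression", "svm", "gradient_boosting",
                 "random_forest")) {
    fd <- train_fd(feats, labels, fd_spec(kind = kind, seed = 5))
    pred <- vapply(feats, function(f) predict_case(fd, f)$label,
                   character(1))
    expect_identical(pred, labels)
    pr <- predict_case(fd, feats[[1]])
    expect_equal(sum(pr$probabilities), 1, tolerance = 1e-6)
  }
})

test_that("a centrally-localised signal is fully separable by the FD stage", {
  set.seed(42)
  labels <- rep(c("acute", "chronic", "normal"), each = 10)
  feats <- lapply(labels, function(l) {
    m <- uniform_matrix()
    if (l != "normal") m[8:17, ] <- onehot_matrix(l, 10)   # central slices
    else m[8:17, ] <- onehot_matrix("normal", 10)
    featurize(m)
  })
  fd <- train_fd(feats, labels, fd_spec(seed = 1))
  pred <- vapply(feats, function(f) predict_case(fd, f)$label, character(1))
  expect_identical(pred, labels)
})

test_that("FD training is deterministic given spec, seed and data", {
  set.seed(10)
  labels <- rep(c("acute", "chronic", "normal"), each = 6)
  feats <- lapply(labels, function(l) {
    m <- uniform_matrix() + matrix(runif(75, 0, 0.2), 25, 3)
    m <- m / rowSums(m)
    if (l != "normal") m[10:14, match(l, colnames(uniform_matrix()))] <-
        m[10:14, match(l, colnames(uniform_matrix()))] + 1
    m <- m / rowSums(m)
    featurize(m)
  })
  probe <- feats[c(2, 9, 16)]
  for (kind in c("logistic_regression", "gradient_boosting",
                 "random_forest")) {
    fd1 <- train_fd(feats, labels, fd_spec(kind = kind, seed = 9))
    fd2 <- train_fd(feats, labels, fd_spec(kind = kind, seed = 9))
    p1 <- lapply(probe, function(f) predict_case(fd1, f))
    p2 <- lapply(probe, function(f) predict_case(fd2, f))
    expect_identical(p1, p2)
  }
})

test_that("FD features export to a case-per-row CSV", {
  feats <- lapply(c("acute", "normal"), function(l) {
    f <- featurize(onehot_matrix(l)); f$case_id <- paste0("case_", l); f
  })
  path <- withr::local_tempfile(fileext = ".csv")
  df <- write_fd_features(feats, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_identical(dim(back), c(2L, 76L))
  expect_identical(back$case_id, c("case_acute", "case_normal"))
  expect_equal(unlist(back[1, -1], use.names = FALSE), feats[[1]]$values)
})

test_that("FD errors are labelled for degenerate inputs", {
  feats <- lapply(rep("acute", 4), function(l) featurize(onehot_matrix(l)))
  expect_error(train_fd(feats, rep("acute", 4), fd_spec()), "degenerate")
  expect_error(train_fd(feats, rep(c("acute", "weird"), 2), fd_spec()),
               "unknown label")
  labels <- rep(c("acute", "chronic"), 4)
  fd <- train_fd(lapply(labels, function(l) featurize(onehot_matrix(l))),
                 labels, fd_spec())
  expect_error(predict_case(fd, list(values = rep(0.5, 10))), "length")
})

test_that("the mean-softmax vote ignores position and underperforms the FD
           classifier on position-structured volumes", {
  # class signal lives in 6 central slices; the other 19 rows lean normal
  make_m <- function(label) {
    m <- matrix(rep(c(0.1, 0.1, 0.8), each = 25), 25, 3)
    colnames(m) <- c("acute", "chronic", "normal")
    if (label != "normal")
      m[10:15, ] <- matrix(rep(onehot_matrix(label, 1), 6), 6, 3,
                           byrow = TRUE)
    m
  }
  labels <- rep(c("acute", "chronic", "normal"), each = 8)
  mats <- lapply(labels, make_m)
  fd <- train_fd(lapply(mats, featurize), labels, fd_spec(seed = 2))
  fd_acc <- mean(vapply(seq_along(mats), function(i)
    predict_case(fd, featurize(mats[[i]]))$label, character(1)) == labels)
  vote_acc <- mean(vapply(mats, function(m) mean_softmax_vote(m)$label,
                          character(1)) == labels)
  expect_lte(vote_acc, fd_acc)
  expect_equal(fd_acc, 1)
  # deterministic tie-break: uniform evidence resolves to the first class
  expect_identical(mean_softmax_vote(uniform_matrix())$label, "acute")
})
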