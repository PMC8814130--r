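# Final-decision (FD) classifier: flattens a case's 25 x 3 softmax matrix
# (row-major by slice index) into a 75-vector and predicts the case label.
# Multinomial ridge logistic regression is the default; SVM, gradient
# boosting and random forest are available behind the same interface.

#' FD classifier specification
#'
#' @param kind one of `"logistic_regression"` (default), `"svm"`,
#'   `"gradient_boosting"`, `"random_forest"`.
#' @param regularization inverse penalty strength for logistic regression
#'   (ridge) and SVM cost; ignored by the tree ensembles.
#' @param seed integer seed for the stochastic fitters.
#' @return object of class `fd_spec`.
#' @export
fd_spec <- function(kind = c("logistic_regression", "svm",
                             "gradient_boosting", "random_forest"),
                    regularization = 1, seed = 1L) {
  kind <- match.arg(kind)
  if (regularization <= 0) stop("regularization must be > 0")
  structure(list(kind = kind, regularization = regularization,
                 seed = as.integer(seed)), class = "fd_spec")
}

#' Flatten a softmax matrix into an FD feature vector
#'
#' Row-major by slice index: values `3k+1 .. 3k+3` (1-based) are slice
#' `k`'s `(acute, chronic, normal)` probabilities. The flattening is
#' invertible: `matrix(values, ncol = 3, byrow = TRUE)` recovers the
#' matrix bit-exactly.
#'
#' @param m a `softmax_matrix` (n_slices x 3).
#' @return `fd_feature`: list with `values` (length `3 * n_slices`) and
#'   `case_id`.
#' @export
featurize <- function(m) {
  if (!is.matrix(m) || ncol(m) != 3)
    stop("expected an n_slices x 3 softmax matrix")
  bad <- which(abs(rowSums(m) - 1) > 1e-6)
  if (length(bad))
    stop("softmax matrix row ", bad[1], " does not sum to 1")
  structure(list(values = as.numeric(t(m)),
                 case_id = attr(m, "case_id") %||% NA_character_),
            class = "fd_feature")
}

fd_feature_matrix <- function(features) {
  lens <- vapply(features, function(f) length(f$values), integer(1))
  if (length(unique(lens)) > 1)
    stop("inconsistent feature lengths: ", paste(unique(lens), collapse = ","))
  do.call(rbind, lapply(features, `[[`, "values"))
}

#' Train the FD classifier
#'
#' @param features list of `fd_feature` (from [featurize()]).
#' @param labels character vector of case labels, same length.
#' @param spec an [fd_spec()].
#' @return object of class `fd_model` with the fitted classifier in `$fit`.
#' @export
train_fd <- function(features, labels, spec = fd_spec()) {
  X <- fd_feature_matrix(features)
  if (length(labels) != nrow(X))
    stop("labels and features differ in length")
  if (!all(labels %in% CSC_LABELS))
    stop("unknown label(s): ",
         paste(setdiff(labels, CSC_LABELS), collapse = ","))
  if (length(unique(labels)) < 2)
    stop("degenerate label set: at least 2 classes required")
  y <- droplevels(factor(labels, levels = CSC_LABELS))
  fit <- with_seed(spec$seed, switch(spec$kind,
    logistic_regression = {
      df <- as.data.frame(X)
      df$.y <- y
      nnet::multinom(.y ~ ., data = df, decay = 1 / spec$regularization,
                     maxit = 300, MaxNWts = 10000, trace = FALSE)
    },
    svm = e1071::svm(x = X, y = y, kernel = "linear",
                     cost = spec$regularization, probability = TRUE),
    gradient_boosting = xgboost::xgboost(
      X, y, nrounds = 50, max_depth = 3, learning_rate = 0.3,
      nthreads = 1, verbosity = 0),
    random_forest = randomForest::randomForest(x = X, y = y, ntree = 200)))
  structure(list(kind = spec$kind, spec = spec, fit = fit,
                 n_features = ncol(X), levels = CSC_LABELS,
                 fit_levels = levels(y)),
            class = "fd_model")
}

#' @export
print.fd_model <- function(x, ...) {
  cat(sprintf("<fd_model> kind=%s, %d features, classes: %s\n", x$kind,
              x$n_features, paste(x$levels, collapse = ", ")))
  invisible(x)
}

fd_predict_matrix <- function(fd, X) {
  P <- switch(fd$kind,
    logistic_regression = {
      pr <- stats::predict(fd$fit, newdata = as.data.frame(X),
                           type = "probs")
      if (is.null(dim(pr))) {
        if (length(fd$fit_levels) == 2)      # binary: P(second level)
          pr <- matrix(c(1 - pr, pr), ncol = 2,
                       dimnames = list(NULL, fd$fit_levels))
        else pr <- matrix(pr, nrow = 1, dimnames = list(NULL, names(pr)))
      }
      pr
    },
    svm = {
      pr <- stats::predict(fd$fit, X, probability = TRUE)
      attr(pr, "probabilities")
    },
    gradient_boosting = {
      pr <- stats::predict(fd$fit, X)
      if (is.null(dim(pr)))            # binary fit: P(second level)
        pr <- matrix(c(1 - pr, pr), ncol = 2,
                     dimnames = list(NULL, fd$fit_levels))
      pr
    },
    random_forest = stats::predict(fd$fit, X, type = "prob"))
  full <- matrix(0, nrow(X), length(fd$levels),
                 dimnames = list(NULL, fd$levels))
  full[, fd$fit_levels] <- P[, fd$fit_levels, drop = FALSE]
  full / rowSums(full)
}

#' Predict a case label from an FD feature
#'
#' @param fd a trained `fd_model`.
#' @param feature an `fd_feature`.
#' @return list with `label` (argmax; ties broken towards the lowest class
#'   index, acute < chronic < normal) and `probabilities` (named, sums
#'   to 1).
#' @export
predict_case <- function(fd, feature) {
  if (length(feature$values) != fd$n_features)
    stop("feature length ", length(feature$values),
         " does not match the trained model (", fd$n_features, ")")
  P <- fd_predict_matrix(fd, matrix(feature$values, 1))
  p <- drop(P)
  names(p) <- fd$levels
  list(label = fd$levels[max.col(P, ties.method = "first")],
       probabilities = p)
}

#' Export FD features for audit
#'
#' One row per case: `case_id` followed by the 75 slice-major softmax
#' values (`s<slice>_<class>` columns).
#'
#' @param features list of `fd_feature`.
#' @param path output CSV path.
#' @return the data.frame, invisibly.
#' @export
write_fd_features <- function(features, path) {
  X <- fd_feature_matrix(features)
  colnames(X) <- paste0("s", rep(seq_len(ncol(X) / 3), each = 3), "_",
                        rep(CSC_LABELS, ncol(X) / 3))
  df <- data.frame(case_id = vapply(features, `[[`, character(1),
                                    "case_id"),
                   X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Position-destroying mean-softmax-vote baseline
#'
#' Averages the 25 per-slice softmax vectors and takes the argmax; discards
#' all slice-position information, so it lower-bounds what a
#' position-aware FD classifier should achieve on position-structured
#' volumes.
#'
#' @param m a `softmax_matrix`.
#' @return list with `label` and `probabilities` (the column means).
#' @export
mean_softmax_vote <- function(m) {
  p <- colMeans(m)
  list(label = CSC_LABELS[which.max(p)], probabilities = p)
}
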