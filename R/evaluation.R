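# Patient-level stratified fivefold cross-validation with the 75/25 SIP/FD
# training sub-split, metric computation (confusion matrix, accuracy,
# per-class and macro sensitivity/specificity, Cohen's kappa), and the
# model-comparison harness.

derive_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 7919 +
                sum(utf8ToInt(tag)) * 104729) %% 2147483629) + 1L
}

#' Patient-level stratified fold assignment
#'
#' Cases are shuffled within each label and dealt round-robin to the `k`
#' folds, so per-fold label counts differ from the proportional share by at
#' most 1 and no patient appears in both a training and a test set. For
#' each fold the training cases are further sub-split 75/25 into SIP and FD
#' training sets (see [split_sip_fd()]).
#'
#' @param cases list of `oct_case`.
#' @param k number of folds (default 5; `k = 1` is the degenerate
#'   single-fold smoke configuration).
#' @param seed integer seed.
#' @param sip_fd_ratio fraction of each fold's training cases used to train
#'   the SIP model; the remainder trains the FD classifier.
#' @return `fold_plan`: list with `k`, `assignments` (named integer vector,
#'   case_id -> fold) and `folds`, a list of `(test, sip, fd)` case-id sets.
#' @export
make_folds <- function(cases, k = 5L, seed = 1L, sip_fd_ratio = 0.75) {
  labels <- case_labels(cases)
  ids <- case_ids(cases)
  if (anyDuplicated(ids)) stop("duplicate case ids")
  k <- as.integer(k)
  if (k > 1) {
    short <- names(which(table(labels) < k))
    if (length(short))
      stop("too few cases of label(s) ", paste(short, collapse = ","),
           " for ", k, " folds")
  }
  assignments <- integer(length(ids))
  names(assignments) <- ids
  with_seed(seed, {
    for (lb in unique(labels)) {
      li <- ids[labels == lb]
      li <- li[sample.int(length(li))]
      assignments[li] <- (seq_along(li) - 1L) %% k + 1L
    }
    folds <- lapply(seq_len(k), function(f) {
      test <- ids[assignments[ids] == f]
      train <- if (k == 1) ids else setdiff(ids, test)
      sp <- split_sip_fd(train, labels[match(train, ids)],
                         ratio = sip_fd_ratio,
                         seed = derive_seed(seed, paste0("sipfd", f)))
      list(test = test, sip = sp$sip, fd = sp$fd)
    })
    structure(list(k = k, assignments = assignments, folds = folds,
                   seed = seed), class = "fold_plan")
  })
}

#' Stratified 75/25 SIP/FD training split
#'
#' Splits the training cases, stratified by label, into the set used to
#' train the single-image prediction model and the disjoint set whose
#' softmax matrices train the final-decision classifier. Per-label SIP
#' shares are within one case of `ratio`; the global SIP count is exactly
#' `round(ratio * n)` (largest-remainder allocation).
#'
#' @param ids character case ids of the training set.
#' @param labels their labels, same order.
#' @param ratio SIP share (default 0.75).
#' @param seed integer seed.
#' @return list with character vectors `sip` and `fd` (disjoint, union =
#'   `ids`).
#' @export
split_sip_fd <- function(ids, labels, ratio = 0.75, seed = 1L) {
  if (length(ids) != length(labels)) stop("ids/labels length mismatch")
  tab <- table(labels)
  if (any(tab < 2))
    stop("degenerate label counts in training set: every label needs >= 2 ",
         "cases")
  with_seed(seed, {
    target <- round(ratio * length(ids))
    lbs <- names(tab)
    base <- floor(ratio * as.numeric(tab))
    frac <- ratio * as.numeric(tab) - base
    rem <- target - sum(base)
    if (rem > 0) {
      up <- order(frac, decreasing = TRUE)[seq_len(rem)]
      base[up] <- base[up] + 1
    } else if (rem < 0) {
      dn <- order(frac)[seq_len(-rem)]
      base[dn] <- base[dn] - 1
    }
    # both stages must see every label
    base <- pmin(pmax(base, 1), as.numeric(tab) - 1)
    sip <- character(0)
    for (i in seq_along(lbs)) {
      li <- ids[labels == lbs[i]]
      li <- li[sample.int(length(li))]
      sip <- c(sip, li[seq_len(base[i])])
    }
    list(sip = sip, fd = setdiff(ids, sip))
  })
}

#' Classification metrics for a 3-class evaluation
#'
#' Confusion matrix (rows = actual, columns = predicted), accuracy,
#' one-vs-rest sensitivity and specificity (per class and macro-averaged),
#' and Cohen's kappa `(p_o - p_e) / (1 - p_e)` with the expected agreement
#' `p_e` from the marginal products.
#'
#' @param actual,predicted equal-length character vectors over
#'   `acute`/`chronic`/`normal`.
#' @return object of class `metrics_report`.
#' @export
compute_metrics <- function(actual, predicted) {
  if (length(actual) == 0 || length(actual) != length(predicted))
    stop("actual and predicted must be equal-length, non-empty")
  bad <- setdiff(unique(c(actual, predicted)), CSC_LABELS)
  if (length(bad))
    stop("label outside the class set: ", paste(bad, collapse = ","))
  a <- factor(actual, levels = CSC_LABELS)
  p <- factor(predicted, levels = CSC_LABELS)
  cm <- table(actual = a, predicted = p)
  n <- sum(cm)
  acc <- sum(diag(cm)) / n
  sens <- diag(cm) / rowSums(cm)
  tn <- vapply(seq_len(3), function(i) sum(cm[-i, -i]), numeric(1))
  fp <- colSums(cm) - diag(cm)
  spec <- tn / (tn + fp)
  names(spec) <- CSC_LABELS
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (abs(1 - pe) < 1e-12) as.numeric(acc >= 1 - 1e-12)
           else (acc - pe) / (1 - pe)
  structure(list(confusion = cm, accuracy = acc,
                 sensitivity = sens,
                 specificity = spec,
                 macro_sensitivity = mean(sens, na.rm = TRUE),
                 macro_specificity = mean(spec, na.rm = TRUE),
                 kappa = kappa, n_cases = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report> n=%d  accuracy=%.3f  ",
                     "sensitivity=%.3f  specificity=%.3f  kappa=%.3f\n"),
              x$n_cases, x$accuracy, x$macro_sensitivity,
              x$macro_specificity, x$kappa))
  print(x$confusion)
  invisible(x)
}

#' Bundle the pipeline configuration
#'
#' Collects the specs every stage of the two-stage pipeline needs; passed
#' to [run_fold()], [cross_validate()] and [compare_models()].
#'
#' @param sip,fd,hyper,p,a component parameter objects.
#' @return a plain list with those five elements.
#' @export
csc_config <- function(sip = sip_spec(), fd = fd_spec(),
                       hyper = train_hyper(), p = preprocess_params(),
                       a = augment_params()) {
  list(sip = sip, fd = fd, hyper = hyper, p = p, a = a)
}

#' Train and evaluate one cross-validation fold
#'
#' Trains the SIP model on the fold's SIP cases (lesion cuts only), scores
#' the FD cases with it to train the FD classifier, then evaluates the
#' untouched test fold end-to-end (all 25 slices, lesion flags unused).
#' Leakage is asserted at runtime: test ids never intersect either training
#' stage.
#'
#' @param plan a `fold_plan` from [make_folds()].
#' @param fold fold index in `1..k`.
#' @param cases the full case list the plan was built from.
#' @param config list of specs from [csc_config()].
#' @param seed integer seed for the fold's training.
#' @return list with `metrics` (a `metrics_report`), `predictions`
#'   (data.frame of per-case labels and probabilities) and `model`.
#' @export
run_fold <- function(plan, fold, cases, config = csc_config(), seed = 1L) {
  fl <- plan$folds[[fold]]
  ids <- case_ids(cases)
  stopifnot(length(intersect(fl$test, c(fl$sip, fl$fd))) == 0)
  train_cases <- cases[match(c(fl$sip, fl$fd), ids)]
  model <- csc_fit(train_cases,
                   sip_ids = fl$sip, fd_ids = fl$fd,
                   sip = config$sip, fd = config$fd, hyper = config$hyper,
                   p = config$p, a = config$a,
                   seed = derive_seed(seed, paste0("fold", fold)))
  test_cases <- cases[match(fl$test, ids)]
  pred <- predict(model, test_cases)
  metrics <- compute_metrics(case_labels(test_cases), pred$label)
  list(metrics = metrics,
       predictions = cbind(pred, actual = case_labels(test_cases)),
       model = model, fold = fold)
}

#' Full k-fold cross-validation of the two-stage pipeline
#'
#' @inheritParams run_fold
#' @param cases list of `oct_case`.
#' @param k number of folds.
#' @return `cv_result`: per-fold metrics, pooled per-case predictions,
#'   pooled metrics over all test predictions, and the mean fold accuracy.
#' @export
cross_validate <- function(cases, k = 5L, config = csc_config(),
                           seed = 1L) {
  plan <- make_folds(cases, k = k, seed = derive_seed(seed, "folds"))
  fold_results <- lapply(seq_len(plan$k), function(f)
    run_fold(plan, f, cases, config, seed = seed))
  preds <- do.call(rbind, lapply(fold_results, `[[`, "predictions"))
  pooled <- compute_metrics(preds$actual, preds$label)
  structure(list(
    plan = plan,
    fold_metrics = lapply(fold_results, `[[`, "metrics"),
    fold_accuracy = vapply(fold_results, function(r) r$metrics$accuracy,
                           numeric(1)),
    predictions = preds, pooled = pooled,
    mean_accuracy = mean(vapply(fold_results,
                                function(r) r$metrics$accuracy,
                                numeric(1)))),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds, mean accuracy %.3f\n",
              length(x$fold_accuracy), x$mean_accuracy))
  cat("fold accuracies:", sprintf("%.3f", x$fold_accuracy), "\n")
  cat(sprintf("pooled: accuracy=%.3f sensitivity=%.3f specificity=%.3f ",
              x$pooled$accuracy, x$pooled$macro_sensitivity,
              x$pooled$macro_specificity))
  cat(sprintf("kappa=%.3f\n", x$pooled$kappa))
  invisible(x)
}

#' Model-comparison harness
#'
#' Evaluates several model configurations on one shared fold plan and
#' returns a table with one row per model, one column per fold, and an
#' `Average` column (unweighted mean over folds; fold sizes differ by at
#' most one case under the stratifier).
#'
#' @param cases list of `oct_case`.
#' @param models named list; each element is either
#'   `list(type = "proposed", config = csc_config())` or
#'   `list(type = "cnn3d"|"cnnlstm", spec = ..., hyper = ..., p = ..., a = ...)`.
#' @param k number of folds.
#' @param seed integer seed; the fold plan is shared across models.
#' @return data.frame (rows = models, columns = folds + `Average`).
#' @export
compare_models <- function(cases, models, k = 5L, seed = 1L) {
  plan <- make_folds(cases, k = k, seed = derive_seed(seed, "folds"))
  ids <- case_ids(cases)
  acc <- matrix(NA_real_, length(models), plan$k,
                dimnames = list(names(models),
                                paste0("fold", seq_len(plan$k))))
  for (f in seq_len(plan$k)) {
    fl <- plan$folds[[f]]
    train_all <- cases[match(c(fl$sip, fl$fd), ids)]
    test_cases <- cases[match(fl$test, ids)]
    actual <- case_labels(test_cases)
    for (mi in seq_along(models)) {
      m <- models[[mi]]
      mseed <- derive_seed(seed, paste0(names(models)[mi], f))
      pred <- if (identical(m$type, "proposed")) {
        r <- run_fold(plan, f, cases, m$config %||% csc_config(),
                      seed = seed)
        r$predictions$label
      } else {
        fit <- train_end_to_end(
          if (identical(m$type, "cnn3d")) build_3dcnn(m$spec, seed = mseed)
          else build_cnn_lstm(m$spec, seed = mseed),
          train_all, hyper = m$hyper, p = m$p %||% preprocess_params(),
          a = m$a %||% augment_params())
        vapply(test_cases, function(cs)
          predict(fit, cs, p = m$p %||% preprocess_params())$label,
          character(1))
      }
      acc[mi, f] <- mean(pred == actual)
    }
  }
  out <- as.data.frame(acc)
  out$Average <- rowMeans(acc)
  out
}
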