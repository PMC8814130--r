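# The two-stage pipeline as a classed model object: csc_fit() trains the
# SIP network on one stratified share of the training cases and the FD
# classifier on the softmax matrices of the remainder, mirroring the
# clinical training protocol; predict() scores whole volumes end-to-end.

#' Fit the two-stage CSC volume classifier
#'
#' Trains the full hierarchical system on a set of labelled cases:
#' the training cases are split (stratified, default 75/25) into a SIP set
#' and an FD set; the single-image prediction network is trained on the SIP
#' set's lesion cuts (plus all slices of its normal cases); each FD-set
#' case is then scored into a 25 x 3 softmax matrix by the trained SIP
#' model, and the final-decision classifier is fitted to those flattened
#' matrices. The two stages never share a patient.
#'
#' @param cases list of `oct_case` training cases.
#' @param sip_ids,fd_ids optional explicit case-id sets for the two stages
#'   (must be disjoint subsets of `cases`); when `NULL`, a stratified
#'   `sip_fd_ratio` split is drawn from `seed`.
#' @param sip a [sip_spec()].
#' @param fd an [fd_spec()].
#' @param hyper a [train_hyper()]; its seed is overridden by `seed` so one
#'   seed reproduces the whole fit.
#' @param p,a preprocessing and augmentation parameters.
#' @param sip_fd_ratio SIP share of the training cases.
#' @param seed integer master seed for the fit.
#' @return object of class `csc_model`.
#' @seealso [cross_validate()] for the fivefold evaluation protocol.
#' @export
csc_fit <- function(cases, sip_ids = NULL, fd_ids = NULL,
                    sip = sip_spec(), fd = fd_spec(),
                    hyper = train_hyper(), p = preprocess_params(),
                    a = augment_params(), sip_fd_ratio = 0.75,
                    seed = 1L) {
  ids <- case_ids(cases)
  labels <- case_labels(cases)
  if (is.null(sip_ids) || is.null(fd_ids)) {
    sp <- split_sip_fd(ids, labels, ratio = sip_fd_ratio,
                       seed = derive_seed(seed, "sipfd"))
    sip_ids <- sp$sip; fd_ids <- sp$fd
  }
  stopifnot(length(intersect(sip_ids, fd_ids)) == 0,
            all(c(sip_ids, fd_ids) %in% ids))
  sip_cases <- cases[match(sip_ids, ids)]
  fd_cases <- cases[match(fd_ids, ids)]

  model <- build_sip(sip, input_shape = c(p$target_height, p$target_width),
                     seed = derive_seed(seed, "sipinit"))
  pool <- select_sip_training_slices(sip_cases)
  hyper$seed <- derive_seed(seed, "siptrain")
  model <- train_sip(model, pool, hyper, p, a)

  feats <- lapply(fd_cases, function(cs) featurize(predict_volume(model, cs, p)))
  fd$seed <- derive_seed(seed, "fdtrain")
  fd_model <- train_fd(feats, case_labels(fd_cases), fd)

  structure(list(sip_model = model, fd_model = fd_model,
                 sip_ids = sip_ids, fd_ids = fd_ids,
                 p = p, a = a, seed = seed, levels = CSC_LABELS),
            class = "csc_model")
}

#' Predict case labels from fitted two-stage model
#'
#' @param object a `csc_model`.
#' @param newdata an `oct_case` or list of them.
#' @param ... unused.
#' @return data.frame with `case_id`, `label` and per-class probabilities.
#' @export
predict.csc_model <- function(object, newdata, ...) {
  if (inherits(newdata, "oct_case")) newdata <- list(newdata)
  rows <- lapply(newdata, function(cs) {
    f <- featurize(predict_volume(object$sip_model, cs, object$p))
    pr <- predict_case(object$fd_model, f)
    data.frame(case_id = cs$case_id, label = pr$label,
               p_acute = pr$probabilities["acute"],
               p_chronic = pr$probabilities["chronic"],
               p_normal = pr$probabilities["normal"],
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' @export
print.csc_model <- function(x, ...) {
  cat(sprintf(paste0("<csc_model> SIP(%s, %d trainable params) + FD(%s); ",
                     "trained on %d SIP / %d FD cases\n"),
              x$sip_model$spec$backbone,
              sip_n_params(x$sip_model, trainable_only = TRUE),
              x$fd_model$kind, length(x$sip_ids), length(x$fd_ids)))
  invisible(x)
}

#' @export
summary.csc_model <- function(object, ...) {
  print(object)
  lg <- object$sip_model$log
  if (!is.null(lg) && nrow(lg))
    cat(sprintf("SIP training: %d epochs, final loss %.4f, final slice ",
                nrow(lg), lg$loss[nrow(lg)]),
        sprintf("accuracy %.3f\n", lg$accuracy[nrow(lg)]))
  invisible(object)
}

#' FD-stage coefficients of the fitted pipeline
#'
#' For the logistic-regression FD classifier, returns the multinomial
#' coefficient matrix (one row per non-reference class, columns = intercept
#' plus the 75 slice-major softmax features); otherwise the underlying fit
#' object.
#'
#' @param object a `csc_model`.
#' @param ... unused.
#' @export
coef.csc_model <- function(object, ...) {
  fdm <- object$fd_model
  if (fdm$kind == "logistic_regression") stats::coef(fdm$fit)
  else fdm$fit
}
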