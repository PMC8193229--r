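## Classification and evaluation: ROC/AUC, metrics with bootstrap CI, SVM
## wrapper, leave-one-out cross-validation with in-fold feature selection,
## and the stratified 7:3 split protocol.

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, with ties counting one half; equals the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric per-case scores (higher = more positive).
#' @param labels Binary labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- code_labels(labels) > 0
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L) stop_("both classes must be present")
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Classification metrics with bootstrap AUC confidence interval
#'
#' Accuracy, sensitivity and specificity from the predicted labels (the
#' positive class is the second label level: AVM, or high grade), AUC from
#' the scores, and a stratified percentile-bootstrap 95% CI for the AUC
#' (positives and negatives resampled separately).
#'
#' @param predicted Predicted binary labels.
#' @param scores Numeric scores used for the AUC.
#' @param labels True binary labels.
#' @param n_boot Bootstrap resamples (default 2,000).
#' @param seed Seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return Object of class `classification_metrics`: list with `acc`,
#'   `sens`, `spec`, `auc`, `auc_ci`, `n_pos`, `n_neg`.
#' @export
classification_metrics <- function(predicted, scores, labels,
                                   n_boot = 2000L, seed = 1L, conf = 0.95) {
  y <- code_labels(labels) > 0
  pred <- code_labels_as(predicted, labels) > 0
  tp <- sum(pred & y); fn <- sum(!pred & y)
  tn <- sum(!pred & !y); fp <- sum(pred & !y)
  auc <- roc_auc(scores, y)
  pos <- which(y); neg <- which(!y)
  boot <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    i <- c(sample(pos, length(pos), replace = TRUE),
           sample(neg, length(neg), replace = TRUE))
    roc_auc(scores[i], y[i])
  }, numeric(1)))
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))
  structure(list(acc = (tp + tn) / length(y), sens = tp / (tp + fn),
                 spec = tn / (tn + fp), auc = auc, auc_ci = ci,
                 n_pos = length(pos), n_neg = length(neg)),
            class = "classification_metrics")
}

## Coerce `predicted` onto the coding of `labels`: accepts the same label
## alphabet or plain logical/0-1.
code_labels_as <- function(predicted, labels) {
  if (is.logical(predicted) || all(predicted %in% c(0, 1, -1))) {
    return(code_labels_logical(predicted))
  }
  u <- sort(unique(if (is.factor(labels)) as.character(labels) else labels))
  ifelse(predicted == u[2], 1, -1)
}

code_labels_logical <- function(x) {
  if (is.logical(x)) return(ifelse(x, 1, -1))
  ifelse(x > 0, 1, -1)
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f)  ACC %.3f  SENS %.3f  SPEC %.3f  (n+ = %d, n- = %d)\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$acc, x$sens, x$spec,
              x$n_pos, x$n_neg))
  invisible(x)
}

## ---- SVM wrapper -------------------------------------------------------

## Fit a (linear by default) SVM on y in {-1, +1}. `cost` may be a single
## value or a grid resolved by stratified 5-fold inner CV accuracy (ties:
## smaller cost). Features are standardized with training statistics.
## Classes are weighted inversely to their training frequency and held-out
## scores are centered at the midpoint between the training class means of
## the decision value: both counter the class-prior shift that leave-one-out
## resampling induces (holding out a case leaves the training set
## imbalanced, which otherwise biases pooled cross-validated scores).
fit_svm <- function(x, y, cost = 1, kernel = "linear", seed = 1L) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- scale(x, mu, sdv)
  yf <- factor(y, levels = c(-1, 1))
  tab <- table(yf)
  cw <- stats::setNames(as.numeric(sum(tab) / (2 * tab)), names(tab))
  if (length(cost) > 1L) {
    nfolds <- min(5L, min(tab))
    if (nfolds >= 2L) {
      folds <- with_seed(seed, stratified_folds(y, nfolds))
      acc <- vapply(cost, function(cc) {
        ok <- 0L
        for (f in seq_len(nfolds)) {
          tr <- folds != f
          m <- e1071::svm(xs[tr, , drop = FALSE], yf[tr], kernel = kernel,
                          cost = cc, scale = FALSE, class.weights = cw)
          ok <- ok + sum(predict(m, xs[!tr, , drop = FALSE]) == yf[!tr])
        }
        ok / length(y)
      }, numeric(1))
      cost <- cost[which.max(acc)]
    } else {
      cost <- cost[1]
    }
  }
  fit <- e1071::svm(xs, yf, kernel = kernel, cost = cost, scale = FALSE,
                    class.weights = cw)
  pr <- predict(fit, xs, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  ## libsvm reports the decision value of the "lev1/lev2" comparison with
  ## positive values favoring lev1; orient so that higher = class +1
  flip <- if (colnames(dv)[1] == "-1/1") -1 else 1
  dvo <- flip * dv[, 1]
  mid <- (mean(dvo[y > 0]) + mean(dvo[y < 0])) / 2
  list(fit = fit, mu = mu, sd = sdv, flip = flip, mid = mid, cost = cost)
}

## Oriented, midpoint-centered decision-value scores of new cases.
predict_svm <- function(model, x) {
  xs <- scale(as.matrix(x), model$mu, model$sd)
  p <- predict(model$fit, xs, decision.values = TRUE)
  model$flip * attr(p, "decision.values")[, 1] - model$mid
}

## ---- evaluation protocols ----------------------------------------------

#' Pipeline configuration
#'
#' Bundles the tunable parameters of the selection + classification stack.
#'
#' @param tau Detector confidence threshold for structure presence.
#' @param isr_iterations,isr_rho,isr_lambda ISR parameters (see
#'   [isr_scores()]).
#' @param n_selected Number of features kept after ISR ranking (selection
#'   is skipped when the feature set is already no larger).
#' @param svm_cost Cost grid (resolved by inner CV) or a single value.
#' @param svm_kernel `"linear"` (default) or any e1071 kernel.
#' @param n_boot Bootstrap resamples for AUC CIs.
#' @param test_fraction Held-out fraction of the stratified split.
#' @param select_once If `TRUE`, run ISR selection once on the full table
#'   before the LOO loop instead of inside each fold. This leaks the
#'   held-out label into selection and is provided only to mirror the
#'   ambiguous variant of the protocol; the default (`FALSE`) is
#'   leakage-free.
#' @param seed Integer seed.
#' @return A list of class `dsa_config`.
#' @export
dsa_config <- function(tau = 0.5, isr_iterations = 50L, isr_rho = 0.8,
                       isr_lambda = "auto", n_selected = 20L,
                       svm_cost = c(0.01, 0.1, 1, 10),
                       svm_kernel = "linear", n_boot = 2000L,
                       test_fraction = 0.3, select_once = FALSE,
                       seed = 1L) {
  structure(as.list(environment()), class = "dsa_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Fields mirror the arguments of [dsa_config()]; unknown fields are
#' rejected.
#'
#' @param path YAML file path.
#' @return A [dsa_config()] list.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop_("the yaml package is required to read configuration files")
  }
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(dsa_config)))
  if (length(unknown)) {
    stop_("unknown configuration field(s): %s",
          paste(unknown, collapse = ", "))
  }
  do.call(dsa_config, vals)
}

## In-fold model: ISR ranking + top-m selection + SVM.
fit_fold <- function(x, y, config, seed) {
  p <- ncol(x)
  sel <- seq_len(p)
  if (p > config$n_selected && p >= 2L) {
    isr <- isr_scores(x, y, K = config$isr_iterations, rho = config$isr_rho,
                      lambda = config$isr_lambda, seed = seed)
    sel <- suppressWarnings(select_features(isr, config$n_selected))
  }
  model <- fit_svm(x[, sel, drop = FALSE], y, cost = config$svm_cost,
                   kernel = config$svm_kernel, seed = seed)
  list(model = model, selected = sel)
}

#' Leave-one-out cross-validation with in-fold selection
#'
#' For each case, ISR feature selection and the SVM are fit on the
#' remaining n - 1 cases only (no leakage of the held-out case into
#' standardization, selection, or hyperparameters; set
#' `config$select_once` to reproduce the leaky variant), and the held-out
#' case is scored with the oriented SVM decision value. Metrics are
#' computed over the n held-out scores.
#'
#' @param features Numeric matrix (cases x features).
#' @param labels Binary labels (positive class = second level).
#' @param config A [dsa_config()].
#' @return List with `metrics` ([classification_metrics()]), `scores`,
#'   `predicted` (0/1 at the decision boundary), `selected` (selection of
#'   the final full-data refit when `select_once`, else of the last fold).
#' @export
loo_cv <- function(features, labels, config = dsa_config()) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (n < 4L) stop_("leave-one-out needs at least 4 cases")
  y <- code_labels(labels)
  if (min(table(y)) < 2L) stop_("each class needs at least 2 cases")
  sel_once <- NULL
  if (isTRUE(config$select_once) && ncol(x) > config$n_selected) {
    isr <- isr_scores(x, y, K = config$isr_iterations, rho = config$isr_rho,
                      lambda = config$isr_lambda, seed = config$seed)
    sel_once <- suppressWarnings(select_features(isr, config$n_selected))
  }
  scores <- numeric(n)
  selected <- NULL
  for (i in seq_len(n)) {
    xt <- x[-i, , drop = FALSE]
    yt <- y[-i]
    if (!is.null(sel_once)) {
      model <- fit_svm(xt[, sel_once, drop = FALSE], yt,
                       cost = config$svm_cost, kernel = config$svm_kernel,
                       seed = config$seed + i)
      scores[i] <- predict_svm(model, x[i, sel_once, drop = FALSE])
      selected <- sel_once
    } else {
      fold <- fit_fold(xt, yt, config, seed = config$seed + i)
      scores[i] <- predict_svm(fold$model, x[i, fold$selected, drop = FALSE])
      selected <- fold$selected
    }
  }
  predicted <- as.integer(scores > 0)
  metrics <- classification_metrics(predicted, scores, y > 0,
                                    n_boot = config$n_boot,
                                    seed = config$seed)
  list(metrics = metrics, scores = scores, predicted = predicted,
       selected = selected)
}

#' Stratified split evaluation (7:3 protocol)
#'
#' Cases are split into a cross-validation cohort and an independent test
#' cohort by a stratified random split (`test_fraction`, default 0.3,
#' per-class counts rounded half up). The model is evaluated on the
#' cross-validation cohort by [loo_cv()], refit once on the whole
#' cross-validation cohort, and scored once on the untouched test cohort.
#'
#' @inheritParams loo_cv
#' @param test_fraction Fraction held out (overrides `config`).
#' @return List with `cv` and `test` metric sets, `selected` feature
#'   indices of the final refit, and the `split` index vector.
#' @export
split_evaluate <- function(features, labels,
                           test_fraction = NULL, config = dsa_config()) {
  x <- as.matrix(features)
  y <- code_labels(labels)
  frac <- test_fraction %||% config$test_fraction
  if (frac <= 0 || frac >= 1) stop_("test_fraction must be in (0, 1)")
  pos <- which(y > 0); neg <- which(y < 0)
  test_idx <- with_seed(config$seed, c(
    sample(pos, round_half_up(length(pos) * frac)),
    sample(neg, round_half_up(length(neg) * frac))))
  train_idx <- setdiff(seq_along(y), test_idx)
  if (min(table(y[test_idx])) < 2L || min(table(y[train_idx])) < 2L) {
    stop_("split leaves fewer than 2 cases of a class in a partition")
  }
  cv <- loo_cv(x[train_idx, , drop = FALSE], y[train_idx], config)
  final <- fit_fold(x[train_idx, , drop = FALSE], y[train_idx], config,
                    seed = config$seed)
  test_scores <- predict_svm(final$model,
                             x[test_idx, final$selected, drop = FALSE])
  test_metrics <- classification_metrics(as.integer(test_scores > 0),
                                         test_scores, y[test_idx] > 0,
                                         n_boot = config$n_boot,
                                         seed = config$seed)
  list(cv = cv$metrics, cv_scores = cv$scores, test = test_metrics,
       test_scores = test_scores, selected = final$selected,
       test_idx = test_idx, train_idx = train_idx)
}
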