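## Iterative sparse representation (ISR) feature scoring: repeated
## L1-penalized least-squares fits of the class label on class-stratified
## subsamples, with the absolute coefficients averaged into importance
## scores.

#' ISR feature importance scores
#'
#' Features are standardized to zero mean / unit variance on the full
#' table (zero-variance features are dropped with score 0) and labels are
#' coded -1/+1. For each of `K` iterations a class-stratified subsample of
#' fraction `rho` is drawn without replacement and the lasso
#' `argmin (1/2n)||y - Xw||^2 + lambda ||w||_1` is solved by coordinate
#' descent (glmnet). The importance score of feature j is `mean_k |w_kj|`
#' and its selection frequency the fraction of iterations with a nonzero
#' coefficient. `lambda = "auto"` picks lambda once by 5-fold
#' cross-validated prediction error on the full table, then holds it fixed
#' across iterations.
#'
#' @param features Numeric matrix or data frame (cases x features).
#' @param labels Binary labels (logical, 0/1, -1/+1, or a 2-level factor);
#'   both classes need at least 2 cases.
#' @param K Number of iterations (default 100).
#' @param rho Subsample fraction in (0, 1] (default 0.8).
#' @param lambda Penalty: a number or `"auto"`.
#' @param seed Integer seed; results are deterministic given the seed.
#' @return Object of class `isr_result`: list with `score`, `frequency`
#'   (named per-feature vectors), `ranking` (feature indices by
#'   nonincreasing score, ties by lower index; zero-variance features
#'   rank last among zeros by index), and `config`.
#' @export
isr_scores <- function(features, labels, K = 100L, rho = 0.8,
                       lambda = "auto", seed = 1L) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  y <- code_labels(labels)
  if (nrow(x) != length(y)) stop_("features and labels disagree in length")
  if (min(table(y)) < 2L) stop_("each class needs at least 2 cases")
  if (anyNA(x)) stop_("features contain missing values")
  if (rho <= 0 || rho > 1) stop_("rho must be in (0, 1]")
  p <- ncol(x)
  sds <- apply(x, 2, stats::sd)
  keep <- which(sds > 0)
  if (length(keep) < 2L) {
    stop_("at least two non-constant features are required")
  }
  xs <- scale(x[, keep, drop = FALSE])
  pos <- which(y > 0); neg <- which(y < 0)
  n_pos <- max(1L, round_half_up(rho * length(pos)))
  n_neg <- max(1L, round_half_up(rho * length(neg)))
  if (rho < 1 && (n_pos >= length(pos) + 1L || n_neg >= length(neg) + 1L ||
                  n_pos < 2L || n_neg < 2L)) {
    stop_("rho leaves fewer than 2 cases in a class")
  }
  res <- with_seed(seed, {
    lam <- if (identical(lambda, "auto")) {
      cv <- glmnet::cv.glmnet(xs, y, family = "gaussian", nfolds = 5,
                              standardize = FALSE)
      cv$lambda.min
    } else as.numeric(lambda)
    path <- sort(unique(c(lam * c(8, 4, 2), lam)), decreasing = TRUE)
    absw <- matrix(0, K, length(keep))
    nz <- matrix(FALSE, K, length(keep))
    for (k in seq_len(K)) {
      idx <- if (rho < 1) c(sample(pos, n_pos), sample(neg, n_neg))
             else seq_along(y)
      w <- lasso_coef(xs[idx, , drop = FALSE], y[idx], path, lam)
      absw[k, ] <- abs(w)
      nz[k, ] <- w != 0
    }
    list(lam = lam, score = colMeans(absw), freq = colMeans(nz))
  })
  score <- stats::setNames(numeric(p), colnames(x))
  freq <- score
  score[keep] <- res$score
  freq[keep] <- res$freq
  ranking <- order(-score, seq_len(p))
  structure(list(score = score, frequency = freq, ranking = ranking,
                 config = list(K = K, rho = rho, lambda = res$lam,
                               seed = seed, n_dropped = p - length(keep))),
            class = "isr_result")
}

## One lasso fit along a short path, returning the coefficients at `lam`.
## Near-degenerate subsamples (heavily collinear columns) can stall the
## coordinate descent on the warm-start path; fall back to a direct
## single-lambda fit, and to a zero vector if that fails too (the
## iteration then simply contributes no selections).
lasso_coef <- function(x, y, path, lam) {
  extract <- function(fit) {
    if (is.null(fit)) return(NULL)
    tryCatch(as.numeric(stats::coef(fit, s = lam))[-1],
             error = function(e) NULL)
  }
  fit <- tryCatch(
    suppressWarnings(glmnet::glmnet(x, y, family = "gaussian",
                                    lambda = path, standardize = FALSE,
                                    thresh = 1e-9, maxit = 1e6)),
    error = function(e) NULL)
  w <- extract(fit)
  if (is.null(w)) {
    fit <- tryCatch(
      suppressWarnings(glmnet::glmnet(x, y, family = "gaussian",
                                      lambda = lam, standardize = FALSE,
                                      maxit = 1e6)),
      error = function(e) NULL)
    w <- extract(fit)
  }
  if (is.null(w)) numeric(ncol(x)) else w
}

code_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.logical(labels)) labels <- as.integer(labels)
  u <- sort(unique(labels))
  if (length(u) != 2L) stop_("labels must contain exactly two classes")
  ifelse(labels == u[2], 1, -1)
}

#' @export
print.isr_result <- function(x, n = 10L, ...) {
  cat(sprintf("ISR feature ranking (K = %d, rho = %.2f, lambda = %.4g; %d features, %d constant dropped)\n",
              x$config$K, x$config$rho, x$config$lambda, length(x$score),
              x$config$n_dropped))
  top <- utils::head(x$ranking, n)
  nm <- names(x$score) %||% as.character(seq_along(x$score))
  for (j in top) {
    cat(sprintf("  %-28s score %.4f  freq %.2f\n", nm[j], x$score[j],
                x$frequency[j]))
  }
  invisible(x)
}

#' Select the top-ranked features
#'
#' Takes the `m` features with the largest ISR scores (ties broken by
#' lower index). With `m = "cv"`, `m` is chosen from the grid
#' {5, 10, 20, 30, 50} by 5-fold cross-validated AUC of a linear SVM on
#' the supplied table. If every score is zero the first `m` features by
#' index are returned with a warning.
#'
#' @param result An [isr_scores()] result.
#' @param m Number of features to keep, or `"cv"`.
#' @param features,labels Required when `m = "cv"`.
#' @param seed Seed for the cross-validation folds.
#' @return Integer vector of selected feature indices.
#' @export
select_features <- function(result, m, features = NULL, labels = NULL,
                            seed = 1L) {
  stopifnot(inherits(result, "isr_result"))
  p <- length(result$score)
  if (identical(m, "cv")) {
    if (is.null(features) || is.null(labels)) {
      stop_("m = \"cv\" needs features and labels")
    }
    grid <- c(5L, 10L, 20L, 30L, 50L)
    grid <- grid[grid <= p]
    auc <- vapply(grid, function(mm) {
      idx <- utils::head(result$ranking, mm)
      cv_auc(as.matrix(features)[, idx, drop = FALSE], labels, seed = seed)
    }, numeric(1))
    m <- grid[which.max(auc)]
  }
  if (!is_count(m) || m <= 0) stop_("m must be a positive integer")
  if (m > p) stop_("m exceeds the number of scored features")
  if (all(result$score == 0)) {
    warning("all ISR scores are zero; returning the first m features by index")
    return(seq_len(m))
  }
  utils::head(result$ranking, m)
}

## 5-fold stratified CV AUC of a linear SVM; helper for m = "cv".
cv_auc <- function(x, labels, seed = 1L, nfolds = 5L) {
  y <- code_labels(labels)
  folds <- with_seed(seed, stratified_folds(y, nfolds))
  scores <- numeric(length(y))
  for (f in seq_len(max(folds))) {
    tr <- folds != f
    fit <- fit_svm(x[tr, , drop = FALSE], y[tr], cost = 1)
    scores[!tr] <- predict_svm(fit, x[!tr, , drop = FALSE])
  }
  roc_auc(scores, y > 0)
}

stratified_folds <- function(y, nfolds) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  folds
}
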