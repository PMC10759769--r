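#' Stratified calibration/test split
#'
#' Randomly assigns two-thirds of each class to calibration and one-third
#' to test (test share rounded up per class), reproducibly from the seed.
#'
#' @param labels Class labels, one per sample (any type; used for
#'   stratification).
#' @param seed Integer seed.
#' @param test_fraction Held-out share per class (default 1/3).
#' @return List with integer index vectors `calibration` and `test`.
#' @export
split_dataset <- function(labels, seed, test_fraction = 1 / 3) {
  labels <- as.factor(labels)
  counts <- table(labels)
  if (any(counts < 3)) {
    stop("every class needs >= 3 samples; smallest has ", min(counts))
  }
  test_idx <- .with_seed(seed, {
    unlist(lapply(levels(labels), function(lv) {
      idx <- which(labels == lv)
      n_test <- ceiling(length(idx) * test_fraction)
      sample(idx, n_test)
    }))
  })
  test_idx <- sort(test_idx)
  list(calibration = setdiff(seq_along(labels), test_idx), test = test_idx)
}

#' Fuse image and e-nose feature vectors
#'
#' Feature-level fusion: concatenation of the 46 visual features followed
#' by the 13 MSR features, a fixed 59-element vector.
#'
#' @param img Numeric vector of length 46.
#' @param enose Numeric vector of length 13.
#' @return Named numeric vector of length 59.
#' @export
fuse_features <- function(img, enose) {
  if (length(img) != 46L) stop("image block must have length 46, got ", length(img))
  if (length(enose) != 13L) stop("e-nose block must have length 13, got ", length(enose))
  c(img, enose)
}

#' Fit a standardised PCA on calibration features
#'
#' Features are z-scored with calibration means and standard deviations
#' (so the decomposition is correlation-based: image and e-nose features
#' live on wildly different scales) and the principal axes come from the
#' singular value decomposition of the standardised matrix. Constant
#' features are dropped with a warning. The stored statistics are reused
#' verbatim when transforming new data — no test-set leakage.
#'
#' @param x Calibration feature matrix (samples x features).
#' @param n_components Number of retained components (default 4).
#' @return A `kiwi_pca` object with `center`, `scale`, `rotation`,
#'   `explained_variance` (fractions, all components) and `n_components`.
#' @export
fit_pca <- function(x, n_components = 4) {
  x <- as.matrix(x)
  if (nrow(x) < n_components + 1) {
    stop("need at least n_components + 1 calibration samples")
  }
  sds <- apply(x, 2, sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " constant feature(s): ",
            paste(head(colnames(x)[!keep], 5), collapse = ", "))
    x <- x[, keep, drop = FALSE]
    sds <- sds[keep]
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  structure(list(center = pc$center, scale = pc$scale,
                 rotation = pc$rotation,
                 explained_variance = pc$sdev^2 / sum(pc$sdev^2),
                 kept_features = colnames(x),
                 n_components = as.integer(n_components)),
            class = "kiwi_pca")
}

#' Project feature vectors onto the retained principal components
#'
#' @param object A `kiwi_pca`.
#' @param newdata Feature matrix or single vector on the original scale.
#' @param ... Unused.
#' @return Score matrix (samples x n_components).
#' @export
predict.kiwi_pca <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) && all(object$kept_features %in% colnames(newdata))) {
    newdata <- newdata[, object$kept_features, drop = FALSE]
  }
  z <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  k <- min(object$n_components, ncol(object$rotation))
  z %*% object$rotation[, seq_len(k), drop = FALSE]
}

#' Classification accuracy and RMSE
#'
#' Accuracy is `100 * correct / total`. RMSE is computed on the integer
#' class codes (Talesh = 1, Langarud = 2, Rasht = 3 for region labels;
#' factor codes otherwise), the convention used to make the grid-search
#' criterion uniform across classification and regression.
#'
#' @param truth,predicted Label vectors of equal length.
#' @return List with `accuracy` (percent) and `rmse`.
#' @export
evaluate_classifier <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stop("length mismatch")
  codes <- function(x) {
    x <- as.character(x)
    if (all(x %in% region_labels())) region_codes(x)
    else as.integer(factor(x, levels = sort(unique(c(as.character(truth),
                                                     as.character(predicted)))))) }
  ct <- codes(truth); cp <- codes(predicted)
  list(accuracy = 100 * mean(ct == cp), rmse = sqrt(mean((ct - cp)^2)))
}

#' Regression RMSE and coefficient of determination
#'
#' RMSE is the root mean squared residual; R-squared is
#' `100 * (1 - SSres / SStot)` (percent), which can go negative for models
#' worse than the mean.
#'
#' @param truth,predictions Numeric vectors of equal length (>= 2 points,
#'   non-constant truth).
#' @return List with `rmse` and `r_squared` (percent).
#' @export
evaluate_regressor <- function(truth, predictions) {
  if (length(truth) != length(predictions)) stop("length mismatch")
  if (length(truth) < 2) stop("need at least 2 points")
  sstot <- sum((truth - mean(truth))^2)
  if (sstot == 0) stop("constant truth: R-squared undefined")
  ssres <- sum((truth - predictions)^2)
  list(rmse = sqrt(mean((truth - predictions)^2)),
       r_squared = 100 * (1 - ssres / sstot))
}

#' The default hyperparameter grid
#'
#' Degree-2 polynomial kernel with cost and gamma each in
#' {0.01, 0.1, 1, 10, 100}: 25 candidate pairs, walked in row-major order
#' (cost outer, gamma inner).
#'
#' @return Data frame with columns `cost` and `gamma` (25 rows).
#' @export
svm_grid <- function() {
  vals <- c(0.01, 0.1, 1, 10, 100)
  expand.grid(gamma = vals, cost = vals)[, c("cost", "gamma")]
}

# Stratified (classification) or plain (regression) fold assignment.
.make_folds <- function(y, folds, seed, stratify) {
  n <- length(y)
  .with_seed(seed, {
    fold <- integer(n)
    if (stratify) {
      for (lv in levels(as.factor(y))) {
        idx <- sample(which(y == lv))
        fold[idx] <- rep_len(seq_len(folds), length(idx))
      }
    } else {
      fold[sample(n)] <- rep_len(seq_len(folds), n)
    }
    fold
  })
}

# One SVM/SVR fit. e1071 standardises the predictors (and, for
# regression, the target) internally and back-transforms predictions;
# this conditions the polynomial kernel across the wide (cost, gamma)
# grid. Extreme pairs that drive the SMO solver into its internal
# iteration cap return a poor fit (and print a solver notice); such
# candidates are never selected because their CV RMSE is large.
.fit_svm <- function(x, y, cost, gamma, degree, type) {
  e1071::svm(x = x, y = y, type = type, kernel = "polynomial",
             degree = degree, gamma = gamma, coef0 = 1, cost = cost,
             scale = TRUE)
}

# Shared grid-search engine. `y` is a factor (classification) or numeric
# (regression). Selection criterion: smallest cross-validation RMSE, ties
# broken by the first pair in row-major grid order.
.grid_search <- function(x, y, grid, folds, seed, degree, classification,
                         test_x = NULL, test_y = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < folds) stop("need at least `folds` samples, got ", n)
  if (classification) {
    y <- factor(y)
    if (nlevels(droplevels(y)) < 2) stop("need at least 2 classes")
    to_code <- function(v) as.integer(factor(as.character(v), levels = levels(y)))
  } else {
    if (sd(y) == 0) stop("constant target")
    if (any(!is.finite(y))) stop("target must be finite")
    to_code <- identity
  }
  fold <- .make_folds(y, folds, seed, stratify = classification)
  type <- if (classification) "C-classification" else "eps-regression"

  # Every grid pair is evaluated by 10-fold CV, with exact early
  # abandoning: the pooled squared error accumulated over the folds run so
  # far, divided by the full n, lower-bounds the pair's final CV RMSE
  # (remaining folds can only add error). Once that bound strictly
  # exceeds the best completed pair's RMSE the pair provably cannot be
  # selected (nor tie an earlier pair), so its remaining folds are
  # skipped. The selected pair is identical to full evaluation,
  # including the first-in-row-major-order tie-break.
  candidates <- grid
  candidates$cv_rmse <- NA_real_
  candidates$completed <- TRUE
  y_codes <- to_code(y)
  best <- 0L
  best_rmse <- Inf
  cv_pred <- NULL
  for (i in seq_len(nrow(grid))) {
    pred <- if (classification) character(n) else numeric(n)
    sse <- 0
    completed <- TRUE
    for (f in sort(unique(fold))) {
      tr <- fold != f
      fit <- .fit_svm(x[tr, , drop = FALSE], y[tr], grid$cost[i], grid$gamma[i],
                      degree, type)
      p <- predict(fit, x[!tr, , drop = FALSE])
      pred[!tr] <- if (classification) as.character(p) else as.numeric(p)
      sse <- sse + sum((to_code(pred[!tr]) - y_codes[!tr])^2)
      if (sqrt(sse / n) > best_rmse) { completed <- FALSE; break }
    }
    candidates$cv_rmse[i] <- sqrt(sse / n)  # lower bound if abandoned
    candidates$completed[i] <- completed
    if (completed && candidates$cv_rmse[i] < best_rmse) {
      best <- i
      best_rmse <- candidates$cv_rmse[i]
      cv_pred <- pred
    }
  }
  cost <- grid$cost[best]; gamma <- grid$gamma[best]
  final <- .fit_svm(x, y, cost, gamma, degree, type)
  cal_pred <- predict(final, x)

  report_row <- function(stage, truth, pred) {
    if (classification) {
      ev <- evaluate_classifier(as.character(truth), as.character(pred))
      data.frame(stage = stage, rmse = sqrt(mean((to_code(pred) - to_code(truth))^2)),
                 accuracy = ev$accuracy, r_squared = NA_real_,
                 cost = cost, gamma = gamma)
    } else {
      ev <- evaluate_regressor(truth, as.numeric(pred))
      data.frame(stage = stage, rmse = ev$rmse, accuracy = NA_real_,
                 r_squared = ev$r_squared, cost = cost, gamma = gamma)
    }
  }
  reports <- rbind(report_row("calibration", y, cal_pred),
                   report_row("validation", y, cv_pred))
  if (!is.null(test_x)) {
    test_pred <- predict(final, as.matrix(test_x))
    reports <- rbind(reports, report_row("test", test_y, test_pred))
  }
  structure(list(model = final, best = list(cost = cost, gamma = gamma),
                 reports = reports, candidates = candidates,
                 classification = classification),
            class = "kiwi_svm_fit")
}

#' Grid-searched polynomial SVM classifier
#'
#' Evaluates all 25 (cost, gamma) pairs of [svm_grid()] by stratified
#' ten-fold cross-validation on the calibration scores, scoring each pair
#' by the RMSE of the integer class codes of its pooled out-of-fold
#' predictions. The pair with the smallest CV RMSE (first in row-major
#' grid order on ties) is refit on all calibration data. One-vs-one
#' voting handles the three classes. Folds of a candidate are abandoned
#' early once its running error provably exceeds the best pair's CV RMSE;
#' the selected pair is identical to exhaustive evaluation, and abandoned
#' rows are flagged `completed = FALSE` in the candidates table (their
#' `cv_rmse` is then a lower bound).
#'
#' @param scores Calibration score matrix (samples x components).
#' @param labels Calibration class labels.
#' @param test_scores,test_labels Optional held-out data for a test-stage
#'   report row.
#' @param grid Hyperparameter grid (default [svm_grid()]).
#' @param folds Cross-validation folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @param degree Polynomial degree (default 2).
#' @return A `kiwi_svm_fit` with the fitted model, chosen pair, per-stage
#'   `reports` (calibration / validation / test) and the 25-row
#'   `candidates` table.
#' @export
grid_search_svm <- function(scores, labels, test_scores = NULL,
                            test_labels = NULL, grid = svm_grid(),
                            folds = 10, seed = 1, degree = 2) {
  .grid_search(scores, labels, grid, folds, seed, degree,
               classification = TRUE, test_x = test_scores, test_y = test_labels)
}

#' Grid-searched polynomial support vector regression
#'
#' Same protocol as [grid_search_svm()] with plain random folds and
#' epsilon-SVR: the (cost, gamma) pair minimising ten-fold CV RMSE is
#' refit on all calibration data; reports carry RMSE and R-squared
#' (percent) per stage.
#'
#' @inheritParams grid_search_svm
#' @param target Numeric calibration target values.
#' @param test_target Optional held-out target values.
#' @return A `kiwi_svm_fit`.
#' @export
grid_search_svr <- function(scores, target, test_scores = NULL,
                            test_target = NULL, grid = svm_grid(),
                            folds = 10, seed = 1, degree = 2) {
  .grid_search(scores, target, grid, folds, seed, degree,
               classification = FALSE, test_x = test_scores, test_y = test_target)
}

#' @export
print.kiwi_svm_fit <- function(x, ...) {
  kind <- if (x$classification) "SVM classifier" else "SVR regressor"
  cat(sprintf("<kiwi_svm_fit> %s, cost = %g, gamma = %g\n",
              kind, x$best$cost, x$best$gamma))
  print(x$reports, row.names = FALSE)
  invisible(x)
}
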