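# Static (non-temporal) baselines trained on the last timepoint of each
# subject: random forest (500 trees), SVM with the stated exhaustive grid,
# and LASSO with 50 log-spaced penalties chosen by 5-fold CV.

#' Last-timepoint dataset of a cohort
#'
#' Static classifiers cannot learn temporal structure, so they are trained
#' on the final-timepoint profile of each subject, labelled with the
#' subject label.
#'
#' @param cohort An `mb_cohort`.
#' @return A list with `X` (one row per subject), `y` (factor labels), and
#'   `subject_ids`.
#' @export
last_timepoint_dataset <- function(cohort) {
  seqs <- cohort_sequences(cohort)
  X <- do.call(rbind, lapply(seqs, function(s) s$X[nrow(s$X), ]))
  rownames(X) <- names(seqs)
  colnames(X) <- cohort$features
  y <- factor(vapply(seqs, function(s) as.character(s$label), character(1)),
              levels = label_levels)
  list(X = X, y = y, subject_ids = names(seqs))
}

#' The SVM hyperparameter grid
#'
#' Exhaustive grid over the linear and Gaussian kernels with costs
#' 1, 10, 100, 1000 and Gaussian gamma 0.001, 0.0001: 4 linear + 8
#' Gaussian = 12 candidates.
#'
#' @return A tibble with columns `kernel`, `cost`, `gamma` (`NA` for
#'   linear).
#' @export
svm_grid <- function() {
  dplyr::bind_rows(
    tidyr::expand_grid(kernel = "linear", cost = c(1, 10, 100, 1000),
                       gamma = NA_real_),
    tidyr::expand_grid(kernel = "radial", cost = c(1, 10, 100, 1000),
                       gamma = c(0.001, 0.0001))
  )
}

#' The LASSO penalty grid
#'
#' 50 numbers evenly log-spaced between 1e-4 and 10^-0.5.
#'
#' @return Numeric vector of length 50, decreasing (as glmnet expects).
#' @export
lasso_alpha_grid <- function() {
  sort(10^seq(-4, -0.5, length.out = 50L), decreasing = TRUE)
}

stratified_foldid <- function(y, n_folds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  id <- integer(length(y))
  for (cl in unique(y)) {
    rows <- sample(which(y == cl))
    id[rows] <- rep_len(sample(n_folds), length(rows))
  }
  id
}

#' Fit a random-forest baseline
#'
#' @param X,y Last-timepoint matrix and factor labels.
#' @param ntree Number of trees (default 500).
#' @param seed Integer seed.
#' @return A list of class `mb_rf`.
#' @export
fit_rf <- function(X, y, ntree = 500L, seed = 1L) {
  set.seed(seed)
  fit <- randomForest::randomForest(x = X, y = y, ntree = ntree)
  structure(list(fit = fit), class = "mb_rf")
}

#' @export
predict.mb_rf <- function(object, X, ...) {
  p <- predict(object$fit, X, type = "prob")[, "allergic"]
  tibble::tibble(p_allergic = as.numeric(p),
                 predicted = factor(ifelse(p > 0.5, "allergic", "non_allergic"),
                                    levels = label_levels))
}

#' Fit the SVM baseline with its exhaustive hyperparameter grid
#'
#' All 12 candidates of [svm_grid()] are scored by stratified 5-fold
#' cross-validated accuracy on the training set; the best is refitted on
#' all rows. Prediction scores are decision-function values oriented so
#' larger means more allergic.
#'
#' @param X,y Last-timepoint matrix and factor labels.
#' @param seed Integer seed (fold assignment).
#' @return A list of class `mb_svm` including the per-candidate CV table.
#' @export
fit_svm <- function(X, y, seed = 1L) {
  grid <- svm_grid()
  foldid <- stratified_foldid(y, 5L, seed = seed)
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    hits <- 0L
    for (f in sort(unique(foldid))) {
      tr <- foldid != f
      fit <- svm_fit_one(X[tr, , drop = FALSE], y[tr], grid[i, ])
      hits <- hits + sum(predict(fit, X[!tr, , drop = FALSE]) == y[!tr])
    }
    hits / length(y)
  }, numeric(1))
  best <- grid[which.max(acc), ]
  fit <- svm_fit_one(X, y, best)
  structure(list(fit = fit, best = best, cv = dplyr::mutate(grid, accuracy = acc)),
            class = "mb_svm")
}

svm_fit_one <- function(X, y, row) {
  if (row$kernel == "linear") {
    e1071::svm(x = X, y = y, kernel = "linear", cost = row$cost, scale = FALSE)
  } else {
    e1071::svm(x = X, y = y, kernel = "radial", cost = row$cost,
               gamma = row$gamma, scale = FALSE)
  }
}

#' @export
predict.mb_svm <- function(object, X, ...) {
  pr <- predict(object$fit, X, decision.values = TRUE)
  dv <- drop(attr(pr, "decision.values"))
  # orient the decision value toward the allergic class
  if (!grepl("^allergic", colnames(attr(pr, "decision.values"))[1L])) dv <- -dv
  tibble::tibble(p_allergic = as.numeric(dv),
                 predicted = factor(as.character(pr), levels = label_levels))
}

#' Fit the LASSO baseline
#'
#' Linear (squared-error) lasso on the 0/1-encoded label with the penalty
#' chosen by 5-fold cross-validation over [lasso_alpha_grid()]. Scores are
#' the linear predictor; hard labels threshold it at 0.5.
#'
#' @param X,y Last-timepoint matrix and factor labels.
#' @param seed Integer seed (fold assignment).
#' @return A list of class `mb_lasso`.
#' @export
fit_lasso <- function(X, y, seed = 1L) {
  yn <- as.integer(y == "allergic")
  n_folds <- min(5L, max(2L, floor(length(y) / 2)))
  foldid <- stratified_foldid(y, n_folds, seed = seed)
  cv <- suppressWarnings(
    glmnet::cv.glmnet(X, yn, family = "gaussian", alpha = 1,
                      lambda = lasso_alpha_grid(), foldid = foldid)
  )
  structure(list(fit = cv), class = "mb_lasso")
}

#' @export
predict.mb_lasso <- function(object, X, ...) {
  sc <- as.numeric(predict(object$fit, X, s = "lambda.min"))
  tibble::tibble(p_allergic = sc,
                 predicted = factor(ifelse(sc > 0.5, "allergic", "non_allergic"),
                                    levels = label_levels))
}
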