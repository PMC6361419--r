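# Repeated cross-validation benchmark: subject-level 20% test split plus
# k-fold CV on the remainder, every (classifier x feature representation)
# cell evaluated with leakage-safe per-fold selection/extraction.

#' Cross-validation scheme
#'
#' Per repeat the subjects are shuffled, 20% held out as the test set, and
#' the remaining 80% split into `n_folds` folds; each fold serves once as
#' the validation set for model selection while the other folds train.
#' Splits are by subject and stratified by class.
#'
#' @param test_fraction Fraction of subjects held out as test (default 0.2).
#' @param n_folds Number of CV folds on the remainder (default 10).
#' @param n_repeats Number of shuffled repeats (default 10).
#' @param seed Integer seed.
#' @return A list of class `cv_scheme`.
#' @export
cv_scheme <- function(test_fraction = 0.2, n_folds = 10L, n_repeats = 10L,
                      seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) abort("test_fraction must be in (0, 1)")
  if (n_folds < 2L) abort("n_folds must be >= 2")
  structure(list(test_fraction = test_fraction, n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Repeated stratified train/validation/test subject splits
#'
#' @param subject_ids Character vector of subject IDs.
#' @param labels Factor of subject labels aligned with `subject_ids`.
#' @param scheme A [cv_scheme()].
#' @return A list with one element per repeat: `list(test = ids,
#'   folds = list_of_id_vectors)`; the folds partition the non-test
#'   subjects.
#' @export
repeated_cv_split <- function(subject_ids, labels, scheme = cv_scheme()) {
  n <- length(subject_ids)
  if (n < scheme$n_folds + 2L) abort("too few subjects for the requested scheme")
  set.seed(scheme$seed)
  lapply(seq_len(scheme$n_repeats), function(r) {
    test <- character(0)
    foldid <- stats::setNames(integer(n), subject_ids)
    for (cl in levels(labels)) {
      ids <- sample(subject_ids[labels == cl])
      n_test <- round(scheme$test_fraction * length(ids))
      test <- c(test, ids[seq_len(n_test)])
      rest <- ids[-seq_len(n_test)]
      foldid[rest] <- rep_len(sample(scheme$n_folds), length(rest))
    }
    cv_ids <- setdiff(subject_ids, test)
    folds <- lapply(seq_len(scheme$n_folds), function(f) {
      cv_ids[foldid[cv_ids] == f]
    })
    list(test = test, folds = folds)
  })
}

#' Rebalance the classes of a (training) cohort
#'
#' `"up"` duplicates minority-class subjects (as new subject IDs) until the
#' classes are at parity; `"down"` subsamples the majority class;
#' `"none"` is the identity.
#'
#' @param cohort An `mb_cohort`.
#' @param mode `"up"`, `"down"`, or `"none"`.
#' @param seed Integer seed.
#' @return An `mb_cohort`.
#' @export
resample_balance <- function(cohort, mode = c("none", "up", "down"), seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "none") return(cohort)
  set.seed(seed)
  labs <- subject_labels(cohort)
  tab <- table(labs$label)
  if (any(tab == 0L)) abort("both classes must be present")
  minority <- names(tab)[which.min(tab)]
  majority <- names(tab)[which.max(tab)]
  if (mode == "down") {
    keep_maj <- sample(labs$subject_id[labs$label == majority], min(tab))
    return(subset_cohort(cohort, c(labs$subject_id[labs$label == minority], keep_maj)))
  }
  need <- max(tab) - min(tab)
  dup <- sample(labs$subject_id[labs$label == minority], need, replace = TRUE)
  samples <- cohort$samples
  profiles <- cohort$profiles
  for (i in seq_along(dup)) {
    add <- cohort$samples[cohort$samples$subject_id == dup[i], , drop = FALSE]
    prof <- cohort$profiles[cohort$samples$subject_id == dup[i], , drop = FALSE]
    add$subject_id <- paste0(dup[i], "__dup", i)
    add$sample_id <- paste0(add$sample_id, "__dup", i)
    rownames(prof) <- add$sample_id
    samples <- dplyr::bind_rows(samples, add)
    profiles <- rbind(profiles, prof)
  }
  ord <- order(samples$subject_id, samples$age, samples$sample_id)
  new_cohort(samples[ord, , drop = FALSE], profiles[ord, , drop = FALSE])
}

# --- feature representations ---------------------------------------------

#' Feature-representation specification
#'
#' The four representations compared in the benchmark: raw profiles,
#' mRMR top-k, variance top-k, and the sparse-autoencoder latent space.
#' Representations are always fitted on training-fold data only.
#'
#' @param method One of `"raw"`, `"mrmr"`, `"variance"`, `"latent"`.
#' @param k Number of selected features / latent size (default 25).
#' @param ae_hidden Hidden sizes for the latent method (default
#'   `c(60, k, 60)`).
#' @param ae_cfg An [ae_config()] for the latent method.
#' @return A list of class `mb_representation_spec`.
#' @export
representation_spec <- function(method = c("raw", "mrmr", "variance", "latent"),
                                k = 25L, ae_hidden = NULL, ae_cfg = ae_config()) {
  method <- match.arg(method)
  name <- switch(method, raw = "raw", mrmr = paste0("mrmr", k),
                 variance = paste0("var", k), latent = paste0("latent", k))
  structure(list(method = method, k = as.integer(k),
                 ae_hidden = ae_hidden %||% c(60L, as.integer(k), 60L),
                 ae_cfg = ae_cfg, name = name),
            class = "mb_representation_spec")
}

rep_spec_from_name <- function(name) {
  if (name == "raw") return(representation_spec("raw"))
  m <- regmatches(name, regexec("^(mrmr|var|latent)([0-9]+)$", name))[[1L]]
  if (length(m) == 0L) abort(sprintf("unknown representation '%s'", name))
  method <- switch(m[2L], mrmr = "mrmr", var = "variance", latent = "latent")
  representation_spec(method, k = as.integer(m[3L]))
}

#' Fit a feature representation on a training cohort
#'
#' @param spec A [representation_spec()].
#' @param train An `mb_cohort` (training folds only).
#' @param seed Integer seed (latent method).
#' @return An object with a `$transform(cohort)` function returning the
#'   reduced cohort, plus the underlying selection or autoencoder fit.
#' @export
fit_representation <- function(spec, train, seed = 1L) {
  if (spec$method == "raw") {
    return(list(spec = spec, transform = identity))
  }
  if (spec$method == "mrmr") {
    sel <- mrmr_select(train$profiles, train$samples$label, k = spec$k)
    return(list(spec = spec, selection = sel,
                transform = function(cohort) apply_selection(cohort, sel)))
  }
  if (spec$method == "variance") {
    sel <- variance_select(train$profiles, k = spec$k)
    return(list(spec = spec, selection = sel,
                transform = function(cohort) apply_selection(cohort, sel)))
  }
  # latent: scale on the training folds, train the sparse AE with an
  # internal 80/20 sample split for best-epoch selection
  scaler <- fit_scaler(train$profiles)
  Xs <- apply_scaler(train$profiles, scaler)
  set.seed(seed)
  n <- nrow(Xs)
  val_idx <- sample(n, max(1L, round(0.2 * n)))
  cfg <- spec$ae_cfg
  cfg$seed <- seed
  fit <- train_autoencoder(Xs[-val_idx, , drop = FALSE],
                           Xs[val_idx, , drop = FALSE],
                           ae_architecture(ncol(Xs), spec$ae_hidden), cfg)
  list(spec = spec, autoencoder = fit, scaler = scaler,
       transform = function(cohort) {
         scaled <- new_cohort(cohort$samples, apply_scaler(cohort$profiles, scaler))
         encode_latent(scaled, fit)
       })
}

# --- classifier registry --------------------------------------------------

#' Classifier specification for the benchmark
#'
#' Known models: `"lstm"` (sequence), `"hmm"` (sequence, unsupervised with
#' supervised state mapping), and the last-timepoint models `"mlpnn"`,
#' `"rf"`, `"svm"`, `"lasso"`.
#'
#' @param model Model name.
#' @param ... Model-specific configuration overrides: `cfg` (an
#'   [lstm_config()] or [mlp_config()]), `ntree`, `n_states`, `n_mixtures`,
#'   `n_iter`.
#' @return A list of class `mb_model_spec` with a `fit(train, val, seed)`
#'   function whose result has `predict(cohort)` returning per-subject
#'   scores, plus the score threshold for hard labels.
#' @export
model_spec <- function(model = c("lstm", "hmm", "mlpnn", "rf", "svm", "lasso"),
                       ...) {
  model <- match.arg(model)
  opts <- list(...)
  fit_fun <- switch(
    model,
    lstm = function(train, val, seed) {
      cfg <- opts$cfg %||% lstm_config()
      cfg$seed <- seed
      fit <- train_lstm(train, val, cfg)
      function(cohort) predict(fit, cohort)
    },
    hmm = function(train, val, seed) {
      scaler <- fit_scaler(train$profiles)
      seqs <- lapply(cohort_sequences(train), function(s) apply_scaler(s$X, scaler))
      labs <- subject_labels(train)
      fit <- hmm_gmm_train(seqs, labs$label,
                           n_states = opts$n_states %||% 2L,
                           n_mixtures = opts$n_mixtures %||% 4L,
                           n_iter = opts$n_iter %||% 100L, seed = seed)
      function(cohort) {
        sq <- cohort_sequences(cohort)
        out <- predict(fit, lapply(sq, function(s) apply_scaler(s$X, scaler)))
        dplyr::mutate(out, subject_id = names(sq), .before = 1L)
      }
    },
    mlpnn = function(train, val, seed) {
      dtr <- last_timepoint_dataset(train)
      dvl <- last_timepoint_dataset(val)
      scaler <- fit_scaler(dtr$X)
      cfg <- opts$cfg %||% mlp_config()
      cfg$seed <- seed
      fit <- train_mlp(apply_scaler(dtr$X, scaler), as.integer(dtr$y),
                       apply_scaler(dvl$X, scaler), as.integer(dvl$y), cfg)
      function(cohort) {
        d <- last_timepoint_dataset(cohort)
        P <- predict(fit, apply_scaler(d$X, scaler))
        tibble::tibble(subject_id = d$subject_ids, p_allergic = P[, 2L],
                       predicted = factor(label_levels[max.col(P)],
                                          levels = label_levels))
      }
    },
    rf = function(train, val, seed) {
      d <- last_timepoint_dataset(train)
      fit <- fit_rf(d$X, d$y, ntree = opts$ntree %||% 500L, seed = seed)
      function(cohort) {
        dd <- last_timepoint_dataset(cohort)
        dplyr::mutate(predict(fit, dd$X), subject_id = dd$subject_ids,
                      .before = 1L)
      }
    },
    svm = function(train, val, seed) {
      d <- last_timepoint_dataset(train)
      scaler <- fit_scaler(d$X)
      fit <- fit_svm(apply_scaler(d$X, scaler), d$y, seed = seed)
      function(cohort) {
        dd <- last_timepoint_dataset(cohort)
        dplyr::mutate(predict(fit, apply_scaler(dd$X, scaler)),
                      subject_id = dd$subject_ids, .before = 1L)
      }
    },
    lasso = function(train, val, seed) {
      d <- last_timepoint_dataset(train)
      scaler <- fit_scaler(d$X)
      fit <- fit_lasso(apply_scaler(d$X, scaler), d$y, seed = seed)
      function(cohort) {
        dd <- last_timepoint_dataset(cohort)
        dplyr::mutate(predict(fit, apply_scaler(dd$X, scaler)),
                      subject_id = dd$subject_ids, .before = 1L)
      }
    }
  )
  threshold <- switch(model, svm = 0, lstm = 0.5, hmm = 0.5, mlpnn = 0.5,
                      rf = 0.5, lasso = 0.5)
  structure(list(name = model, fit = fit_fun, threshold = threshold),
            class = "mb_model_spec")
}

#' Run the repeated-CV benchmark over classifier x representation cells
#'
#' For every repeat: the test subjects are held out; for every fold the
#' remaining subjects are split into training and validation; the feature
#' representation is fitted on the training folds only and applied to all
#' splits; each classifier trains and scores the test subjects. Per-subject
#' test scores are averaged over the folds of a repeat, giving one
#' auROC/MCC value per (cell, repeat).
#'
#' @param cohort An `mb_cohort`.
#' @param models Character vector of model names (see [model_spec()]) or a
#'   list of `mb_model_spec` objects.
#' @param representations Character vector of representation names
#'   (`"raw"`, `"mrmr25"`, `"var25"`, `"latent25"`, ...) or a list of
#'   [representation_spec()] objects.
#' @param scheme A [cv_scheme()].
#' @param resample `"none"` (default), `"up"`, or `"down"`; applied to
#'   training folds only.
#' @param reference `c(model, representation)` cell used for the
#'   Mann-Whitney comparisons in the summary (default LSTM + first
#'   representation).
#' @param progress Print per-repeat progress (default FALSE).
#' @return An `mb_benchmark` object; `tidy()` gives per-repeat fold
#'   results, `summary()`/`glance()` the per-cell mean (sd) auROC/MCC with
#'   Mann-Whitney p-values against the reference cell.
#' @export
run_benchmark <- function(cohort, models = c("lstm", "lasso"),
                          representations = "mrmr25",
                          scheme = cv_scheme(), resample = "none",
                          reference = NULL, progress = FALSE) {
  if (is.character(models)) models <- lapply(models, model_spec)
  if (is.character(representations)) {
    representations <- lapply(representations, rep_spec_from_name)
  }
  labs <- subject_labels(cohort)
  splits <- repeated_cv_split(labs$subject_id,
                              labs$label, scheme)
  results <- list()
  errors <- list()
  for (r in seq_along(splits)) {
    sp <- splits[[r]]
    test_cohort <- subset_cohort(cohort, sp$test)
    test_labs <- subject_labels(test_cohort)
    # score accumulator: [cell][subject] running sum over folds
    acc <- list()
    nfold <- list()
    for (f in seq_along(sp$folds)) {
      val_ids <- sp$folds[[f]]
      train_ids <- setdiff(unlist(sp$folds), val_ids)
      if (length(val_ids) == 0L) next
      fold_seed <- scheme$seed + 7919L * r + 104729L * f
      train_cohort <- subset_cohort(cohort, train_ids)
      if (resample != "none") {
        train_cohort <- resample_balance(train_cohort, resample,
                                         seed = fold_seed)
      }
      val_cohort <- subset_cohort(cohort, val_ids)
      for (rs in representations) {
        cell_err <- NULL
        rf_fit <- tryCatch(fit_representation(rs, train_cohort, seed = fold_seed),
                           error = function(e) {
                             cell_err <<- conditionMessage(e)
                             NULL
                           })
        for (ms in models) {
          key <- paste(ms$name, rs$name, sep = "|")
          if (is.null(rf_fit)) {
            errors[[length(errors) + 1L]] <- tibble::tibble(
              model = ms$name, representation = rs$name, rep = r, fold = f,
              error = cell_err)
            next
          }
          sc <- tryCatch({
            pred <- ms$fit(rf_fit$transform(train_cohort),
                           rf_fit$transform(val_cohort), fold_seed)
            pred(rf_fit$transform(test_cohort))
          }, error = function(e) e)
          if (inherits(sc, "error")) {
            errors[[length(errors) + 1L]] <- tibble::tibble(
              model = ms$name, representation = rs$name, rep = r, fold = f,
              error = conditionMessage(sc))
            next
          }
          v <- stats::setNames(sc$p_allergic, sc$subject_id)[test_labs$subject_id]
          acc[[key]] <- (acc[[key]] %||% 0) + v
          nfold[[key]] <- (nfold[[key]] %||% 0L) + 1L
        }
      }
    }
    for (ms in models) {
      for (rs in representations) {
        key <- paste(ms$name, rs$name, sep = "|")
        if (is.null(acc[[key]])) next
        score <- acc[[key]] / nfold[[key]]
        predicted <- factor(ifelse(score > ms$threshold, "allergic", "non_allergic"),
                            levels = label_levels)
        cc <- confusion_counts(predicted, test_labs$label)
        ss <- sensitivity_specificity(cc$TP, cc$FN, cc$TN, cc$FP)
        results[[length(results) + 1L]] <- tibble::tibble(
          model = ms$name, representation = rs$name, rep = r,
          auROC = roc_auc(score, test_labs$label),
          MCC = mcc(cc$TP, cc$FP, cc$TN, cc$FN),
          sensitivity = ss$sensitivity, specificity = ss$specificity,
          TP = cc$TP, FP = cc$FP, TN = cc$TN, FN = cc$FN,
          n_test = nrow(test_labs))
      }
    }
    if (progress) message(sprintf("repeat %d/%d done", r, length(splits)))
  }
  reference <- reference %||% c(models[[1L]]$name, representations[[1L]]$name)
  structure(
    list(results = dplyr::bind_rows(results),
         errors = if (length(errors)) dplyr::bind_rows(errors) else NULL,
         reference = reference, scheme = scheme, resample = resample),
    class = "mb_benchmark"
  )
}

#' @export
tidy.mb_benchmark <- function(x, ...) x$results

#' @export
glance.mb_benchmark <- function(x, ...) summary(x)

#' @exportS3Method base::summary
summary.mb_benchmark <- function(object, ...) {
  res <- object$results
  ref <- dplyr::filter(res, .data$model == object$reference[1L],
                       .data$representation == object$reference[2L])
  res |>
    dplyr::group_by(.data$model, .data$representation) |>
    dplyr::summarise(
      auROC_mean = mean(.data$auROC), auROC_sd = sd(.data$auROC),
      auROC_p = if (nrow(ref)) mann_whitney_compare(ref$auROC, .data$auROC) else NA_real_,
      MCC_mean = mean(.data$MCC), MCC_sd = sd(.data$MCC),
      MCC_p = if (nrow(ref)) mann_whitney_compare(ref$MCC, .data$MCC) else NA_real_,
      n_repeats = dplyr::n(),
      .groups = "drop"
    )
}

#' @exportS3Method base::print
print.mb_benchmark <- function(x, ...) {
  cat(sprintf("<mb_benchmark> %d cells x %d repeats (reference %s + %s)\n",
              dplyr::n_distinct(paste(x$results$model, x$results$representation)),
              max(x$results$rep), x$reference[1L], x$reference[2L]))
  print(summary(x))
  if (!is.null(x$errors)) {
    cat(sprintf("%d cell failure(s); see $errors\n", nrow(x$errors)))
  }
  invisible(x)
}

#' @export
autoplot.mb_benchmark <- function(object, metric = c("auROC", "MCC"), ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$representation,
                               y = .data[[metric]],
                               colour = .data$model)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = if (metric == "auROC") 0.5 else 0,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "feature representation", y = metric,
                  title = "Repeated-CV benchmark") +
    ggplot2::theme_minimal()
}
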