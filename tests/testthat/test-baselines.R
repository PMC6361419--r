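test_that("last-timepoint dataset takes one age-ordered final profile per subject", {
  co <- make_separable_cohort(n_subjects = 10, timepoints = 4)
  d <- last_timepoint_dataset(co)
  expect_equal(nrow(d$X), 10L)
  expect_equal(length(d$y), 10L)
  # the row is the final-age profile
  s3 <- co$samples[co$samples$subject_id == "S03", ]
  last_id <- s3$sample_id[which.max(s3$age)]
  expect_equal(unname(d$X["S03", ]), unname(co$profiles[last_id, ]))
})

test_that("HMM-GMM recovers well-separated regimes and maps states by accuracy", {
  set.seed(30)
  # two regimes in 2-d: sequences dwell in their class's regime
  mk <- function(center, Tt) {
    matrix(rnorm(Tt * 2, mean = center, sd = 0.3), Tt, 2)
  }
  seqs <- c(lapply(1:10, function(i) mk(0, sample(3:6, 1))),
            lapply(1:10, function(i) mk(4, sample(3:6, 1))))
  labels <- factor(rep(c("non_allergic", "allergic"), each = 10),
                   levels = c("non_allergic", "allergic"))
  fit <- hmm_gmm_train(seqs, labels, n_iter = 40, seed = 2)
  pred <- predict(fit, seqs)
  expect_gt(mean(pred$predicted == labels), 0.9)
  # posterior scores are probabilities
  expect_true(all(pred$p_allergic >= 0 & pred$p_allergic <= 1))
  # reproducibility
  fit2 <- hmm_gmm_train(seqs, labels, n_iter = 40, seed = 2)
  expect_equal(predict(fit2, seqs), pred)
  # flipping the labels flips the state mapping, not the fit
  fit_flip <- hmm_gmm_train(seqs, rev(labels), n_iter = 40, seed = 2)
  expect_equal(fit_flip$mapping, rev(fit$mapping))
  # viterbi path agrees on well-separated data
  pred_v <- predict(fit, seqs, method = "viterbi")
  expect_gt(mean(pred_v$predicted == labels), 0.9)
})

test_that("single-timepoint sequences are predictable by the HMM", {
  set.seed(31)
  seqs <- c(lapply(1:6, function(i) matrix(rnorm(8, 0, 0.3), 4, 2)),
            lapply(1:6, function(i) matrix(rnorm(8, 3, 0.3), 4, 2)))
  labels <- factor(rep(c("non_allergic", "allergic"), each = 6),
                   levels = c("non_allergic", "allergic"))
  fit <- hmm_gmm_train(seqs, labels, n_iter = 30, seed = 4)
  one <- predict(fit, list(matrix(c(3, 3), 1, 2)))
  expect_equal(nrow(one), 1L)
  expect_equal(as.character(one$predicted), "allergic")
})

test_that("the MLP learns a separable toy and disables dropout at inference", {
  set.seed(40)
  n <- 60
  y <- rep(1:2, each = n / 2)
  X <- matrix(rnorm(n * 4), n, 4)
  X[y == 2, 1] <- X[y == 2, 1] + 4
  cfg <- mlp_config(hidden = c(16, 8), epochs = 150, seed = 3)
  fit <- train_mlp(X[1:40, ], y[1:40], X[41:60, ], y[41:60], cfg)
  # training accuracy reaches 1 on separable data
  expect_equal(mean(max.col(predict(fit, X[1:40, ])) == y[1:40]), 1)
  # inference is deterministic (no dropout): two passes identical
  expect_identical(predict(fit, X), predict(fit, X))
  # reproducible training
  fit2 <- train_mlp(X[1:40, ], y[1:40], X[41:60, ], y[41:60], cfg)
  expect_equal(fit$history, fit2$history)
})

test_that("MLP gradients match finite differences (dropout off)", {
  set.seed(41)
  params <- mblstm:::mlp_init(3, c(4, 3), seed = 8)
  X <- matrix(rnorm(15), 5, 3)
  y <- c(1, 2, 1, 2, 2)
  ana <- mblstm:::mlp_grad(X, y, params)
  num <- fd_gradient(function(p) mblstm:::mlp_loss(X, y, p), params)
  expect_lt(max_rel_err(ana, num), 1e-5)
})

test_that("random forest separates a pure-signal toy perfectly", {
  set.seed(50)
  y <- factor(rep(c("non_allergic", "allergic"), each = 20),
              levels = c("non_allergic", "allergic"))
  X <- matrix(rnorm(40), 40, 1)
  X[y == "allergic", 1] <- X[y == "allergic", 1] + 10
  colnames(X) <- "g1"
  fit <- fit_rf(X, y, seed = 1)
  pred <- predict(fit, X)
  expect_equal(roc_auc(pred$p_allergic, y), 1)
})

test_that("the SVM grid enumerates exactly the stated 12 candidates", {
  g <- svm_grid()
  expect_equal(nrow(g), 12L)
  expect_equal(sum(g$kernel == "linear"), 4L)
  expect_equal(sum(g$kernel == "radial"), 8L)
  expect_setequal(unique(g$cost), c(1, 10, 100, 1000))
  expect_setequal(unique(g$gamma[g$kernel == "radial"]), c(0.001, 0.0001))
  set.seed(51)
  y <- factor(rep(c("non_allergic", "allergic"), each = 15),
              levels = c("non_allergic", "allergic"))
  X <- matrix(rnorm(60), 30, 2)
  X[y == "allergic", ] <- X[y == "allergic", ] + 3
  fit <- fit_svm(X, y, seed = 1)
  expect_equal(nrow(fit$cv), 12L)
  pred <- predict(fit, X)
  # decision values oriented toward the allergic class
  expect_gt(roc_auc(pred$p_allergic, y), 0.95)
})

test_that("the LASSO penalty grid has 50 log-spaced values and scores linearly", {
  grid <- lasso_alpha_grid()
  expect_length(grid, 50L)
  expect_equal(max(grid), 10^-0.5)
  expect_equal(min(grid), 1e-4)
  # evenly log-spaced
  expect_equal(diff(log10(grid)), rep(-3.5 / 49, 49), tolerance = 1e-12)
  set.seed(52)
  y <- factor(rep(c("non_allergic", "allergic"), each = 20),
              levels = c("non_allergic", "allergic"))
  X <- matrix(rnorm(40 * 5), 40, 5)
  X[y == "allergic", 2] <- X[y == "allergic", 2] + 3
  colnames(X) <- paste0("g", 1:5)
  fit <- fit_lasso(X, y, seed = 1)
  pred <- predict(fit, X)
  expect_gt(roc_auc(pred$p_allergic, y), 0.95)
  expect_equal(as.character(pred$predicted),
               ifelse(pred$p_allergic > 0.5, "allergic", "non_allergic"))
})
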