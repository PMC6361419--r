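test_that("autoencoder forward pass matches the layer-by-layer oracle", {
  set.seed(4)
  params <- mblstm:::ae_init(c(4, 3, 2, 3, 4), seed = 9)
  for (i in 1:100) {
    x <- abs(rnorm(4))
    got <- ae_forward(x, params)
    expect_equal(got$recon, oracle_ae_forward(x, params), tolerance = 1e-10)
  }
  # latent is the middle hidden layer (length 2 here)
  expect_length(ae_forward(abs(rnorm(4)), params)$latent, 2L)
})

test_that("degenerate and identity-like nets behave as expected", {
  zero <- mblstm:::ae_init(c(4, 3, 2, 3, 4), seed = 1)
  zero$W <- lapply(zero$W, function(w) w * 0)
  fw <- ae_forward(c(1, 2, 3, 4), zero)
  expect_equal(fw$recon, rep(0, 4))
  expect_equal(fw$latent, rep(0, 2))
  # identity 2-2-2-2-2 net with W = I, b = 0 reproduces non-negative input
  id <- list(W = replicate(4, diag(2), simplify = FALSE),
             b = replicate(4, rep(0, 2), simplify = FALSE))
  x <- c(0.5, 2)
  expect_equal(ae_forward(x, id)$recon, x)
  expect_error(ae_forward(c(NA, 1), id), "non-finite")
})

test_that("KL sparsity penalty matches its closed form and is monotone", {
  expect_equal(kl_sparsity_penalty(0.2, c(0.2, 0.2, 0.2)), 0)
  expect_equal(kl_sparsity_penalty(0.01, 0.5),
               0.01 * log(0.02) + 0.99 * log(1.98), tolerance = 1e-12)
  # strictly increasing as a single mean activation moves away from rho
  vals_up <- vapply(seq(0.05, 0.9, by = 0.05),
                    function(r) kl_sparsity_penalty(0.05, r), numeric(1))
  expect_true(all(diff(vals_up) > 0))
  vals_dn <- vapply(seq(0.05, 1e-4, by = -0.005),
                    function(r) kl_sparsity_penalty(0.05, r), numeric(1))
  expect_true(all(diff(vals_dn) > 0))
  # clamping keeps out-of-range activations finite
  expect_true(is.finite(kl_sparsity_penalty(0.01, c(0, 1.7, 12))))
  expect_gte(kl_sparsity_penalty(0.01, c(0.3, 0.005)), 0)
})

test_that("autoencoder loss decomposes into recon + l2 + kl", {
  # hand computation on a 2-sample, 2-feature single-layer-pair toy
  params <- list(W = list(matrix(c(1, 0, 0, 1), 2), matrix(c(2, 0, 0, 0.5), 2)),
                 b = list(c(0, 0), c(0, 0)))
  X <- rbind(c(1, 2), c(3, 4))
  cfg <- ae_config(lambda = 0.1, rho = 0.25, beta = 2)
  out <- ae_loss(X, params, cfg)
  # recon: x' = diag(2, .5) %*% x => rows (2,1),(6,2); errors (1,-1),(3,-2)
  expect_equal(out$recon, ((1 + 1) + (9 + 4)) / 2)
  expect_equal(out$l2, 0.1 * (2 + 4.25))
  # latent = x itself (identity first layer; m=2 -> middle layer index 2)
  rho_hat <- pmin(pmax(colMeans(X), 1e-6), 1 - 1e-6)
  expect_equal(out$kl, 2 * kl_sparsity_penalty(0.25, rho_hat))
  expect_equal(out$total, out$recon + out$l2 + out$kl)
  # perfect reconstruction with lambda = beta = 0 gives 0
  id <- list(W = list(diag(2), diag(2)), b = list(rep(0, 2), rep(0, 2)))
  expect_equal(ae_loss(X, id, ae_config(lambda = 0, beta = 0))$total, 0)
  expect_error(ae_loss(X[0, , drop = FALSE], id, cfg), "empty")
})

test_that("autoencoder backprop gradients match finite differences", {
  # fixture chosen away from ReLU kinks and KL clamp boundaries so the
  # loss is differentiable at the test point
  params <- mblstm:::ae_init(c(4, 3, 2, 3, 4), seed = 16)
  set.seed(116)
  X <- matrix(abs(rnorm(20)) + 0.2, 5, 4)
  cfg <- ae_config(lambda = 0.03, rho = 0.05, beta = 2)
  fw <- ae_forward(X, params)
  expect_true(all(abs(unlist(fw$preacts)) > 1e-3)) # fixture validity
  ana <- mblstm:::ae_grad(X, params, cfg)
  num <- fd_gradient(function(p) ae_loss(X, p, cfg)$total, params)
  expect_lt(max_rel_err(ana, num), 1e-5)
})

test_that("training reduces loss, is seed-reproducible, and encodes cohorts", {
  set.seed(2)
  X <- matrix(abs(rnorm(40 * 6)), 40, 6)
  arch <- ae_architecture(6, c(5, 3, 5))
  cfg <- ae_config(epochs = 30, seed = 3)
  fit <- train_autoencoder(X[1:30, ], X[31:40, ], arch, cfg)
  expect_s3_class(fit, "mb_autoencoder")
  expect_equal(fit$status, "converged")
  expect_lt(fit$history$train_loss[fit$best_epoch], fit$history$train_loss[1])
  fit2 <- train_autoencoder(X[1:30, ], X[31:40, ], arch, cfg)
  expect_equal(fit$history, fit2$history)
  # loss never exactly zero with lambda > 0 and non-zero weights
  expect_gt(min(fit$history$train_loss), 0)

  co <- make_separable_cohort(n_subjects = 6, n_features = 6)
  enc <- encode_latent(co, fit)
  expect_equal(ncol(enc$profiles), 3L)
  expect_equal(enc$samples, co$samples)
  # per-sample equivalence with ae_forward
  expect_equal(unname(enc$profiles[3, ]),
               ae_forward(co$profiles[3, ], fit$params)$latent)
  expect_error(encode_latent(apply_selection(co, variance_select(co$profiles, 4)), fit),
               "expects")
})

test_that("the KL term drives mean latent activation down", {
  set.seed(14)
  X <- matrix(abs(rnorm(60 * 8)), 60, 8)
  arch <- ae_architecture(8, c(6, 4, 6))
  f0 <- train_autoencoder(X[1:48, ], X[49:60, ], arch,
                          ae_config(beta = 0, epochs = 40, seed = 5))
  f3 <- train_autoencoder(X[1:48, ], X[49:60, ], arch,
                          ae_config(beta = 3, epochs = 40, seed = 5))
  act0 <- mean(ae_forward(X, f0$params)$latent)
  act3 <- mean(ae_forward(X, f3$params)$latent)
  expect_lt(act3, act0)
})

test_that("architecture grid search reports losses and flags non-convergence", {
  set.seed(6)
  X <- matrix(abs(rnorm(50 * 6)), 50, 6)
  tab <- architecture_grid_search(X[1:30, ], X[31:40, ], X[41:50, ],
                                  grid = list(c(5, 3, 5), c(4, 2, 4)),
                                  cfg = ae_config(epochs = 15, seed = 2))
  expect_equal(nrow(tab), 2L)
  expect_true(all(c("architecture", "n_params", "status", "train_loss",
                    "val_loss", "test_loss", "selected") %in% names(tab)))
  expect_equal(sum(tab$selected), 1L)
  expect_equal(which(tab$selected), which.min(tab$test_loss))
  # a wildly divergent configuration is labelled, not thrown
  bad <- train_autoencoder(X[1:30, ] * 1e154, X[31:40, ] * 1e154,
                           ae_architecture(6, c(5, 3, 5)),
                           ae_config(epochs = 3, seed = 1, learning_rate = 1))
  expect_equal(bad$status, "non_converged")
})

test_that("under-capacity latent spaces reconstruct structured data worse", {
  set.seed(33)
  # strongly structured data: 3 latent factors in 12 features
  n <- 80
  F3 <- matrix(abs(rnorm(n * 3)), n, 3)
  L <- matrix(abs(rnorm(3 * 12)), 3, 12)
  X <- F3 %*% L
  cfg <- ae_config(epochs = 60, seed = 4, beta = 0, lambda = 0)
  small <- train_autoencoder(X[1:60, ], X[61:70, ],
                             ae_architecture(12, c(8, 1, 8)), cfg)
  right <- train_autoencoder(X[1:60, ], X[61:70, ],
                             ae_architecture(12, c(8, 4, 8)), cfg)
  l_small <- ae_loss(X[71:80, ], small$params, cfg)$total
  l_right <- ae_loss(X[71:80, ], right$params, cfg)$total
  expect_gt(l_small, l_right)
})
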