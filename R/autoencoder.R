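# Sparse autoencoder: fully-connected ReLU encoder/decoder trained to
# reconstruct per-sample profiles under a loss with three terms --
# mean squared reconstruction error, L2 weight decay, and a KL-divergence
# penalty driving the mean latent activation toward a small target rho.

#' Autoencoder training configuration
#'
#' Defaults follow the reference setting: L2 coefficient `lambda = 0.05`,
#' sparsity target `rho = 0.01` with weight `beta = 3`, Adam with learning
#' rate 0.001, batch size 5, 300 epochs.
#'
#' @param lambda L2 coefficient on the weight matrices (biases excluded).
#' @param rho Sparsity target in (0, 1).
#' @param beta Weight of the KL sparsity penalty.
#' @param learning_rate,batch_size,epochs Adam optimizer settings.
#' @param eps Clamp applied to mean latent activations before the KL term
#'   (ReLU activations are unbounded, so means are clamped to
#'   `[eps, 1 - eps]`).
#' @param seed Integer seed for initialization and batch shuffling.
#' @return A list of class `ae_config`.
#' @export
ae_config <- function(lambda = 0.05, rho = 0.01, beta = 3,
                      learning_rate = 0.001, batch_size = 5L, epochs = 300L,
                      eps = 1e-6, seed = 1L) {
  if (rho <= 0 || rho >= 1) abort("rho must be in (0, 1)")
  if (beta < 0 || lambda < 0) abort("beta and lambda must be >= 0")
  structure(list(lambda = lambda, rho = rho, beta = beta,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), eps = eps,
                 seed = as.integer(seed)),
            class = "ae_config")
}

#' Autoencoder architecture
#'
#' Five layers: input, three hidden (the middle one is the latent
#' representation), output; input and output sizes must match.
#'
#' @param d_in Input (= output) dimension.
#' @param hidden Integer vector of the three hidden-layer sizes, e.g.
#'   `c(60, 25, 60)`.
#' @return Integer vector of all five layer sizes.
#' @export
ae_architecture <- function(d_in, hidden = c(60L, 25L, 60L)) {
  if (length(hidden) != 3L) abort("exactly 3 hidden layers are required")
  sizes <- as.integer(c(d_in, hidden, d_in))
  if (any(sizes < 1L)) abort("all layer sizes must be >= 1")
  sizes
}

ae_init <- function(arch, seed = 1L) {
  set.seed(seed)
  m <- length(arch) - 1L
  W <- vector("list", m)
  b <- vector("list", m)
  for (l in seq_len(m)) {
    W[[l]] <- init_uniform(arch[l + 1L], arch[l])
    b[[l]] <- rep(0, arch[l + 1L])
  }
  list(W = W, b = b)
}

ae_n_params <- function(params) {
  sum_rec(params, function(x) x * 0 + 1)
}

#' Forward pass of the sparse autoencoder
#'
#' Every layer applies `ReLU(W x + b)`; the latent representation is the
#' activation of the middle hidden layer.
#'
#' @param x A profile vector or a samples-by-features matrix.
#' @param params Autoencoder parameters (list with `W`, `b` per layer).
#' @return A list with `recon` (reconstruction, same shape as `x`),
#'   `latent`, and `activations` (per-layer activations including the
#'   input).
#' @export
ae_forward <- function(x, params) {
  vec <- is.null(dim(x))
  A <- if (vec) matrix(x, nrow = 1L) else x
  check_finite(A, "autoencoder input")
  m <- length(params$W)
  latent_layer <- (m %/% 2L) + 1L # middle hidden layer (m = 4 -> layer 3 of 5)
  acts <- vector("list", m + 1L)
  pre <- vector("list", m)
  acts[[1L]] <- A
  for (l in seq_len(m)) {
    Z <- acts[[l]] %*% t(params$W[[l]]) +
      matrix(params$b[[l]], nrow(A), length(params$b[[l]]), byrow = TRUE)
    pre[[l]] <- Z
    acts[[l + 1L]] <- pmax(Z, 0)
  }
  latent <- acts[[latent_layer]]
  recon <- acts[[m + 1L]]
  if (vec) {
    latent <- drop(latent)
    recon <- drop(recon)
  }
  list(recon = recon, latent = latent, activations = acts, preacts = pre)
}

#' KL-divergence sparsity penalty
#'
#' `sum_j rho*log(rho/rho_hat_j) + (1-rho)*log((1-rho)/(1-rho_hat_j))`,
#' the KL divergence between Bernoulli(rho) and Bernoulli(rho_hat_j),
#' summed over latent neurons. Mean activations are clamped to
#' `[eps, 1-eps]` first (under ReLU they can exceed 1).
#'
#' @param rho Sparsity target in (0, 1).
#' @param rho_hat Vector of mean latent activations.
#' @param eps Clamp width (default 1e-6).
#' @return Non-negative penalty; 0 iff every clamped `rho_hat` equals `rho`.
#' @export
kl_sparsity_penalty <- function(rho, rho_hat, eps = 1e-6) {
  if (rho <= 0 || rho >= 1) abort("rho must be in (0, 1)")
  rh <- pmin(pmax(rho_hat, eps), 1 - eps)
  sum(rho * log(rho / rh) + (1 - rho) * log((1 - rho) / (1 - rh)))
}

#' Sparse-autoencoder loss
#'
#' `total = recon + l2 + kl` where `recon` is the mean squared
#' reconstruction error over datapoints, `l2` is `lambda` times the summed
#' squared Frobenius norms of all weight matrices (biases excluded), and
#' `kl` is `beta` times [kl_sparsity_penalty()] of the mean latent
#' activations over the batch.
#'
#' @param X Non-empty samples-by-features matrix.
#' @param params Autoencoder parameters.
#' @param cfg An [ae_config()].
#' @return A list with `total`, `recon`, `l2`, `kl`, and `rho_hat`.
#' @export
ae_loss <- function(X, params, cfg = ae_config()) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (nrow(X) == 0L) abort("empty batch")
  fw <- ae_forward(X, params)
  n <- nrow(X)
  recon <- sum((fw$recon - X)^2) / n
  l2 <- cfg$lambda * sum_rec(params$W, function(w) w^2)
  rho_hat <- colMeans(matrix(fw$latent, nrow = n))
  kl <- cfg$beta * kl_sparsity_penalty(cfg$rho, rho_hat, cfg$eps)
  list(total = recon + l2 + kl, recon = recon, l2 = l2, kl = kl,
       rho_hat = rho_hat)
}

# Analytic gradient of ae_loss via backpropagation.
ae_grad <- function(X, params, cfg = ae_config()) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  n <- nrow(X)
  fw <- ae_forward(X, params)
  m <- length(params$W)
  latent_layer <- (m %/% 2L) + 1L
  dW <- vector("list", m)
  db <- vector("list", m)
  dA <- 2 * (fw$activations[[m + 1L]] - X) / n
  # KL term: d/dA_latent of beta * KL(rho || clamp(colMeans(A_latent)))
  rho_hat <- colMeans(fw$activations[[latent_layer]])
  inside <- rho_hat > cfg$eps & rho_hat < 1 - cfg$eps
  rh <- pmin(pmax(rho_hat, cfg$eps), 1 - cfg$eps)
  dkl <- ifelse(inside, -cfg$rho / rh + (1 - cfg$rho) / (1 - rh), 0)
  for (l in rev(seq_len(m))) {
    dZ <- dA * (fw$preacts[[l]] > 0)
    dW[[l]] <- t(dZ) %*% fw$activations[[l]] + 2 * cfg$lambda * params$W[[l]]
    db[[l]] <- colSums(dZ)
    dA <- dZ %*% params$W[[l]]
    if (l == latent_layer) {
      dA <- dA + matrix(cfg$beta * dkl / n, n, length(dkl), byrow = TRUE)
    }
  }
  list(W = dW, b = db)
}

#' Train a sparse autoencoder
#'
#' Minibatch Adam training of the sparse-autoencoder loss. The KL term uses
#' the minibatch mean activation during training and the full-set mean for
#' the reported epoch losses. The parameters from the epoch with minimum
#' validation loss are returned. A run that produces non-finite loss is not
#' an error: it is returned with `status = "non_converged"`.
#'
#' @param train,val Samples-by-features matrices (same column count).
#' @param arch An [ae_architecture()].
#' @param cfg An [ae_config()].
#' @return An object of class `mb_autoencoder` with elements `params`
#'   (best-epoch parameters), `arch`, `cfg`, `history` (tibble of per-epoch
#'   train/val losses), `best_epoch`, and `status`
#'   (`"converged"`/`"non_converged"`).
#' @export
train_autoencoder <- function(train, val, arch, cfg = ae_config()) {
  if (ncol(train) != arch[1L] || ncol(val) != arch[1L]) {
    abort("column count must equal the architecture's input size")
  }
  set.seed(cfg$seed)
  params <- ae_init(arch, seed = cfg$seed)
  opt <- adam_init(lr = cfg$learning_rate)
  n <- nrow(train)
  best <- list(val = Inf, params = params, epoch = 0L)
  hist <- vector("list", cfg$epochs)
  status <- "converged"
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(n)
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      g <- ae_grad(train[idx, , drop = FALSE], params, cfg)
      params <- adam_step(opt, params, g)
    }
    tr <- ae_loss(train, params, cfg)$total
    vl <- ae_loss(val, params, cfg)$total
    hist[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = tr, val_loss = vl)
    if (!is.finite(tr) || !is.finite(vl)) {
      status <- "non_converged"
      break
    }
    if (vl < best$val) best <- list(val = vl, params = params, epoch = epoch)
  }
  structure(
    list(params = best$params, arch = arch, cfg = cfg,
         history = dplyr::bind_rows(hist), best_epoch = best$epoch,
         status = status),
    class = "mb_autoencoder"
  )
}

#' @exportS3Method base::print
print.mb_autoencoder <- function(x, ...) {
  vl <- if (x$best_epoch > 0L) x$history$val_loss[x$best_epoch] else NA_real_
  cat(sprintf("<mb_autoencoder> %s, %s, best epoch %d, val loss %.4g\n",
              paste(x$arch, collapse = "-"), x$status, x$best_epoch, vl))
  invisible(x)
}

#' @export
tidy.mb_autoencoder <- function(x, ...) {
  tidyr::pivot_longer(x$history, c("train_loss", "val_loss"),
                      names_to = "split", values_to = "loss") |>
    dplyr::mutate(split = sub("_loss$", "", .data$split))
}

#' @export
glance.mb_autoencoder <- function(x, ...) {
  tibble::tibble(
    architecture = paste(x$arch, collapse = "-"),
    n_params = ae_n_params(x$params),
    status = x$status,
    best_epoch = x$best_epoch,
    train_loss = if (x$best_epoch > 0L) x$history$train_loss[x$best_epoch] else NA_real_,
    val_loss = if (x$best_epoch > 0L) x$history$val_loss[x$best_epoch] else NA_real_
  )
}

#' @export
autoplot.mb_autoencoder <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$epoch, y = .data$loss,
                               colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss",
                  title = "Sparse autoencoder training trajectory") +
    ggplot2::theme_minimal()
}

#' Replace cohort profiles by their latent representation
#'
#' @param cohort An `mb_cohort` whose feature count equals the
#'   autoencoder's input size.
#' @param fit An `mb_autoencoder` (or a raw parameter list).
#' @return An `mb_cohort` whose profiles are the latent activations;
#'   sequence structure preserved.
#' @export
encode_latent <- function(cohort, fit) {
  params <- if (inherits(fit, "mb_autoencoder")) fit$params else fit
  d_in <- ncol(params$W[[1L]])
  if (length(cohort$features) != d_in) {
    abort(sprintf("cohort has %d features but the autoencoder expects %d",
                  length(cohort$features), d_in))
  }
  latent <- ae_forward(cohort$profiles, params)$latent
  colnames(latent) <- sprintf("latent_%02d", seq_len(ncol(latent)))
  rownames(latent) <- rownames(cohort$profiles)
  new_cohort(cohort$samples, latent)
}

#' Architecture grid search for the sparse autoencoder
#'
#' Trains one autoencoder per architecture and reports the best-epoch loss
#' on the train/validation/test splits, labelling non-finite runs as
#' non-convergent. The selected architecture is the converged one with the
#' smallest test loss, ties broken toward fewer parameters.
#'
#' @param train,val,test Samples-by-features matrices.
#' @param grid A list of hidden-layer size triples, e.g.
#'   `list(c(60, 25, 60), c(50, 15, 50))`.
#' @param cfg An [ae_config()].
#' @return A tibble with one row per architecture (`architecture`,
#'   `n_params`, `status`, `train_loss`, `val_loss`, `test_loss`,
#'   `selected`).
#' @export
architecture_grid_search <- function(train, val, test, grid, cfg = ae_config()) {
  if (length(grid) == 0L) abort("empty architecture grid")
  rows <- purrr::map(grid, function(hidden) {
    arch <- ae_architecture(ncol(train), hidden)
    fit <- train_autoencoder(train, val, arch, cfg)
    g <- glance(fit)
    g$test_loss <- if (fit$status == "converged") {
      ae_loss(test, fit$params, cfg)$total
    } else {
      NA_real_
    }
    g
  })
  out <- dplyr::bind_rows(rows)
  ok <- out$status == "converged" & is.finite(out$test_loss)
  out$selected <- FALSE
  if (any(ok)) {
    cand <- which(ok)
    best <- cand[order(out$test_loss[cand], out$n_params[cand])][1L]
    out$selected[best] <- TRUE
  }
  out
}
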