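# Multi-layer perceptron baseline: two ReLU hidden layers (128, 256),
# softmax head, inverted dropout (p = 0.5) during training, Adam, best
# epoch by validation loss. Operates on last-timepoint profiles.

#' MLP training configuration
#'
#' @param hidden Hidden-layer sizes (default `c(128, 256)`).
#' @param dropout Probability of dropping a hidden neuron during training
#'   (default 0.5; inference never drops).
#' @param learning_rate,batch_size,epochs Adam settings (defaults 0.001, 5, 50).
#' @param seed Integer seed.
#' @return A list of class `mlp_config`.
#' @export
mlp_config <- function(hidden = c(128L, 256L), dropout = 0.5,
                       learning_rate = 0.001, batch_size = 5L,
                       epochs = 50L, seed = 1L) {
  if (dropout < 0 || dropout >= 1) abort("dropout must be in [0, 1)")
  structure(list(hidden = as.integer(hidden), dropout = dropout,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "mlp_config")
}

mlp_init <- function(d, hidden, n_classes = 2L, seed = 1L) {
  set.seed(seed)
  sizes <- c(d, hidden, n_classes)
  m <- length(sizes) - 1L
  list(W = lapply(seq_len(m), function(l) init_uniform(sizes[l + 1L], sizes[l])),
       b = lapply(seq_len(m), function(l) rep(0, sizes[l + 1L])))
}

# Forward pass; masks is NULL (inference) or a list of inverted-dropout
# masks for the hidden layers.
mlp_forward <- function(X, params, masks = NULL) {
  m <- length(params$W)
  A <- X
  acts <- vector("list", m + 1L)
  pre <- vector("list", m)
  acts[[1L]] <- A
  for (l in seq_len(m)) {
    Z <- A %*% t(params$W[[l]]) +
      matrix(params$b[[l]], nrow(X), length(params$b[[l]]), byrow = TRUE)
    pre[[l]] <- Z
    A <- if (l < m) pmax(Z, 0) else Z
    if (l < m && !is.null(masks)) A <- A * masks[[l]]
    acts[[l + 1L]] <- A
  }
  list(logits = A, probs = softmax_rows(A), activations = acts, preacts = pre)
}

# Mean cross-entropy over the batch (y: 1-based class indices).
mlp_loss <- function(X, y, params, masks = NULL) {
  fw <- mlp_forward(X, params, masks)
  -mean(log(fw$probs[cbind(seq_along(y), y)]))
}

mlp_grad <- function(X, y, params, masks = NULL) {
  n <- nrow(X)
  fw <- mlp_forward(X, params, masks)
  m <- length(params$W)
  dW <- vector("list", m); db <- vector("list", m)
  dZ <- fw$probs
  dZ[cbind(seq_len(n), y)] <- dZ[cbind(seq_len(n), y)] - 1
  dZ <- dZ / n
  for (l in rev(seq_len(m))) {
    dW[[l]] <- t(dZ) %*% fw$activations[[l]]
    db[[l]] <- colSums(dZ)
    if (l > 1L) {
      dA <- dZ %*% params$W[[l]]
      if (!is.null(masks)) dA <- dA * masks[[l - 1L]]
      dZ <- dA * (fw$preacts[[l - 1L]] > 0)
    }
  }
  list(W = dW, b = db)
}

#' Train the MLP baseline
#'
#' @param X,y Training matrix (rows = subjects' last-timepoint profiles,
#'   already scaled) and 1-based integer class labels.
#' @param Xv,yv Validation split used for best-epoch selection (evaluated
#'   without dropout).
#' @param cfg An [mlp_config()].
#' @return A list of class `mb_mlp` with `params`, `cfg`, `history`, and
#'   `best_epoch`.
#' @export
train_mlp <- function(X, y, Xv, yv, cfg = mlp_config()) {
  set.seed(cfg$seed)
  params <- mlp_init(ncol(X), cfg$hidden, 2L, seed = cfg$seed)
  opt <- adam_init(lr = cfg$learning_rate)
  n <- nrow(X)
  keep <- 1 - cfg$dropout
  best <- list(val = Inf, params = params, epoch = 0L)
  hist <- vector("list", cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(n)
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      nb <- length(idx)
      masks <- if (cfg$dropout > 0) {
        lapply(cfg$hidden, function(hh) {
          matrix(rbinom(nb * hh, 1L, keep), nb, hh) / keep
        })
      }
      g <- mlp_grad(X[idx, , drop = FALSE], y[idx], params, masks)
      params <- adam_step(opt, params, g)
    }
    trl <- mlp_loss(X, y, params)
    vll <- mlp_loss(Xv, yv, params)
    if (!is.finite(trl) || !is.finite(vll)) {
      abort(sprintf("MLP training diverged at epoch %d", epoch))
    }
    hist[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = trl, val_loss = vll)
    if (vll < best$val) best <- list(val = vll, params = params, epoch = epoch)
  }
  structure(list(params = best$params, cfg = cfg,
                 history = dplyr::bind_rows(hist), best_epoch = best$epoch),
            class = "mb_mlp")
}

#' @export
predict.mb_mlp <- function(object, X, ...) {
  mlp_forward(X, object$params)$probs
}
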