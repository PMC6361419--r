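# LSTM sequence classifier with last-timepoint readout.
#
# Gate equations (sigmoid gates, tanh candidate/state squashing):
#   f_t = sigma(W_f x_t + U_f h_{t-1} + b_f)      forget gate
#   i_t = sigma(W_i x_t + U_i h_{t-1} + b_i)      input gate
#   c~  = tanh (W_c x_t + U_c h_{t-1} + b_c)      candidate state
#   C_t = f_t * C_{t-1} + i_t * c~                cell state (elementwise)
#   o_t = sigma(W_o x_t + U_o h_{t-1} + b_o)      output gate
#   h_t = o_t * tanh(C_t)                         hidden state
# The hidden state after the final timepoint feeds a linear dense head and
# a softmax; training minimizes summed cross-entropy at the last timepoint
# plus an L2 penalty on the input-to-gate matrices W_j, j in {f,i,c,o,z}.

GATES <- c("f", "i", "c", "o")

#' LSTM training configuration
#'
#' @param hidden_size Number of LSTM hidden units (default 64).
#' @param lambda L2 coefficient over the `W` matrices of the gates and the
#'   dense head (recurrent `U` matrices and biases are excluded; set
#'   `l2_include_u = TRUE` to include `U`).
#' @param learning_rate,batch_size,epochs Adam settings (defaults 0.001, 5,
#'   100; the best epoch is chosen by validation loss).
#' @param l2_include_u Also penalize the recurrent matrices (default FALSE).
#' @param seed Integer seed.
#' @return A list of class `lstm_config`.
#' @export
lstm_config <- function(hidden_size = 64L, lambda = 0.01,
                        learning_rate = 0.001, batch_size = 5L,
                        epochs = 100L, l2_include_u = FALSE, seed = 1L) {
  if (lambda < 0) abort("lambda must be >= 0")
  if (hidden_size < 1L) abort("hidden_size must be >= 1")
  structure(list(hidden_size = as.integer(hidden_size), lambda = lambda,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 l2_include_u = isTRUE(l2_include_u),
                 seed = as.integer(seed)),
            class = "lstm_config")
}

#' Initialize LSTM parameters
#'
#' Input-to-gate matrices get scaled-uniform init, recurrent matrices are
#' orthogonal, biases are zero except the forget-gate bias (1, the standard
#' stabilization).
#'
#' @param input_size Feature dimension of the inputs.
#' @param hidden_size Hidden units.
#' @param n_classes Output classes (default 2).
#' @param seed Integer seed.
#' @return Parameter list with `W`, `U`, `b` (one entry per gate
#'   `f, i, c, o`), dense head `Wz`, `bz`.
#' @export
lstm_init <- function(input_size, hidden_size = 64L, n_classes = 2L, seed = 1L) {
  set.seed(seed)
  W <- U <- b <- stats::setNames(vector("list", 4L), GATES)
  for (g in GATES) {
    W[[g]] <- init_uniform(hidden_size, input_size)
    U[[g]] <- init_orthogonal(hidden_size)
    b[[g]] <- rep(0, hidden_size)
  }
  b$f <- rep(1, hidden_size)
  list(W = W, U = U, b = b,
       Wz = init_uniform(n_classes, hidden_size), bz = rep(0, n_classes))
}

#' One LSTM cell step
#'
#' Applies the gate equations to a single timepoint.
#'
#' @param x_t Input vector at time t.
#' @param h_prev,C_prev Previous hidden and cell state vectors.
#' @param params Parameters from [lstm_init()].
#' @return A list with the updated `h` and `C`.
#' @export
lstm_cell_step <- function(x_t, h_prev, C_prev, params) {
  check_finite(c(x_t, h_prev, C_prev), "lstm_cell_step input")
  a <- lapply(GATES, function(g) {
    drop(params$W[[g]] %*% x_t + params$U[[g]] %*% h_prev) + params$b[[g]]
  })
  names(a) <- GATES
  f <- sigmoid(a$f); i <- sigmoid(a$i); o <- sigmoid(a$o)
  cand <- tanh(a$c)
  C <- f * C_prev + i * cand
  list(h = o * tanh(C), C = C)
}

#' Run an LSTM over one sequence and return the final hidden state
#'
#' Iterates [lstm_cell_step()] over the rows of `X` (timepoints in age
#' order) from zero initial states.
#'
#' @param X Timepoints-by-features matrix with at least one row.
#' @param params Parameters from [lstm_init()].
#' @return The final hidden state vector `h_last`.
#' @export
sequence_forward <- function(X, params) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (nrow(X) == 0L) abort("empty sequence")
  h <- rep(0, nrow(params$W$f))
  C <- h
  for (t in seq_len(nrow(X))) {
    st <- lstm_cell_step(X[t, ], h, C, params)
    h <- st$h; C <- st$C
  }
  h
}

#' Class probabilities from a final hidden state
#'
#' Linear dense head followed by softmax; the predicted class is the
#' arg-max.
#'
#' @param h_last Final hidden state vector.
#' @param params Parameters from [lstm_init()].
#' @return Probability vector over classes (sums to 1).
#' @export
predict_proba <- function(h_last, params) {
  softmax_vec(drop(params$Wz %*% h_last) + params$bz)
}

# --- batched forward/backward over variable-length sequences --------------

add_bias <- function(M, b) sweep(M, 2L, b, "+")

# Xs: list of T_i x d matrices. Returns h_last (B x h) and, if cache=TRUE,
# per-step quantities for backpropagation through time. The four gates are
# computed with one stacked matrix product per step (columns ordered
# f, i, o, c) to keep the per-timestep overhead low.
lstm_forward_batch <- function(Xs, params, cache = FALSE) {
  B <- length(Xs)
  lens <- vapply(Xs, nrow, integer(1))
  h <- nrow(params$W$f)
  tWall <- t(do.call(rbind, params$W[c("f", "i", "o", "c")]))
  tUall <- t(do.call(rbind, params$U[c("f", "i", "o", "c")]))
  ball <- c(params$b$f, params$b$i, params$b$o, params$b$c)
  cols <- lapply(0:3, function(k) k * h + seq_len(h))
  H <- matrix(0, B, h); C <- matrix(0, B, h)
  hlast <- matrix(0, B, h)
  steps <- if (cache) vector("list", max(lens)) else NULL
  for (t in seq_len(max(lens))) {
    idx <- which(lens >= t)
    Xt <- do.call(rbind, lapply(idx, function(bb) Xs[[bb]][t, ]))
    Hp <- H[idx, , drop = FALSE]; Cp <- C[idx, , drop = FALSE]
    A <- add_bias(Xt %*% tWall + Hp %*% tUall, ball)
    f <- sigmoid(A[, cols[[1L]], drop = FALSE])
    i <- sigmoid(A[, cols[[2L]], drop = FALSE])
    o <- sigmoid(A[, cols[[3L]], drop = FALSE])
    cand <- tanh(A[, cols[[4L]], drop = FALSE])
    Cn <- f * Cp + i * cand
    tC <- tanh(Cn)
    Hn <- o * tC
    H[idx, ] <- Hn; C[idx, ] <- Cn
    done <- lens[idx] == t
    if (any(done)) hlast[idx[done], ] <- Hn[done, , drop = FALSE]
    if (cache) {
      steps[[t]] <- list(idx = idx, Xt = Xt, Hp = Hp, Cp = Cp,
                         f = f, i = i, o = o, cand = cand, tC = tC)
    }
  }
  list(hlast = hlast, steps = steps, lens = lens)
}

lstm_l2 <- function(params, cfg) {
  s <- sum_rec(params$W, function(w) w^2) + sum(params$Wz^2)
  if (cfg$l2_include_u) s <- s + sum_rec(params$U, function(u) u^2)
  cfg$lambda * s
}

#' LSTM loss over a batch of labelled sequences
#'
#' Sum over subjects of the cross-entropy between the one-hot label and the
#' softmax output at the last timepoint, plus `lambda` times the summed
#' squared Frobenius norms of the `W` matrices of the four gates and the
#' dense head.
#'
#' @param Xs Non-empty list of timepoints-by-features matrices.
#' @param y Integer class indices (1-based), one per sequence.
#' @param params Parameters from [lstm_init()].
#' @param cfg An [lstm_config()].
#' @return A list with `total`, `ce`, and `l2`.
#' @export
lstm_loss <- function(Xs, y, params, cfg = lstm_config()) {
  if (length(Xs) == 0L) abort("empty batch")
  fw <- lstm_forward_batch(Xs, params)
  P <- softmax_rows(add_bias(fw$hlast %*% t(params$Wz), params$bz))
  ce <- -sum(log(P[cbind(seq_along(y), y)]))
  l2 <- lstm_l2(params, cfg)
  list(total = ce + l2, ce = ce, l2 = l2)
}

# Analytic gradient of lstm_loss via backpropagation through time.
# `ce_weight` scales the cross-entropy term (1 reproduces the summed loss;
# 1/B gives the mean-per-batch reduction used during training).
lstm_grad <- function(Xs, y, params, cfg = lstm_config(), ce_weight = 1) {
  B <- length(Xs)
  fw <- lstm_forward_batch(Xs, params, cache = TRUE)
  h <- nrow(params$W$f)
  Z <- add_bias(fw$hlast %*% t(params$Wz), params$bz)
  P <- softmax_rows(Z)
  dZ <- P
  dZ[cbind(seq_len(B), y)] <- dZ[cbind(seq_len(B), y)] - 1
  dZ <- dZ * ce_weight
  gWz <- t(dZ) %*% fw$hlast + 2 * cfg$lambda * params$Wz
  gbz <- colSums(dZ)
  dhlast <- dZ %*% params$Wz

  # stacked over the gates in f, i, o, c column order (as in the forward)
  Uall <- do.call(rbind, params$U[c("f", "i", "o", "c")]) # 4h x h
  d_in <- ncol(params$W$f)
  gWall <- matrix(0, 4L * h, d_in)
  gUall <- matrix(0, 4L * h, h)
  gball <- rep(0, 4L * h)
  dH <- matrix(0, B, h); dC <- matrix(0, B, h)
  for (t in rev(seq_along(fw$steps))) {
    st <- fw$steps[[t]]
    idx <- st$idx
    dHt <- dH[idx, , drop = FALSE]
    fin <- fw$lens[idx] == t
    if (any(fin)) {
      dHt[fin, ] <- dHt[fin, , drop = FALSE] + dhlast[idx[fin], , drop = FALSE]
    }
    dCt <- dC[idx, , drop = FALSE] + dHt * st$o * (1 - st$tC^2)
    do_ <- dHt * st$tC
    df <- dCt * st$Cp
    di <- dCt * st$cand
    dcand <- dCt * st$i
    da_all <- cbind(df * st$f * (1 - st$f),
                    di * st$i * (1 - st$i),
                    do_ * st$o * (1 - st$o),
                    dcand * (1 - st$cand^2))
    gWall <- gWall + crossprod(da_all, st$Xt)
    gUall <- gUall + crossprod(da_all, st$Hp)
    gball <- gball + colSums(da_all)
    dH[idx, ] <- da_all %*% Uall
    dC[idx, ] <- dCt * st$f
  }
  rows <- stats::setNames(lapply(0:3, function(k) k * h + seq_len(h)),
                          c("f", "i", "o", "c"))
  gW <- gU <- gb <- list()
  for (g in GATES) {
    gW[[g]] <- gWall[rows[[g]], , drop = FALSE] + 2 * cfg$lambda * params$W[[g]]
    gU[[g]] <- gUall[rows[[g]], , drop = FALSE]
    if (cfg$l2_include_u) gU[[g]] <- gU[[g]] + 2 * cfg$lambda * params$U[[g]]
    gb[[g]] <- gball[rows[[g]]]
  }
  list(W = gW[GATES], U = gU[GATES], b = gb[GATES], Wz = gWz, bz = gbz)
}

# Scale and split a cohort into a list of per-subject sequence matrices
# plus integer labels.
cohort_to_sequences <- function(cohort, scaler) {
  seqs <- cohort_sequences(cohort)
  Xs <- lapply(seqs, function(s) apply_scaler(s$X, scaler))
  y <- vapply(seqs, function(s) as.integer(s$label), integer(1))
  list(Xs = Xs, y = y, subject_ids = names(seqs))
}

#' Train the LSTM classifier on a longitudinal cohort
#'
#' Profiles are log(1+x)-transformed and z-scored per feature using
#' training-cohort statistics, then fed as variable-length age-ordered
#' sequences. Training uses minibatch Adam on the summed last-timepoint
#' cross-entropy with L2 regularization; the parameters from the epoch with
#' the lowest validation cross-entropy are kept (the constant-form L2 term
#' is excluded from model selection).
#'
#' @param train,val `mb_cohort` objects with identical features.
#' @param cfg An [lstm_config()].
#' @return An object of class `mb_lstm` with `params`, `scaler`, `cfg`,
#'   `history` (per-epoch train/val loss tibble), and `best_epoch`.
#' @export
train_lstm <- function(train, val, cfg = lstm_config()) {
  set.seed(cfg$seed)
  scaler <- fit_scaler(train$profiles)
  tr <- cohort_to_sequences(train, scaler)
  vl <- cohort_to_sequences(val, scaler)
  params <- lstm_init(length(train$features), cfg$hidden_size, 2L, seed = cfg$seed)
  opt <- adam_init(lr = cfg$learning_rate)
  n <- length(tr$Xs)
  best <- list(val = Inf, params = params, epoch = 0L)
  hist <- vector("list", cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(n)
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      # mean-per-batch cross-entropy (the conventional reduction), with the
      # L2 term at full strength
      g <- lstm_grad(tr$Xs[idx], tr$y[idx], params, cfg,
                     ce_weight = 1 / length(idx))
      params <- adam_step(opt, params, g)
    }
    trl <- lstm_loss(tr$Xs, tr$y, params, cfg)
    vll <- lstm_loss(vl$Xs, vl$y, params, cfg)
    if (!is.finite(trl$total) || !is.finite(vll$total)) {
      abort(sprintf("LSTM training diverged at epoch %d (non-finite loss)", epoch))
    }
    hist[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = trl$total,
                                    val_loss = vll$total, val_ce = vll$ce)
    # model selection on the validation cross-entropy: the L2 term is a
    # training-time regularizer and only biases the comparison of epochs
    if (vll$ce < best$val) best <- list(val = vll$ce, params = params, epoch = epoch)
  }
  structure(
    list(params = best$params, scaler = scaler, cfg = cfg,
         features = train$features, history = dplyr::bind_rows(hist),
         best_epoch = best$epoch),
    class = "mb_lstm"
  )
}

#' Predict allergy probabilities for the subjects of a cohort
#'
#' @param object An `mb_lstm` from [train_lstm()].
#' @param cohort An `mb_cohort` with the same features the model was
#'   trained on.
#' @param ... Unused.
#' @return A tibble with `subject_id`, `p_allergic` (softmax probability of
#'   the allergic class at the last timepoint), and `predicted`
#'   (arg-max label).
#' @export
predict.mb_lstm <- function(object, cohort, ...) {
  sq <- cohort_to_sequences(cohort, object$scaler)
  fw <- lstm_forward_batch(sq$Xs, object$params)
  P <- softmax_rows(add_bias(fw$hlast %*% t(object$params$Wz), object$params$bz))
  tibble::tibble(
    subject_id = sq$subject_ids,
    p_allergic = P[, 2L],
    predicted = factor(label_levels[max.col(P)], levels = label_levels)
  )
}

#' @exportS3Method base::print
print.mb_lstm <- function(x, ...) {
  cat(sprintf("<mb_lstm> %d features, %d hidden units, best epoch %d (val loss %.4f)\n",
              length(x$features), x$cfg$hidden_size, x$best_epoch,
              x$history$val_loss[x$best_epoch]))
  invisible(x)
}

#' @export
tidy.mb_lstm <- function(x, ...) {
  tidyr::pivot_longer(x$history, c("train_loss", "val_loss"),
                      names_to = "split", values_to = "loss") |>
    dplyr::mutate(split = sub("_loss$", "", .data$split))
}

#' @export
glance.mb_lstm <- function(x, ...) {
  tibble::tibble(
    hidden_size = x$cfg$hidden_size,
    n_features = length(x$features),
    best_epoch = x$best_epoch,
    train_loss = x$history$train_loss[x$best_epoch],
    val_loss = x$history$val_loss[x$best_epoch]
  )
}

#' @export
autoplot.mb_lstm <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$epoch, y = .data$loss,
                               colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::labs(x = "epoch", y = "loss",
                  title = "LSTM training trajectory") +
    ggplot2::theme_minimal()
}
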