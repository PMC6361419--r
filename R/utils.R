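# Shared numerical helpers: activations, input scaling, Adam optimizer,
# weight initializers. All stochastic code in the package draws from R's
# RNG after an explicit set.seed(), so results are reproducible per seed.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise softmax with max-shift for numerical stability.
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

softmax_vec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# log1p + per-feature z-scoring, fitted on training data only.
# Constant features get sd 1 so they map to a constant 0 column.
fit_scaler <- function(X) {
  L <- log1p(X)
  mu <- colMeans(L)
  s <- apply(L, 2L, sd)
  s[!is.finite(s) | s < 1e-8] <- 1
  list(mu = mu, sd = s)
}

apply_scaler <- function(X, scaler) {
  L <- log1p(X)
  sweep(sweep(L, 2L, scaler$mu, "-"), 2L, scaler$sd, "/")
}

# --- recursive helpers over (possibly nested) lists of numeric arrays ----

map_rec <- function(x, f) {
  if (is.list(x)) lapply(x, map_rec, f = f) else f(x)
}

map2_rec <- function(x, y, f) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- map2_rec(x[[i]], y[[i]], f)
    out
  } else {
    f(x, y)
  }
}

sum_rec <- function(x, f = identity) {
  if (is.list(x)) sum(vapply(x, sum_rec, numeric(1), f = f)) else sum(f(x))
}

# --- Adam -----------------------------------------------------------------

adam_init <- function(lr = 0.001, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps
  e$t <- 0L; e$m <- NULL; e$v <- NULL
  e
}

adam_step <- function(opt, params, grads) {
  if (is.null(opt$m)) {
    opt$m <- map_rec(params, function(x) x * 0)
    opt$v <- opt$m
  }
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  opt$m <- map2_rec(opt$m, grads, function(m, g) b1 * m + (1 - b1) * g)
  opt$v <- map2_rec(opt$v, grads, function(v, g) b2 * v + (1 - b2) * g * g)
  c1 <- 1 / (1 - b1^opt$t)
  c2 <- 1 / (1 - b2^opt$t)
  lr <- opt$lr; eps <- opt$eps
  upd <- map2_rec(opt$m, opt$v, function(m, v) lr * (m * c1) / (sqrt(v * c2) + eps))
  map2_rec(params, upd, function(p, u) p - u)
}

# --- initializers ---------------------------------------------------------

# Glorot-style scaled-uniform init.
init_uniform <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# Orthogonal init for recurrent matrices (QR of a Gaussian matrix).
init_orthogonal <- function(n) {
  q <- qr.Q(qr(matrix(rnorm(n * n), n, n)))
  q * sign(diag(q))[1L]
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    abort(sprintf("non-finite values in %s", what))
  }
  invisible(x)
}
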