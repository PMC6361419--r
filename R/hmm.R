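# First-order HMM with Gaussian-mixture emissions (diagonal covariance),
# trained unsupervised by EM (Baum-Welch) on variable-length sequences.
# Labels enter only afterwards, to pick the state -> phenotype mapping that
# maximizes training accuracy at the final timepoint.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Per-row log density under each (state, mixture) component.
# X: N x d, mu/var: lists [state][mixture] of d-vectors.
# Returns array N x S x M.
hmm_component_loglik <- function(X, mu, varr) {
  S <- length(mu); M <- length(mu[[1L]])
  N <- nrow(X); d <- ncol(X)
  out <- array(0, c(N, S, M))
  for (s in seq_len(S)) {
    for (m in seq_len(M)) {
      v <- varr[[s]][[m]]
      ctr <- sweep(X, 2L, mu[[s]][[m]], "-")
      out[, s, m] <- -0.5 * (sum(log(2 * pi * v)) +
                               rowSums(sweep(ctr^2, 2L, v, "/")))
    }
  }
  out
}

# State emission log-probabilities: logsumexp over mixtures of
# log(weight) + component loglik. Returns N x S.
hmm_emission_loglik <- function(comp_ll, logw) {
  N <- dim(comp_ll)[1L]; S <- dim(comp_ll)[2L]
  M <- dim(comp_ll)[3L]
  out <- matrix(0, N, S)
  for (s in seq_len(S)) {
    A <- sweep(matrix(comp_ll[, s, ], N, M), 2L, logw[s, ], "+")
    mx <- apply(A, 1L, max)
    out[, s] <- mx + log(rowSums(exp(A - mx)))
  }
  out
}

# Forward-backward for one sequence; logB: T x S emission logliks.
hmm_forward_backward <- function(logB, logpi, logA) {
  Tt <- nrow(logB); S <- ncol(logB)
  la <- matrix(-Inf, Tt, S); lb <- matrix(0, Tt, S)
  la[1L, ] <- logpi + logB[1L, ]
  if (Tt > 1L) {
    for (t in 2L:Tt) {
      for (s in seq_len(S)) {
        la[t, s] <- logB[t, s] + logsumexp(la[t - 1L, ] + logA[, s])
      }
    }
    for (t in (Tt - 1L):1L) {
      for (s in seq_len(S)) {
        lb[t, s] <- logsumexp(logA[s, ] + logB[t + 1L, ] + lb[t + 1L, ])
      }
    }
  }
  ll <- logsumexp(la[Tt, ])
  gamma <- exp(la + lb - ll)
  list(log_alpha = la, log_beta = lb, loglik = ll, gamma = gamma)
}

#' Train an HMM with Gaussian-mixture emissions
#'
#' Unsupervised Baum-Welch EM over variable-length sequences with
#' diagonal-covariance Gaussian-mixture emissions (default two states, four
#' mixture components per state, up to 100 iterations). After EM, the
#' state-to-phenotype mapping is chosen as the assignment with the highest
#' training accuracy at the final timepoint.
#'
#' @param seqs List of timepoints-by-features matrices (already scaled).
#' @param labels Factor of subject labels aligned with `seqs` (used only
#'   for the state mapping).
#' @param n_states,n_mixtures,n_iter EM settings (defaults 2, 4, 100).
#' @param var_floor Diagonal-variance floor guarding against degenerate
#'   components (default 1e-6).
#' @param tol Relative log-likelihood change for early stopping.
#' @param seed Integer seed for initialization.
#' @return An object of class `mb_hmm`.
#' @export
hmm_gmm_train <- function(seqs, labels, n_states = 2L, n_mixtures = 4L,
                          n_iter = 100L, var_floor = 1e-6, tol = 1e-8,
                          seed = 1L) {
  if (length(seqs) == 0L) abort("no sequences")
  set.seed(seed)
  X <- do.call(rbind, seqs)
  N <- nrow(X); d <- ncol(X)
  lens <- vapply(seqs, nrow, integer(1))
  seq_rows <- split(seq_len(N), rep(seq_along(seqs), lens))
  S <- n_states; M <- n_mixtures

  # init: k-means centers partitioned over states; pooled variances
  km <- tryCatch(
    kmeans(X, centers = min(S * M, N), nstart = 3L, iter.max = 50L),
    error = function(e) NULL
  )
  centers <- if (!is.null(km) && nrow(km$centers) == S * M) {
    km$centers
  } else {
    X[sample(N, S * M, replace = N < S * M), , drop = FALSE] +
      matrix(rnorm(S * M * d, sd = 0.01), S * M, d)
  }
  gvar <- pmax(apply(X, 2L, var), var_floor)
  mu <- lapply(seq_len(S), function(s) {
    lapply(seq_len(M), function(m) centers[(s - 1L) * M + m, ])
  })
  varr <- lapply(seq_len(S), function(s) lapply(seq_len(M), function(m) gvar))
  logw <- matrix(log(1 / M), S, M)
  logpi <- rep(log(1 / S), S)
  logA <- log(matrix(0.2 / (S - 1), S, S) + diag(0.8 - 0.2 / (S - 1), S))

  ll_trace <- numeric(0)
  prev_ll <- -Inf
  for (iter in seq_len(n_iter)) {
    comp_ll <- hmm_component_loglik(X, mu, varr)
    logB <- hmm_emission_loglik(comp_ll, logw)
    # accumulators
    acc_pi <- rep(0, S)
    acc_A <- matrix(0, S, S)
    gamma_all <- matrix(0, N, S)
    total_ll <- 0
    for (i in seq_along(seqs)) {
      rows <- seq_rows[[i]]
      fb <- hmm_forward_backward(logB[rows, , drop = FALSE], logpi, logA)
      total_ll <- total_ll + fb$loglik
      gamma_all[rows, ] <- fb$gamma
      acc_pi <- acc_pi + fb$gamma[1L, ]
      Tt <- length(rows)
      if (Tt > 1L) {
        for (t in seq_len(Tt - 1L)) {
          lx <- outer(fb$log_alpha[t, ], rep(1, S)) + logA +
            matrix(logB[rows[t + 1L], ] + fb$log_beta[t + 1L, ],
                   S, S, byrow = TRUE) - fb$loglik
          acc_A <- acc_A + exp(lx)
        }
      }
    }
    ll_trace <- c(ll_trace, total_ll)
    # mixture responsibilities r[n, s, m]
    for (s in seq_len(S)) {
      comp_s <- sweep(matrix(comp_ll[, s, ], N, M), 2L, logw[s, ], "+")
      r <- exp(comp_s - logB[, s]) * gamma_all[, s]
      wsum <- colSums(r)
      logw[s, ] <- log(pmax(wsum, 1e-300) / sum(pmax(wsum, 1e-300)))
      for (m in seq_len(M)) {
        rw <- r[, m]
        tot <- sum(rw)
        if (tot < 1e-10) next # starved component: keep previous parameters
        mu[[s]][[m]] <- colSums(X * rw) / tot
        ctr <- sweep(X, 2L, mu[[s]][[m]], "-")
        varr[[s]][[m]] <- pmax(colSums(ctr^2 * rw) / tot, var_floor)
      }
    }
    logpi <- log(pmax(acc_pi, 1e-300) / sum(pmax(acc_pi, 1e-300)))
    rs <- rowSums(acc_A)
    logA <- log(sweep(pmax(acc_A, 1e-300), 1L, pmax(rs, 1e-300), "/"))
    if (is.finite(prev_ll) &&
        abs(total_ll - prev_ll) < tol * (abs(prev_ll) + 1)) break
    prev_ll <- total_ll
  }

  model <- structure(
    list(logpi = logpi, logA = logA, logw = logw, mu = mu, varr = varr,
         n_states = S, n_mixtures = M, loglik = ll_trace,
         mapping = NULL),
    class = "mb_hmm"
  )
  model$mapping <- hmm_best_mapping(model, seqs, labels)
  model
}

# Posterior state probabilities at the final timepoint of one sequence.
hmm_final_posterior <- function(model, X) {
  comp_ll <- hmm_component_loglik(X, model$mu, model$varr)
  logB <- hmm_emission_loglik(comp_ll, model$logw)
  fb <- hmm_forward_backward(logB, model$logpi, model$logA)
  fb$gamma[nrow(X), ]
}

# Choose the state -> label assignment maximizing training accuracy of the
# final-timepoint posterior arg-max (all assignments tried; 2 for 2 states).
hmm_best_mapping <- function(model, seqs, labels) {
  states <- vapply(seqs, function(X) which.max(hmm_final_posterior(model, X)),
                   integer(1))
  perms <- list(label_levels, rev(label_levels))
  acc <- vapply(perms, function(pm) mean(pm[states] == as.character(labels)),
                numeric(1))
  perms[[which.max(acc)]]
}

#' Predict from a trained HMM-GMM
#'
#' The prediction for a sequence is the mapped label of the arg-max
#' posterior state at the final timepoint; the score is the posterior
#' probability mass of the allergic-mapped state(s). Set
#' `method = "viterbi"` to use the final state of the Viterbi path instead.
#'
#' @param object An `mb_hmm`.
#' @param seqs List of timepoints-by-features matrices.
#' @param method `"posterior"` (default) or `"viterbi"`.
#' @param ... Unused.
#' @return A tibble with `p_allergic` and `predicted`.
#' @export
predict.mb_hmm <- function(object, seqs, method = c("posterior", "viterbi"), ...) {
  method <- match.arg(method)
  allergic_states <- which(object$mapping == "allergic")
  rows <- lapply(seqs, function(X) {
    post <- hmm_final_posterior(object, X)
    score <- sum(post[allergic_states])
    state <- if (method == "viterbi") hmm_viterbi_final(object, X) else which.max(post)
    tibble::tibble(p_allergic = score,
                   predicted = factor(object$mapping[state], levels = label_levels))
  })
  dplyr::bind_rows(rows)
}

hmm_viterbi_final <- function(model, X) {
  comp_ll <- hmm_component_loglik(X, model$mu, model$varr)
  logB <- hmm_emission_loglik(comp_ll, model$logw)
  Tt <- nrow(logB); S <- ncol(logB)
  delta <- model$logpi + logB[1L, ]
  if (Tt > 1L) {
    for (t in 2L:Tt) {
      delta <- apply(delta + model$logA, 2L, max) + logB[t, ]
    }
  }
  which.max(delta)
}
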