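# Shared fixtures and independent oracles used across test files.

# Small abundance table + metadata written to temp files.
write_profile_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  prof <- data.frame(
    sample_id = c("s1", "s2", "s3"),
    Bacteroides = c(10.5, 0, 3.2),
    Bifidobacterium = c(1.1, 2.2, 3.3),
    Faecalibacterium = c(0, 0.4, 8),
    Escherichia = c(5, 5, 5)
  )
  path <- file.path(dir, "profiles.tsv")
  utils::write.table(prof, path, sep = "\t", row.names = FALSE, quote = FALSE)
  list(path = path, data = prof)
}

# Hand-built cohort: matrix plus metadata for filter tests.
make_meta_fixture <- function() {
  # subject A: 3 labelled + 1 unlabelled sample -> kept with 3 timepoints
  # subject B: 2 labelled samples -> dropped by the <3-timepoint filter
  # subject C: 4 labelled samples -> kept
  tibble::tibble(
    sample_id = sprintf("s%02d", 1:10),
    subject_id = c("A", "A", "A", "A", "B", "B", "C", "C", "C", "C"),
    age = c(100, 30, 200, 300, 10, 20, 5, 50, 500, 900),
    milk = c(0, 0, 0, NA, 0, 1, 0, 0, 0, 1),
    egg = c(0, 0, 1, 0, 0, 0, 0, 0, 0, 0),
    peanut = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0)
  )
}

make_profile_matrix <- function(sample_ids, n_features = 4L, seed = 42L) {
  set.seed(seed)
  m <- matrix(stats::rexp(length(sample_ids) * n_features),
              length(sample_ids), n_features)
  rownames(m) <- sample_ids
  colnames(m) <- paste0("g", seq_len(n_features))
  m
}

# Independent scalar-loop oracle of the LSTM gate equations (no reuse of
# package internals beyond the parameter container).
oracle_lstm_sequence <- function(X, params) {
  h <- rep(0, nrow(params$W$f))
  C <- h
  sig <- function(z) 1 / (1 + exp(-z))
  for (t in seq_len(nrow(X))) {
    x <- X[t, ]
    f <- i <- o <- cand <- numeric(length(h))
    for (j in seq_along(h)) {
      f[j] <- sig(sum(params$W$f[j, ] * x) + sum(params$U$f[j, ] * h) + params$b$f[j])
      i[j] <- sig(sum(params$W$i[j, ] * x) + sum(params$U$i[j, ] * h) + params$b$i[j])
      o[j] <- sig(sum(params$W$o[j, ] * x) + sum(params$U$o[j, ] * h) + params$b$o[j])
      cand[j] <- tanh(sum(params$W$c[j, ] * x) + sum(params$U$c[j, ] * h) + params$b$c[j])
    }
    C <- f * C + i * cand
    h <- o * tanh(C)
  }
  h
}

# Independent layer-by-layer oracle of the autoencoder forward pass.
oracle_ae_forward <- function(x, params) {
  a <- x
  for (l in seq_along(params$W)) {
    z <- as.numeric(params$W[[l]] %*% a) + params$b[[l]]
    a <- pmax(z, 0)
  }
  a
}

# Brute-force greedy mRMR (MID) oracle: re-evaluates the criterion for
# every candidate at every step using the package's MI estimator as the
# shared primitive but an independent selection loop.
oracle_mrmr <- function(X, y, k, n_bins = 10L) {
  p <- ncol(X)
  selected <- integer(0)
  for (step in seq_len(k)) {
    crit <- rep(-Inf, p)
    for (j in seq_len(p)) {
      if (j %in% selected) next
      rel <- estimate_mutual_information(X[, j], y, n_bins)
      red <- if (length(selected) == 0L) 0 else {
        mean(vapply(selected, function(s2) {
          estimate_mutual_information(X[, j], X[, s2], n_bins)
        }, numeric(1)))
      }
      crit[j] <- rel - red
    }
    # same tie convention as the implementation: round, lowest index wins
    selected <- c(selected, which.max(round(crit, 10L)))
  }
  selected
}

# Pair-counting auROC oracle: U / (n1 * n0) with ties counted 1/2.
oracle_auc_paircount <- function(scores, labels) {
  pos <- which(labels)
  neg <- which(!labels)
  u <- 0
  for (i in pos) for (j in neg) {
    u <- u + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  u / (length(pos) * length(neg))
}

# Central finite-difference gradient of f at params (flat walk over a
# nested list of arrays).
fd_gradient <- function(f, params, eps = 1e-6) {
  walk <- function(p, path) {
    if (is.list(p)) {
      for (nm in seq_along(p)) p[[nm]] <- walk(p[[nm]], c(path, nm))
      p
    } else {
      g <- p * 0
      for (i in seq_along(p)) {
        up <- dn <- params
        pluck_set <- function(obj, path, idx, val) {
          if (length(path) == 0L) {
            obj[idx] <- val
            obj
          } else {
            obj[[path[1L]]] <- pluck_set(obj[[path[1L]]], path[-1L], idx, val)
            obj
          }
        }
        up <- pluck_set(up, path, i, p[i] + eps)
        dn <- pluck_set(dn, path, i, p[i] - eps)
        g[i] <- (f(up) - f(dn)) / (2 * eps)
      }
      g
    }
  }
  walk(params, integer(0))
}

max_rel_err <- function(a, b) {
  num <- max(abs(unlist_rec(a) - unlist_rec(b)))
  num / max(abs(unlist_rec(b)), 1e-8)
}

unlist_rec <- function(x) unlist(x, use.names = FALSE)

# Tiny cohort with a planted, easily separable class difference.
make_separable_cohort <- function(n_subjects = 20L, n_features = 6L,
                                  timepoints = 3L, shift = 5, seed = 7L) {
  set.seed(seed)
  allergic <- rep(c(TRUE, FALSE), length.out = n_subjects)
  rows <- list()
  meta <- list()
  for (s in seq_len(n_subjects)) {
    for (t in seq_len(timepoints)) {
      x <- stats::rexp(n_features)
      if (allergic[s]) x[1L] <- x[1L] + shift
      rows[[length(rows) + 1L]] <- x
      meta[[length(meta) + 1L]] <- tibble::tibble(
        sample_id = sprintf("S%02d_t%d", s, t),
        subject_id = sprintf("S%02d", s), age = t * 100,
        label = ifelse(allergic[s], "allergic", "non_allergic"))
    }
  }
  meta <- dplyr::bind_rows(meta)
  m <- do.call(rbind, rows)
  rownames(m) <- meta$sample_id
  colnames(m) <- paste0("g", seq_len(n_features))
  meta$label <- factor(meta$label, levels = c("non_allergic", "allergic"))
  mblstm:::new_cohort(meta, m)
}
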