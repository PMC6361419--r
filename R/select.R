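# Feature selection: mutual information with equal-frequency binning,
# greedy mRMR (MID criterion), variance ranking, and column subsetting of
# cohorts. Ties are always broken toward the lowest feature index.

# Discretize into (up to) n_bins equal-frequency bins; constant vectors
# collapse to a single bin. Returns integer bin codes.
bin_equal_freq <- function(x, n_bins = 10L) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                        names = FALSE, type = 7))
  if (length(br) < 2L) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE, labels = FALSE))
}

# Plug-in MI (nats) between two integer code vectors.
mi_from_codes <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / (px[row(p)[nz]] * py[col(p)[nz]])))
}

#' Plug-in mutual information between a feature and a (possibly binary) target
#'
#' The continuous vector is discretized into equal-frequency bins; the
#' target is used as-is when it has at most `n_bins` distinct values and is
#' binned identically otherwise. Returns the plug-in estimate of mutual
#' information in nats (non-negative; 0 for a constant feature).
#'
#' @param x Numeric feature vector.
#' @param y Target vector (binary labels or a second continuous feature).
#' @param n_bins Number of equal-frequency bins (default 10).
#' @return Non-negative mutual information in nats.
#' @export
estimate_mutual_information <- function(x, y, n_bins = 10L) {
  if (length(x) != length(y)) abort("x and y must have the same length")
  if (length(x) < 2L) abort("need at least 2 observations")
  xb <- bin_equal_freq(x, n_bins)
  yb <- if (length(unique(y)) <= n_bins) as.integer(factor(y)) else bin_equal_freq(y, n_bins)
  max(0, mi_from_codes(xb, yb))
}

new_selection <- function(method, indices, scores, feature_names, k) {
  structure(
    list(method = method, k = k,
         indices = as.integer(indices), scores = as.numeric(scores),
         feature_names = feature_names),
    class = "mb_selection"
  )
}

#' @exportS3Method base::print
print.mb_selection <- function(x, ...) {
  cat(sprintf("<mb_selection> method=%s, k=%d\n", x$method, length(x$indices)))
  print(utils::head(tidy(x), 10L))
  invisible(x)
}

#' @export
tidy.mb_selection <- function(x, ...) {
  tibble::tibble(rank = seq_along(x$indices), index = x$indices,
                 feature = x$feature_names, score = x$scores,
                 method = x$method)
}

#' Minimum-redundancy maximum-relevance (mRMR) feature selection
#'
#' Greedy forward selection under the MID criterion: the first feature
#' maximizes `MI(f; y)`; each subsequent feature maximizes
#' `MI(f; y) - mean over selected s of MI(f; s)`. Mutual information uses
#' the plug-in equal-frequency-binning estimator of
#' [estimate_mutual_information()]. Ties break toward the lowest index.
#'
#' @param X Samples-by-features numeric matrix.
#' @param y Binary label vector, one per row of `X`.
#' @param k Number of features to select (default 25).
#' @param n_bins Bins for the MI estimator (default 10).
#' @return An `mb_selection` with `indices` in selection order and the
#'   greedy criterion value of each pick in `scores`.
#' @export
mrmr_select <- function(X, y, k = 25L, n_bins = 10L) {
  p <- ncol(X)
  if (k > p) abort("k must be <= number of features")
  if (nrow(X) < 2L) abort("need at least 2 samples")
  if (length(y) != nrow(X)) abort("y must align with rows of X")
  codes <- lapply(seq_len(p), function(j) bin_equal_freq(X[, j], n_bins))
  yb <- as.integer(factor(y))
  relevance <- vapply(codes, function(cj) mi_from_codes(cj, yb), numeric(1))

  selected <- integer(0)
  scores <- numeric(0)
  red_sum <- numeric(p) # running sum of MI(f; s) over selected s
  for (step in seq_len(k)) {
    crit <- if (length(selected) == 0L) relevance else relevance - red_sum / length(selected)
    crit[selected] <- -Inf
    # rounding guards the lowest-index tie-break against float jitter in
    # otherwise exactly tied binned-MI criteria
    pick <- which.max(round(crit, 10L))
    selected <- c(selected, pick)
    scores <- c(scores, crit[pick])
    if (step < k) {
      upd <- setdiff(seq_len(p), selected)
      red_sum[upd] <- red_sum[upd] +
        vapply(upd, function(j) mi_from_codes(codes[[j]], codes[[pick]]), numeric(1))
    }
  }
  new_selection("mrmr", selected, scores, colnames(X)[selected] %||% as.character(selected), k)
}

#' Top-k most variable features
#'
#' Selects the `k` features with the largest sample variance, in descending
#' order; ties break toward the lowest index.
#'
#' @inheritParams mrmr_select
#' @return An `mb_selection` with variances as `scores`.
#' @export
variance_select <- function(X, k = 25L) {
  p <- ncol(X)
  if (k > p) abort("k must be <= number of features")
  v <- apply(X, 2L, var)
  ord <- order(-v, seq_len(p))[seq_len(k)]
  new_selection("variance", ord, v[ord], colnames(X)[ord] %||% as.character(ord), k)
}

#' Pass-through (raw) selection
#'
#' @param X Samples-by-features matrix.
#' @return An `mb_selection` retaining all features in original order.
#' @export
raw_select <- function(X) {
  p <- ncol(X)
  new_selection("raw", seq_len(p), rep(NA_real_, p),
                colnames(X) %||% as.character(seq_len(p)), p)
}

#' Restrict a cohort to selected features
#'
#' @param cohort An `mb_cohort`.
#' @param selection An `mb_selection` computed on a matrix with the same
#'   feature set.
#' @return An `mb_cohort` whose profile columns are restricted and
#'   reordered to the selection; sequence structure unchanged.
#' @export
apply_selection <- function(cohort, selection) {
  if (max(selection$indices) > length(cohort$features)) {
    abort("selection indices out of range for this cohort")
  }
  if (!is.null(selection$feature_names) && !all(is.na(selection$scores)) &&
      !all(selection$feature_names %in% c(cohort$features, as.character(selection$indices)))) {
    abort("selection was computed on a different feature set")
  }
  new_cohort(cohort$samples, cohort$profiles[, selection$indices, drop = FALSE])
}
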