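#' Simulation configuration for synthetic longitudinal cohorts
#'
#' The generator emulates the structure of a three-country infant
#' gut-microbiome cohort: ~215 genus-level features, ~150 subjects with
#' 3-10 stool samples each at irregular ages between birth and 3 years,
#' class imbalance near 52:96 allergic:non-allergic, compositional
#' abundance structure, and a class-dependent temporal signal in a small
#' subset of genera.
#'
#' Each subject draws a baseline composition from a Dirichlet distribution
#' around a power-law rank-abundance template (between-subject
#' heterogeneity); allergic subjects add a log-linear age-dependent slope
#' (`signal_effect * age/max_age`) to the signal features. Each sample then
#' adds independent log-normal jitter (sd `sample_sigma`) to the
#' subdominant (low-abundance) half of the features, emulating the
#' order-of-magnitude day-to-day fluctuation and intermittent detection of
#' rare gut genera, while the dominant community remains stable. A model
#' reading only the last timepoint faces that single-draw noise at full
#' strength, whereas a sequence model can pool it over the trajectory --
#' the temporal structure this framework assumes. Counts are drawn
#' multinomially at a sequencing depth from `depth_range` and
#' RPKM-normalized with 1-kb genome lengths.
#'
#' @param n_subjects Number of subjects (default 148).
#' @param class_balance Fraction of allergic subjects (default 52/148).
#' @param n_features Number of genus features (default 215).
#' @param timepoints_range Integer `c(min, max)` samples per subject;
#'   minimum must be >= 3 (default `c(3, 10)`).
#' @param age_range Collection-age range in days (default `c(0, 1095)`).
#' @param n_signal_features Number of genera carrying the class signal
#'   (default 5); drawn from the low-abundance half of the template so the
#'   signal is low-variance.
#' @param signal_effect Log-scale slope of the class-dependent signal at
#'   `max(age_range)` (default 2).
#' @param dispersion Mean per-feature Dirichlet concentration of the
#'   between-subject baseline draw (concentration vector
#'   `dispersion * n_features * template`); smaller means more individual
#'   baselines. The default 20 gives a log-scale baseline sd around 0.6
#'   for the rare tail.
#' @param sample_sigma Log-scale sd of the independent per-sample jitter
#'   on the subdominant half of the features (default 3: rare genera
#'   fluctuate over orders of magnitude between stools).
#' @param depth_range Sequencing-depth range, reads per sample
#'   (default `c(5e4, 2e5)`).
#' @param seed Integer seed; all randomness derives from it.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 148L,
                       class_balance = 52 / 148,
                       n_features = 215L,
                       timepoints_range = c(3L, 10L),
                       age_range = c(0, 1095),
                       n_signal_features = 5L,
                       signal_effect = 2,
                       dispersion = 20,
                       sample_sigma = 3,
                       depth_range = c(5e4, 2e5),
                       seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), class_balance = class_balance,
    n_features = as.integer(n_features),
    timepoints_range = as.integer(timepoints_range),
    age_range = as.numeric(age_range),
    n_signal_features = as.integer(n_signal_features),
    signal_effect = signal_effect, dispersion = dispersion,
    sample_sigma = sample_sigma,
    depth_range = depth_range, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$timepoints_range[1L] < 3L) abort("timepoints_range minimum must be >= 3")
  if (cfg$timepoints_range[2L] < cfg$timepoints_range[1L]) abort("invalid timepoints_range")
  if (cfg$class_balance <= 0 || cfg$class_balance >= 1) abort("class_balance must be in (0, 1)")
  if (cfg$n_signal_features > cfg$n_features) abort("n_signal_features must be <= n_features")
  if (cfg$signal_effect < 0) abort("signal_effect must be >= 0")
  if (cfg$dispersion <= 0) abort("dispersion must be positive")
  if (cfg$sample_sigma < 0) abort("sample_sigma must be >= 0")
  if (any(cfg$depth_range <= 0) || cfg$depth_range[2L] < cfg$depth_range[1L]) {
    abort("invalid depth_range")
  }
  invisible(cfg)
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = pmax(alpha, 1e-12), rate = 1)
  if (sum(g) == 0) g <- g + 1e-12
  g / sum(g)
}

# Power-law rank-abundance template shared by all subjects.
sim_template <- function(n_features) {
  t <- (seq_len(n_features))^(-1)
  t / sum(t)
}

# Composition of one sample before count sampling: subject baseline, the
# class x age log-linear effect on the signal features, and independent
# log-normal jitter on the subdominant feature set.
sim_sample_composition <- function(baseline, age, max_age, signal_idx,
                                   signal_effect, allergic,
                                   subdominant_idx = integer(0),
                                   jitter = numeric(0)) {
  l <- log(baseline)
  if (allergic && signal_effect > 0 && length(signal_idx)) {
    l[signal_idx] <- l[signal_idx] + signal_effect * age / max_age
  }
  if (length(subdominant_idx)) {
    l[subdominant_idx] <- l[subdominant_idx] + jitter
  }
  e <- exp(l - max(l))
  e / sum(e)
}

#' Simulate a synthetic longitudinal cohort with a planted temporal signal
#'
#' @param config A [sim_config()].
#' @return A list with `cohort` (an `mb_cohort`) and `truth` (a list with
#'   `signal_features` indices, per-subject `classes`, and the generating
#'   config).
#' @seealso [simulate_null_cohort()]
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  p <- config$n_features
  template <- sim_template(p)
  # plant the signal in the low-abundance half -> low-variance features
  low_half <- which(rank(template, ties.method = "first") <= p / 2)
  signal_idx <- sort(sample(low_half, config$n_signal_features))
  max_age <- config$age_range[2L]

  classes <- rbinom(config$n_subjects, 1L, config$class_balance) == 1L
  subject_ids <- sprintf("S%03d", seq_len(config$n_subjects))

  rows <- list()
  meta <- list()
  for (s in seq_len(config$n_subjects)) {
    baseline <- rdirichlet1(config$dispersion * p * template)
    baseline <- pmax(baseline, 1e-12)
    n_t <- sample(seq(config$timepoints_range[1L], config$timepoints_range[2L]), 1L)
    ages <- sort(runif(n_t, config$age_range[1L], config$age_range[2L]))
    for (t in seq_len(n_t)) {
      comp <- sim_sample_composition(
        baseline, ages[t], max_age, signal_idx,
        config$signal_effect, classes[s],
        subdominant_idx = low_half,
        jitter = rnorm(length(low_half), 0, config$sample_sigma))
      depth <- round(runif(1L, config$depth_range[1L], config$depth_range[2L]))
      counts <- as.numeric(rmultinom(1L, depth, comp))
      rows[[length(rows) + 1L]] <- counts
      meta[[length(meta) + 1L]] <- tibble::tibble(
        sample_id = sprintf("%s_t%02d", subject_ids[s], t),
        subject_id = subject_ids[s], age = ages[t],
        label = ifelse(classes[s], "allergic", "non_allergic")
      )
    }
  }
  counts <- do.call(rbind, rows)
  meta <- dplyr::bind_rows(meta)
  rownames(counts) <- meta$sample_id
  colnames(counts) <- sprintf("genus_%03d", seq_len(p))
  # RPKM with 1-kb genome lengths: value = count / (depth / 1e6)
  values <- normalize_rpkm(counts, genome_lengths = rep(1e3, p),
                           library_sizes = rowSums(counts))
  meta$label <- factor(meta$label, levels = label_levels)
  cohort <- new_cohort(meta, values)
  attr(cohort, "seed") <- config$seed
  truth <- list(
    signal_features = signal_idx,
    signal_feature_names = colnames(counts)[signal_idx],
    classes = stats::setNames(classes, subject_ids),
    config = config
  )
  list(cohort = cohort, truth = truth)
}

#' Simulate a null cohort (no class signal, labels independent of data)
#'
#' Equivalent to [simulate_cohort()] with `signal_effect = 0` and subject
#' labels re-drawn independently of the abundance data. Any classifier's
#' test auROC on such a cohort should hover around 0.5.
#'
#' @param config A [sim_config()].
#' @return An `mb_cohort`.
#' @export
simulate_null_cohort <- function(config = sim_config()) {
  config$signal_effect <- 0
  sim <- simulate_cohort(config)
  cohort <- sim$cohort
  labs <- subject_labels(cohort)
  perm <- sample(nrow(labs))
  new_lab <- stats::setNames(as.character(labs$label)[perm], labs$subject_id)
  cohort$samples$label <- factor(new_lab[cohort$samples$subject_id],
                                 levels = label_levels)
  attr(cohort, "seed") <- config$seed
  cohort
}
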