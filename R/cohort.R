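#' Read a taxonomic profile table
#'
#' Reads a delimited samples-by-genera abundance table (RPKM-normalized,
#' non-negative) with sample identifiers in the first column and genus names
#' in the header row. Orientation can be flipped for tables stored
#' genera-by-samples.
#'
#' @param path Path to a TSV or CSV file. The delimiter is taken from the
#'   file extension (`.csv` comma, otherwise tab) unless `delim` is given.
#' @param orientation `"samples_rows"` (default) or `"features_rows"`.
#' @param delim Optional field delimiter overriding the extension heuristic.
#'
#' @return A numeric matrix (samples in rows, genus features in columns)
#'   with sample IDs as row names and genus names as column names.
#' @export
read_profile_table <- function(path,
                               orientation = c("samples_rows", "features_rows"),
                               delim = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- tryCatch(
    readr::read_delim(path, delim = delim, col_types = readr::cols(),
                      progress = FALSE, show_col_types = FALSE),
    error = function(e) abort(sprintf("failed to parse %s: %s", path, conditionMessage(e)))
  )
  if (nrow(df) == 0L || ncol(df) < 2L) {
    abort(sprintf("profile table %s is empty or has no feature columns", path))
  }
  ids <- as.character(df[[1L]])
  num <- df[-1L]
  bad <- !vapply(num, is.numeric, logical(1))
  if (any(bad)) {
    abort(sprintf("non-numeric abundance column(s): %s",
                  paste(names(num)[bad], collapse = ", ")))
  }
  values <- as.matrix(num)
  rownames(values) <- ids
  if (orientation == "features_rows") values <- t(values)
  validate_profile_matrix(values)
  values
}

validate_profile_matrix <- function(values, nonneg = TRUE) {
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    abort(sprintf("missing/unparseable abundance at row '%s', column '%s'",
                  rownames(values)[idx[1L]], colnames(values)[idx[2L]]))
  }
  if (nonneg && any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1L, ]
    abort(sprintf("negative abundance at row '%s', column '%s'",
                  rownames(values)[idx[1L]], colnames(values)[idx[2L]]))
  }
  if (anyDuplicated(rownames(values))) abort("duplicate sample IDs in profile table")
  if (anyDuplicated(colnames(values))) abort("duplicate feature names in profile table")
  invisible(values)
}

#' Derive the food-allergy label from per-allergen flags
#'
#' A subject (or sample) is labelled allergic if it is allergic to milk,
#' egg, or peanut. The OR is three-valued: any `TRUE` flag gives
#' `"allergic"` regardless of missing flags; all-`FALSE` gives
#' `"non_allergic"`; otherwise (no `TRUE`, at least one missing) the label
#' cannot be determined and is `NA`.
#'
#' @param milk,egg,peanut Logical (or 0/1) vectors; `NA` marks a missing
#'   measurement.
#'
#' @return A factor with levels `non_allergic`, `allergic`; `NA` where the
#'   label cannot be derived.
#' @export
derive_allergy_label <- function(milk, egg, peanut) {
  flags <- cbind(as.logical(milk), as.logical(egg), as.logical(peanut))
  any_true <- rowSums(flags, na.rm = TRUE) > 0
  any_missing <- rowSums(is.na(flags)) > 0
  out <- ifelse(any_true, "allergic",
                ifelse(any_missing, NA_character_, "non_allergic"))
  factor(out, levels = c("non_allergic", "allergic"))
}

label_levels <- c("non_allergic", "allergic")

#' Assemble a longitudinal cohort from a profile table and sample metadata
#'
#' Applies the preprocessing rules of the framework: samples without a
#' food-allergy label are removed first, then subjects left with fewer than
#' `min_timepoints` samples are dropped entirely. Each remaining subject's
#' profiles are ordered by collection age; the subject-level label is the
#' label of the last timepoint.
#'
#' @param profiles Numeric matrix as returned by [read_profile_table()].
#' @param meta Data frame with columns `sample_id`, `subject_id`, `age`
#'   (days; `age_days` also accepted), optionally `country`, and either a
#'   `label` column (`allergic`/`non_allergic`/`NA`) or per-allergen flag
#'   columns `milk`, `egg`, `peanut` (1/0/NA).
#' @param min_timepoints Minimum number of labelled samples a subject must
#'   retain (default 3).
#'
#' @return An object of class `mb_cohort`: a list with a `samples` tibble
#'   (`sample_id`, `subject_id`, `age`, `label`, optional `country`), the
#'   profile matrix row-aligned to `samples`, the feature names, and the
#'   filter counts. See [cohort_sequences()] for the per-subject view.
#' @export
assemble_cohort <- function(profiles, meta, min_timepoints = 3L) {
  validate_profile_matrix(profiles)
  meta <- tibble::as_tibble(meta)
  if (!is.null(meta[["age_days"]]) && is.null(meta[["age"]])) {
    meta$age <- meta$age_days
  }
  req <- c("sample_id", "subject_id", "age")
  miss <- setdiff(req, names(meta))
  if (length(miss)) abort(paste("metadata is missing column(s):", paste(miss, collapse = ", ")))
  meta$sample_id <- as.character(meta$sample_id)
  meta$subject_id <- as.character(meta$subject_id)
  if (any(meta$age < 0, na.rm = TRUE)) abort("negative collection age in metadata")
  unknown <- setdiff(meta$sample_id, rownames(profiles))
  if (length(unknown)) {
    abort(sprintf("metadata references sample IDs absent from the profile table: %s",
                  paste(head(unknown, 5L), collapse = ", ")))
  }
  if (is.null(meta[["label"]])) {
    flg <- setdiff(c("milk", "egg", "peanut"), names(meta))
    if (length(flg)) {
      abort("metadata needs either a 'label' column or milk/egg/peanut flag columns")
    }
    meta$label <- derive_allergy_label(meta$milk, meta$egg, meta$peanut)
  } else {
    meta$label <- factor(as.character(meta$label), levels = label_levels)
  }

  n_input <- nrow(meta)
  labelled <- dplyr::filter(meta, !is.na(.data$label))
  n_missing <- n_input - nrow(labelled)
  counts <- dplyr::count(labelled, .data$subject_id)
  keep_subj <- counts$subject_id[counts$n >= min_timepoints]
  kept <- dplyr::filter(labelled, .data$subject_id %in% keep_subj)
  n_short <- nrow(labelled) - nrow(kept)
  if (nrow(kept) == 0L) abort("no samples left after filtering")

  kept <- dplyr::arrange(kept, .data$subject_id, .data$age, .data$sample_id)
  tied <- kept |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(tie = anyDuplicated(.data$age) > 0L) |>
    dplyr::filter(.data$tie)
  if (nrow(tied)) {
    warning(sprintf("tied collection ages within subject(s) %s; stable (age, sample_id) order used",
                    paste(tied$subject_id, collapse = ", ")), call. = FALSE)
  }

  keep_cols <- intersect(c("sample_id", "subject_id", "age", "country", "label"), names(kept))
  new_cohort(
    samples = kept[keep_cols],
    profiles = profiles[kept$sample_id, , drop = FALSE],
    filter_counts = list(
      n_input_samples = n_input,
      n_dropped_missing_label = n_missing,
      n_dropped_short_subject = n_short,
      n_kept_samples = nrow(kept)
    )
  )
}

# Low-level constructor; samples must already be sorted by (subject, age).
# Derived cohorts (scaled or latent features) may carry negative values, so
# non-negativity is enforced only at the raw-abundance entry points.
new_cohort <- function(samples, profiles, filter_counts = NULL) {
  stopifnot(nrow(samples) == nrow(profiles))
  validate_profile_matrix(profiles, nonneg = FALSE)
  structure(
    list(
      samples = tibble::as_tibble(samples),
      profiles = profiles,
      features = colnames(profiles),
      filter_counts = filter_counts
    ),
    class = "mb_cohort"
  )
}

#' @exportS3Method base::print
print.mb_cohort <- function(x, ...) {
  labs <- subject_labels(x)
  cat(sprintf("<mb_cohort> %d samples, %d subjects (%d allergic), %d features\n",
              nrow(x$samples), nrow(labs), sum(labs$label == "allergic"),
              length(x$features)))
  invisible(x)
}

#' Subject-level labels of a cohort
#'
#' The subject label is the label recorded at the subject's last timepoint.
#'
#' @param cohort An `mb_cohort`.
#' @return A tibble with columns `subject_id` and `label`.
#' @export
subject_labels <- function(cohort) {
  cohort$samples |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::slice_tail(n = 1L) |>
    dplyr::ungroup() |>
    dplyr::select("subject_id", "label")
}

#' Per-subject sequence view of a cohort
#'
#' @param cohort An `mb_cohort`.
#' @return A named list (one element per subject) of lists with fields
#'   `X` (timepoints-by-features profile matrix, age-ordered), `ages`, and
#'   `label`.
#' @export
cohort_sequences <- function(cohort) {
  idx <- split(seq_len(nrow(cohort$samples)), cohort$samples$subject_id)
  lapply(idx, function(i) {
    list(
      X = cohort$profiles[i, , drop = FALSE],
      ages = cohort$samples$age[i],
      label = cohort$samples$label[i][length(i)]
    )
  })
}

#' Restrict a cohort to a set of subjects
#'
#' @param cohort An `mb_cohort`.
#' @param subject_ids Character vector of subject IDs to keep.
#' @return An `mb_cohort` with only those subjects, sample order preserved.
#' @export
subset_cohort <- function(cohort, subject_ids) {
  keep <- cohort$samples$subject_id %in% subject_ids
  if (!any(keep)) abort("no samples match the requested subjects")
  new_cohort(cohort$samples[keep, , drop = FALSE],
             cohort$profiles[keep, , drop = FALSE])
}

#' @export
as_tibble.mb_cohort <- function(x, ...) {
  dplyr::bind_cols(x$samples, tibble::as_tibble(x$profiles))
}

#' RPKM normalization of a read-count matrix
#'
#' Reads per kilobase of genome per million sample reads:
#' `count / (genome_length/1e3) / (library_size/1e6)`.
#'
#' @param counts Samples-by-features matrix of non-negative read counts.
#' @param genome_lengths Per-feature genome lengths in base pairs
#'   (strictly positive).
#' @param library_sizes Per-sample total read counts (strictly positive).
#' @return Matrix of RPKM values, same dimnames as `counts`.
#' @export
normalize_rpkm <- function(counts, genome_lengths, library_sizes) {
  if (length(genome_lengths) != ncol(counts)) abort("genome_lengths length must equal ncol(counts)")
  if (length(library_sizes) != nrow(counts)) abort("library_sizes length must equal nrow(counts)")
  if (any(genome_lengths <= 0)) abort("genome lengths must be strictly positive")
  if (any(library_sizes <= 0)) abort("library sizes must be strictly positive")
  out <- sweep(counts, 2L, genome_lengths / 1e3, "/")
  sweep(out, 1L, library_sizes / 1e6, "/")
}

#' Write / read a cohort directory
#'
#' A cohort is serialized as plain text: `profiles.tsv` (samples x
#' features), `samples.tsv` (metadata), and `manifest.json` (feature order,
#' filter counts, optional simulation seed).
#'
#' @param cohort An `mb_cohort`.
#' @param dir Directory to create/read.
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns
#'   an `mb_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prof <- tibble::as_tibble(cohort$profiles)
  prof <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(cohort$profiles)), prof)
  readr::write_tsv(prof, file.path(dir, "profiles.tsv"))
  readr::write_tsv(cohort$samples, file.path(dir, "samples.tsv"))
  manifest <- list(
    features = cohort$features,
    filter_counts = cohort$filter_counts,
    seed = attr(cohort, "seed")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  prof <- read_profile_table(file.path(dir, "profiles.tsv"))
  samples <- readr::read_tsv(file.path(dir, "samples.tsv"),
                             col_types = readr::cols(), progress = FALSE,
                             show_col_types = FALSE)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  samples$sample_id <- as.character(samples$sample_id)
  samples$subject_id <- as.character(samples$subject_id)
  samples$label <- factor(as.character(samples$label), levels = label_levels)
  feats <- unlist(manifest$features)
  new_cohort(samples, prof[samples$sample_id, feats, drop = FALSE],
             filter_counts = manifest$filter_counts)
}
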