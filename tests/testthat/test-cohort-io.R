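test_that("profile tables round-trip through TSV with validation", {
  fx <- write_profile_fixture()
  tab <- read_profile_table(fx$path)
  expect_equal(dim(tab), c(3L, 4L))
  expect_equal(rownames(tab), c("s1", "s2", "s3"))
  expect_equal(tab["s1", "Bacteroides"], 10.5)

  # negative abundance -> validation error naming the cell
  bad <- fx$data
  bad$Bacteroides[2] <- -1
  path <- file.path(dirname(fx$path), "neg.tsv")
  utils::write.table(bad, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_profile_table(path), "negative abundance.*s2",
               ignore.case = TRUE)

  # empty file -> parse error
  empty <- file.path(dirname(fx$path), "empty.tsv")
  file.create(empty)
  expect_error(read_profile_table(empty), "parse|empty")

  # duplicate sample IDs -> validation error
  dup <- fx$data
  dup$sample_id <- c("s1", "s1", "s3")
  path2 <- file.path(dirname(fx$path), "dup.tsv")
  utils::write.table(dup, path2, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_profile_table(path2), "duplicate")
})

test_that("allergy label derivation implements the three-valued OR", {
  # exhaustive truth table over {TRUE, FALSE, NA}^3 against an independent
  # three-valued OR oracle
  vals <- c(TRUE, FALSE, NA)
  grid <- expand.grid(milk = vals, egg = vals, peanut = vals)
  got <- derive_allergy_label(grid$milk, grid$egg, grid$peanut)
  oracle <- apply(grid, 1, function(r) {
    if (isTRUE(any(unlist(r)))) return("allergic")
    if (anyNA(unlist(r))) return(NA_character_)
    "non_allergic"
  })
  expect_equal(as.character(got), oracle)
  # the printed rule: allergic to milk OR egg OR peanut
  expect_equal(as.character(derive_allergy_label(TRUE, FALSE, FALSE)), "allergic")
  expect_equal(as.character(derive_allergy_label(NA, FALSE, FALSE)), NA_character_)
})

test_that("cohort assembly applies the label filter then the timepoint filter", {
  meta <- make_meta_fixture()
  prof <- make_profile_matrix(meta$sample_id)
  co <- suppressWarnings(assemble_cohort(prof, meta, min_timepoints = 3))
  labs <- subject_labels(co)
  # B (2 labelled samples) dropped; A kept with 3 labelled of 4 samples
  expect_setequal(labs$subject_id, c("A", "C"))
  expect_equal(sum(co$samples$subject_id == "A"), 3L)
  # A's unlabelled sample (milk NA at age 300) was dropped first
  expect_false("s04" %in% co$samples$sample_id)
  # profiles sorted by age within subject
  expect_equal(co$samples$age[co$samples$subject_id == "A"], c(30, 100, 200))
  # subject label = last timepoint's label (A: egg=1 at age 200)
  expect_equal(as.character(labs$label[labs$subject_id == "A"]), "allergic")
  expect_equal(as.character(labs$label[labs$subject_id == "C"]), "allergic")
  # count conservation
  fc <- co$filter_counts
  expect_equal(fc$n_kept_samples + fc$n_dropped_missing_label +
                 fc$n_dropped_short_subject, fc$n_input_samples)
  # min_timepoints = 1 keeps all subjects with any labelled sample
  co1 <- assemble_cohort(prof, meta, min_timepoints = 1)
  expect_setequal(subject_labels(co1)$subject_id, c("A", "B", "C"))
  # unknown sample id -> error
  meta_bad <- meta
  meta_bad$sample_id[1] <- "zzz"
  expect_error(assemble_cohort(prof, meta_bad, 3), "absent")
})

test_that("cohort assembly is order-independent and idempotent", {
  meta <- make_meta_fixture()
  prof <- make_profile_matrix(meta$sample_id)
  co <- assemble_cohort(prof, meta, min_timepoints = 3)
  set.seed(1)
  shuffled <- meta[sample(nrow(meta)), ]
  co2 <- assemble_cohort(prof, shuffled, min_timepoints = 3)
  expect_equal(co$samples, co2$samples)
  expect_equal(co$profiles, co2$profiles)
  # fixed point: re-assembling the filtered output changes nothing
  meta_out <- dplyr::mutate(co$samples, label = as.character(label))
  co3 <- assemble_cohort(co$profiles, meta_out, min_timepoints = 3)
  expect_equal(co3$samples$sample_id, co$samples$sample_id)
  expect_equal(co3$profiles, co$profiles)
})

test_that("RPKM normalization matches hand arithmetic and scaling identities", {
  counts <- matrix(c(1000, 0, 10, 500), 2, 2,
                   dimnames = list(c("a", "b"), c("g1", "g2")))
  out <- normalize_rpkm(counts, genome_lengths = c(1e6, 1e3),
                        library_sizes = c(1e6, 2e6))
  expect_equal(out["a", "g1"], 1) # 1000 / (1e6/1e3) / (1e6/1e6)
  expect_equal(out["b", "g1"], 0)
  # doubling a library size halves that row
  out2 <- normalize_rpkm(counts, c(1e6, 1e3), c(2e6, 2e6))
  expect_equal(out2["a", ], out["a", ] / 2)
  expect_error(normalize_rpkm(counts, c(0, 1e3), c(1e6, 1e6)), "positive")
  expect_error(normalize_rpkm(counts, c(1e6, 1e3), c(1e6, -1)), "positive")
})

test_that("cohorts serialize to a directory and back unchanged", {
  co <- make_separable_cohort(n_subjects = 6)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  co2 <- read_cohort(dir)
  expect_equal(co2$samples$sample_id, co$samples$sample_id)
  expect_equal(unname(co2$profiles), unname(co$profiles), tolerance = 1e-12)
  expect_equal(co2$features, co$features)
})

test_that("age ties are kept with a stable order and flagged", {
  meta <- tibble::tibble(
    sample_id = c("x1", "x2", "x3"), subject_id = "S",
    age = c(10, 10, 20), label = "allergic"
  )
  prof <- make_profile_matrix(meta$sample_id)
  expect_warning(co <- assemble_cohort(prof, meta, 3), "tied collection ages")
  expect_equal(co$samples$sample_id, c("x1", "x2", "x3"))
})
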