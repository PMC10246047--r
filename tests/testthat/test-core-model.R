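test_that("validation passes well-formed data and names constructed violations", {
  d <- toy_dataset()
  expect_no_violations(d)

  # quantitative row referencing an unknown run
  d_bad <- d
  d_bad$quantitative$sample_id[1] <- "deadbeef"
  v <- validate(d_bad)
  expect_true(any(grepl("experiments", v)))

  # imputed ratio outside [0,1]
  d_bad2 <- d
  d_bad2$accounting$imputed[3] <- 1.5
  expect_true(any(grepl("imputed out of \\[0,1\\]", validate(d_bad2))))

  # validation reports, never throws, and is side-effect free
  expect_identical(validate(d_bad2), validate(d_bad2))
  expect_no_violations(d)
})

test_that("sample identifiers are deterministic 8-character digests", {
  a <- make_sample_id("a.tsv", "s1.raw")
  expect_identical(a, make_sample_id("a.tsv", "s1.raw"))
  expect_identical(nchar(a), 8L)
  expect_false(a == make_sample_id("a.tsv", "s2.raw"))
  # first 8 hex chars of SHA-1("a.tsv|s1.raw"), fixed independently
  expect_identical(a, "a0a0778f")
  expect_error(make_sample_id("", "s1.raw"), "empty source name")
})

test_that("the ledger records one entry per verb in order", {
  sim <- simulate_dataset(n_proteins = 30, seed = 5)
  d <- sim$dataset
  expect_length(operations(d), 1)
  expect_match(operations(d)[1], "^1\\. simulate")

  d2 <- subset(d, "!description %like% 'keratin'")
  d3 <- normalize(d2, methods = "median")
  ops <- operations(d3)
  expect_length(ops, 3)
  expect_match(ops[2], "subset")
  expect_match(ops[3], "normalize.*method=median")
})

test_that("merge unions tables, preserves per-source identifiers, resolves collisions", {
  m1 <- matrix(2^rnorm(8, 20, 1), nrow = 4,
               dimnames = list(paste0("A", 1:4), NULL))
  m2 <- matrix(2^rnorm(12, 20, 1), nrow = 4,
               dimnames = list(paste0("B", 1:4), NULL))
  a <- make_protein_dataset(m1, c("ctrl", "ctrl"))
  b <- make_protein_dataset(m2, c("kndw", "kndw", "kndw"))
  b$experiments$import_file <- "toy2.tsv"
  b$experiments$sample_id <- make_sample_id("toy2.tsv", b$experiments$sample_file)
  b$quantitative$sample_id <- rep(b$experiments$sample_id, each = 4)
  b$accounting$sample_id <- b$quantitative$sample_id

  m <- merge(a, b)
  expect_equal(nrow(m$experiments), 5)
  expect_no_violations(m)
  # no row loss or duplication per source
  expect_equal(sum(m$quantitative$protein %in% rownames(m1)), nrow(a$quantitative))
  expect_equal(sum(m$quantitative$protein %in% rownames(m2)), nrow(b$quantitative))
  expect_identical(ledger_verb_tail(m), "merge")

  # identical (import_file, sample_file) pairs collide: ids regenerated,
  # replicates relabeled, nothing dropped
  m_dup <- merge(a, a)
  expect_equal(nrow(m_dup$experiments), 4)
  expect_no_violations(m_dup)
  expect_true(any(grepl("\\.2$", m_dup$experiments$replicate)))

  pep <- toy_peptide_dataset()
  expect_error(merge(a, pep), "level mismatch")
})

test_that("reassign rewrites matched experiment rows and suffixes collisions", {
  d <- toy_dataset()
  r <- reassign(d, "sample_file %like% 'ctrl'", "sample", "control")
  expect_identical(sort(unique(r$experiments$sample)), c("control", "kndw"))
  # quantitative join untouched
  expect_identical(r$quantitative, d$quantitative)

  # collapsing both groups into one name collides replicate labels
  r2 <- reassign(d, "sample %like% '.'", "sample", "all")
  expect_no_violations(r2)
  expect_setequal(r2$experiments$replicate, c("1", "2", "1.2", "2.2"))

  expect_error(reassign(d, "sample == 'absent'", "sample", "x"), "no samples matched")
  expect_error(reassign(d, "flavour == 'x'", "sample", "x"), "unknown experiment field")
})

test_that("summary groups by sample field or annotation term with brute-force counts", {
  d <- toy_dataset()
  s <- summary(d, by = "sample")
  expect_equal(nrow(s), 2)
  # brute-force distinct-identifier tally per group
  long <- to_table(d, "long")
  counts <- long |> dplyr::filter(!is.na(abundance)) |>
    dplyr::group_by(sample) |> dplyr::summarise(n = dplyr::n_distinct(protein))
  expect_equal(s$n_identifiers[match(counts$sample, s$group)], counts$n)

  s2 <- summary(d, by = "molecular function")
  expect_setequal(s2$group, c("metal ion binding", "catalytic activity"))
  expect_error(summary(d, by = "nonexistent"), "available fields")
})

test_that("long and wide exports agree and preserve every value", {
  d <- toy_dataset()
  long <- to_table(d, "long")
  expect_equal(nrow(long), 10 * 4)
  wide <- to_table(d, "wide")
  expect_equal(dim(wide), c(10, 1 + 4))
  # every non-missing value identical across the two shapes
  back <- tidyr::pivot_longer(wide, -protein, names_to = "col",
                              values_to = "abundance") |>
    dplyr::mutate(col = sub("^abundance_", "", col))
  key_long <- paste(long$protein, paste0(long$sample, "_", long$replicate))
  expect_equal(back$abundance[match(key_long, paste(back$protein, back$col))],
               long$abundance)
})

test_that("set_normalization switches the channel used downstream", {
  d <- normalize(toy_dataset(), methods = c("median", "linear"))
  d2 <- set_normalization(d, "median")
  expect_identical(d2$selected_channel, "median")
  expect_error(set_normalization(d, "vsn"), "unknown channel")
  s_raw <- summary(set_normalization(d, "raw"), by = "sample")
  s_med <- summary(d2, by = "sample")
  expect_false(isTRUE(all.equal(s_raw$abundance_total, s_med$abundance_total)))
})
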