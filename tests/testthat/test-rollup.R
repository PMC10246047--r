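test_that("peptide ownership follows the inference method", {
  d <- toy_peptide_dataset()  # A: 3 unique, B: 1 unique, s1 shared
  razor <- assign_peptides(d, "razor")
  expect_identical(razor$protein[razor$peptide == "s1"], "A")
  expect_equal(nrow(razor), 5)  # every peptide owned exactly once

  nh <- assign_peptides(d, "non_homologous")
  expect_false("s1" %in% nh$peptide)

  ap <- assign_peptides(d, "all_possible")
  expect_equal(sum(ap$peptide == "s1"), 2)
  # unshared peptides have the same single owner under all methods
  for (own in list(razor, nh, ap)) {
    expect_identical(own$protein[own$peptide == "a1"], "A")
  }
  expect_error(assign_peptides(collapse(d), "razor"), "already protein level")
})

test_that("razor ties break by total peptides then accession", {
  # C and D both have 1 unique peptide; D has one extra shared peptide
  qn <- tibble::tibble(
    sample_id = make_sample_id("t.tsv", "a_1"),
    protein = c("C", "D", "C", "D", "D", "E"),
    peptide = c("c1", "d1", "s1", "s1", "s2", "s2"),
    modification = NA_character_,
    raw = 10)
  ac <- dplyr::mutate(qn[, 1:4], imputed = 0, num_peptides = 1L,
                      num_unique_peptides = 0L, num_proteins = 1L)
  ex <- tibble::tibble(sample_id = unique(qn$sample_id), import_file = "t.tsv",
                       sample_file = "a_1", sample = "a", replicate = "1")
  d <- new_proteomics_dataset(ex, qn, ac, level = "peptides")
  razor <- assign_peptides(d, "razor")
  # s1: C and D tie on unique count (1), D has 3 total vs C's 2
  expect_identical(razor$protein[razor$peptide == "s1"], "D")
})

test_that("shared-peptide splitting is proportional with an equal-split fallback", {
  s <- split_shared(100, c(A = 300, B = 100))
  expect_equal(unname(s), c(75, 25))
  expect_equal(sum(s), 100)
  expect_equal(unname(split_shared(100, c(A = 0, B = 0))), c(50, 50))
  expect_equal(unname(split_shared(100, c(A = NA, B = NA))), c(50, 50))
  expect_equal(unname(split_shared(100, c(A = 42))), 100)
})

test_that("collapse aggregates with summary functions and top-n ranking", {
  # single protein with three peptides at 10, 20, 30 in each of 2 runs
  ex <- tibble::tibble(sample_id = make_sample_id("t.tsv", c("a_1", "a_2")),
                       import_file = "t.tsv", sample_file = c("a_1", "a_2"),
                       sample = "a", replicate = c("1", "2"))
  qn <- tidyr::crossing(sample_id = ex$sample_id,
                        tibble::tibble(protein = "P", peptide = c("p1", "p2", "p3"),
                                       modification = NA_character_,
                                       raw = c(10, 20, 30))) |>
    dplyr::select(sample_id, protein, peptide, modification, raw)
  ac <- dplyr::mutate(qn[, 1:4], imputed = 0, num_peptides = 1L,
                      num_unique_peptides = 1L, num_proteins = 1L)
  d <- new_proteomics_dataset(ex, qn, ac, level = "peptides")

  all_sum <- collapse(d, summary_fn = "sum")
  expect_equal(unique(all_sum$quantitative$raw), 60)
  expect_identical(all_sum$level, "proteins")
  top2 <- collapse(d, top_n = 2, summary_fn = "sum")
  expect_equal(unique(top2$quantitative$raw), 50)
  med <- collapse(d, summary_fn = "median")
  expect_equal(unique(med$quantitative$raw), 20)
  expect_equal(unique(all_sum$accounting$num_peptides), 3L)
  expect_no_violations(all_sum)
})

test_that("proportional splitting conserves per-sample totals on simulated data", {
  sim <- simulate_dataset(n_proteins = 120, shared_peptide_fraction = 0.15,
                          seed = 31)
  d <- sim$dataset
  p <- collapse(d, "all_possible", split_abundance = TRUE, summary_fn = "sum")
  # peptide totals count each distinct peptide once
  pep_tot <- d$quantitative |>
    dplyr::distinct(peptide, modification, sample_id, raw) |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(total = sum(raw, na.rm = TRUE))
  prot_tot <- p$quantitative |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(total = sum(raw, na.rm = TRUE))
  expect_equal(prot_tot$total[match(pep_tot$sample_id, prot_tot$sample_id)],
               pep_tot$total, tolerance = 1e-9)
  expect_no_violations(p)

  # razor: every peptide contributes exactly once
  razor_own <- assign_peptides(d, "razor")
  expect_equal(nrow(razor_own),
               dplyr::n_distinct(paste(d$quantitative$peptide,
                                       d$quantitative$modification)))
})

test_that("collapse propagates imputed fractions and missingness correctly", {
  d <- toy_peptide_dataset()
  # make peptide a1 missing in run 1 and mark a2 imputed in run 1
  r1 <- d$experiments$sample_id[1]
  d$quantitative$raw[d$quantitative$peptide == "a1" &
                       d$quantitative$sample_id == r1] <- NA
  d$accounting$imputed[d$accounting$peptide == "a2" &
                         d$accounting$sample_id == r1] <- 1
  p <- collapse(d, "razor", summary_fn = "sum")
  accA <- p$accounting[p$accounting$protein == "A" & p$accounting$sample_id == r1, ]
  # A contributes a2, a3, s1 in run 1 (a1 missing): one of three imputed
  expect_equal(accA$num_peptides, 3L)
  expect_equal(accA$imputed, 1 / 3, tolerance = 1e-12)
  brute <- mean(c(1, 0, 0))
  expect_equal(accA$imputed, brute)

  # protein missing only when every contributing peptide is missing
  d2 <- toy_peptide_dataset()
  d2$quantitative$raw[d2$quantitative$protein == "B" &
                        d2$quantitative$peptide == "b1" &
                        d2$quantitative$sample_id == r1] <- NA
  p2 <- collapse(d2, "non_homologous", summary_fn = "sum")
  expect_true(is.na(p2$quantitative$raw[p2$quantitative$protein == "B" &
                                          p2$quantitative$sample_id == r1]))
  expect_false(is.na(p2$quantitative$raw[p2$quantitative$protein == "A" &
                                           p2$quantitative$sample_id == r1]))
})
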