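write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("directives parse with defaults and reject unmapped protein columns", {
  f <- write_lines_tmp(c(
    "identifier_map:", "  protein: accession", "  peptide: sequence",
    "abundance_pattern: '^ab_(.+)$'"), ".yaml")
  d <- read_directive(f)
  expect_s3_class(d, "import_directive")
  expect_identical(d$orientation, "wide")
  expect_identical(d$level, "peptides")

  f2 <- write_lines_tmp(c("identifier_map:", "  peptide: sequence",
                          "abundance_pattern: '^ab_(.+)$'"), ".yaml")
  expect_error(read_directive(f2), "no protein column mapped")

  builtin <- read_directive("generic-wide")
  expect_identical(builtin$platform, "generic-wide")
  expect_identical(builtin$level, "peptides")
})

test_that("wide imports parse groups and replicates and coerce zeros to missing", {
  f <- write_lines_tmp(c(
    "protein\tpeptide\tmodification\tdescription\tabundance_ctrl_1\tabundance_ctrl_2\tabundance_kndw_1\tabundance_kndw_2",
    "P1\tAAK\t\tsome protein\t100\t110\t0\t90",
    "P2\tCCR\t\tother protein\t200\t\t210\t220"))
  d <- import_data(f, "generic-wide")
  expect_no_violations(d)
  expect_equal(nrow(d$experiments), 4)
  expect_setequal(unique(d$experiments$sample), c("ctrl", "kndw"))
  expect_setequal(unique(d$experiments$replicate), c("1", "2"))
  long <- to_table(d, "long")
  # zero and empty cells are missing, never zero
  expect_true(is.na(long$abundance[long$protein == "P1" & long$sample == "kndw" &
                                     long$replicate == "1"]))
  expect_equal(sum(is.na(long$abundance)), 2)
  expect_identical(ledger_verb_tail(d), "import")
  # description column became an annotation term
  expect_setequal(d$annotations$term, "description")
})

test_that("wide and long renderings of one dataset import identically", {
  sim <- simulate_dataset(n_proteins = 40, seed = 8)
  fw <- withr::local_tempfile(fileext = ".tsv")
  fl <- withr::local_tempfile(fileext = ".tsv")
  write_fixture(sim$dataset, "generic-wide", fw)
  write_fixture(sim$dataset, "generic-long", fl)
  dw <- import_data(fw, "generic-wide")
  dl <- import_data(fl, "generic-long")
  key <- function(x) {
    t <- to_table(x, "long")
    t[order(t$protein, t$peptide, t$sample, t$replicate), ]
  }
  tw <- key(dw); tl <- key(dl)
  expect_equal(tw$abundance, tl$abundance)
  expect_identical(tw$protein, tl$protein)

  # and both reproduce the simulated values exactly
  ts <- key(sim$dataset)
  expect_identical(tw$abundance, ts$abundance)
})

test_that("export then re-import reproduces quantitative values exactly", {
  sim <- simulate_dataset(n_proteins = 30, seed = 13)
  d <- sim$dataset
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fixture(d, "generic-wide", f)
  d2 <- import_data(f, "generic-wide")
  o <- function(x) {
    t <- to_table(x, "long")
    t$abundance[order(t$protein, t$peptide, t$sample, t$replicate)]
  }
  expect_identical(o(d2), o(d))

  # csv export uses commas, tsv uses tabs
  fc <- withr::local_tempfile(fileext = ".csv")
  export_tabular(d, fc, format = "csv", shape = "wide")
  expect_true(grepl(",", readLines(fc, n = 1)))
  ft <- withr::local_tempfile(fileext = ".tsv")
  export_tabular(d, ft, format = "tsv", shape = "wide")
  header <- strsplit(readLines(ft, n = 1), "\t")[[1]]
  expect_equal(sum(grepl("^abundance_", header)), nrow(d$experiments))
})

test_that("dataset bundles round-trip value-identically including the ledger", {
  sim <- simulate_dataset(n_proteins = 25, seed = 17)
  d <- normalize(sim$dataset, methods = "median")
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  d2 <- read_dataset(dir)
  expect_equal(d2$quantitative$raw, d$quantitative$raw)
  expect_equal(d2$quantitative$median, d$quantitative$median)
  expect_identical(operations(d2), operations(d))
  expect_identical(d2$selected_channel, d$selected_channel)
  expect_no_violations(d2)
})

test_that("annotations load with join counts and deduplication", {
  d <- toy_dataset()
  f <- write_lines_tmp(c(
    "accession\tlocation\tpathway",
    "P001\tnucleus\tproteolysis",
    "P002\tcytosol\ttranslation",
    "P003\tcytosol\t",
    "P001\tnucleus\tproteolysis",
    "UNKNOWN\tmembrane\tnone"))
  expect_message(
    d2 <- load_annotations(d, f, "accession", c("location", "pathway")),
    "matched no protein")
  loc <- dplyr::filter(d2$annotations, term == "location")
  expect_equal(nrow(loc), 3)  # duplicate collapsed, unknown skipped
  expect_equal(sum(d2$annotations$term == "pathway"), 2)
  expect_no_violations(d2)

  f_none <- write_lines_tmp(c("accession\tlocation", "ZZZ\tnowhere"))
  expect_error(load_annotations(d, f_none, "accession", "location"),
               "no annotations matched")
})

test_that("the MaxQuant-style dialect imports protein tables", {
  f <- write_lines_tmp(c(
    paste("Majority protein IDs", "Protein names", "Peptides", "Unique peptides",
          "Intensity ctrl_1", "Intensity ctrl_2", "Intensity kd_1",
          sep = "\t"),
    "P10809\tHSP60\t12\t10\t1e7\t1.1e7\t9e6",
    "P55072\tVCP/p97\t20\t18\t2e7\t0\t5e6"))
  d <- import_data(f, "maxquant-proteins")
  expect_identical(d$level, "proteins")
  expect_equal(nrow(d$experiments), 3)
  expect_setequal(unique(d$experiments$sample), c("ctrl", "kd"))
  expect_equal(d$accounting$num_peptides[d$accounting$protein == "P55072"][1], 20L)
  expect_true(is.na(d$quantitative$raw[d$quantitative$protein == "P55072"][2]))
  expect_no_violations(d)
})

test_that("duplicate identifier rows error unless the directive aggregates", {
  lines <- c("protein\tpeptide\tmodification\tabundance_a_1",
             "P1\tAAK\t\t10", "P1\tAAK\t\t20")
  f <- write_lines_tmp(lines)
  expect_error(import_data(f, "generic-wide"), "non-unique identifiers")

  fy <- write_lines_tmp(c(
    "identifier_map:", "  protein: protein", "  peptide: peptide",
    "abundance_pattern: '^abundance_(.+)$'", "aggregate: sum"), ".yaml")
  d <- import_data(f, read_directive(fy))
  expect_equal(d$quantitative$raw, 30)
})
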