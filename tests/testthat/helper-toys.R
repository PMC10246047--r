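# In-code fixtures shared across the suite.

# Protein-level dataset from an abundance matrix (rows = proteins,
# columns = runs); NA cells stay recorded as missing.
make_protein_dataset <- function(mat, sample_groups, replicates = NULL) {
  if (is.null(replicates)) {
    replicates <- as.character(stats::ave(seq_along(sample_groups),
                                          sample_groups, FUN = seq_along))
  }
  sample_file <- paste0(sample_groups, "_", replicates)
  ex <- tibble::tibble(
    sample_id = make_sample_id("toy.tsv", sample_file),
    import_file = "toy.tsv", sample_file = sample_file,
    sample = sample_groups, replicate = replicates)
  prot <- rownames(mat)
  if (is.null(prot)) prot <- sprintf("P%03d", seq_len(nrow(mat)))
  qn <- tibble::tibble(
    sample_id = rep(ex$sample_id, each = nrow(mat)),
    protein = rep(prot, times = ncol(mat)),
    raw = as.vector(mat))
  ac <- tibble::tibble(
    sample_id = qn$sample_id, protein = qn$protein, imputed = 0,
    num_peptides = 3L, num_unique_peptides = 2L, num_proteins = 1L)
  new_proteomics_dataset(ex, qn, ac, level = "proteins")
}

# 10 proteins x 2 groups x 2 replicates; two proteins described as
# ribosomal; a "molecular function" annotation term.
toy_dataset <- function() {
  set.seed(11)
  mat <- matrix(2^rnorm(40, 20, 1), nrow = 10)
  rownames(mat) <- sprintf("P%03d", 1:10)
  d <- make_protein_dataset(mat, c("ctrl", "ctrl", "kndw", "kndw"))
  descr <- c("60S ribosome subunit protein L4", "40S ribosome subunit protein S3",
             paste("Ubiquitin ligase subunit", 3:10))
  mf <- rep(c("metal ion binding", "catalytic activity"), 5)
  d$annotations <- dplyr::bind_rows(
    tibble::tibble(protein = rownames(mat), term = "description",
                   annotation = descr),
    tibble::tibble(protein = rownames(mat), term = "molecular function",
                   annotation = mf))
  d
}

# Peptide-level toy exercising shared-peptide ownership: protein A has
# unique peptides a1,a2,a3; protein B has unique b1; peptide s1 is shared
# by A and B. Two runs in one group, identical values.
toy_peptide_dataset <- function(x_s1 = 100, u_a = c(100, 120, 80), u_b = 100) {
  ex <- tibble::tibble(
    sample_id = make_sample_id("pep.tsv", c("g_1", "g_2")),
    import_file = "pep.tsv", sample_file = c("g_1", "g_2"),
    sample = "g", replicate = c("1", "2"))
  rows <- tibble::tibble(
    protein = c("A", "A", "A", "B", "A", "B"),
    peptide = c("a1", "a2", "a3", "b1", "s1", "s1"),
    modification = NA_character_,
    value = c(u_a, u_b, x_s1, x_s1))
  qn <- tidyr::crossing(ex[, "sample_id"], rows) |>
    dplyr::rename(raw = value) |>
    dplyr::select(sample_id, protein, peptide, modification, raw)
  ac <- qn |>
    dplyr::mutate(imputed = 0, num_peptides = 1L,
                  num_unique_peptides = ifelse(peptide == "s1", 0L, 1L),
                  num_proteins = ifelse(peptide == "s1", 2L, 1L),
                  raw = NULL)
  new_proteomics_dataset(ex, qn, ac, level = "peptides")
}

expect_no_violations <- function(dataset) {
  testthat::expect_length(validate(dataset), 0)
}

ledger_verb_tail <- function(dataset) {
  dataset$ledger[[length(dataset$ledger)]]$verb
}
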