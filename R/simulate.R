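# Synthetic peptide-level data with full ground truth. The defaults model
# a small two-group label-free comparison (control vs knockdown, four
# replicates each) and every downstream stage — rollup, normalization,
# imputation, expression, enrichment — is exercisable against the truth
# tables the generator returns.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_peptides <- function(n) {
  len <- sample(7:14, n, replace = TRUE)
  vapply(len, function(l) paste(sample(AA, l, replace = TRUE), collapse = ""),
         character(1))
}

#' Simulate a peptide-level proteomics dataset with known ground truth
#'
#' Generates a wide-format-style quantified peptide experiment:
#'
#' * protein base log2 abundances are Normal(`log2_mu`, `log2_sigma`);
#'   each peptide adds a Normal(0, 0.5) log2 offset.
#' * a `de_fraction` of (non-contaminant) proteins carry a group effect of
#'   `log2_effect` log2 units (sign randomized per protein) applied to the
#'   *last* listed group, so ratios like `kndw/ctrl` are interpretable.
#' * replicate noise is multiplicative with coefficient of variation
#'   `replicate_cv` (log-normal, exact on the log scale).
#' * a fraction of peptides is shared: the peptide also appears under a
#'   second random protein with the identical abundance.
#' * a fraction of proteins are keratin contaminants (tagged in the
#'   `description` annotation term).
#' * missingness is abundance-dependent (MNAR): an observation at log2
#'   abundance `x` drops out with probability
#'   `plogis(-mnar_slope * (x - mnar_midpoint))`, followed by uniform MCAR
#'   dropout at `mcar_rate`.
#' * each entry of `terms` adds an annotation term whose first
#'   (`enriched`) annotation preferentially collects the up-regulated
#'   differential proteins, giving a known enrichment signal.
#'
#' Identical seeds give bitwise-identical output.
#'
#' @param n_proteins Number of proteins.
#' @param peptides_per_protein Mean peptide count (1 + Poisson).
#' @param groups Named integer vector: replicate count per sample group;
#'   the effect applies to the last group.
#' @param log2_mu,log2_sigma Protein base-abundance distribution (log2).
#' @param de_fraction,log2_effect Differential fraction and effect size.
#' @param replicate_cv Technical CV on the linear scale.
#' @param shared_peptide_fraction,contaminant_fraction See above.
#' @param mnar_midpoint,mnar_slope Logistic dropout parameters (log2
#'   units).
#' @param mcar_rate Uniform dropout rate.
#' @param terms List of term specs:
#'   `list(term =, n_annotations =, enriched =)`.
#' @param seed RNG seed.
#' @return List: `dataset` (a peptide-level `proteomics_dataset`) and
#'   `truth` (tibbles `proteins`, `observations`, `enriched`).
#' @export
simulate_dataset <- function(n_proteins = 500,
                             peptides_per_protein = 3,
                             groups = c(ctrl = 4, kndw = 4),
                             log2_mu = 20, log2_sigma = 2.5,
                             de_fraction = 0.1, log2_effect = 2,
                             replicate_cv = 0.1,
                             shared_peptide_fraction = 0.05,
                             contaminant_fraction = 0.02,
                             mnar_midpoint = 14, mnar_slope = 1,
                             mcar_rate = 0.02,
                             terms = list(list(term = "biological process",
                                               n_annotations = 6,
                                               enriched = "proteolysis")),
                             seed = 1) {
  stopifnot(n_proteins >= 2, all(groups >= 2), length(groups) >= 2,
            de_fraction >= 0, de_fraction <= 1,
            shared_peptide_fraction >= 0, shared_peptide_fraction <= 1,
            contaminant_fraction >= 0, contaminant_fraction <= 1,
            mcar_rate >= 0, mcar_rate <= 1, replicate_cv >= 0)
  set.seed(seed)

  protein <- sprintf("P%05d", seq_len(n_proteins))
  base_log2 <- stats::rnorm(n_proteins, log2_mu, log2_sigma)
  n_cont <- round(contaminant_fraction * n_proteins)
  is_cont <- seq_len(n_proteins) %in% sample.int(n_proteins, n_cont)
  n_de <- round(de_fraction * n_proteins)
  de_pool <- which(!is_cont)
  de_idx <- sample(de_pool, min(n_de, length(de_pool)))
  is_de <- seq_len(n_proteins) %in% de_idx
  effect <- ifelse(is_de, sample(c(-1, 1), n_proteins, replace = TRUE) * log2_effect, 0)

  truth_proteins <- tibble::tibble(protein = protein, base_log2 = base_log2,
                                   effect = effect, is_de = is_de,
                                   is_contaminant = is_cont)

  n_pep <- 1L + stats::rpois(n_proteins, max(peptides_per_protein - 1, 0))
  owner1 <- rep(seq_len(n_proteins), n_pep)
  peptide <- random_peptides(sum(n_pep))
  dup <- duplicated(peptide)
  peptide[dup] <- paste0(peptide[dup], which(dup))
  offset <- stats::rnorm(length(peptide), 0, 0.5)

  n_shared <- round(shared_peptide_fraction * length(peptide))
  shared_idx <- if (n_shared > 0) sample(seq_along(peptide), n_shared) else integer()
  owner2 <- vapply(shared_idx, function(i) {
    sample(setdiff(seq_len(n_proteins), owner1[i]), 1)
  }, integer(1))

  last_group <- names(groups)[length(groups)]
  ex <- tibble::tibble(
    sample = rep(names(groups), groups),
    replicate = as.character(unlist(lapply(groups, seq_len), use.names = FALSE))
  )
  ex$sample_file <- paste0(ex$sample, "_", ex$replicate)
  ex$import_file <- "simulated.tsv"
  ex$sample_id <- make_sample_id(ex$import_file, ex$sample_file)
  ex <- ex[, c("sample_id", "import_file", "sample_file", "sample", "replicate")]

  n_obs <- length(peptide) * nrow(ex)
  obs <- tibble::tibble(
    pep_i = rep(seq_along(peptide), each = nrow(ex)),
    sample_id = rep(ex$sample_id, times = length(peptide)),
    sample = rep(ex$sample, times = length(peptide)),
    replicate = rep(ex$replicate, times = length(peptide))
  )
  obs$peptide <- peptide[obs$pep_i]
  obs$protein <- protein[owner1[obs$pep_i]]
  in_last <- obs$sample == last_group
  obs$true_log2 <- base_log2[owner1[obs$pep_i]] + offset[obs$pep_i] +
    ifelse(in_last, effect[owner1[obs$pep_i]], 0)
  sd_log2 <- sqrt(log(1 + replicate_cv^2)) / log(2)
  obs$observed_log2 <- obs$true_log2 + stats::rnorm(n_obs, 0, sd_log2)

  # slope 0 disables the abundance-dependent mechanism entirely
  p_mnar <- if (mnar_slope > 0) {
    stats::plogis(-mnar_slope * (obs$observed_log2 - mnar_midpoint))
  } else 0
  u1 <- stats::runif(n_obs)
  u2 <- stats::runif(n_obs)
  mnar <- u1 < p_mnar
  mcar <- !mnar & u2 < mcar_rate
  obs$mechanism <- dplyr::case_when(mnar ~ "MNAR", mcar ~ "MCAR",
                                    .default = NA_character_)
  obs$missing <- mnar | mcar

  # candidate rows: owner 1 for every peptide, owner 2 for shared peptides
  cand <- tibble::tibble(pep_i = c(seq_along(peptide), shared_idx),
                         owner = c(owner1, owner2))
  n_owner <- table(cand$pep_i)
  qn <- dplyr::inner_join(cand, obs, by = "pep_i",
                          relationship = "many-to-many")
  qn$protein <- protein[qn$owner]
  qn$modification <- NA_character_
  qn$raw <- ifelse(qn$missing, NA_real_, 2^qn$observed_log2)
  qn$n_owner <- as.integer(n_owner[as.character(qn$pep_i)])
  quant <- dplyr::arrange(
    dplyr::select(qn, "sample_id", "protein", "peptide", "modification", "raw"),
    .data$protein, .data$peptide, .data$sample_id)

  acc <- dplyr::arrange(
    dplyr::mutate(
      dplyr::select(qn, "sample_id", "protein", "peptide", "modification",
                    "n_owner"),
      imputed = 0,
      num_peptides = 1L,
      num_unique_peptides = ifelse(.data$n_owner == 1L, 1L, 0L),
      num_proteins = .data$n_owner,
      n_owner = NULL),
    .data$protein, .data$peptide, .data$sample_id)

  descr_pool <- c("ATP-dependent helicase", "Ubiquitin ligase subunit",
                  "Mitochondrial carrier", "Heat shock cognate protein",
                  "Translation initiation factor", "Zinc finger protein",
                  "Proteasome regulatory subunit", "Actin-related protein")
  descr <- paste0(sample(descr_pool, n_proteins, replace = TRUE), " ",
                  seq_len(n_proteins))
  descr[is_cont] <- paste0("Keratin, type II cytoskeletal ", which(is_cont))
  ann <- tibble::tibble(protein = protein, term = "description",
                        annotation = descr)
  enriched_truth <- tibble::tibble(term = character(), annotation = character())
  for (tm in terms) {
    k <- tm$n_annotations
    # the enriched annotation collects the up-shifted differential
    # proteins (90% capture); everything else spreads over the remaining
    # labels uniformly
    assign <- sample(sprintf("annotation_%02d", seq_len(k - 1) + 1),
                     n_proteins, replace = TRUE)
    up <- which(is_de & effect > 0)
    take <- up[stats::runif(length(up)) < 0.9]
    assign[take] <- tm$enriched
    ann <- dplyr::bind_rows(ann, tibble::tibble(protein = protein,
                                                term = tm$term,
                                                annotation = assign))
    enriched_truth <- dplyr::bind_rows(
      enriched_truth, tibble::tibble(term = tm$term, annotation = tm$enriched))
  }

  dataset <- new_proteomics_dataset(ex, quant, acc, dplyr::distinct(ann),
                                    level = "peptides")
  dataset <- append_ledger(dataset, "simulate", list(
    n_proteins = n_proteins, groups = paste(names(groups), groups,
                                            sep = "=", collapse = ","),
    de_fraction = de_fraction, log2_effect = log2_effect,
    replicate_cv = replicate_cv, seed = seed))

  truth_obs <- dplyr::select(obs, "protein", "peptide", "sample_id", "sample",
                             "replicate", "true_log2", "observed_log2",
                             "missing", "mechanism")
  list(dataset = dataset,
       truth = list(proteins = truth_proteins, observations = truth_obs,
                    enriched = enriched_truth))
}

#' Inject smooth intensity-dependent bias into samples
#'
#' Distorts the raw channel of selected runs with a sample-specific smooth
#' curve on the log2 scale — one sinusoidal period across the central
#' abundance range with a random phase per run plus a small random offset
#' — emulating the nonlinear instrument-response drift that constant-shift
#' normalization cannot remove but curve-based methods (loess, random
#' forest) can. Used to study normalization selection against a known
#' distortion.
#'
#' @param dataset A `proteomics_dataset`.
#' @param sample_ids Runs to distort (default: all).
#' @param amplitude Curve amplitude in log2 units.
#' @param seed RNG seed for the per-run phases.
#' @return The dataset with the raw channel distorted (logged).
#' @export
simulate_nonlinear_bias <- function(dataset, sample_ids = NULL,
                                    amplitude = 0.5, seed = 1) {
  stopifnot(inherits(dataset, "proteomics_dataset"))
  if (is.null(sample_ids)) sample_ids <- dataset$experiments$sample_id
  set.seed(seed)
  lraw <- log2(dataset$quantitative$raw)
  lo <- stats::quantile(lraw, 0.025, na.rm = TRUE, names = FALSE)
  hi <- stats::quantile(lraw, 0.975, na.rm = TRUE, names = FALSE)
  for (s in sample_ids) {
    i <- dataset$quantitative$sample_id == s
    phase <- stats::runif(1, 0, 2 * pi)
    shift <- stats::rnorm(1, 0, amplitude / 2)
    lraw[i] <- lraw[i] + amplitude *
      sin(2 * pi * (lraw[i] - lo) / (hi - lo) + phase) + shift
  }
  dataset$quantitative$raw <- 2^lraw
  append_ledger(dataset, "simulate_nonlinear_bias",
                list(amplitude = amplitude, n_samples = length(sample_ids),
                     seed = seed))
}

#' Write a dataset as an importable platform-style fixture
#'
#' Renders the raw channel as a single delimited file in the canonical
#' generic dialects, suitable for [import_data()] with the matching
#' built-in directive; missing values are empty cells and the round trip
#' reproduces every quantitative value exactly.
#'
#' @param dataset A peptide-level `proteomics_dataset`.
#' @param style `"generic-wide"` (one `abundance_<sample>_<replicate>`
#'   column per run) or `"generic-long"` (`sample` + `abundance` columns).
#' @param path Output file path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_fixture <- function(dataset, style = c("generic-wide", "generic-long"),
                          path) {
  style <- match.arg(style)
  stopifnot(inherits(dataset, "proteomics_dataset"))
  idc <- id_cols(dataset)
  descr <- dataset$annotations |>
    dplyr::filter(.data$term == "description") |>
    dplyr::distinct(.data$protein, .keep_all = TRUE) |>
    dplyr::select("protein", description = "annotation")
  long <- dataset_long(dataset, "raw") |>
    dplyr::mutate(token = paste0(.data$sample, "_", .data$replicate)) |>
    dplyr::left_join(descr, by = "protein")
  if (style == "generic-wide") {
    tab <- long |>
      dplyr::select(dplyr::all_of(idc), "description", "token", "abundance") |>
      dplyr::mutate(token = paste0("abundance_", .data$token)) |>
      tidyr::pivot_wider(names_from = "token", values_from = "abundance") |>
      dplyr::arrange(dplyr::across(dplyr::all_of(idc)))
  } else {
    tab <- long |>
      dplyr::select(dplyr::all_of(idc), "description", sample = "token",
                    "abundance") |>
      dplyr::arrange(dplyr::across(dplyr::all_of(idc)), .data$sample)
  }
  readr::write_tsv(format_full_precision(tab), path, na = "")
  invisible(path)
}
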