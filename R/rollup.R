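# peptide key independent of owning protein
pep_key <- function(tab) paste(tab$peptide, tab$modification, sep = "\r")

#' Assign peptides to proteins
#'
#' Resolves shared-peptide ownership ahead of [collapse()]:
#'
#' * `all_possible` — every peptide is owned by every candidate protein it
#'   was reported under.
#' * `razor` — each shared peptide is owned solely by the candidate with
#'   the most unique peptides (ties: most total peptides, then the
#'   lexicographically smallest accession).
#' * `non_homologous` — shared peptides are discarded entirely.
#'
#' Unshared peptides keep their single owner under every method.
#'
#' @param dataset A peptide-level `proteomics_dataset`.
#' @param method Inference method (above).
#' @return Tibble of retained (protein, peptide, modification) ownership
#'   rows.
#' @export
assign_peptides <- function(dataset,
                            method = c("all_possible", "razor", "non_homologous")) {
  stopifnot(inherits(dataset, "proteomics_dataset"))
  if (dataset$level != "peptides") stop("already protein level", call. = FALSE)
  method <- match.arg(method)
  cand <- dplyr::distinct(dataset$quantitative[, c("protein", "peptide", "modification")])
  cand$.pep <- pep_key(cand)
  n_owner <- table(cand$.pep)
  cand$.n_owner <- as.integer(n_owner[cand$.pep])

  if (method == "all_possible") {
    out <- cand
  } else if (method == "non_homologous") {
    out <- cand[cand$.n_owner == 1L, ]
  } else {
    uniq_count <- table(cand$protein[cand$.n_owner == 1L])
    tot_count <- table(cand$protein)
    cand$.uniq <- as.integer(uniq_count[cand$protein]); cand$.uniq[is.na(cand$.uniq)] <- 0L
    cand$.tot <- as.integer(tot_count[cand$protein])
    out <- cand |>
      dplyr::group_by(.data$.pep) |>
      dplyr::arrange(dplyr::desc(.data$.uniq), dplyr::desc(.data$.tot),
                     .data$protein, .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
  }
  dplyr::select(out, "protein", "peptide", "modification")
}

#' Split a shared peptide's abundance among candidate proteins
#'
#' Divides one observed abundance among owner proteins in proportion to
#' each owner's unique-peptide abundance total in that sample; when every
#' total is zero or absent the value splits equally. Contributions always
#' sum back to the input value exactly.
#'
#' @param value Observed peptide abundance (single positive number).
#' @param unique_totals Named numeric vector: per owner protein, the sum of
#'   its unique-peptide abundances in the same sample (`NA` treated as 0).
#' @return Named numeric vector of contributions, one per owner.
#' @export
#' @examples
#' split_shared(100, c(A = 300, B = 100))  # A 75, B 25
split_shared <- function(value, unique_totals) {
  u <- unique_totals
  u[is.na(u)] <- 0
  if (sum(u) <= 0) {
    w <- rep(1 / length(u), length(u))
  } else {
    w <- u / sum(u)
  }
  stats::setNames(value * w, names(unique_totals))
}

summary_function <- function(summary_fn) {
  if (is.function(summary_fn)) return(summary_fn)
  switch(summary_fn,
         sum = sum, mean = mean, median = stats::median,
         stop("unknown summary function '", summary_fn, "'", call. = FALSE))
}

#' Collapse a peptide dataset to protein level
#'
#' Rolls quantified peptides up to proteins: ownership is resolved by the
#' chosen inference method ([assign_peptides()]); with
#' `assign_method = "all_possible"` and `split_abundance = TRUE`, shared
#' peptides are divided among owners by their per-sample unique-peptide
#' abundance proportions ([split_shared()], computed on the `raw` channel).
#' Per protein, peptides are ranked once by mean non-missing abundance
#' across samples and the top `top_n` retained (ties break
#' lexicographically); the summary function then aggregates the non-missing
#' contributions per sample and channel. A protein is missing in a sample
#' only when every contributing peptide is. Accounting counts peptides and
#' unique peptides per sample and carries the imputed fraction forward;
#' annotations transfer by protein.
#'
#' @param x A peptide-level `proteomics_dataset`.
#' @param assign_method `"all_possible"`, `"razor"` or `"non_homologous"`.
#' @param ... Unused.
#' @param split_abundance Split shared peptides proportionally
#'   (`all_possible` only).
#' @param top_n Number of peptides per protein, ranked by abundance;
#'   `Inf` (the default) uses all.
#' @param summary_fn `"sum"`, `"mean"`, `"median"`, or a function.
#' @return A protein-level `proteomics_dataset`.
#' @export
collapse <- function(x, ...) UseMethod("collapse")

#' @rdname collapse
#' @export
#' @exportS3Method dplyr::collapse
collapse.proteomics_dataset <- function(x, assign_method = c("all_possible", "razor", "non_homologous"),
                                        split_abundance = FALSE, top_n = Inf,
                                        summary_fn = "sum", ...) {
  dataset <- x
  if (dataset$level != "peptides") stop("already protein level", call. = FALSE)
  if (!nrow(dataset$quantitative)) stop("empty dataset", call. = FALSE)
  assign_method <- match.arg(assign_method)
  stopifnot(is.infinite(top_n) || top_n >= 1)
  fn <- summary_function(summary_fn)
  chans <- channel_names(dataset)

  own <- assign_peptides(dataset, assign_method)
  own$.pep <- pep_key(own)
  cand <- dplyr::distinct(dataset$quantitative[, c("protein", "peptide", "modification")])
  n_owner <- table(pep_key(cand))

  # one value per (peptide, sample, channel): candidate duplicates carry
  # identical abundances, so collapse them by mean
  qn <- dataset$quantitative
  qn$.pep <- pep_key(qn)
  vals <- qn |>
    dplyr::group_by(.data$.pep, .data$peptide, .data$modification, .data$sample_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(chans),
                                   ~ if (all(is.na(.x))) NA_real_ else mean(.x, na.rm = TRUE)),
                     .groups = "drop")

  contrib <- dplyr::inner_join(own, vals, by = c(".pep", "peptide", "modification"),
                               relationship = "many-to-many")
  contrib$.n_owner <- as.integer(n_owner[contrib$.pep])

  if (assign_method == "all_possible" && split_abundance) {
    uniq_tot <- contrib |>
      dplyr::filter(.data$.n_owner == 1L) |>
      dplyr::group_by(.data$protein, .data$sample_id) |>
      dplyr::summarise(.u = sum(.data$raw, na.rm = TRUE), .groups = "drop")
    contrib <- dplyr::left_join(contrib, uniq_tot, by = c("protein", "sample_id"))
    contrib$.u[is.na(contrib$.u)] <- 0
    contrib <- contrib |>
      dplyr::group_by(.data$.pep, .data$sample_id) |>
      dplyr::mutate(.w = if (sum(.data$.u) > 0) .data$.u / sum(.data$.u)
                    else 1 / dplyr::n()) |>
      dplyr::ungroup()
    for (ch in chans) contrib[[ch]] <- contrib[[ch]] * contrib$.w
    contrib$.u <- contrib$.w <- NULL
  }

  # one abundance ranking per protein, shared across samples
  ranked <- contrib |>
    dplyr::group_by(.data$protein, .data$.pep) |>
    dplyr::summarise(.mean_ab = if (all(is.na(.data$raw))) -Inf else
      mean(.data$raw, na.rm = TRUE), .groups = "drop_last") |>
    dplyr::arrange(dplyr::desc(.data$.mean_ab), .data$.pep, .by_group = TRUE) |>
    dplyr::mutate(.rank = dplyr::row_number()) |>
    dplyr::ungroup()
  keep <- ranked[is.infinite(top_n) | ranked$.rank <= top_n, c("protein", ".pep")]
  contrib <- dplyr::semi_join(contrib, keep, by = c("protein", ".pep"))

  # imputed flags per (peptide, sample) from peptide-level accounting
  acc <- dataset$accounting
  acc$.pep <- pep_key(acc)
  imp <- acc |>
    dplyr::group_by(.data$.pep, .data$sample_id) |>
    dplyr::summarise(.imp = max(.data$imputed, na.rm = TRUE), .groups = "drop")
  contrib <- dplyr::left_join(contrib, imp, by = c(".pep", "sample_id"))
  contrib$.imp[is.na(contrib$.imp)] <- 0
  # contribution counting follows the channel analyses read (imputed cells
  # count as contributing there), not the raw channel
  sel <- if (dataset$selected_channel %in% chans) dataset$selected_channel else "raw"
  contrib$.cnt <- !is.na(contrib[[sel]])

  quant <- contrib |>
    dplyr::group_by(.data$protein, .data$sample_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(chans),
                                   ~ if (all(is.na(.x))) NA_real_ else fn(.x[!is.na(.x)])),
                     .groups = "drop") |>
    dplyr::select("sample_id", "protein", dplyr::all_of(chans))
  # a protein whose peptides all carry zero split weight has no abundance
  for (ch in chans) quant[[ch]][!is.na(quant[[ch]]) & quant[[ch]] <= 0] <- NA_real_

  account <- contrib |>
    dplyr::group_by(.data$protein, .data$sample_id) |>
    dplyr::summarise(
      imputed = if (any(.data$.cnt)) mean(.data$.imp[.data$.cnt]) else 0,
      num_peptides = sum(.data$.cnt),
      num_unique_peptides = sum(.data$.cnt & .data$.n_owner == 1L),
      num_proteins = 1L,
      .groups = "drop") |>
    dplyr::select("sample_id", "protein", "imputed", "num_peptides",
                  "num_unique_peptides", "num_proteins")

  out <- new_proteomics_dataset(
    experiments  = dataset$experiments,
    quantitative = quant,
    accounting   = account,
    annotations  = dplyr::filter(dataset$annotations,
                                 .data$protein %in% unique(quant$protein)),
    level = "proteins",
    selected_channel = dataset$selected_channel,
    ledger = dataset$ledger
  )
  append_ledger(out, "collapse", list(
    assign_method = assign_method, split_abundance = split_abundance,
    top_n = if (is.infinite(top_n)) "ALL" else top_n,
    summary_fn = if (is.function(summary_fn)) "user_function" else summary_fn
  ))
}
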