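#' The four-table quantitative proteomics data object
#'
#' A `proteomics_dataset` standardizes quantified peptide- or protein-level
#' data from any search platform into four non-redundant tables:
#'
#' * `experiments` — one row per LCMS run: `sample_id` (an 8-character
#'   digest identifier), `import_file`, `sample_file`, `sample` (the sample
#'   group) and `replicate`.
#' * `quantitative` — one row per (run, identifier) with one abundance
#'   column per channel; the `raw` channel is always present and further
#'   channels are named after the normalization method that produced them
#'   (`median`, `linear`, `loess`, `randomforest`). Missing abundances are
#'   `NA`, never zero.
#' * `accounting` — per (run, identifier) bookkeeping: the fraction of
#'   values imputed (`imputed`, in \[0,1\]) and integer counts of peptides,
#'   unique peptides and candidate proteins.
#' * `annotations` — a one-to-many map from a protein identifier to
#'   (`term`, `annotation`) pairs, e.g. term `"molecular function"`,
#'   annotation `"metal ion binding"`.
#'
#' The object additionally carries `level` (`"peptides"` or `"proteins"`),
#' `selected_channel` (the channel used by all downstream analyses and
#' plots) and an append-only operations ledger recording every
#' transformation (see [operations()]).
#'
#' Identifiers are the `protein` accession at protein level and the
#' (`protein`, `peptide`, `modification`) triple at peptide level. A shared
#' peptide appears once per candidate protein with an identical abundance.
#'
#' @param experiments,quantitative,accounting,annotations Tibbles following
#'   the schema above.
#' @param level `"peptides"` or `"proteins"`.
#' @param selected_channel Name of the abundance channel used downstream.
#' @param ledger A list of ledger entries (see [operations()]); normally
#'   left empty and populated by the pipeline verbs.
#'
#' @return A `proteomics_dataset` object.
#' @seealso [validate()], [operations()], [to_table()], [import_data()]
#' @export
new_proteomics_dataset <- function(experiments, quantitative, accounting,
                                   annotations = NULL,
                                   level = c("peptides", "proteins"),
                                   selected_channel = "raw",
                                   ledger = list()) {
  level <- match.arg(level)
  if (is.null(annotations)) {
    annotations <- tibble::tibble(protein = character(), term = character(),
                                  annotation = character())
  }
  x <- structure(
    list(
      experiments  = tibble::as_tibble(experiments),
      quantitative = tibble::as_tibble(quantitative),
      accounting   = tibble::as_tibble(accounting),
      annotations  = tibble::as_tibble(annotations),
      ledger       = ledger,
      level        = level,
      selected_channel = selected_channel
    ),
    class = "proteomics_dataset"
  )
  x
}

#' @export
print.proteomics_dataset <- function(x, ...) {
  chans <- channel_names(x)
  cat(sprintf("<proteomics_dataset> level=%s\n", x$level))
  cat(sprintf("  experiments:  %d runs, %d sample groups\n",
              nrow(x$experiments), dplyr::n_distinct(x$experiments$sample)))
  cat(sprintf("  quantitative: %d identifiers x %d runs\n",
              dplyr::n_distinct(identifier_key(x)), nrow(x$experiments)))
  cat(sprintf("  channels:     %s (selected: %s)\n",
              paste(chans, collapse = ", "), x$selected_channel))
  cat(sprintf("  annotations:  %d rows, terms: %s\n", nrow(x$annotations),
              paste(unique(x$annotations$term), collapse = ", ")))
  cat(sprintf("  operations:   %d recorded\n", length(x$ledger)))
  invisible(x)
}

# identifier columns for the current quantitation level
id_cols <- function(x) {
  if (x$level == "peptides") c("protein", "peptide", "modification") else "protein"
}

# abundance channel columns of the quantitative table
channel_names <- function(x) {
  setdiff(names(x$quantitative), c("sample_id", "protein", "peptide", "modification"))
}

# single string key per quantitative row (identifier only, not sample)
identifier_key <- function(x, table = x$quantitative) {
  do.call(paste, c(unname(as.list(table[intersect(id_cols(x), names(table))])),
                   sep = "\r"))
}

experiment_fields <- function() c("sample_id", "import_file", "sample_file", "sample", "replicate")
accounting_fields <- function(x) {
  setdiff(names(x$accounting), c("sample_id", "protein", "peptide", "modification"))
}

#' Generate the 8-character sample identifier
#'
#' Deterministic identifier for one LCMS run: the first 8 lowercase hex
#' characters of the SHA-1 digest of `"<import_file>|<sample_file>"`. The
#' same pair of names always yields the same identifier, so re-imports and
#' merges are stable.
#'
#' @param import_file,sample_file Non-empty source-file and run-file names.
#'   Vectorized over both.
#' @return Character vector of 8-character identifiers.
#' @export
#' @examples
#' make_sample_id("a.tsv", "s1.raw")
make_sample_id <- function(import_file, sample_file) {
  if (any(!nzchar(import_file)) || any(!nzchar(sample_file))) {
    stop("empty source name", call. = FALSE)
  }
  vapply(paste0(import_file, "|", sample_file),
         function(s) substr(cli::hash_sha1(s), 1L, 8L),
         character(1), USE.NAMES = FALSE)
}

# ---- operations ledger -------------------------------------------------

# literature references attached to ledger entries, per method
.op_citations <- list(
  loess        = "Cleveland WS (1979) Robust locally weighted regression. JASA 74:829-836",
  randomforest = "Breiman L (2001) Random forests. Mach Learn 45:5-32",
  missforest   = "Stekhoven DJ, Buehlmann P (2012) MissForest. Bioinformatics 28:112-118",
  limma_moderated = "Smyth GK (2004) Linear models and empirical Bayes methods. SAGMB 3:Art3",
  gsea         = "Subramanian A et al. (2005) Gene set enrichment analysis. PNAS 102:15545-15550",
  bh           = "Benjamini Y, Hochberg Y (1995) Controlling the false discovery rate. JRSS-B 57:289-300"
)

append_ledger <- function(x, verb, params = list(), citations = character()) {
  params <- lapply(params, function(v) paste(format(v, trim = TRUE), collapse = ","))
  entry <- list(
    ordinal   = length(x$ledger) + 1L,
    verb      = verb,
    params    = params,
    citations = citations
  )
  x$ledger <- c(x$ledger, list(entry))
  x
}

#' Retrieve the operations ledger
#'
#' Every transformation applied to a dataset appends one entry to an
#' immutable ledger: an ordinal, the verb, its parameters, and any relevant
#' literature citations. `operations()` renders the ledger as
#' human-readable lines in order of application.
#'
#' @param dataset A `proteomics_dataset`.
#' @return Character vector, one line per recorded operation.
#' @export
operations <- function(dataset) {
  stopifnot(inherits(dataset, "proteomics_dataset"))
  vapply(dataset$ledger, function(e) {
    p <- if (length(e$params)) {
      paste(names(e$params), unlist(e$params), sep = "=", collapse = ", ")
    } else ""
    refs <- if (length(e$citations)) {
      paste0("  [", paste(e$citations, collapse = "; "), "]")
    } else ""
    sprintf("%d. %s(%s)%s", e$ordinal, e$verb, p, refs)
  }, character(1))
}

ledger_verbs <- function(dataset) {
  vapply(dataset$ledger, `[[`, character(1), "verb")
}

# ---- validation --------------------------------------------------------

#' Validate a proteomics dataset against its schema invariants
#'
#' Checks every structural invariant of the four-table model and returns a
#' report; validation never throws. An empty report means the dataset is
#' well formed.
#'
#' Rules checked: 8-character unique sample identifiers; unique
#' (sample, replicate) pairs; every quantitative `sample_id` present in
#' `experiments`; strictly positive non-missing abundances; identifier
#' columns matching the quantitation level; `imputed` in \[0,1\];
#' `num_unique_peptides <= num_peptides`; accounting keys a subset of
#' quantitative keys; no duplicated (identifier, term, annotation) rows;
#' consecutive ledger ordinals; and a `selected_channel` that exists.
#'
#' @param dataset A `proteomics_dataset`.
#' @return Character vector of violation descriptions (possibly empty),
#'   each naming the table, the key involved, and the violated rule.
#' @export
validate <- function(dataset) {
  UseMethod("validate")
}

#' @export
validate.proteomics_dataset <- function(dataset) {
  x <- dataset
  bad <- character()
  ex <- x$experiments
  qn <- x$quantitative

  if (any(nchar(ex$sample_id) != 8L)) {
    bad <- c(bad, sprintf("experiments: sample_id '%s' is not 8 characters",
                          ex$sample_id[nchar(ex$sample_id) != 8L]))
  }
  dup_id <- ex$sample_id[duplicated(ex$sample_id)]
  if (length(dup_id)) {
    bad <- c(bad, sprintf("experiments: sample_id '%s' is not unique", unique(dup_id)))
  }
  sr <- paste(ex$sample, ex$replicate)
  if (anyDuplicated(sr)) {
    bad <- c(bad, sprintf("experiments: (sample, replicate) pair '%s' duplicated",
                          unique(sr[duplicated(sr)])))
  }

  orphan <- setdiff(unique(qn$sample_id), ex$sample_id)
  if (length(orphan)) {
    bad <- c(bad, sprintf("experiments: quantitative sample_id '%s' absent from experiments",
                          orphan))
  }

  need <- id_cols(x)
  miss_col <- setdiff(need, names(qn))
  if (length(miss_col)) {
    bad <- c(bad, sprintf("quantitative: identifier column '%s' missing at level=%s",
                          miss_col, x$level))
  }
  if (x$level == "proteins" && any(c("peptide", "modification") %in% names(qn))) {
    bad <- c(bad, "quantitative: peptide columns present at level=proteins")
  }

  chans <- channel_names(x)
  if (!"raw" %in% chans) bad <- c(bad, "quantitative: required channel 'raw' absent")
  for (ch in chans) {
    v <- qn[[ch]]
    if (!is.numeric(v)) {
      bad <- c(bad, sprintf("quantitative: channel '%s' is not numeric", ch))
    } else if (any(v[!is.na(v)] <= 0)) {
      bad <- c(bad, sprintf("quantitative: channel '%s' has non-positive abundances", ch))
    }
  }
  if (!x$selected_channel %in% chans) {
    bad <- c(bad, sprintf("quantitative: selected channel '%s' not in channel set",
                          x$selected_channel))
  }

  ac <- x$accounting
  if (nrow(ac)) {
    out_imp <- !is.na(ac$imputed) & (ac$imputed < 0 | ac$imputed > 1)
    if (any(out_imp)) {
      bad <- c(bad, sprintf("accounting: key (%s, %s) imputed out of [0,1]",
                            ac$sample_id[out_imp], identifier_key(x, ac)[out_imp]))
    }
    if (all(c("num_unique_peptides", "num_peptides") %in% names(ac))) {
      over <- !is.na(ac$num_unique_peptides) & !is.na(ac$num_peptides) &
        ac$num_unique_peptides > ac$num_peptides
      if (any(over)) {
        bad <- c(bad, sprintf("accounting: key (%s, %s) num_unique_peptides exceeds num_peptides",
                              ac$sample_id[over], identifier_key(x, ac)[over]))
      }
    }
    qkey <- paste(qn$sample_id, identifier_key(x, qn))
    akey <- paste(ac$sample_id, identifier_key(x, ac))
    stray <- setdiff(akey, qkey)
    if (length(stray)) {
      bad <- c(bad, sprintf("accounting: key '%s' absent from quantitative", stray))
    }
  }

  an <- x$annotations
  if (nrow(an)) {
    akey <- paste(an$protein, an$term, an$annotation, sep = "\r")
    if (anyDuplicated(akey)) {
      bad <- c(bad, sprintf("annotations: duplicated (identifier, term, annotation) row for protein '%s'",
                            unique(an$protein[duplicated(akey)])))
    }
  }

  ords <- vapply(x$ledger, `[[`, integer(1), "ordinal")
  if (length(ords) && !identical(ords, seq_along(ords))) {
    bad <- c(bad, "ledger: ordinals are not consecutive from 1")
  }

  unique(bad)
}

# ---- merge -------------------------------------------------------------

# relabel duplicated (sample, replicate) pairs by suffixing ".2", ".3", ...
dedupe_replicates <- function(experiments) {
  key <- paste(experiments$sample, experiments$replicate)
  changed <- character()
  while (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    rep0 <- experiments$replicate[i]
    n <- 2L
    repeat {
      cand <- paste0(rep0, ".", n)
      if (!any(experiments$sample == experiments$sample[i] &
               experiments$replicate == cand)) break
      n <- n + 1L
    }
    experiments$replicate[i] <- cand
    changed <- c(changed, sprintf("%s:%s->%s", experiments$sample[i], rep0, cand))
    key <- paste(experiments$sample, experiments$replicate)
  }
  list(experiments = experiments, relabeled = changed)
}

#' Merge proteomics datasets
#'
#' Combines two or more datasets of the same quantitation level and channel
#' set into one collective: experiments, quantitative, accounting and
#' annotation tables are unioned. Sample identifiers are regenerated from
#' (`import_file`, `sample_file`); when the same pair occurs in more than
#' one input the later `sample_file` is disambiguated with a `#2` suffix
#' before digesting. Duplicate (sample, replicate) pairs are relabeled with
#' a numeric suffix and the relabeling is recorded. Ledgers are
#' concatenated per source, then a `merge` entry is appended.
#'
#' @param x,y `proteomics_dataset` objects.
#' @param ... Further datasets.
#' @return A merged `proteomics_dataset`.
#' @export
merge.proteomics_dataset <- function(x, y, ...) {
  datasets <- c(list(x, y), list(...))
  stopifnot(all(vapply(datasets, inherits, logical(1), "proteomics_dataset")))
  lv <- unique(vapply(datasets, `[[`, character(1), "level"))
  if (length(lv) > 1) stop("level mismatch: ", paste(lv, collapse = " vs "), call. = FALSE)
  chans <- lapply(datasets, channel_names)
  if (length(unique(lapply(chans, sort))) > 1) {
    stop("channel mismatch: datasets carry different channel sets", call. = FALSE)
  }

  seen_pairs <- character()
  parts <- lapply(datasets, function(d) {
    ex <- d$experiments
    pair <- paste0(ex$import_file, "|", ex$sample_file)
    for (i in seq_along(pair)) {
      n <- 2L
      while (pair[i] %in% seen_pairs) {
        ex$sample_file[i] <- paste0(d$experiments$sample_file[i], "#", n)
        pair[i] <- paste0(ex$import_file[i], "|", ex$sample_file[i])
        n <- n + 1L
      }
      seen_pairs <<- c(seen_pairs, pair[i])
    }
    new_id <- make_sample_id(ex$import_file, ex$sample_file)
    map <- stats::setNames(new_id, d$experiments$sample_id)
    ex$sample_id <- new_id
    qn <- d$quantitative; qn$sample_id <- unname(map[qn$sample_id])
    ac <- d$accounting;   ac$sample_id <- unname(map[ac$sample_id])
    list(ex = ex, qn = qn, ac = ac, an = d$annotations)
  })

  ex <- dplyr::bind_rows(lapply(parts, `[[`, "ex"))
  dd <- dedupe_replicates(ex)
  merged <- new_proteomics_dataset(
    experiments  = dd$experiments,
    quantitative = dplyr::bind_rows(lapply(parts, `[[`, "qn")),
    accounting   = dplyr::bind_rows(lapply(parts, `[[`, "ac")),
    annotations  = dplyr::distinct(dplyr::bind_rows(lapply(parts, `[[`, "an"))),
    level        = lv,
    selected_channel = datasets[[1]]$selected_channel
  )
  entries <- unlist(lapply(datasets, `[[`, "ledger"), recursive = FALSE)
  merged$ledger <- lapply(seq_along(entries), function(i) {
    e <- entries[[i]]; e$ordinal <- i; e
  })
  merged <- append_ledger(merged, "merge", list(
    n_datasets = length(datasets),
    relabeled = if (length(dd$relabeled)) paste(dd$relabeled, collapse = ";") else "none"
  ))
  merged
}

#' Reassign sample groups or replicates
#'
#' Rewrites the `sample` or `replicate` field of the experiment rows
#' matched by a semantic selector (see [parse_expression()]), e.g. to
#' collect runs from several sources into one sample group. Quantitative
#' and accounting joins are untouched (they key on `sample_id`). Any
#' (sample, replicate) collision created by the reassignment is resolved by
#' suffixing the replicate label.
#'
#' @param dataset A `proteomics_dataset`.
#' @param selector Filter expression over experiment fields, as text (e.g.
#'   `"sample_file %like% 'ctrl'"`) or a parsed `filter_expression`.
#' @param field `"sample"` or `"replicate"`.
#' @param value Replacement string.
#' @return The modified dataset (a new value; inputs are never mutated).
#' @export
reassign <- function(dataset, selector, field = c("sample", "replicate"), value) {
  stopifnot(inherits(dataset, "proteomics_dataset"))
  field <- match.arg(field)
  fx <- as_filter_expression(selector)
  if (!fx$variable %in% experiment_fields()) {
    stop(sprintf("unknown experiment field '%s'; available: %s", fx$variable,
                 paste(experiment_fields(), collapse = ", ")), call. = FALSE)
  }
  hit <- eval_predicate(dataset$experiments, fx)
  if (!any(hit)) stop("no samples matched by '", deparse_filter(fx), "'", call. = FALSE)
  ex <- dataset$experiments
  ex[[field]][hit] <- value
  dd <- dedupe_replicates(ex)
  dataset$experiments <- dd$experiments
  append_ledger(dataset, "reassign", list(
    selector = deparse_filter(fx), field = field, value = value,
    n_matched = sum(hit),
    relabeled = if (length(dd$relabeled)) paste(dd$relabeled, collapse = ";") else "none"
  ))
}

# ---- summaries ---------------------------------------------------------

#' Summarize a dataset by sample field or annotation term
#'
#' Group-wise summary statistics over the selected channel: number of
#' distinct identifiers observed, total and mean abundance, the median
#' within-group coefficient of variation of replicate measurements, and
#' the mean imputed fraction. Groups come either from an experiment field
#' (`sample`, `replicate`, ...) or from the values of any annotation term
#' present in the dataset (e.g. `"molecular function"`).
#'
#' @param object A `proteomics_dataset`.
#' @param by Experiment field or annotation term name.
#' @param ... Unused.
#' @return A tibble with one row per group.
#' @export
summary.proteomics_dataset <- function(object, by = "sample", ...) {
  x <- object
  long <- dataset_long(x, x$selected_channel)
  terms <- unique(x$annotations$term)
  if (by %in% setdiff(experiment_fields(), "sample_id")) {
    long$group <- long[[by]]
  } else if (by %in% terms) {
    ann <- dplyr::filter(x$annotations, .data$term == by)
    long <- dplyr::inner_join(long, dplyr::select(ann, "protein", group = "annotation"),
                              by = "protein", relationship = "many-to-many")
  } else {
    stop(sprintf("unknown grouping '%s'; available fields: %s; annotation terms: %s",
                 by, paste(setdiff(experiment_fields(), "sample_id"), collapse = ", "),
                 if (length(terms)) paste(terms, collapse = ", ") else "<none>"),
         call. = FALSE)
  }
  cvs <- long |>
    dplyr::group_by(.data$group, .data$.id, .data$sample) |>
    dplyr::summarise(
      cv = ifelse(sum(!is.na(.data$abundance)) >= 2,
                  stats::sd(.data$abundance, na.rm = TRUE) /
                    mean(.data$abundance, na.rm = TRUE), NA_real_),
      .groups = "drop") |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(cv_median = stats::median(.data$cv, na.rm = TRUE), .groups = "drop")
  base <- long |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_identifiers = dplyr::n_distinct(.data$.id[!is.na(.data$abundance)]),
      abundance_total = sum(.data$abundance, na.rm = TRUE),
      abundance_mean = mean(.data$abundance, na.rm = TRUE),
      imputed_mean = mean(.data$imputed, na.rm = TRUE),
      .groups = "drop")
  dplyr::left_join(base, cvs, by = "group")
}

# long helper: one row per (identifier, run) with abundance of `channel`
# plus experiment fields and accounting columns; .id is the identifier key
dataset_long <- function(x, channel = x$selected_channel) {
  if (!channel %in% channel_names(x)) {
    stop(sprintf("unknown channel '%s'; available: %s", channel,
                 paste(channel_names(x), collapse = ", ")), call. = FALSE)
  }
  idc <- id_cols(x)
  qn <- dplyr::select(x$quantitative, "sample_id", dplyr::all_of(idc),
                      abundance = dplyr::all_of(channel))
  qn$.id <- identifier_key(x, qn)
  qn <- dplyr::left_join(qn, x$experiments, by = "sample_id")
  acc <- x$accounting
  if (nrow(acc)) {
    qn <- dplyr::left_join(qn, acc, by = c("sample_id", idc))
  }
  qn
}

#' Export a dataset as a long or wide table
#'
#' Long shape yields one row per (identifier, run) with the abundance of
#' the requested channel plus accounting columns; wide shape yields one row
#' per identifier with one `abundance_<sample>_<replicate>` column per run.
#' Missing values stay `NA` (rendered as empty cells on write). The
#' wide/long renderings are value-identical under round trip.
#'
#' @param dataset A `proteomics_dataset`.
#' @param shape `"long"` or `"wide"`.
#' @param channel Abundance channel to export (default: selected channel).
#' @return A tibble.
#' @export
to_table <- function(dataset, shape = c("long", "wide"),
                     channel = dataset$selected_channel) {
  stopifnot(inherits(dataset, "proteomics_dataset"))
  shape <- match.arg(shape)
  idc <- id_cols(dataset)
  long <- dataset_long(dataset, channel)
  long <- dplyr::select(long, dplyr::all_of(idc), "sample_id", "sample",
                        "replicate", "abundance",
                        dplyr::any_of(c("imputed", "num_peptides",
                                        "num_unique_peptides", "num_proteins")))
  if (shape == "long") return(long)
  long |>
    dplyr::mutate(col = paste0("abundance_", .data$sample, "_", .data$replicate)) |>
    dplyr::select(dplyr::all_of(idc), "col", "abundance") |>
    tidyr::pivot_wider(names_from = "col", values_from = "abundance") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(idc)))
}

#' Set the active abundance channel
#'
#' Downstream analyses and plot builders read `selected_channel`; this
#' overrides any automatic choice made by [select_normalization()].
#'
#' @param dataset A `proteomics_dataset`.
#' @param channel Existing channel name.
#' @return The dataset with `selected_channel` updated (logged).
#' @export
set_normalization <- function(dataset, channel) {
  stopifnot(inherits(dataset, "proteomics_dataset"))
  if (!channel %in% channel_names(dataset)) {
    stop(sprintf("unknown channel '%s'; available: %s", channel,
                 paste(channel_names(dataset), collapse = ", ")), call. = FALSE)
  }
  dataset$selected_channel <- channel
  append_ledger(dataset, "set_normalization", list(channel = channel))
}
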