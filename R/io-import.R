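#' Read a declarative import directive
#'
#' An import directive maps the columns of a platform's flat-file export
#' onto the canonical four-table schema, so that almost any delimited
#' export can be consumed without a native parser. Directives are YAML
#' key/value files with fields:
#'
#' * `platform` — free-text name.
#' * `orientation` — `wide` (one abundance column per run) or `long` (a
#'   sample column plus an abundance column).
#' * `level` — `peptides` or `proteins`.
#' * `identifier_map` — canonical field (`protein`, and `peptide` /
#'   `modification` at peptide level) to source column name.
#' * `abundance_pattern` — wide: a regular expression with one capture
#'   group yielding the sample token, e.g. `"^abundance_(.+)$"`; long: give
#'   `sample_column` and `abundance_column` instead.
#' * `accounting_map` (optional) — accounting field to source column.
#' * `annotation_map` (optional) — annotation term to source column.
#' * `aggregate` (optional) — `"sum"` to sum duplicated identifier rows
#'   instead of erroring.
#' * `replicate_pattern` (optional) — regex with one capture extracting the
#'   replicate from the sample token (default: trailing `_<int>`).
#'
#' The delimiter defaults from the data-file extension (`.csv` comma,
#' `.tsv`/`.txt` tab) and can be overridden with `delimiter`.
#'
#' Two built-in directives ship with the package and can be named directly
#' in [import_data()]: `"generic-wide"` and `"generic-long"` (the canonical
#' fixture dialects, peptide level) and `"maxquant-proteins"` (a
#' protein-table dialect with `Intensity <sample>` columns).
#'
#' @param path Path to a directive file, or the name of a built-in.
#' @return An `import_directive` object.
#' @export
read_directive <- function(path) {
  builtin <- system.file("extdata", "directives", paste0(path, ".yaml"),
                         package = "proteopost")
  if (!file.exists(path) && nzchar(builtin)) path <- builtin
  if (!file.exists(path)) stop("directive not found: ", path, call. = FALSE)
  d <- yaml::read_yaml(path)
  defaults <- list(platform = "custom", orientation = "wide", level = "peptides",
                   delimiter = NULL, accounting_map = list(),
                   annotation_map = list(), aggregate = "error",
                   replicate_pattern = "_([0-9]+)$",
                   sample_column = NULL, abundance_column = NULL)
  d <- utils::modifyList(defaults, d)
  if (is.null(d$identifier_map) || is.null(d$identifier_map$protein)) {
    stop("no protein column mapped in directive", call. = FALSE)
  }
  if (d$level == "peptides" && is.null(d$identifier_map$peptide)) {
    stop("level=peptides requires a peptide column mapping", call. = FALSE)
  }
  if (d$orientation == "wide" && is.null(d$abundance_pattern)) {
    stop("wide orientation requires abundance_pattern", call. = FALSE)
  }
  if (d$orientation == "long" &&
      (is.null(d$sample_column) || is.null(d$abundance_column))) {
    stop("long orientation requires sample_column and abundance_column", call. = FALSE)
  }
  structure(d, class = "import_directive")
}

delimiter_for <- function(directive, file) {
  if (!is.null(directive$delimiter)) return(directive$delimiter)
  if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
}

# split a sample token into (sample group, replicate)
parse_sample_token <- function(token, replicate_pattern = "_([0-9]+)$") {
  m <- stringr::str_match(token, replicate_pattern)
  replicate <- ifelse(is.na(m[, 2]), "1", m[, 2])
  sample <- ifelse(is.na(m[, 2]), token,
                   stringr::str_remove(token, replicate_pattern))
  list(sample = sample, replicate = replicate)
}

#' Import platform exports into a proteomics dataset
#'
#' Reads one or more delimited export files sharing a schema through an
#' import directive (or the name of a built-in directive) and populates the
#' four-table data object. Sample names are parsed from the abundance
#' column headers (wide) or the sample column (long); the replicate is the
#' trailing `_<int>` of the sample token, else `"1"`. Zeros and empty cells
#' become missing values — abundances are never stored as zero. Only the
#' `raw` channel exists after import. Contaminant or decoy rows are *not*
#' dropped: removal is an explicit [subset()] decision.
#'
#' @param files Character vector of file paths.
#' @param directive An `import_directive`, a directive file path, or a
#'   built-in directive name.
#' @return A `proteomics_dataset` with an `import` ledger entry.
#' @export
import_data <- function(files, directive = "generic-wide") {
  if (!inherits(directive, "import_directive")) directive <- read_directive(directive)
  stopifnot(length(files) >= 1, all(file.exists(files)))
  parts <- lapply(files, function(f) import_one(f, directive))
  ex <- dplyr::bind_rows(lapply(parts, `[[`, "ex"))
  dd <- dedupe_replicates(ex)
  x <- new_proteomics_dataset(
    experiments  = dd$experiments,
    quantitative = dplyr::bind_rows(lapply(parts, `[[`, "qn")),
    accounting   = dplyr::bind_rows(lapply(parts, `[[`, "ac")),
    annotations  = dplyr::distinct(dplyr::bind_rows(lapply(parts, `[[`, "an"))),
    level        = directive$level
  )
  append_ledger(x, "import", list(platform = directive$platform,
                                  files = paste(basename(files), collapse = ",")))
}

import_one <- function(file, d) {
  delim <- delimiter_for(d, file)
  # read everything as text: numeric conversion goes through strtod so a
  # full-precision export parses back to the identical double
  raw <- readr::read_delim(file, delim = delim, show_col_types = FALSE,
                           progress = FALSE, name_repair = "minimal",
                           col_types = readr::cols(.default = readr::col_character()))
  idc <- if (d$level == "peptides") c("protein", "peptide", "modification") else "protein"
  idmap <- d$identifier_map
  ids <- tibble::tibble(.rows = nrow(raw))
  for (f in idc) {
    src <- idmap[[f]]
    ids[[f]] <- if (!is.null(src) && src %in% names(raw)) {
      as.character(raw[[src]])
    } else NA_character_
  }
  if (all(is.na(ids$protein))) stop("no protein column mapped in data", call. = FALSE)

  if (d$orientation == "wide") {
    hits <- stringr::str_match(names(raw), d$abundance_pattern)
    ab_cols <- names(raw)[!is.na(hits[, 1])]
    if (!length(ab_cols)) {
      stop("no abundance columns matched pattern '", d$abundance_pattern, "'",
           call. = FALSE)
    }
    tokens <- hits[!is.na(hits[, 1]), 2]
    quant <- raw[ab_cols]
    names(quant) <- tokens
    long <- dplyr::bind_cols(ids, quant) |>
      tidyr::pivot_longer(dplyr::all_of(tokens), names_to = ".token",
                          values_to = "raw") |>
      dplyr::mutate(raw = suppressWarnings(as.numeric(.data$raw)))
  } else {
    if (!all(c(d$sample_column, d$abundance_column) %in% names(raw))) {
      stop("no abundance columns matched pattern '",
           paste(d$sample_column, d$abundance_column, sep = "/"), "'", call. = FALSE)
    }
    long <- dplyr::bind_cols(ids, tibble::tibble(
      .token = as.character(raw[[d$sample_column]]),
      raw = suppressWarnings(as.numeric(raw[[d$abundance_column]]))
    ))
  }
  long$raw[!is.na(long$raw) & long$raw <= 0] <- NA_real_

  # duplicated identifier rows within one run
  key <- do.call(paste, c(long[c(idc, ".token")], sep = "\r"))
  if (anyDuplicated(key)) {
    if (identical(d$aggregate, "sum")) {
      long <- long |>
        dplyr::group_by(dplyr::across(dplyr::all_of(c(idc, ".token")))) |>
        dplyr::summarise(raw = if (all(is.na(.data$raw))) NA_real_ else
          sum(.data$raw, na.rm = TRUE), .groups = "drop")
    } else {
      stop("non-unique identifiers in ", basename(file),
           "; set aggregate: sum in the directive to combine them", call. = FALSE)
    }
  }

  tok <- sort(unique(long$.token))
  pr <- parse_sample_token(tok, d$replicate_pattern)
  ex <- tibble::tibble(
    sample_id = make_sample_id(basename(file), tok),
    import_file = basename(file), sample_file = tok,
    sample = pr$sample, replicate = pr$replicate
  )
  long$sample_id <- ex$sample_id[match(long$.token, tok)]
  qn <- dplyr::select(long, "sample_id", dplyr::all_of(idc), "raw")

  ac <- dplyr::select(long, "sample_id", dplyr::all_of(idc))
  ac$imputed <- 0
  shared <- ids |>
    dplyr::distinct() |>
    dplyr::count(dplyr::across(dplyr::all_of(setdiff(idc, "protein"))),
                 name = ".n_prot")
  if (d$level == "peptides") {
    ac <- dplyr::left_join(ac, shared, by = setdiff(idc, "protein"))
    ac$num_peptides <- 1L
    ac$num_unique_peptides <- ifelse(ac$.n_prot == 1L, 1L, 0L)
    ac$num_proteins <- as.integer(ac$.n_prot)
    ac$.n_prot <- NULL
  } else {
    ac$num_peptides <- NA_integer_
    ac$num_unique_peptides <- NA_integer_
    ac$num_proteins <- 1L
  }
  for (f in names(d$accounting_map)) {
    src <- d$accounting_map[[f]]
    if (src %in% names(raw)) {
      v <- dplyr::bind_cols(ids, tibble::tibble(.v = raw[[src]])) |> dplyr::distinct()
      ac[[f]] <- NULL
      ac <- dplyr::left_join(ac, stats::setNames(v, c(idc, f)), by = idc)
      ac[[f]] <- if (f == "match_between_runs") as.logical(ac[[f]]) else
        as.integer(ac[[f]])
    }
  }

  an <- tibble::tibble(protein = character(), term = character(),
                       annotation = character())
  for (term in names(d$annotation_map)) {
    src <- d$annotation_map[[term]]
    if (src %in% names(raw)) {
      an <- dplyr::bind_rows(an, tibble::tibble(
        protein = ids$protein, term = term,
        annotation = as.character(raw[[src]])
      ) |> dplyr::filter(!is.na(.data$annotation), nzchar(.data$annotation)) |>
        dplyr::distinct())
    }
  }
  list(ex = ex, qn = qn, ac = ac, an = an)
}

#' Attach annotations from a flat file
#'
#' Joins an annotation table (identifier, term, annotation columns) to the
#' dataset's proteins. Rows whose identifier matches no protein are counted
#' and reported, not fatal; duplicated (identifier, term, annotation) rows
#' collapse to one.
#'
#' @param dataset A `proteomics_dataset`.
#' @param path Delimited annotation file (`.csv` or `.tsv`).
#' @param identifier_column Column holding the protein accession.
#' @param term_columns Character vector of columns to load, each becoming
#'   one annotation term named after the column.
#' @return The dataset with annotation rows appended (logged).
#' @export
load_annotations <- function(dataset, path, identifier_column, term_columns) {
  stopifnot(inherits(dataset, "proteomics_dataset"))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  stopifnot(identifier_column %in% names(tab), all(term_columns %in% names(tab)))
  ann <- tab |>
    dplyr::select(protein = dplyr::all_of(identifier_column),
                  dplyr::all_of(term_columns)) |>
    tidyr::pivot_longer(dplyr::all_of(term_columns), names_to = "term",
                        values_to = "annotation") |>
    dplyr::filter(!is.na(.data$annotation), nzchar(.data$annotation)) |>
    dplyr::mutate(protein = as.character(.data$protein)) |>
    dplyr::distinct()
  known <- unique(dataset$quantitative$protein)
  n_unmatched <- sum(!unique(ann$protein) %in% known)
  ann <- dplyr::filter(ann, .data$protein %in% known)
  if (!nrow(ann)) stop("no annotations matched dataset proteins", call. = FALSE)
  if (n_unmatched > 0) {
    message(n_unmatched, " annotation identifier(s) matched no protein; skipped")
  }
  dataset$annotations <- dplyr::distinct(dplyr::bind_rows(dataset$annotations, ann))
  append_ledger(dataset, "load_annotations", list(
    file = basename(path), terms = paste(term_columns, collapse = ","),
    skipped = n_unmatched
  ))
}

#' Export a dataset to a delimited file
#'
#' Writes the [to_table()] rendering of the selected (or given) channel.
#' Missing values are empty cells; re-importing a wide export through a
#' matching directive reproduces the quantitative values exactly.
#'
#' @param dataset A `proteomics_dataset`.
#' @param path Output file path.
#' @param format `"csv"` or `"tsv"`.
#' @param shape `"long"` or `"wide"`.
#' @param channel Abundance channel to export.
#' @return `path`, invisibly.
#' @export
export_tabular <- function(dataset, path, format = c("tsv", "csv"),
                           shape = c("wide", "long"),
                           channel = dataset$selected_channel) {
  format <- match.arg(format)
  shape <- match.arg(shape)
  tab <- to_table(dataset, shape = shape, channel = channel)
  tab <- format_full_precision(tab)
  if (format == "csv") readr::write_csv(tab, path, na = "")
  else readr::write_tsv(tab, path, na = "")
  invisible(path)
}

# render numeric columns at full precision so delimited round trips are
# bitwise exact (the default writer keeps only 15 significant digits)
format_full_precision <- function(tab) {
  for (col in names(tab)) {
    if (is.double(tab[[col]])) {
      v <- sprintf("%.17g", tab[[col]])
      v[is.na(tab[[col]])] <- NA_character_
      tab[[col]] <- v
    }
  }
  tab
}

# ---- dataset bundle on disk -------------------------------------------

#' Write / read a dataset bundle
#'
#' The on-disk form of a `proteomics_dataset` is a directory of
#' tab-delimited UTF-8 tables — `experiments.tsv`, `quantitative.tsv`
#' (long, all channels), `accounting.tsv`, `annotations.tsv` — plus
#' `operations.json` carrying the ledger, level and selected channel.
#' Empty cells encode missing values. `read_dataset()` restores a
#' value-identical object.
#'
#' @param dataset A `proteomics_dataset`.
#' @param dir Bundle directory (created if needed).
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()`
#'   returns the restored dataset.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "proteomics_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(dataset$experiments, file.path(dir, "experiments.tsv"), na = "")
  readr::write_tsv(format_full_precision(dataset$quantitative),
                   file.path(dir, "quantitative.tsv"), na = "")
  readr::write_tsv(format_full_precision(dataset$accounting),
                   file.path(dir, "accounting.tsv"), na = "")
  readr::write_tsv(dataset$annotations, file.path(dir, "annotations.tsv"), na = "")
  meta <- list(level = dataset$level, selected_channel = dataset$selected_channel,
               ledger = dataset$ledger)
  jsonlite::write_json(meta, file.path(dir, "operations.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  rd <- function(f) {
    readr::read_tsv(file.path(dir, f), show_col_types = FALSE, progress = FALSE,
                    na = "", col_types = readr::cols(.default = readr::col_character()))
  }
  key_cols <- c("sample_id", "protein", "peptide", "modification")
  meta <- jsonlite::read_json(file.path(dir, "operations.json"))
  ex <- rd("experiments.tsv")
  qn <- rd("quantitative.tsv")
  for (col in setdiff(names(qn), key_cols)) qn[[col]] <- as.numeric(qn[[col]])
  ac <- rd("accounting.tsv")
  for (col in setdiff(names(ac), key_cols)) {
    ac[[col]] <- if (startsWith(col, "num_")) as.integer(ac[[col]]) else
      as.numeric(ac[[col]])
  }
  an <- rd("annotations.tsv")
  ledger <- lapply(meta$ledger, function(e) {
    list(ordinal = as.integer(e$ordinal), verb = e$verb,
         params = lapply(e$params, as.character),
         citations = as.character(unlist(e$citations)))
  })
  new_proteomics_dataset(ex, qn, ac, an, level = meta$level,
                         selected_channel = meta$selected_channel,
                         ledger = ledger)
}
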