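#' Regular-expression containment operator
#'
#' `a %like% pattern` is `TRUE` where `pattern` matches anywhere in `a`,
#' case-insensitively. This is the containment semantic used by the
#' [subset()] filter grammar, exposed as an ordinary operator for use on
#' plain vectors.
#'
#' @param a Character vector.
#' @param pattern Single regular expression (unanchored).
#' @return Logical vector.
#' @export
#' @examples
#' c("60S ribosomal protein", "Keratin") %like% "ribosome|ribosomal"
`%like%` <- function(a, pattern) {
  stringr::str_detect(as.character(a),
                      stringr::regex(pattern, ignore_case = TRUE)) & !is.na(a)
}

#' Parse a semantic filter expression
#'
#' The curation grammar is a single predicate:
#' `[!] variable (== | != | < | <= | > | >= | %like%) value`, with the
#' variable and value optionally quoted (so annotation terms containing
#' spaces can be addressed, e.g. `'molecular function' == 'kinase'`).
#' Numeric literals are detected by syntax; `%like%` performs
#' case-insensitive unanchored regular-expression search. Compound
#' (AND/OR) expressions are deliberately out of grammar: chain [subset()]
#' calls instead.
#'
#' @param text Expression text.
#' @return A `filter_expression`: list with `negated`, `variable`,
#'   `operator`, `value`.
#' @export
#' @examples
#' parse_expression("!description %like% 'ribosome'")
#' parse_expression("imputed == 0")
parse_expression <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  re <- paste0(
    "^\\s*(!?)\\s*",
    "(?:'([^']+)'|\"([^\"]+)\"|([A-Za-z_][A-Za-z0-9_.]*))\\s*",
    "(==|!=|<=|>=|<|>|%like%)\\s*",
    "(?:'([^']*)'|\"([^\"]*)\"|(\\S+))\\s*$"
  )
  m <- stringr::str_match(text, re)
  if (is.na(m[1, 1])) {
    # locate the first offending token for a positioned error message
    op_hit <- stringr::str_locate(text, "==|!=|<=|>=|<|>|%like%")
    pos <- if (is.na(op_hit[1, 1])) nchar(text) else op_hit[1, 2]
    stop(sprintf("malformed filter expression near position %d: '%s'", pos, text),
         call. = FALSE)
  }
  variable <- m[1, 3]
  if (is.na(variable)) variable <- m[1, 4]
  if (is.na(variable)) variable <- m[1, 5]
  value <- m[1, 7]; quoted <- TRUE
  if (is.na(value)) value <- m[1, 8]
  if (is.na(value)) { value <- m[1, 9]; quoted <- FALSE }
  if (!quoted && grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", value)) {
    value <- as.numeric(value)
  }
  op <- m[1, 6]
  if (op %in% c("<", "<=", ">", ">=") && !is.numeric(value)) {
    stop("ordering operator '", op, "' requires a numeric value: ", text, call. = FALSE)
  }
  if (op == "%like%" && is.numeric(value)) {
    stop("%like% applies to string values only: ", text, call. = FALSE)
  }
  structure(list(negated = m[1, 2] == "!", variable = variable,
                 operator = if (op == "%like%") "like" else op,
                 value = value),
            class = "filter_expression")
}

as_filter_expression <- function(x) {
  if (inherits(x, "filter_expression")) return(x)
  if (is.character(x)) return(parse_expression(x))
  stop("selector must be a filter expression or its text", call. = FALSE)
}

deparse_filter <- function(fx) {
  v <- if (is.numeric(fx$value)) format(fx$value) else paste0("'", fx$value, "'")
  var <- if (grepl("[^A-Za-z0-9_.]", fx$variable)) paste0("'", fx$variable, "'") else fx$variable
  paste0(if (fx$negated) "!" else "", var, " ",
         if (fx$operator == "like") "%like%" else fx$operator, " ", v)
}

# evaluate the bare (un-negated) comparison of fx on a vector
compare_values <- function(v, fx) {
  val <- fx$value
  out <- switch(fx$operator,
    "like" = v %like% val,
    "==" = if (is.numeric(val)) suppressWarnings(as.numeric(v)) == val else as.character(v) == val,
    "!=" = if (is.numeric(val)) suppressWarnings(as.numeric(v)) != val else as.character(v) != val,
    "<"  = suppressWarnings(as.numeric(v)) <  val,
    "<=" = suppressWarnings(as.numeric(v)) <= val,
    ">"  = suppressWarnings(as.numeric(v)) >  val,
    ">=" = suppressWarnings(as.numeric(v)) >= val
  )
  out & !is.na(out)
}

# evaluate fx (including negation) row-wise on a data frame
eval_predicate <- function(df, fx) {
  if (!fx$variable %in% names(df)) {
    stop(sprintf("unknown field '%s'; available: %s", fx$variable,
                 paste(names(df), collapse = ", ")), call. = FALSE)
  }
  out <- compare_values(df[[fx$variable]], fx)
  if (fx$negated) !out else out
}

# where does a filter variable resolve in this dataset?
resolve_variable <- function(x, variable) {
  if (variable %in% intersect(id_cols(x), names(x$quantitative))) return("identifier")
  if (variable %in% setdiff(experiment_fields(), "sample_id")) return("experiment")
  if (variable %in% accounting_fields(x)) return("accounting")
  if (variable %in% unique(x$annotations$term)) return("annotation")
  stop(sprintf(
    "filter variable '%s' resolves nowhere; identifier fields: %s; experiment fields: %s; accounting fields: %s; annotation terms: %s",
    variable,
    paste(id_cols(x), collapse = ", "),
    paste(setdiff(experiment_fields(), "sample_id"), collapse = ", "),
    paste(accounting_fields(x), collapse = ", "),
    if (nrow(x$annotations)) paste(unique(x$annotations$term), collapse = ", ") else "<none>"
  ), call. = FALSE)
}

#' Filter a dataset with a semantic expression
#'
#' `subset()` evaluates one predicate (see [parse_expression()]) against
#' the dataset and keeps what satisfies it:
#'
#' * identifier fields (`protein`, `peptide`, `modification`) and
#'   annotation terms select whole identifiers across all runs. An
#'   annotation predicate matches an identifier if *any* of its annotation
#'   rows for that term satisfies the comparison; negation then keeps
#'   identifiers with no matching row, so
#'   `!description %like% 'ribosome'` keeps proteins whose description
#'   does not mention ribosome.
#' * experiment fields (`sample`, `replicate`, `sample_file`,
#'   `import_file`) select whole runs.
#' * accounting fields (`imputed`, `num_peptides`, ...) are per-run values;
#'   an identifier is kept if the predicate holds in at least one run, so
#'   partially supported identifiers survive.
#'
#' @param x A `proteomics_dataset`.
#' @param expression Predicate as text, a parsed `filter_expression`, or an
#'   unquoted expression (e.g. `!description %like% 'ribosome'`).
#' @param ... Unused.
#' @return The filtered dataset; dropping every identifier or run is an
#'   error rather than an empty dataset.
#' @export
subset.proteomics_dataset <- function(x, expression, ...) {
  fx <- tryCatch(as_filter_expression(expression), error = function(e) e)
  if (inherits(fx, "error")) {
    txt <- paste(deparse(substitute(expression)), collapse = " ")
    fx <- parse_expression(txt)
  }
  scope <- resolve_variable(x, fx$variable)
  idc <- id_cols(x)

  if (scope == "experiment") {
    keep <- eval_predicate(x$experiments, fx)
    if (!any(keep)) stop("empty dataset: no runs satisfy '", deparse_filter(fx), "'",
                         call. = FALSE)
    ids <- x$experiments$sample_id[keep]
    x$experiments <- x$experiments[keep, ]
    x$quantitative <- dplyr::filter(x$quantitative, .data$sample_id %in% ids)
    x$accounting <- dplyr::filter(x$accounting, .data$sample_id %in% ids)
  } else {
    all_ids <- unique(identifier_key(x))
    keep_ids <- switch(scope,
      identifier = {
        hit <- eval_predicate(x$quantitative, fx)
        unique(identifier_key(x)[hit])
      },
      accounting = {
        raw <- compare_values(x$accounting[[fx$variable]], fx)
        hit_ids <- unique(identifier_key(x, x$accounting)[raw])
        if (fx$negated) setdiff(all_ids, hit_ids) else hit_ids
      },
      annotation = {
        ann <- dplyr::filter(x$annotations, .data$term == fx$variable)
        hit_prot <- unique(ann$protein[compare_values(ann$annotation, fx)])
        hit_ids <- unique(identifier_key(x)[x$quantitative$protein %in% hit_prot])
        if (fx$negated) setdiff(all_ids, hit_ids) else hit_ids
      }
    )
    if (!length(keep_ids)) {
      stop("empty dataset: no identifiers satisfy '", deparse_filter(fx), "'",
           call. = FALSE)
    }
    x$quantitative <- x$quantitative[identifier_key(x) %in% keep_ids, ]
    x$accounting <- x$accounting[identifier_key(x, x$accounting) %in% keep_ids, ]
    x$annotations <- dplyr::filter(x$annotations,
                                   .data$protein %in% unique(x$quantitative$protein))
  }
  append_ledger(x, "subset", list(where = deparse_filter(fx)))
}
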