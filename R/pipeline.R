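pipeline_verbs <- c("import", "simulate", "load_annotations", "subset",
                    "reassign", "normalize", "select_normalization",
                    "set_normalization", "impute", "collapse", "expression",
                    "enrichment", "summary", "export", "operations")

#' Run a configuration-driven analysis pipeline
#'
#' Applies an ordered list of pipeline steps to a dataset, mirroring the
#' interactive verb chain while keeping every run reproducible from one
#' config. Steps may come in any order — normalization before or after
#' imputation, curation wherever it belongs — the order of operations is
#' deliberately unconstrained. The config is validated up front: an
#' unknown verb fails before anything executes.
#'
#' Config structure (a list, or the path of a YAML file):
#'
#' ```yaml
#' input: path/to/bundle        # or a first step of verb import/simulate
#' output: out/                 # bundle written here at the end
#' checkpoint: false            # also write the bundle after each step
#' seed: 1                      # default seed for stochastic steps
#' steps:
#'   - verb: import
#'     files: [peptides.tsv]
#'     directive: generic-wide
#'   - verb: subset
#'     where: "!description %like% 'keratin'"
#'   - verb: normalize
#'     methods: [median, loess]
#'   - verb: impute
#'     method: minimum
#'     scope: within
#'   - verb: collapse
#'   - verb: expression
#'     ratio: kndw/ctrl
#'     method: limma_moderated
#' ```
#'
#' Side-product steps (`expression`, `enrichment`, `summary`) write their
#' result tables under the output directory and keep the dataset flowing;
#' `export` writes a delimited rendering. All randomness (random forest,
#' permutations, simulation) flows from step-level or config-level seeds.
#'
#' @param config List or YAML file path.
#' @param output Output directory (overrides `config$output`).
#' @return Invisibly, a list with the final `dataset` and any side
#'   `results` keyed by step.
#' @export
run_pipeline <- function(config, output = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  steps <- config$steps
  if (is.null(steps) || !length(steps)) stop("config has no steps", call. = FALSE)
  verbs <- vapply(steps, function(s) s$verb %||% "", character(1))
  bad <- setdiff(verbs, pipeline_verbs)
  if (length(bad)) {
    stop("unknown pipeline verb '", paste(bad, collapse = "', '"),
         "'; available: ", paste(pipeline_verbs, collapse = ", "), call. = FALSE)
  }
  if (is.null(config$input) && !verbs[1] %in% c("import", "simulate")) {
    stop("first step must be import/simulate, or config$input must name a bundle",
         call. = FALSE)
  }
  output <- output %||% config$output
  default_seed <- config$seed %||% 1

  dataset <- if (!is.null(config$input)) read_dataset(config$input) else NULL
  results <- list()
  for (k in seq_along(steps)) {
    s <- steps[[k]]
    t0 <- Sys.time()
    dataset <- switch(s$verb,
      import = import_data(unlist(s$files), s$directive %||% "generic-wide"),
      simulate = {
        sim <- do.call(simulate_dataset,
                       c(s[setdiff(names(s), c("verb"))],
                         if (is.null(s$seed)) list(seed = default_seed)))
        results[[paste0(k, "_truth")]] <- sim$truth
        sim$dataset
      },
      load_annotations = load_annotations(dataset, s$path, s$identifier_column,
                                          unlist(s$term_columns)),
      subset = base::subset(dataset, s$where),
      reassign = reassign(dataset, s$selector, s$field, s$value),
      normalize = normalize(dataset,
                            methods = unlist(s$methods) %||% norm_methods,
                            basis = s$basis, seed = s$seed %||% default_seed),
      select_normalization = select_normalization(
        dataset, weights = unlist(s$weights) %||% c(1, 1, 1) / 3),
      set_normalization = set_normalization(dataset, s$channel),
      impute = impute(dataset, method = s$method %||% "minimum",
                      scope = s$scope %||% "within",
                      seed = s$seed %||% default_seed),
      collapse = collapse(dataset,
                          assign_method = s$assign_method %||% "all_possible",
                          split_abundance = s$split_abundance %||% TRUE,
                          top_n = s$top_n %||% Inf,
                          summary_fn = s$summary_fn %||% "sum"),
      expression = {
        ratio <- strsplit(s$ratio, "/", fixed = TRUE)[[1]]
        r <- expression_analysis(dataset, ratio[1], ratio[2],
                                 method = s$method %||% "t_test")
        results[[paste0(k, "_expression")]] <- r
        if (!is.null(output)) {
          dir.create(output, showWarnings = FALSE, recursive = TRUE)
          readr::write_tsv(r, file.path(output, sprintf(
            "expression_%s.tsv", gsub("/", "_vs_", s$ratio))), na = "")
        }
        attr(r, "dataset")
      },
      enrichment = {
        prev <- results[grepl("_expression$", names(results))]
        if (!length(prev)) stop("enrichment step needs a prior expression step",
                                call. = FALSE)
        e <- enrichment(prev[[length(prev)]], dataset, term = s$term,
                        method = s$method %||% "gsea",
                        n_permutations = s$n_permutations %||% 1000,
                        seed = s$seed %||% default_seed)
        results[[paste0(k, "_enrichment")]] <- e
        if (!is.null(output)) {
          dir.create(output, showWarnings = FALSE, recursive = TRUE)
          readr::write_tsv(e, file.path(output, sprintf(
            "enrichment_%s.tsv", gsub("[^A-Za-z0-9]+", "_", s$term))), na = "")
        }
        dataset
      },
      summary = {
        sm <- summary(dataset, by = s$by %||% "sample")
        results[[paste0(k, "_summary")]] <- sm
        if (!is.null(output)) {
          dir.create(output, showWarnings = FALSE, recursive = TRUE)
          readr::write_tsv(sm, file.path(output, sprintf(
            "summary_%s.tsv", gsub("[^A-Za-z0-9]+", "_", s$by %||% "sample"))),
            na = "")
        }
        dataset
      },
      export = {
        export_tabular(dataset, s$path, format = s$format %||% "tsv",
                       shape = s$shape %||% "wide")
        dataset
      },
      operations = {
        writeLines(operations(dataset))
        dataset
      }
    )
    message(sprintf("[%02d] %-22s %5.2fs", k, s$verb,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    if (isTRUE(config$checkpoint) && !is.null(output)) {
      write_dataset(dataset, output)
    }
  }
  if (!is.null(output)) write_dataset(dataset, output)
  invisible(list(dataset = dataset, results = results))
}
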