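# Plot-DATA builders: every figure family is backed by a pure function of
# the dataset returning a plain table; the ggplot renderers below are thin
# adapters over these tables and carry no science of their own.

#' Identifier counts per run
#'
#' Counts identifiers with a non-missing raw abundance per (sample,
#' replicate), with a per-sample-group mean and t-based 95% confidence
#' interval across replicates (omitted below 2 replicates). When the
#' accounting table carries a logical `match_between_runs` column (mapped
#' by an import directive), counts are additionally split by it.
#'
#' @param dataset A `proteomics_dataset`.
#' @return List of tibbles: `counts` (per run) and `ci` (per group).
#' @export
counts_data <- function(dataset) {
  long <- dataset_long(dataset, "raw")
  grouping <- c("sample", "replicate")
  if ("match_between_runs" %in% names(long)) {
    grouping <- c(grouping, "match_between_runs")
  }
  counts <- long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(n = dplyr::n_distinct(.data$.id[!is.na(.data$abundance)]),
                     .groups = "drop")
  ci <- counts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(setdiff(grouping, "replicate")))) |>
    dplyr::summarise(
      mean_n = mean(.data$n),
      n_reps = dplyr::n(),
      ci_half = ifelse(dplyr::n() >= 2,
                       stats::qt(0.975, dplyr::n() - 1) *
                         stats::sd(.data$n) / sqrt(dplyr::n()), NA_real_),
      .groups = "drop")
  list(counts = counts, ci = ci)
}

#' Abundance rank curves per sample group
#'
#' Identifiers rank-ordered (1 = most abundant) by mean non-missing
#' abundance of the selected channel within each sample group, with the
#' log10 mean and the log10-scale spread (sd) across replicates.
#'
#' @param dataset A `proteomics_dataset`.
#' @return Tibble: `sample`, `rank`, identifier key, `log10_abundance`,
#'   `log10_sd`.
#' @export
quantrank_data <- function(dataset) {
  long <- dataset_long(dataset)
  long |>
    dplyr::filter(!is.na(.data$abundance)) |>
    dplyr::group_by(.data$sample, .data$.id) |>
    dplyr::summarise(mean_ab = mean(.data$abundance),
                     log10_sd = stats::sd(log10(.data$abundance)),
                     .groups = "drop_last") |>
    dplyr::arrange(dplyr::desc(.data$mean_ab), .data$.id, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  log10_abundance = log10(.data$mean_ab)) |>
    dplyr::ungroup() |>
    dplyr::select("sample", "rank", identifier = ".id", "log10_abundance",
                  "log10_sd")
}

#' Identifier overlap regions between sample groups
#'
#' For 2 to 4 sample groups, counts identifiers in every one of the
#' `2^k - 1` membership regions (the numbers behind a Venn or Euler
#' rendering). An identifier is present in a group when it has a
#' non-missing raw abundance in at least one replicate; the regions
#' partition the union of identifiers.
#'
#' @param dataset A `proteomics_dataset`.
#' @param groups Sample-group names (default: all, 2-4 required).
#' @return Tibble: `region` (group names joined by `&`), `n_groups`,
#'   `count`.
#' @export
overlap_data <- function(dataset, groups = NULL) {
  long <- dataset_long(dataset, "raw")
  if (is.null(groups)) groups <- unique(dataset$experiments$sample)
  k <- length(groups)
  if (k < 2 || k > 4) stop("overlap requires 2 to 4 groups, got ", k, call. = FALSE)
  present <- lapply(groups, function(g) {
    unique(long$.id[long$sample == g & !is.na(long$abundance)])
  })
  names(present) <- groups
  universe <- unique(unlist(present))
  membership <- vapply(present, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1,
                                                  dimnames = list(NULL, groups))
  pattern <- apply(membership, 1, function(row) paste(groups[row], collapse = "&"))
  combos <- unlist(lapply(seq_len(k), function(m) {
    utils::combn(groups, m, paste, collapse = "&", simplify = FALSE)
  }))
  tibble::tibble(
    region = combos,
    n_groups = lengths(strsplit(combos, "&", fixed = TRUE)),
    count = as.integer(table(factor(pattern, levels = combos))[combos])
  )
}

#' CV versus abundance (dynamic-range heat map data)
#'
#' Per identifier per sample group with 2+ observations: the log10 mean
#' abundance and the linear-scale coefficient of variation — the pairs
#' behind the hex-binned CV/abundance density plot — plus the running mean
#' of CV over abundance deciles within each group, which makes the rise of
#' CVs at the low end of the dynamic range visible.
#'
#' @param dataset A `proteomics_dataset`.
#' @param channel Abundance channel (default: selected).
#' @return List of tibbles: `points` and `deciles`.
#' @export
dynamic_range_data <- function(dataset, channel = dataset$selected_channel) {
  long <- dataset_long(dataset, channel)
  points <- long |>
    dplyr::filter(!is.na(.data$abundance)) |>
    dplyr::group_by(.data$sample, .data$.id) |>
    dplyr::summarise(n = dplyr::n(), mean_ab = mean(.data$abundance),
                     cv = stats::sd(.data$abundance) / mean(.data$abundance),
                     .groups = "drop") |>
    dplyr::filter(.data$n >= 2) |>
    dplyr::mutate(log10_abundance = log10(.data$mean_ab)) |>
    dplyr::select("sample", identifier = ".id", "log10_abundance", "cv")
  deciles <- points |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(decile = dplyr::ntile(.data$log10_abundance, 10)) |>
    dplyr::group_by(.data$sample, .data$decile) |>
    dplyr::summarise(mean_cv = mean(.data$cv),
                     mean_log10_abundance = mean(.data$log10_abundance),
                     .groups = "drop")
  list(points = points, deciles = deciles)
}

#' PCA of samples
#'
#' Principal components of the identifier-centered log2 matrix (complete
#' identifiers only): per-sample scores on the first two components and
#' the explained-variance fraction of every component (the cumulative
#' curve used when comparing normalizations). Score signs follow a
#' deterministic convention: the largest-magnitude loading of each
#' component is positive.
#'
#' @param dataset A `proteomics_dataset` with 3+ samples and 3+ complete
#'   identifiers.
#' @param channel Abundance channel.
#' @return List: `scores` (sample_id, sample, replicate, PC1, PC2) and
#'   `variance` (component, var_fraction, cumulative).
#' @export
pca_data <- function(dataset, channel = dataset$selected_channel) {
  mat <- channel_matrix(dataset, channel)
  if (ncol(mat) < 3) stop("PCA requires >= 3 samples", call. = FALSE)
  complete <- mat[stats::complete.cases(mat), , drop = FALSE]
  if (nrow(complete) < 3) stop("fewer than 3 complete identifiers for PCA",
                               call. = FALSE)
  pc <- stats::prcomp(t(complete), center = TRUE, scale. = FALSE)
  for (j in seq_len(ncol(pc$rotation))) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  v <- pc$sdev^2
  ex <- dataset$experiments
  scores <- tibble::tibble(
    sample_id = rownames(pc$x),
    sample = ex$sample[match(rownames(pc$x), ex$sample_id)],
    replicate = ex$replicate[match(rownames(pc$x), ex$sample_id)],
    PC1 = pc$x[, 1],
    PC2 = if (ncol(pc$x) >= 2) pc$x[, 2] else 0
  )
  variance <- tibble::tibble(component = seq_along(v),
                             var_fraction = v / sum(v),
                             cumulative = cumsum(v) / sum(v))
  list(scores = scores, variance = variance)
}

#' Heat-map matrix with clustering orders
#'
#' Z-scores each complete identifier's log2 abundances across samples and
#' clusters rows and columns by average-linkage hierarchical clustering on
#' Euclidean distance; leaf order is deterministic (ties keep input
#' order).
#'
#' @param dataset A `proteomics_dataset` (preconditions as [pca_data()]).
#' @param channel Abundance channel.
#' @return List: `z` (matrix), `row_order`, `col_order`, and the two
#'   `stats::hclust` trees.
#' @export
heatmap_data <- function(dataset, channel = dataset$selected_channel) {
  mat <- channel_matrix(dataset, channel)
  if (ncol(mat) < 3) stop("heat map requires >= 3 samples", call. = FALSE)
  complete <- mat[stats::complete.cases(mat), , drop = FALSE]
  if (nrow(complete) < 3) stop("fewer than 3 complete identifiers", call. = FALSE)
  z <- t(apply(complete, 1, function(r) (r - mean(r)) / stats::sd(r)))
  z[!is.finite(z)] <- 0
  hr <- stats::hclust(stats::dist(z), method = "average")
  hc <- stats::hclust(stats::dist(t(z)), method = "average")
  list(z = z, row_order = hr$order, col_order = hc$order,
       row_hclust = hr, col_hclust = hc)
}

#' Volcano and proportion plot tables
#'
#' Classifies every identifier of an expression result as `up`, `down` or
#' `ns` using thresholds on the adjusted p-value and absolute log2 fold
#' change. `volcano_data()` returns `(log2_fc, -log10 adj_p)` pairs;
#' `proportion_data()` replaces the y axis with each identifier's share of
#' total average abundance (summing to 1), emphasizing how much of the
#' proteome the regulated identifiers represent.
#'
#' @param expression_result Table from [expression_analysis()].
#' @param p_threshold Adjusted-p significance cutoff (default 0.05).
#' @param fc_threshold Minimum |log2 fold change| (default 1).
#' @return Tibble with plotting columns and a `class` label; class counts
#'   are in attribute `"class_counts"`.
#' @export
volcano_data <- function(expression_result, p_threshold = 0.05, fc_threshold = 1) {
  r <- expression_result
  cls <- dplyr::case_when(
    r$adj_p_value < p_threshold & r$log2_fc >= fc_threshold ~ "up",
    r$adj_p_value < p_threshold & r$log2_fc <= -fc_threshold ~ "down",
    .default = "ns")
  out <- dplyr::mutate(
    dplyr::select(r, dplyr::any_of(c("protein", "peptide", "modification")),
                  "log2_fc", "adj_p_value"),
    neg_log10_adj_p = -log10(.data$adj_p_value), class = cls)
  attr(out, "class_counts") <- table(factor(cls, c("up", "down", "ns")))
  out
}

#' @rdname volcano_data
#' @export
proportion_data <- function(expression_result, p_threshold = 0.05,
                            fc_threshold = 1) {
  r <- expression_result
  cls <- dplyr::case_when(
    r$adj_p_value < p_threshold & r$log2_fc >= fc_threshold ~ "up",
    r$adj_p_value < p_threshold & r$log2_fc <= -fc_threshold ~ "down",
    .default = "ns")
  out <- dplyr::mutate(
    dplyr::select(r, dplyr::any_of(c("protein", "peptide", "modification")),
                  "log2_fc", "average_abundance"),
    proportion = .data$average_abundance / sum(.data$average_abundance),
    class = cls)
  attr(out, "class_counts") <- table(factor(cls, c("up", "down", "ns")))
  out
}

#' Enrichment results ordered for plotting
#'
#' Annotations sorted ascending by p-value (the order the enrichment
#' figure ranks terms in), ties broken by |nes| descending; the sort is
#' stable and invariant to the input row order.
#'
#' @param enrichment_result Table from [enrichment()].
#' @return The sorted tibble.
#' @export
enrichment_plot_data <- function(enrichment_result) {
  stopifnot(nrow(enrichment_result) > 0)
  r <- dplyr::arrange(enrichment_result, .data$term, .data$annotation)
  key <- ifelse(is.na(r$nes), 0, -abs(r$nes))
  r[order(r$p_value, key), ]
}

# ---- thin renderers ----------------------------------------------------

#' Render plot data with ggplot2
#'
#' Minimal renderings of the plot-data tables; all science lives in the
#' `*_data()` builders, and these adapters only map columns to aesthetics.
#'
#' @param dataset A `proteomics_dataset`.
#' @param ... Passed to the corresponding `*_data()` builder.
#' @return A ggplot object.
#' @export
plot_counts <- function(dataset, ...) {
  d <- counts_data(dataset, ...)
  ggplot2::ggplot(d$counts, ggplot2::aes(x = .data$replicate, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~sample) +
    ggplot2::labs(y = "identifiers observed")
}

#' @rdname plot_counts
#' @export
plot_quantrank <- function(dataset, ...) {
  d <- quantrank_data(dataset, ...)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$log10_abundance,
                                  color = .data$sample)) +
    ggplot2::geom_line()
}

#' @rdname plot_counts
#' @param expression_result Expression table (volcano).
#' @export
plot_volcano <- function(expression_result, ...) {
  d <- volcano_data(expression_result, ...)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_fc, y = .data$neg_log10_adj_p,
                                  color = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p")
}

#' @rdname plot_counts
#' @export
plot_pca <- function(dataset, ...) {
  d <- pca_data(dataset, ...)
  vf <- d$variance$var_fraction
  ggplot2::ggplot(d$scores, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                         color = .data$sample)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * vf[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * vf[2]))
}
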