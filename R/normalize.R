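norm_methods <- c("median", "linear", "loess", "randomforest")

#' Compute normalization channels
#'
#' Adds one abundance channel per requested method, computed on the log2
#' scale against a per-identifier reference vector \eqn{r(i)} — the median of
#' the log2 raw abundance of identifier `i` across samples — and stored
#' back on the linear scale. The missingness pattern and identifier set are
#' never changed.
#'
#' * `median` — each sample is shifted so every per-sample log2 median
#'   equals the global median of sample medians.
#' * `linear` — each sample is shifted by the least-squares intercept of
#'   \eqn{r - sample} (mean offset alignment).
#' * `loess` — subtracts a locally weighted regression fit of
#'   `sample - r` versus `r` (default span 0.5, degree 1), removing smooth
#'   intensity-dependent bias.
#' * `randomforest` — subtracts `f(r) - r` where `f` is a random-forest
#'   regression of the sample on `r` (default 100 trees, seeded).
#'
#' A `basis` filter restricts the *fit* to a subset of identifiers — e.g.
#' spike-in analytes or the bait of an immunoprecipitation — and the fitted
#' correction is then applied to all identifiers. The constant-shift
#' methods accept any non-empty basis (a single bait protein suffices); the
#' curve-fitting methods (`loess`, `randomforest`) require at least 10
#' basis identifiers to constrain the fit.
#'
#' @param dataset A `proteomics_dataset` with a `raw` channel.
#' @param methods Channel names to compute (subset of `median`, `linear`,
#'   `loess`, `randomforest`).
#' @param basis Optional filter expression (text or parsed) selecting the
#'   identifiers the correction is fitted on.
#' @param span,degree Loess parameters.
#' @param rf_trees,rf_nodesize,seed Random-forest parameters;
#'   `rf_nodesize = NULL` uses `max(32, 2%)` of the fitted points, keeping
#'   the fitted transfer curve smooth so it corrects systematic bias
#'   rather than absorbing replicate noise or genuine group effects.
#' @return The dataset with new channels (one ledger entry per method).
#' @export
normalize <- function(dataset, methods = norm_methods, basis = NULL,
                      span = 0.5, degree = 1, rf_trees = 100,
                      rf_nodesize = NULL, seed = 42) {
  stopifnot(inherits(dataset, "proteomics_dataset"), length(methods) >= 1)
  unknown <- setdiff(methods, norm_methods)
  if (length(unknown)) {
    stop("unknown normalization method '", paste(unknown, collapse = "', '"),
         "'; available: ", paste(norm_methods, collapse = ", "), call. = FALSE)
  }
  if (!"raw" %in% channel_names(dataset)) stop("raw channel absent", call. = FALSE)

  qn <- dataset$quantitative
  ids <- identifier_key(dataset)
  lraw <- log2(qn$raw)
  ref <- tapply(lraw, ids, stats::median, na.rm = TRUE)
  r <- as.numeric(ref[ids])

  basis_ids <- unique(ids)
  basis_txt <- "all"
  if (!is.null(basis)) {
    fx <- as_filter_expression(basis)
    basis_txt <- deparse_filter(fx)
    sub <- base::subset(dataset, fx)
    basis_ids <- unique(identifier_key(sub))
  }
  in_basis <- ids %in% basis_ids
  curve_methods <- intersect(methods, c("loess", "randomforest"))
  if (length(curve_methods) && length(basis_ids) < 10) {
    stop("basis too small: ", length(basis_ids),
         " identifiers; loess/randomforest need >= 10", call. = FALSE)
  }
  if (!length(basis_ids)) stop("basis too small: 0 identifiers", call. = FALSE)

  sample_ids <- dataset$experiments$sample_id
  for (m in methods) {
    lnorm <- lraw
    if (m == "median") {
      meds <- vapply(sample_ids, function(s) {
        stats::median(lraw[qn$sample_id == s & in_basis], na.rm = TRUE)
      }, numeric(1))
      target <- stats::median(meds)
      for (s in sample_ids) {
        i <- qn$sample_id == s
        lnorm[i] <- lraw[i] + (target - meds[[s]])
      }
    } else if (m == "linear") {
      for (s in sample_ids) {
        i <- qn$sample_id == s
        fit_i <- i & in_basis & !is.na(lraw) & !is.na(r)
        shift <- mean(r[fit_i] - lraw[fit_i])
        lnorm[i] <- lraw[i] + shift
      }
    } else if (m == "loess") {
      for (s in sample_ids) {
        i <- qn$sample_id == s
        fit_i <- i & in_basis & !is.na(lraw) & !is.na(r)
        fit <- stats::loess(d ~ r, data = data.frame(d = lraw[fit_i] - r[fit_i],
                                                     r = r[fit_i]),
                            span = span, degree = degree, family = "gaussian",
                            control = stats::loess.control(surface = "direct"))
        pred <- stats::predict(fit, newdata = data.frame(r = r[i]))
        lnorm[i] <- lraw[i] - pred
      }
    } else if (m == "randomforest") {
      set.seed(seed)
      for (s in sample_ids) {
        i <- qn$sample_id == s
        fit_i <- i & in_basis & !is.na(lraw) & !is.na(r)
        ns <- rf_nodesize
        if (is.null(ns)) ns <- max(32, ceiling(0.02 * sum(fit_i)))
        fit <- randomForest::randomForest(x = data.frame(r = r[fit_i]),
                                          y = lraw[fit_i], ntree = rf_trees,
                                          nodesize = ns)
        idx <- which(i & !is.na(r))
        pred <- stats::predict(fit, newdata = data.frame(r = r[idx]))
        lnorm[idx] <- lraw[idx] - (pred - r[idx])
      }
    }
    dataset$quantitative[[m]] <- 2^lnorm
    cites <- switch(m, loess = .op_citations$loess,
                    randomforest = .op_citations$randomforest, character())
    dataset <- append_ledger(dataset, "normalize",
                             list(method = m, basis = basis_txt), cites)
  }
  dataset
}

#' Quality metrics for one abundance channel
#'
#' Three unit-incommensurable metrics summarize a channel:
#'
#' * `cv` — per (identifier, sample group) coefficient of variation
#'   (sd/mean, linear scale, needing 2+ observations), medianed over
#'   identifiers within each group and then across groups.
#' * `dynamic_range` — width of the central 95% interval
#'   (P97.5 - P2.5) of all non-missing log10 abundances.
#' * `pca_var3` — cumulative fraction of variance captured by the first
#'   three principal components of the identifier-centered log2 matrix
#'   (complete identifiers only).
#'
#' @param dataset A `proteomics_dataset`.
#' @param channel Channel name.
#' @return A one-row tibble: `channel`, `cv`, `dynamic_range`, `pca_var3`.
#' @export
channel_metrics <- function(dataset, channel) {
  long <- dataset_long(dataset, channel)
  cv_tab <- long |>
    dplyr::group_by(.data$sample, .data$.id) |>
    dplyr::summarise(cv = ifelse(sum(!is.na(.data$abundance)) >= 2,
                                 stats::sd(.data$abundance, na.rm = TRUE) /
                                   mean(.data$abundance, na.rm = TRUE),
                                 NA_real_), .groups = "drop_last") |>
    dplyr::summarise(cv = stats::median(.data$cv, na.rm = TRUE), .groups = "drop")
  cv <- stats::median(cv_tab$cv, na.rm = TRUE)
  ab <- long$abundance[!is.na(long$abundance)]
  qs <- stats::quantile(log10(ab), c(0.025, 0.975), names = FALSE)
  mat <- channel_matrix(dataset, channel)
  complete <- mat[stats::complete.cases(mat), , drop = FALSE]
  if (nrow(complete) < 3) {
    stop("fewer than 3 complete identifiers for PCA in channel '", channel, "'",
         call. = FALSE)
  }
  pc <- stats::prcomp(t(complete), center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  pca_var3 <- sum(v[seq_len(min(3, length(v)))]) / sum(v)
  tibble::tibble(channel = channel, cv = cv, dynamic_range = qs[2] - qs[1],
                 pca_var3 = pca_var3)
}

# identifiers x samples matrix of log2 abundances for one channel
channel_matrix <- function(dataset, channel = dataset$selected_channel) {
  qn <- dataset$quantitative
  if (!channel %in% channel_names(dataset)) {
    stop(sprintf("unknown channel '%s'; available: %s", channel,
                 paste(channel_names(dataset), collapse = ", ")), call. = FALSE)
  }
  ids <- identifier_key(dataset)
  uid <- unique(ids)
  sample_ids <- dataset$experiments$sample_id
  mat <- matrix(NA_real_, nrow = length(uid), ncol = length(sample_ids),
                dimnames = list(uid, sample_ids))
  mat[cbind(match(ids, uid), match(qn$sample_id, sample_ids))] <- log2(qn[[channel]])
  mat
}

#' Automatically select the optimal normalization
#'
#' Scores every non-raw channel by a weighted mean of three dimensionless
#' quality terms derived from [channel_metrics()], each expressed as a
#' relative change against the raw channel so their magnitudes are
#' commensurable:
#'
#' * precision: `cv / cv(raw)` — smaller is better;
#' * dynamic-range preservation: `|dr - dr(raw)| / dr(raw)` — a good
#'   normalization lowers variance *without* compressing or stretching
#'   the abundance range;
#' * structure: `1 - pca_var3 / pca_var3(raw)` — losing variance
#'   concentration in the leading components signals that real structure
#'   was removed along with the bias.
#'
#' The channel with the minimal weighted score becomes
#' `selected_channel`; ties resolve in the priority order median, linear,
#' loess, randomforest. Relative changes rather than metric ranks are
#' combined so a large precision gain cannot be outvoted by hairline
#' differences on the other two terms.
#'
#' @param dataset A `proteomics_dataset` with at least two non-raw
#'   channels.
#' @param weights Length-3 non-negative weights (cv, dynamic range, PCA);
#'   normalized to sum to 1.
#' @return The dataset with `selected_channel` set and a ledger entry
#'   recording every metric value.
#' @export
select_normalization <- function(dataset, weights = c(1, 1, 1) / 3) {
  stopifnot(inherits(dataset, "proteomics_dataset"),
            length(weights) == 3, all(weights >= 0), sum(weights) > 0)
  weights <- weights / sum(weights)
  chans <- setdiff(channel_names(dataset), "raw")
  if (length(chans) < 2) {
    stop("need >= 2 non-raw channels; run normalize() first", call. = FALSE)
  }
  metrics <- lapply(c("raw", chans), function(ch) {
    tryCatch(channel_metrics(dataset, ch), error = function(e) NULL)
  })
  names(metrics) <- c("raw", chans)
  if (is.null(metrics$raw) || all(vapply(metrics[chans], is.null, logical(1)))) {
    stop("metrics incomputable for all channels", call. = FALSE)
  }
  ok <- chans[!vapply(metrics[chans], is.null, logical(1))]
  tab <- dplyr::bind_rows(metrics[ok])
  eps <- .Machine$double.eps
  cv_raw <- max(metrics$raw$cv, eps)
  dr_raw <- max(metrics$raw$dynamic_range, eps)
  pca_raw <- max(metrics$raw$pca_var3, eps)
  score <- weights[1] * tab$cv / cv_raw +
    weights[2] * abs(tab$dynamic_range - metrics$raw$dynamic_range) / dr_raw +
    weights[3] * (1 - tab$pca_var3 / pca_raw)
  priority <- match(tab$channel, norm_methods)
  best <- order(score, priority)[1]
  winner <- tab$channel[best]
  dataset$selected_channel <- winner
  params <- list(selected = winner,
                 weights = paste(signif(weights, 4), collapse = ","))
  for (i in seq_len(nrow(tab))) {
    params[[paste0(tab$channel[i], "_metrics")]] <- sprintf(
      "cv=%.4g,dr=%.4g,pca3=%.4g", tab$cv[i], tab$dynamic_range[i], tab$pca_var3[i])
  }
  append_ledger(dataset, "select_normalization", params)
}
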