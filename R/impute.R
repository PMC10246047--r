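#' Impute missing abundances
#'
#' Fills missing cells of the selected channel only; observed values are
#' never modified and other channels are left untouched, so imputation and
#' normalization can be applied in either order. Summary methods operate
#' on the log2 scale and exponentiate back:
#'
#' * `scope = "within"` — a missing value of identifier `i` in sample `s`
#'   is the summary of `i`'s observed values in the *same sample group*.
#'   When the group has no observation at all (e.g. a knocked-out protein,
#'   or affinity flowthrough), the value falls back to the group floor —
#'   the minimum observed abundance of any identifier in that group —
#'   unless `strict = TRUE`, which leaves it missing. The fallback needs
#'   evidence the identifier exists: one observed in no group at all
#'   always stays missing.
#' * `scope = "between"` — the summary of `i`'s observed values across all
#'   samples; identifiers observed nowhere stay missing and are reported.
#' * `method = "randomforest"` — iterative random-forest matrix completion
#'   over the full log2 matrix (see [impute_randomforest()]); implies
#'   `scope = "between"`.
#'
#' Minimum-value imputation within groups suits missing-not-at-random
#' designs (knockouts, affinity capture) where absence is informative;
#' random-forest imputation suits missing-at-random gaps in otherwise
#' structured data. The `imputed` accounting column is updated to the
#' fraction of values imputed per (identifier, sample).
#'
#' @param dataset A `proteomics_dataset` with missing values in the
#'   selected channel.
#' @param method `"minimum"`, `"mean"`, `"median"`, `"randomforest"`, or a
#'   summary function taking a numeric vector.
#' @param scope `"within"` or `"between"` sample groups.
#' @param strict Disable the group-floor fallback for `within`.
#' @param max_iterations,seed Random-forest parameters.
#' @return The dataset with missing cells filled (logged).
#' @export
impute <- function(dataset, method = "minimum", scope = c("within", "between"),
                   strict = FALSE, max_iterations = 10, seed = 42) {
  stopifnot(inherits(dataset, "proteomics_dataset"))
  scope <- match.arg(scope)
  chan <- dataset$selected_channel
  qn <- dataset$quantitative
  v <- qn[[chan]]
  if (!anyNA(v)) {
    warning("no missing values; impute() is a no-op", call. = FALSE)
    return(append_ledger(dataset, "impute",
                         list(method = method_name(method), note = "no missing values")))
  }

  if (identical(method, "randomforest")) {
    if (scope != "between") stop("randomforest imputation implies scope=between",
                                 call. = FALSE)
    mat <- channel_matrix(dataset, chan)
    done <- impute_randomforest(mat, max_iterations = max_iterations, seed = seed)
    ids <- identifier_key(dataset)
    filled <- 2^done[cbind(match(ids, rownames(done)),
                           match(qn$sample_id, colnames(done)))]
    newv <- ifelse(is.na(v), filled, v)
  } else {
    fn <- if (is.function(method)) method else switch(method,
      minimum = min, mean = mean, median = stats::median,
      stop("unknown imputation method '", method, "'", call. = FALSE))
    ids <- identifier_key(dataset)
    grp <- dataset$experiments$sample[match(qn$sample_id, dataset$experiments$sample_id)]
    lv <- log2(v)
    newv <- v
    if (scope == "within") {
      pool_key <- paste(ids, grp, sep = "\r")
      floor_by_grp <- tapply(lv, grp, min, na.rm = TRUE)
    } else {
      pool_key <- ids
    }
    obs <- !is.na(lv)
    pool_vals <- split(lv[obs], pool_key[obs])
    fill <- vapply(split(seq_along(lv), pool_key), function(rows) {
      p <- pool_vals[[pool_key[rows[1]]]]
      if (length(p)) fn(p) else NA_real_
    }, numeric(1))
    miss <- is.na(v)
    newv[miss] <- 2^fill[pool_key[miss]]
    if (scope == "within" && !strict) {
      # knockout fallback: only identifiers observed in some other group
      # earn the group floor; identifiers observed nowhere stay missing
      seen <- ids %in% unique(ids[obs])
      still <- is.na(newv) & seen
      newv[still] <- 2^as.numeric(floor_by_grp[grp[still]])
    }
  }

  was_missing <- is.na(v) & !is.na(newv)
  dataset$quantitative[[chan]] <- newv
  idc <- id_cols(dataset)
  imp_tab <- qn[was_missing, c("sample_id", idc)]
  if (nrow(imp_tab)) {
    key_acc <- do.call(paste, c(dataset$accounting[c("sample_id", idc)], sep = "\r"))
    key_imp <- unique(do.call(paste, c(imp_tab, sep = "\r")))
    dataset$accounting$imputed[key_acc %in% key_imp] <- 1
  }
  n_left <- sum(is.na(newv))
  cites <- if (identical(method, "randomforest")) .op_citations$missforest else character()
  dataset <- append_ledger(dataset, "impute", c(
    list(method = method_name(method), scope = scope, channel = chan,
         n_imputed = sum(was_missing)),
    if (n_left) list(n_unfilled = n_left)
  ), cites)
  if (n_left) message(n_left, " value(s) had no observations in scope and remain missing")
  dataset
}

method_name <- function(method) {
  if (is.function(method)) "user_function" else method
}

#' Iterative random-forest matrix completion
#'
#' Completes a log2 abundance matrix (identifiers in rows, samples in
#' columns) with the iterative scheme of missForest-style imputation:
#' missing cells are initialized with row means (column means when a row
#' has no observation); then, repeatedly, each sample column in order of
#' ascending missingness is regressed by a random forest on all other
#' columns using its observed rows, and its missing rows predicted. The
#' loop stops when the relative change of the imputed values increases
#' (returning the matrix from before that iteration) or after
#' `max_iterations`. Deterministic under a fixed seed.
#'
#' @param mat Numeric matrix with `NA` gaps; every column needs at least
#'   one observation.
#' @param max_iterations Iteration cap (default 10).
#' @param seed RNG seed.
#' @param ntree Trees per forest.
#' @return The completed matrix.
#' @export
impute_randomforest <- function(mat, max_iterations = 10, seed = 42, ntree = 100) {
  stopifnot(is.matrix(mat))
  if (!anyNA(mat)) return(mat)
  if (any(colSums(!is.na(mat)) == 0)) stop("sample has no observations", call. = FALSE)
  miss <- is.na(mat)
  row_mean <- rowMeans(mat, na.rm = TRUE)
  col_mean <- colMeans(mat, na.rm = TRUE)
  filled <- mat
  for (j in seq_len(ncol(mat))) {
    mj <- miss[, j]
    filled[mj, j] <- row_mean[mj]
    still <- is.na(filled[, j])
    filled[still, j] <- col_mean[j]
  }
  col_order <- order(colSums(miss))
  set.seed(seed)
  prev <- filled
  prev_diff <- Inf
  for (iter in seq_len(max_iterations)) {
    cur <- prev
    for (j in col_order) {
      mj <- miss[, j]
      if (!any(mj)) next
      x_obs <- cur[!mj, -j, drop = FALSE]
      y_obs <- mat[!mj, j]
      fit <- randomForest::randomForest(x = as.data.frame(x_obs), y = y_obs,
                                        ntree = ntree)
      cur[mj, j] <- stats::predict(fit, newdata = as.data.frame(cur[mj, -j, drop = FALSE]))
    }
    diff <- sum((cur[miss] - prev[miss])^2) / max(sum(cur[miss]^2), .Machine$double.eps)
    if (diff > prev_diff) return(prev)
    prev <- cur
    prev_diff <- diff
  }
  prev
}
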