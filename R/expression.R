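#' Two-group differential expression
#'
#' Tests every identifier with at least two non-missing selected-channel
#' values per group for a difference between a numerator and a denominator
#' sample group (e.g. `kndw/ctrl`). Tests run on log2-transformed values;
#' the reported fold change is the ratio of linear-scale group means, so
#' `log2_fc = log2(mean_num / mean_den)`.
#'
#' * `t_test` — Welch two-sample t.
#' * `wilcoxon` — two-sided rank-sum ([stats::wilcox.test()]; exact when
#'   both groups have 8 or fewer observations and no ties, otherwise the
#'   tie-corrected normal approximation).
#' * `limma_moderated` — empirical-Bayes moderated t: per-identifier pooled
#'   variances are shrunk toward a prior estimated from all identifiers
#'   (see [moderate_variances()]), and the t statistic uses the posterior
#'   variance with `d0 + d` degrees of freedom.
#'
#' P-values are Benjamini-Hochberg adjusted over all tested identifiers.
#' Identifiers excluded for insufficient replication are returned in the
#' `"excluded"` attribute, not silently dropped.
#'
#' @param dataset A `proteomics_dataset`.
#' @param numerator,denominator Sample-group names (must differ, each with
#'   2+ replicates).
#' @param method `"t_test"`, `"wilcoxon"` or `"limma_moderated"`.
#' @return A tibble with one row per tested identifier: identifier
#'   columns, `mean_numerator`, `mean_denominator`, `log2_fc`,
#'   `average_abundance`, `statistic`, `p_value`, `adj_p_value`, `n_num`,
#'   `n_den`, `imputed_fraction`. The dataset's updated ledger is carried
#'   in attribute `"dataset"`.
#' @export
expression_analysis <- function(dataset, numerator, denominator,
                                method = c("t_test", "wilcoxon", "limma_moderated")) {
  stopifnot(inherits(dataset, "proteomics_dataset"))
  method <- match.arg(method)
  if (identical(numerator, denominator)) {
    stop("numerator and denominator must differ", call. = FALSE)
  }
  ex <- dataset$experiments
  for (g in c(numerator, denominator)) {
    if (sum(ex$sample == g) < 2) {
      stop("sample group '", g, "' missing or has fewer than 2 replicates",
           call. = FALSE)
    }
  }
  long <- dataset_long(dataset, dataset$selected_channel)
  long <- dplyr::filter(long, .data$sample %in% c(numerator, denominator))
  idc <- id_cols(dataset)

  per_id <- long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(".id", idc)))) |>
    dplyr::summarise(
      num = list(.data$abundance[.data$sample == numerator &
                                   !is.na(.data$abundance)]),
      den = list(.data$abundance[.data$sample == denominator &
                                   !is.na(.data$abundance)]),
      imputed_fraction = mean(.data$imputed, na.rm = TRUE),
      .groups = "drop")
  per_id$n_num <- lengths(per_id$num)
  per_id$n_den <- lengths(per_id$den)
  testable <- per_id$n_num >= 2 & per_id$n_den >= 2
  excluded <- per_id[!testable, c(idc, "n_num", "n_den")]
  per_id <- per_id[testable, ]
  if (!nrow(per_id)) stop("zero testable identifiers", call. = FALSE)

  res <- per_id
  res$mean_numerator <- vapply(res$num, mean, numeric(1))
  res$mean_denominator <- vapply(res$den, mean, numeric(1))
  res$log2_fc <- log2(res$mean_numerator / res$mean_denominator)
  res$average_abundance <- (res$mean_numerator + res$mean_denominator) / 2

  lnum <- lapply(res$num, log2)
  lden <- lapply(res$den, log2)
  if (method == "t_test") {
    tt <- mapply(function(a, b) {
      if (stats::var(a) + stats::var(b) == 0) {
        # degenerate zero-variance case: identical means are a perfect null
        diff <- mean(a) - mean(b)
        return(c(if (diff == 0) 0 else sign(diff) * Inf, as.numeric(diff == 0)))
      }
      h <- stats::t.test(a, b)
      c(h$statistic, h$p.value)
    }, lnum, lden)
    res$statistic <- unname(tt[1, ]); res$p_value <- unname(tt[2, ])
  } else if (method == "wilcoxon") {
    tt <- mapply(function(a, b) {
      h <- suppressWarnings(stats::wilcox.test(
        a, b, exact = length(a) <= 8 && length(b) <= 8, correct = FALSE))
      c(h$statistic, h$p.value)
    }, lnum, lden)
    res$statistic <- unname(tt[1, ]); res$p_value <- unname(tt[2, ])
  } else {
    n1 <- res$n_num; n2 <- res$n_den
    m1 <- vapply(lnum, mean, numeric(1)); m2 <- vapply(lden, mean, numeric(1))
    ss <- mapply(function(a, b) sum((a - mean(a))^2) + sum((b - mean(b))^2),
                 lnum, lden)
    d <- n1 + n2 - 2
    s2 <- ss / d
    mod <- moderate_variances(s2, d)
    tstat <- (m1 - m2) / sqrt(mod$s2_post * (1 / n1 + 1 / n2))
    df_total <- mod$d0 + d
    res$statistic <- tstat
    res$p_value <- 2 * stats::pt(-abs(tstat), df = df_total)
  }
  res$adj_p_value <- stats::p.adjust(res$p_value, method = "BH")
  out <- dplyr::select(res, dplyr::all_of(idc), "mean_numerator",
                       "mean_denominator", "log2_fc", "average_abundance",
                       "statistic", "p_value", "adj_p_value", "n_num", "n_den",
                       "imputed_fraction")
  cites <- c(if (method == "limma_moderated") .op_citations$limma_moderated,
             .op_citations$bh)
  dataset <- append_ledger(dataset, "expression", list(
    ratio = paste0(numerator, "/", denominator), method = method,
    channel = dataset$selected_channel,
    n_tested = nrow(out), n_excluded = nrow(excluded)
  ), cites)
  attr(out, "excluded") <- excluded
  attr(out, "dataset") <- dataset
  attr(out, "ratio") <- paste0(numerator, "/", denominator)
  out
}

# Newton inversion of the trigamma function (solve trigamma(y) = x, x > 0)
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:60) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif / y) < 1e-10) break
    }
    y
  }, numeric(1))
}

#' Empirical-Bayes moderation of per-identifier variances
#'
#' Fits the scaled-F model `s2 ~ s0^2 * F(d, d0)` to the observed sample
#' variances by the method of moments on `log(s2)`: the mean and variance
#' of `log(s2)` (after removing the digamma/trigamma contribution of the
#' known residual degrees of freedom `d`) identify the prior degrees of
#' freedom `d0` and prior variance `s0^2` through digamma/trigamma
#' inversion. The posterior (moderated) variance for each identifier is
#'
#' `s2_post = (d0 * s0^2 + d * s2) / (d0 + d)`
#'
#' so `d0 = 0` returns the observed variances unchanged and `d0 = Inf`
#' (which arises when the observed log-variance spread is no larger than
#' expected from `d` alone, e.g. all variances equal) returns `s0^2`
#' everywhere.
#'
#' @param s2 Numeric vector of per-identifier sample variances (10+ finite
#'   positive values recommended).
#' @param d Residual degrees of freedom, scalar or per identifier.
#' @return List with `d0`, `s0_2` and `s2_post`.
#' @export
moderate_variances <- function(s2, d) {
  stopifnot(length(s2) >= 1)
  d <- rep_len(d, length(s2))
  ok <- is.finite(s2) & s2 > 0 & d >= 1
  if (sum(ok) < 2) stop("too few positive variances to moderate", call. = FALSE)
  z <- log(s2[ok])
  dk <- d[ok]
  e <- z - digamma(dk / 2) + log(dk / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(dk / 2))
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s0_2 <- exp(emean)
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2)) else {
    (d0 * s0_2 + d * s2) / (d0 + d)
  }
  list(d0 = d0, s0_2 = s0_2, s2_post = s2_post)
}

#' Compare two expression analyses
#'
#' Inner-joins two expression result tables on identifier and flags each
#' identifier by where it is significant (`adj_p < alpha`): `"both"`,
#' `"A"`, `"B"` or `"neither"`. Useful for contrasting two treatments
#' against the same control, or two statistical methods on one dataset.
#'
#' @param result_a,result_b Tables from [expression_analysis()].
#' @param alpha Significance threshold on the adjusted p-value.
#' @return Joined tibble with `log2_fc_A`, `log2_fc_B`, per-side adjusted
#'   p-values and a `significant` flag.
#' @export
compare_expressions <- function(result_a, result_b, alpha = 0.05) {
  stopifnot(nrow(result_a) > 0, nrow(result_b) > 0)
  idc <- intersect(c("protein", "peptide", "modification"),
                   intersect(names(result_a), names(result_b)))
  joined <- dplyr::inner_join(
    dplyr::select(result_a, dplyr::all_of(idc), log2_fc_A = "log2_fc",
                  adj_p_A = "adj_p_value"),
    dplyr::select(result_b, dplyr::all_of(idc), log2_fc_B = "log2_fc",
                  adj_p_B = "adj_p_value"),
    by = idc)
  if (!nrow(joined)) stop("empty join: no shared identifiers", call. = FALSE)
  sig_a <- joined$adj_p_A < alpha
  sig_b <- joined$adj_p_B < alpha
  joined$significant <- dplyr::case_when(
    sig_a & sig_b ~ "both", sig_a ~ "A", sig_b ~ "B", .default = "neither")
  joined
}
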