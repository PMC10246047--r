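#' GSEA running-sum enrichment score
#'
#' Weighted Kolmogorov-Smirnov statistic (weight exponent 1) over a ranked
#' list: walking down the list sorted by score descending, members of the
#' set increment the running sum by `|score| / sum(|score| of members)`
#' and non-members decrement it by `1 / (N - n_members)`; the enrichment
#' score is the signed extremum of the running sum, bounded in \[-1, 1\].
#' When every member score is zero, hits increment equally.
#'
#' @param identifiers Character vector sorted by score descending.
#' @param scores Numeric scores aligned with `identifiers` (e.g. log2 fold
#'   changes), sorted descending.
#' @param members Character vector, a non-empty subset of `identifiers`.
#' @return List with `es` and the `running` sum profile.
#' @export
gsea_es <- function(identifiers, scores, members) {
  stopifnot(length(identifiers) == length(scores), length(members) >= 1)
  if (!all(members %in% identifiers)) {
    stop("member set not contained in ranked list", call. = FALSE)
  }
  hit <- identifiers %in% members
  n <- length(identifiers)
  n_hit <- sum(hit)
  if (n_hit == n) stop("member set spans the whole list; no out-group", call. = FALSE)
  w <- abs(scores)
  denom <- sum(w[hit])
  inc <- if (denom > 0) w * hit / denom else hit / n_hit
  dec <- (!hit) / (n - n_hit)
  running <- cumsum(inc - dec)
  es <- running[which.max(abs(running))]
  list(es = es, running = running)
}

# es only, on a logical membership vector over a pre-sorted list (fast
# path for permutations)
gsea_es_hit <- function(w, hit, n_out) {
  denom <- sum(w[hit])
  inc <- if (denom > 0) w * hit / denom else hit / sum(hit)
  running <- cumsum(inc - (!hit) / n_out)
  running[which.max(abs(running))]
}

#' Term enrichment of an expression analysis
#'
#' Joins an expression result to the dataset's annotations for one term
#' and tests every annotation of that term for enrichment in the ranking
#' by log2 fold change:
#'
#' * `gsea` — running-sum enrichment score ([gsea_es()]) with a seeded
#'   permutation null built by shuffling identifier labels (replicate
#'   counts in typical designs are too small for sample permutation).
#'   `p = (1 + #same-sign permutations with |es| >= |es_obs|) /
#'   (1 + #same-sign permutations)`; the +1 smoothing keeps p in (0, 1].
#'   `nes = es / mean(|es| of same-sign permutations)`.
#' * `wilcoxon` — two-sided rank-sum of in-term versus out-of-term log2
#'   fold changes.
#'
#' Annotations smaller than `min_size`, larger than `max_size`, or carried
#' by every ranked identifier are skipped and listed in the `"skipped"`
#' attribute. P-values are BH-adjusted across the annotations of the term.
#'
#' @param expression_result Table from [expression_analysis()].
#' @param dataset The `proteomics_dataset` carrying the annotations (or a
#'   tibble with `protein`, `term`, `annotation` columns).
#' @param term Annotation term to test (e.g. `"biological process"`).
#' @param method `"gsea"` or `"wilcoxon"`.
#' @param n_permutations,seed Permutation null parameters (gsea).
#' @param min_size,max_size Annotation size bounds.
#' @return Tibble per annotation: `term`, `annotation`, `size`, `es`,
#'   `nes`, `p_value`, `adj_p_value`, `method`.
#' @export
enrichment <- function(expression_result, dataset, term,
                       method = c("gsea", "wilcoxon"),
                       n_permutations = 1000, seed = 7,
                       min_size = 3, max_size = 500) {
  method <- match.arg(method)
  ann <- if (inherits(dataset, "proteomics_dataset")) dataset$annotations else
    tibble::as_tibble(dataset)
  ann <- dplyr::filter(ann, .data$term == !!term)
  if (!nrow(ann)) stop("no annotations for term '", term, "'", call. = FALSE)

  res <- expression_result[!is.na(expression_result$log2_fc) &
                             is.finite(expression_result$log2_fc), ]
  ord <- order(-res$log2_fc)
  ids <- res$protein[ord]
  scores <- res$log2_fc[ord]
  n <- length(ids)

  sets <- split(ann$protein, ann$annotation)
  sets <- lapply(sets, function(p) unique(p[p %in% ids]))
  sizes <- lengths(sets)
  usable <- sizes >= min_size & sizes <= max_size & sizes < n
  skipped <- tibble::tibble(annotation = names(sets)[!usable],
                            size = sizes[!usable])
  sets <- sets[usable]
  if (!length(sets)) {
    stop("no annotation of term '", term, "' meets min_size=", min_size,
         call. = FALSE)
  }

  w <- abs(scores)
  if (method == "gsea") {
    set.seed(seed)
    rows <- lapply(names(sets), function(a) {
      memb <- sets[[a]]
      k <- length(memb)
      es_obs <- gsea_es(ids, scores, memb)$es
      es_perm <- vapply(seq_len(n_permutations), function(i) {
        hit <- logical(n)
        hit[sample.int(n, k)] <- TRUE
        gsea_es_hit(w, hit, n - k)
      }, numeric(1))
      same <- es_perm * sign(es_obs) > 0
      p <- (1 + sum(same & abs(es_perm) >= abs(es_obs))) / (1 + sum(same))
      nes <- if (any(same)) es_obs / mean(abs(es_perm[same])) else NA_real_
      tibble::tibble(annotation = a, size = k, es = es_obs, nes = nes, p_value = p)
    })
    out <- dplyr::bind_rows(rows)
  } else {
    rows <- lapply(names(sets), function(a) {
      hit <- ids %in% sets[[a]]
      h <- suppressWarnings(stats::wilcox.test(scores[hit], scores[!hit]))
      tibble::tibble(annotation = a, size = sum(hit), es = NA_real_,
                     nes = NA_real_, p_value = h$p.value)
    })
    out <- dplyr::bind_rows(rows)
  }
  out$adj_p_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- dplyr::bind_cols(tibble::tibble(term = term, .rows = nrow(out)), out)
  out$method <- method
  attr(out, "skipped") <- skipped
  out
}
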