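test_that("count tables match a brute-force tally with t-based intervals", {
  d <- toy_dataset()
  cd <- counts_data(d)
  expect_equal(nrow(cd$counts), 4)
  expect_equal(nrow(cd$ci), 2)
  long <- to_table(d, "long")
  brute <- tapply(!is.na(long$abundance),
                  paste(long$sample, long$replicate), sum)
  expect_equal(cd$counts$n, as.vector(brute[paste(cd$counts$sample,
                                                  cd$counts$replicate)]))
  # identical replicates: zero-width interval
  base <- 2^rnorm(15, 20, 1)
  d0 <- make_protein_dataset(cbind(base, base), c("a", "a"))
  expect_equal(counts_data(d0)$ci$ci_half, 0)
})

test_that("rank curves are monotone and top-ranked by the global maximum", {
  d <- toy_dataset()
  qr <- quantrank_data(d)
  for (g in unique(qr$sample)) {
    v <- qr$log10_abundance[qr$sample == g]
    expect_true(all(diff(v) <= 1e-12))
    # rank 1 is the brute-force maximum of group means
    long <- to_table(d, "long")
    means <- tapply(long$abundance[long$sample == g],
                    long$protein[long$sample == g], mean, na.rm = TRUE)
    expect_identical(qr$identifier[qr$sample == g][1],
                     names(which.max(means)))
  }
})

test_that("overlap regions partition the union across group counts", {
  sim <- simulate_dataset(n_proteins = 60, groups = c(a = 2, b = 2, c = 2),
                          seed = 81)
  d <- sim$dataset
  ov <- overlap_data(d)
  expect_equal(nrow(ov), 2^3 - 1)
  long <- to_table(d, "long")
  present <- lapply(unique(long$sample), function(g) {
    unique(paste(long$protein, long$peptide)[long$sample == g &
                                               !is.na(long$abundance)])
  })
  expect_equal(sum(ov$count), length(unique(unlist(present))))
  # brute-force one region: all three groups
  inter3 <- length(Reduce(intersect, present))
  expect_equal(ov$count[ov$region == "a&b&c"], inter3)

  # identical groups: all mass in the full intersection
  base <- 2^rnorm(10, 20, 1)
  d2 <- make_protein_dataset(cbind(base, base), c("x", "y"))
  ov2 <- overlap_data(d2)
  expect_equal(ov2$count[ov2$region == "x&y"], 10)
  expect_equal(sum(ov2$count), 10)
  expect_error(overlap_data(d2, groups = "x"), "2 to 4")
})

test_that("CV-vs-abundance pairs and decile trends track the simulation", {
  # constant replicates: every CV is zero
  base <- 2^rnorm(20, 20, 1)
  d0 <- make_protein_dataset(cbind(base, base, base), c("a", "a", "a"))
  dr0 <- dynamic_range_data(d0, "raw")
  expect_equal(dr0$points$cv, rep(0, 20))

  # noise sd proportional to 1/abundance: CV falls with abundance
  set.seed(82)
  n_id <- 300
  mu <- sort(rnorm(n_id, 20, 2))
  cv_true <- 0.4 * exp(-(mu - min(mu)) / 3)
  sd_l2 <- sqrt(log(1 + cv_true^2)) / log(2)
  mat <- 2^vapply(1:4, function(i) mu + rnorm(n_id, 0, sd_l2), numeric(n_id))
  d1 <- make_protein_dataset(mat, rep("a", 4))
  dr1 <- dynamic_range_data(d1, "raw")
  expect_equal(nrow(dr1$points), n_id)
  expect_lt(mean(dr1$deciles$mean_cv[dr1$deciles$decile > 7]),
            mean(dr1$deciles$mean_cv[dr1$deciles$decile < 4]))
})

test_that("PCA scores are deterministic and variances match eigendecomposition", {
  set.seed(83)
  mat <- 2^matrix(rnorm(120, 20, 1), nrow = 20)
  d <- make_protein_dataset(mat, c("a", "a", "a", "b", "b", "b"))
  p <- pca_data(d, "raw")
  expect_equal(sum(p$variance$var_fraction), 1, tolerance = 1e-9)
  # brute-force eigendecomposition of the centered covariance
  x <- t(log2(mat)); x <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(x))$values
  expect_equal(p$variance$var_fraction[1:5], (ev / sum(ev))[1:5],
               tolerance = 1e-9)
  expect_identical(pca_data(d, "raw")$scores$PC1, p$scores$PC1)

  # duplicated samples land on identical scores
  d2 <- make_protein_dataset(mat[, c(1, 1, 2, 3)], c("a", "a", "b", "b"))
  s <- pca_data(d2, "raw")$scores
  expect_equal(unname(s$PC1[1]), unname(s$PC1[2]), tolerance = 1e-9)
})

test_that("heat-map rows are z-scored and linkage matches a hand-run of average linkage", {
  mat <- 2^matrix(c(1, 2, 3, 4,
                    1.1, 2.1, 3.1, 4.1,
                    8, 7, 6, 5,
                    4, 4, 5, 6,
                    2, 3, 2, 3), nrow = 5, byrow = TRUE)
  d <- make_protein_dataset(mat, c("a", "a", "b", "b"))
  h <- heatmap_data(d, "raw")
  expect_equal(unname(rowMeans(h$z)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(h$z, 1, sd)), rep(1, 5), tolerance = 1e-12)
  # brute-force average linkage on the same 5x4 toy
  ref <- stats::hclust(stats::dist(h$z), method = "average")
  expect_equal(h$row_hclust$height, ref$height, tolerance = 1e-12)
  expect_identical(h$row_order, ref$order)

  # identical samples cluster adjacently
  d2 <- make_protein_dataset(mat[, c(1, 2, 1, 3)], c("a", "a", "b", "b"))
  h2 <- heatmap_data(d2, "raw")
  o <- h2$col_order
  expect_equal(abs(which(o == 1) - which(o == 3)), 1)
})

test_that("volcano and proportion tables classify by thresholds and sum to one", {
  set.seed(84)
  sim <- simulate_dataset(n_proteins = 120, seed = 84)
  d <- collapse(sim$dataset, "razor")
  r <- expression_analysis(d, "kndw", "ctrl", method = "limma_moderated")
  v <- volcano_data(r)
  brute <- ifelse(r$adj_p_value < 0.05 & r$log2_fc >= 1, "up",
                  ifelse(r$adj_p_value < 0.05 & r$log2_fc <= -1, "down", "ns"))
  expect_identical(v$class, brute)
  expect_equal(as.vector(attr(v, "class_counts")), as.vector(table(
    factor(brute, c("up", "down", "ns")))))

  p <- proportion_data(r)
  expect_equal(sum(p$proportion), 1, tolerance = 1e-12)

  # an all-null simulation yields no significant classes
  null <- simulate_dataset(n_proteins = 100, de_fraction = 0, seed = 85)
  rn <- expression_analysis(collapse(null$dataset, "razor"), "kndw", "ctrl")
  vn <- volcano_data(rn)
  expect_identical(unique(vn$class), "ns")
})

test_that("enrichment ordering is stable under input shuffling", {
  e <- tibble::tibble(term = "t", annotation = letters[1:5], size = 5,
                      es = c(0.9, -0.8, 0.5, 0.4, 0.2),
                      nes = c(2, -1.9, 1.2, 1.1, 0.3),
                      p_value = c(0.001, 0.001, 0.2, 0.5, 0.9),
                      adj_p_value = c(0.005, 0.005, 0.3, 0.6, 0.9))
  o1 <- enrichment_plot_data(e)
  set.seed(86)
  o2 <- enrichment_plot_data(e[sample(5), ])
  expect_identical(o1$annotation, o2$annotation)
  expect_identical(o1$annotation[1], "a")  # p tie broken by |nes|
  expect_identical(o1$annotation[5], "e")
})
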