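test_that("identical groups give zero fold change and null p-values", {
  base <- 2^rnorm(20, 20, 1)
  d <- make_protein_dataset(cbind(base, base, base, base),
                            c("ctrl", "ctrl", "kndw", "kndw"))
  r <- expression_analysis(d, "kndw", "ctrl", method = "t_test")
  expect_equal(r$log2_fc, rep(0, 20))
  expect_true(all(r$p_value > 0.99))
})

test_that("fold changes are exact ratios of linear means", {
  d <- make_protein_dataset(matrix(c(8, 8, 8, 8, 2, 2, 2, 2), nrow = 1),
                            c(rep("num", 4), rep("den", 4)))
  r <- expression_analysis(d, "num", "den")
  expect_equal(r$log2_fc, 2)
  expect_equal(r$mean_numerator, 8)
  expect_equal(r$average_abundance, 5)
})

test_that("the Welch t matches a closed-form hand computation", {
  a <- c(3.1, 3.3, 3.2); b <- c(1.0, 1.2, 1.1)
  d <- make_protein_dataset(matrix(2^c(a, b), nrow = 1),
                            c(rep("num", 3), rep("den", 3)))
  r <- expression_analysis(d, "num", "den", method = "t_test")
  # hand-computed Welch statistic and Welch-Satterthwaite p
  se <- sqrt(var(a) / 3 + var(b) / 3)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(r$statistic, t_hand, tolerance = 1e-9)
  expect_equal(r$p_value, p_hand, tolerance = 1e-9)
})

test_that("swapping numerator and denominator negates log2_fc, keeps p", {
  sim <- simulate_dataset(n_proteins = 80, seed = 61)
  d <- collapse(sim$dataset, "razor")
  r1 <- expression_analysis(d, "kndw", "ctrl")
  r2 <- expression_analysis(d, "ctrl", "kndw")
  j <- match(r1$protein, r2$protein)
  expect_equal(r1$log2_fc, -r2$log2_fc[j], tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value[j], tolerance = 1e-12)
  expect_true(all(r1$adj_p_value >= r1$p_value))
})

test_that("identifiers with thin replication are excluded and reported", {
  mat <- rbind(A = c(4, 8, NA, 16, 32, NA), B = c(4, NA, NA, 8, 16, 32),
               C = 2^rnorm(6, 5, 0.1))
  d <- make_protein_dataset(mat, c(rep("g1", 3), rep("g2", 3)))
  r <- expression_analysis(d, "g2", "g1")
  expect_setequal(r$protein, c("A", "C"))
  expect_identical(attr(r, "excluded")$protein, "B")
  expect_error(expression_analysis(d, "g2", "g2"), "must differ")
  expect_error(expression_analysis(d, "g2", "nope"), "missing or has fewer")
})

test_that("variance moderation matches an independent moment solver", {
  set.seed(62)
  n_id <- 200; d0_true <- 6; s0_true <- 0.05; df <- 6
  s2_true <- s0_true * d0_true / rchisq(n_id, d0_true)
  s2 <- s2_true * rchisq(n_id, df) / df
  fit <- moderate_variances(s2, df)

  # independent oracle: solve the two moment equations numerically
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  rhs <- var(e) - trigamma(df / 2)
  d0_oracle <- 2 * uniroot(function(y) trigamma(y) - rhs, c(1e-6, 1e6),
                           tol = 1e-12)$root
  s0_oracle <- exp(mean(e) + digamma(d0_oracle / 2) - log(d0_oracle / 2))
  expect_equal(fit$d0, d0_oracle, tolerance = 1e-6)
  expect_equal(fit$s0_2, s0_oracle, tolerance = 1e-6)

  # cross-check against the reference empirical-Bayes implementation
  if (requireNamespace("limma", quietly = TRUE)) {
    sq <- limma::squeezeVar(s2, df)
    expect_equal(fit$d0, sq$df.prior, tolerance = 1e-6)
    expect_equal(fit$s0_2, sq$var.prior, tolerance = 1e-6)
    expect_equal(fit$s2_post, sq$var.post, tolerance = 1e-6)
  }
})

test_that("moderation limits behave: d0=0 keeps s2, d0=Inf flattens to s0", {
  s2 <- c(0.5, 1, 2, 4)
  post0 <- (0 * 1 + 4 * s2) / (0 + 4)
  expect_equal(post0, s2)  # the formula's d0=0 limit is the identity
  # all variances equal => infinite prior df branch
  fit <- moderate_variances(rep(0.3, 50), 4)
  expect_identical(fit$d0, Inf)
  expect_equal(fit$s2_post, rep(fit$s0_2, 50))

  # moderated t with a degenerate zero-spread prior equals the pooled t
  set.seed(63)
  a <- rnorm(4, 5, 0.3); b <- rnorm(4, 4, 0.3)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 6
  t_pooled <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  t_mod <- (mean(a) - mean(b)) / sqrt(((0 * 1 + 6 * sp2) / 6) * (1 / 4 + 1 / 4))
  expect_equal(t_mod, t_pooled, tolerance = 1e-12)
})

test_that("rank-sum and moderated analyses run and compare cleanly", {
  sim <- simulate_dataset(n_proteins = 100, seed = 64)
  d <- collapse(sim$dataset, "razor")
  rw <- expression_analysis(d, "kndw", "ctrl", method = "wilcoxon")
  rm_ <- expression_analysis(d, "kndw", "ctrl", method = "limma_moderated")
  expect_true(all(rw$p_value >= 0 & rw$p_value <= 1))

  cmp <- compare_expressions(rm_, rw)
  expect_equal(nrow(cmp), length(intersect(rm_$protein, rw$protein)))
  # self-comparison sits on the identity line with consistent flags
  self <- compare_expressions(rm_, rm_)
  expect_equal(self$log2_fc_A, self$log2_fc_B)
  expect_setequal(unique(self$significant), c("both", "neither"))
  counts <- table(self$significant)
  expect_equal(unname(counts["both"]), sum(rm_$adj_p_value < 0.05))

  rb <- rm_; rb$protein <- paste0("ZZZ_", rb$protein)
  expect_error(compare_expressions(rm_, rb), "empty join")
})
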