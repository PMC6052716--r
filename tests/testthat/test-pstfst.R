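test_that("variance components match the ANOVA oracle on unbalanced data", {
  set.seed(5)
  groups <- rep(c("a", "b", "c", "d"), c(4, 9, 6, 12))
  values <- rnorm(length(groups), mean = rep(c(0, 1, -1, 2), c(4, 9, 6, 12)))
  vc <- variance_components(values, groups)
  fit <- anova(lm(values ~ groups))
  expect_equal(vc$ms_within, fit["Residuals", "Mean Sq"])
  expect_equal(vc$ms_between, fit["groups", "Mean Sq"])
  n <- c(4, 9, 6, 12)
  n0 <- (sum(n) - sum(n^2) / sum(n)) / 3
  expect_equal(vc$sigma2_B,
               max(0, (vc$ms_between - vc$ms_within) / n0))
})

test_that("variance components reject degenerate groups", {
  expect_error(variance_components(rep(1, 10), rep(c("a", "b"), 5)),
               "degenerate")
  expect_error(variance_components(c(1, 2, 3), c("a", "a", "b")), "b")
  expect_error(variance_components(1:4, rep("a", 4)), "two groups")
})

test_that("well-separated groups dominate the within variance", {
  values <- c(0, 0, 0, 10, 10, 10) + c(-1, 0, 1, -1, 0, 1) * 1e-3
  vc <- variance_components(values, rep(c("a", "b"), each = 3))
  expect_gt(vc$sigma2_B / vc$sigma2_W, 1e4)
})

test_that("variance component estimates recover the truth on average", {
  est <- vapply(1:200, function(s) {
    with_seed <- stickpop:::with_seed
    with_seed(3000 + s, {
      mu <- rnorm(7, 0, sqrt(2))
      values <- rnorm(210, rep(mu, each = 30), 1)
      vc <- variance_components(values, rep(1:7, each = 30))
      c(vc$sigma2_B, vc$sigma2_W)
    })
  }, c(0, 0))
  expect_lt(abs(mean(est[1, ]) - 2), 0.1)
  expect_lt(abs(mean(est[2, ]) - 1), 0.1)
})

test_that("P_ST and the neutral variance follow their closed forms", {
  expect_equal(pst(0, 1), 0)
  expect_equal(pst(2, 1), 0.5)
  expect_equal(pst(1, 1), 1 / 3)
  expect_error(pst(1, 0), "sigma2_W")
  expect_equal(neutral_sigma2b(1 / 3, 3), 3)
  expect_equal(neutral_sigma2b(0.5, 1), 2)
  expect_lt(neutral_sigma2b(1e-9, 1), 1e-8)
  expect_error(neutral_sigma2b(1, 1), "fst")
  # strictly increasing in sigma2_B for fixed sigma2_W
  s2b <- seq(0, 5, by = 0.1)
  expect_true(all(diff(pst(s2b, 1)) > 0))
})

test_that("the neutral null is unbiased, centred and reproducible", {
  null <- build_neutral_null(0.1, 1, df = 6, n_draws = 100000, seed = 1)
  s2b_star <- (null$draws + 0.1) * 2 / (1 - (null$draws + 0.1))
  expect_lt(abs(mean(s2b_star) / neutral_sigma2b(0.1, 1) - 1), 0.01)
  expect_lt(abs(median(null$draws)), 0.02)
  null2 <- build_neutral_null(0.1, 1, df = 6, n_draws = 100000, seed = 1)
  expect_identical(null$draws, null2$draws)
  expect_error(build_neutral_null(0.1, n_draws = 10), "n_draws")
  expect_error(build_neutral_null(2, 1), "fst")
})

test_that("tail quantiles of the default null match a large reference run", {
  big <- build_neutral_null(0.1, 1, df = 6, n_draws = 1000000, seed = 2)
  std <- build_neutral_null(0.1, 1, df = 6, n_draws = 10000, seed = 3)
  qs <- c(0.9, 0.95, 0.99)
  expect_lt(max(abs(quantile(big$draws, qs) - quantile(std$draws, qs))),
            0.02)
})

test_that("the undivided chi-square variant inflates the null mean by df", {
  scaled <- build_neutral_null(0.1, 1, df = 6, n_draws = 50000, seed = 4)
  raw <- build_neutral_null(0.1, 1, df = 6, n_draws = 50000, seed = 4,
                            scale_by_df = FALSE)
  mean_s2b <- function(n) mean((n$draws + n$fst) * 2 / (1 - (n$draws + n$fst)))
  expect_lt(abs(mean_s2b(raw) / mean_s2b(scaled) - 6), 0.2)
})

test_that("selection p-values follow the upper-tail rule", {
  null <- build_neutral_null(0.1, 1, df = 6, seed = 5)
  at_fst <- selection_pvalue(0.1, null)
  expect_gt(at_fst$p, 0.3)
  expect_lt(at_fst$p, 0.7)
  extreme <- selection_pvalue(0.999, null)
  expect_identical(extreme$p, 0)
  # non-increasing in the observed value
  obs <- seq(0.05, 0.9, by = 0.05)
  ps <- vapply(obs, function(o) selection_pvalue(o, null)$p, 0)
  expect_true(all(diff(ps) <= 0))
  # exact exceedance count granularity
  expect_equal(selection_pvalue(0.1, null)$p * null$n_draws,
               sum(null$draws >= 0))
  expect_error(selection_pvalue(0.2, null, fst = 0.15), "match")
})

test_that("pst_fst fits the whole chain with a formula interface", {
  ph <- simulate_neutral_phenotype(rep(30, 7), fst = 0.1, seed = 6)
  fit <- pst_fst(trait ~ deme, ph, fst = 0.1, seed = 7)
  expect_s3_class(fit, "pst_fst")
  expect_equal(fit$null$df, 6)
  expect_equal(fit$pst, pst(fit$vc))
  expect_output(print(fit), "P_ST-F_ST")
  expect_output(summary(fit), "null 2.5")
  # divergent trait is flagged
  ph$trait <- ph$trait + 5 * (as.integer(factor(ph$deme)) %% 2)
  strong <- pst_fst(trait ~ deme, ph, fst = 0.1, seed = 7)
  expect_identical(strong$test$p, 0)
})

test_that("F_STQ equals theta on the recoded single locus", {
  expect_equal(fstq(c("CC", "CC", "LL", "LL"), c("a", "a", "b", "b")), 1)
  same <- fstq(rep(c("CC", "CL", "LL"), 10),
               rep(c("a", "b"), each = 15))
  expect_lt(abs(same), 0.05)
  # internal consistency with wc_fst on the 0/1/2 dosage matrix
  set.seed(10)
  gt <- sample(c("CC", "CL", "LL"), 60, replace = TRUE,
               prob = c(0.5, 0.3, 0.2))
  deme <- rep(c("a", "b", "c"), each = 20)
  dosage <- c(CC = 0L, CL = 1L, LL = 2L)[gt]
  g <- make_g(matrix(dosage, ncol = 1), deme)
  expect_identical(fstq(gt, deme), wc_fst(g)$theta)
  pw <- fstq(gt, deme, pairwise = TRUE)
  expect_identical(dim(pw), c(3L, 3L))
  expect_error(fstq(rep("CC", 10), rep(c("a", "b"), 5)), "monomorphic")
  expect_error(fstq(c("CC", "XX"), c("a", "b")), "CC, CL or LL")
})
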