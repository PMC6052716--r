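test_that("Hardy-Weinberg expected counts match the worked example and conserve totals", {
  expect_equal(hwe_expected(c(24, 0, 3)), c(21.3, 5.3, 0.3), tolerance = 0.05)
  expect_equal(hwe_expected(c(25, 50, 25)), c(25, 50, 25))
  expect_equal(hwe_expected(c(10, 0, 0)), c(10, 0, 0))
  for (counts in list(c(3, 5, 9), c(1, 1, 1), c(0, 7, 2), c(12, 0, 4))) {
    expect_equal(sum(hwe_expected(counts)), sum(counts))
  }
  expect_error(hwe_expected(c(0, 0, 0)), "zero")
  expect_error(hwe_expected(c(-1, 2, 3)), "non-negative")
})

test_that("Hardy-Weinberg chi-square test matches hand evaluation", {
  # hand evaluation from expected counts (64/3, 16/3, 1/3):
  # (8/3)^2*3/64 + 16/3 + (8/3)^2*3 = 1/3 + 16/3 + 64/3 = 27
  res <- suppressWarnings(hwe_test(c(24, 0, 3)))
  expect_equal(res$chi2, 27, tolerance = 1e-12)
  expect_identical(res$df, 1L)
  expect_lt(res$p, 1e-6)
  expect_warning(hwe_test(c(24, 0, 3)), "below 1")
  perfect <- hwe_test(c(25, 50, 25))
  expect_equal(perfect$chi2, 0)
  expect_equal(perfect$p, 1)
  fixed <- hwe_test(c(0, 0, 10))
  expect_equal(fixed$chi2, 0)
  # agreement with stats::chisq.test given the HWE expectation
  obs <- c(30, 18, 12)
  e <- hwe_expected(obs)
  ref <- stats::chisq.test(obs, p = e / sum(e), correct = FALSE)
  expect_equal(hwe_test(obs)$chi2, unname(ref$statistic))
})

test_that("per-deme summaries match exhaustive enumeration", {
  calls <- rbind(
    c(0L, 0L, 2L, 1L, NA),
    c(0L, 1L, 2L, 1L, 0L),
    c(0L, 0L, 2L, 0L, 0L),
    c(0L, 0L, 1L, 0L, 2L),
    c(2L, 0L, 2L, 0L, NA),
    c(1L, 0L, 2L, 0L, 0L))
  deme <- c("d1", "d1", "d2", "d2", "d3", "d3")
  g <- make_g(calls, deme)
  for (d in c("d1", "d2", "d3")) {
    got <- summarize_population(g, d)
    want <- summary_oracle(calls, deme, d)
    expect_equal(got$private, want$private, info = d)
    expect_equal(got$pct_polymorphic, want$pct_polymorphic, info = d)
    expect_equal(got$n_loci, want$n_loci, info = d)
  }
})

test_that("private alleles and polymorphism handle degenerate inputs", {
  # allele a (dosage > 0) present only in deme2
  g <- make_g(rbind(c(0L, 0L), c(0L, 1L)), deme = c("d1", "d2"))
  expect_equal(summarize_population(g, "d2")$private, 1)
  expect_equal(summarize_population(g, "d1")$private, 0)
  mono <- make_g(matrix(0L, 4, 3), deme = rep(c("d1", "d2"), 2))
  s <- summarize_population(mono, "d1")
  expect_equal(s$pct_polymorphic, 0)
  expect_equal(s$private, 0)
  expect_error(summarize_population(g, "nope"), "not present")
})

test_that("locus summaries use the unbiased pairwise-difference pi", {
  g <- make_g(rbind(c(1L), c(1L)), deme = c("d1", "d1"),
              locus_ids = "L1")
  ls <- locus_summary(g, "d1")
  expect_equal(ls$het_exp, 0.5)           # 2pq at p = 0.5
  expect_equal(ls$pi, 0.5 * 4 / 3)        # 2pq * 2n/(2n-1), n = 2
  expect_equal(ls$f_is, 1 - 1 / (2 / 3))  # Ho = 1
  expect_true(all(ls$p_major >= 0.5))
})

test_that("the filter cascade removes loci for the first failing rule", {
  set.seed(1)
  # unequal deme sizes so a locus can clear the 75% call threshold while
  # still being absent from 3 of the 8 demes
  deme <- rep(paste0("d", 1:8), rep(c(8L, 2L), c(5, 3)))
  n <- length(deme)  # 46
  base <- matrix(rbinom(n * 4, 2, 0.4), n)
  # locus 5: called in only half the individuals
  sparse <- c(rbinom(n / 2, 2, 0.4), rep(NA_integer_, n - n %/% 2))
  # locus 6: called in 40/46 individuals but present in only 5 of 8 demes
  five_pop <- ifelse(deme %in% paste0("d", 1:5), rbinom(n, 2, 0.4),
                     NA_integer_)
  # locus 7: minor allele frequency 1/92
  rare <- c(1L, rep(0L, n - 1))
  # locus 8: all heterozygotes, F_IS near -1
  het <- rep(1L, n)
  g <- make_g(cbind(base, sparse, five_pop, rare, het), deme,
              locus_ids = paste0("L", 1:8))
  res <- apply_filters(g, min_ind_fraction = 0.75, min_pops = 6,
                       min_maf = 0.02, min_fis = -0.3)
  reasons <- setNames(res$rejected$reason, res$rejected$locus_id)
  expect_identical(unname(reasons["L5"]), "min_ind_fraction")
  expect_identical(unname(reasons["L6"]), "min_pops")
  expect_identical(unname(reasons["L7"]), "min_maf")
  expect_identical(unname(reasons["L8"]), "min_fis")
  expect_true(all(paste0("L", 1:4) %in% res$genotypes$locus_ids))
})

test_that("filtering is idempotent and depth masking precedes locus filters", {
  g <- sim_island(sim_config(n_demes = 8, n_per_deme = 10, n_loci = 300,
                             fst = 0.05, missing_rate = 0.1, seed = 21))
  once <- apply_filters(g, min_pops = 6)
  twice <- apply_filters(once$genotypes, min_pops = 6)
  expect_identical(nrow(twice$rejected), 0L)
  expect_identical(twice$genotypes$calls, once$genotypes$calls)
  # depth below threshold masks the call before locus filters run
  calls <- matrix(rep(c(0L, 1L), 8), 4)
  depth <- matrix(10, 4, 4)
  depth[, 1] <- 1
  gd <- genotype_matrix(calls, deme = c("a", "a", "b", "b"), depth = depth)
  res <- apply_filters(gd, min_ind_fraction = 0.75, min_pops = 1,
                       min_maf = 0, min_fis = -2, min_depth = 4)
  expect_true("L1" %in% res$rejected$locus_id)
  expect_identical(res$rejected$reason[res$rejected$locus_id == "L1"],
                   "min_ind_fraction")
})

test_that("individual filter drops low-coverage fish first", {
  calls <- rbind(matrix(0:1, 6, 10), rep(NA_integer_, 10))
  g <- make_g(calls, deme = c(rep("a", 4), rep("b", 3)),
              ids = paste0("i", 1:7))
  res <- apply_filters(g, min_ind_fraction = 0, min_pops = 1, min_maf = 0,
                       min_fis = -2, min_loci_per_ind = 5)
  expect_identical(res$dropped_individuals, "i7")
  expect_identical(nrow(res$genotypes$calls), 6L)
})

test_that("Weir-Cockerham components match direct evaluation on small instances", {
  set.seed(99)
  for (case in 1:60) {
    k <- sample(2:3, 1)
    n_per <- sample(2:4, k, replace = TRUE)
    n_loci <- sample(1:3, 1)
    deme <- rep(paste0("d", seq_len(k)), n_per)
    calls <- matrix(sample(c(0L, 1L, 2L, NA), sum(n_per) * n_loci,
                           replace = TRUE, prob = c(0.4, 0.3, 0.25, 0.05)),
                    sum(n_per))
    g <- make_g(calls, deme)
    got <- wc_fst_components_for_test(g)
    for (j in seq_len(n_loci)) {
      want <- wc_direct(calls[, j], deme)
      expect_equal(unlist(got[j, c("a", "b", "c")]),
                   c(a = want[["a"]], b = want[["b"]], c = want[["c"]]),
                   tolerance = 1e-10)
    }
  }
})

test_that("theta hits the boundary cases", {
  # complete fixation between two demes
  fixed <- make_g(rbind(matrix(0L, 10, 1), matrix(2L, 10, 1)),
                  deme = rep(c("a", "b"), each = 10))
  expect_equal(unname(wc_fst(fixed)$per_locus), 1)
  # two demes with identical genotype arrays: theta near (possibly below) 0
  block <- matrix(rep(c(0L, 1L, 2L), each = 10), 30, 5)
  same <- make_g(rbind(block, block), deme = rep(c("a", "b"), each = 30))
  th <- wc_fst(same)$theta
  expect_lte(th, 0)
  expect_lt(abs(th), 0.05)
  expect_error(wc_fst(make_g(cbind(c(0L, 1L)), deme = c("a", "a"))),
               "two demes")
})

test_that("theta is invariant to locus order and allele relabelling", {
  g <- sim_island(sim_config(n_demes = 4, n_per_deme = 15, n_loci = 100,
                             fst = 0.1, seed = 31))
  perm <- sample(ncol(g$calls))
  expect_equal(wc_fst(g[, perm])$theta, wc_fst(g)$theta)
  swapped <- genotype_matrix(2L - g$calls, deme = g$deme,
                             locus_ids = g$locus_ids)
  expect_equal(wc_fst(swapped)$theta, wc_fst(g)$theta)
  expect_equal(unname(wc_fst(swapped)$per_locus),
               unname(wc_fst(g)$per_locus))
})

test_that("per-locus theta stays in [-1, 1] and bounds the global estimate", {
  g <- sim_island(sim_config(n_demes = 5, n_per_deme = 12, n_loci = 400,
                             fst = 0.08, missing_rate = 0.1, seed = 77))
  res <- wc_fst(g)
  pl <- res$per_locus[!is.na(res$per_locus)]
  expect_true(all(pl >= -1 & pl <= 1))
  expect_lte(res$theta, max(pl))
})

test_that("pairwise theta is consistent with the global two-deme estimate", {
  g <- sim_island(sim_config(n_demes = 2, n_per_deme = 20, n_loci = 200,
                             fst = 0.1, seed = 8))
  pw <- pairwise_fst(g)
  expect_equal(pw["deme1", "deme2"], wc_fst(g)$theta)
  # three identical demes: all entries near 0
  block <- matrix(rep(c(0L, 1L, 2L), each = 8), 24, 6)
  g3 <- make_g(rbind(block, block, block),
               deme = rep(c("a", "b", "c"), each = 24))
  expect_lt(max(abs(pairwise_fst(g3)[lower.tri(diag(3))])), 0.05)
})

test_that("permutation significance separates signal from noise", {
  fixed <- make_g(cbind(rep(c(0L, 2L), each = 10),
                        rep(c(0L, 2L), each = 10)),
                  deme = rep(c("a", "b"), each = 10))
  res <- fst_significance(fixed, c("a", "b"), n_perm = 199, seed = 1)
  expect_equal(res$p, 1 / 200)
  res2 <- fst_significance(fixed, c("a", "b"), n_perm = 199, seed = 1)
  expect_identical(res, res2)
  # identical demes: p is null-uniform, rarely small
  block <- matrix(rep(c(0L, 1L, 2L, 1L), each = 5), 20, 8)
  same <- make_g(rbind(block, block), deme = rep(c("a", "b"), each = 20))
  ps <- vapply(1:20, function(s)
    fst_significance(same, c("a", "b"), n_perm = 99, seed = s)$p, 0)
  expect_gte(mean(ps > 0.05), 0.9)
})
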