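# Standing-variation summaries, the filter cascade, HWE tests and the
# Weir-Cockerham theta estimator of F_ST.

# Pooled (across all demes) per-locus tallies: called individuals, alt
# frequency, observed het proportion, unbiased expected het, F_IS.
pooled_locus_stats <- function(g) {
  called <- colSums(!is.na(g$calls))
  alt <- colSums(g$calls, na.rm = TRUE)
  p <- ifelse(called > 0, alt / (2 * called), NA_real_)
  ho <- ifelse(called > 0,
               colSums(g$calls == 1L, na.rm = TRUE) / called, NA_real_)
  he_u <- 2 * p * (1 - p) * (2 * called) / pmax(2 * called - 1, 1)
  fis <- ifelse(!is.na(he_u) & he_u > 0, 1 - ho / he_u, NA_real_)
  list(n = called, p_alt = p, maf = pmin(p, 1 - p), het_obs = ho,
       het_exp_u = he_u, f_is = fis)
}

#' Per-locus summary statistics for one deme
#'
#' For each variant locus sequenced in the deme: number of called
#' individuals, major-allele frequency, observed and expected
#' heterozygosity, per-site nucleotide diversity and the inbreeding
#' coefficient. `het_exp` is the plain `2pq`; `pi` is the unbiased
#' pairwise-difference form `2pq * 2n / (2n - 1)`, which is also the
#' denominator of `f_is = 1 - het_obs / pi`.
#'
#' @param g a [genotype_matrix()].
#' @param deme deme label present in `g`.
#' @return A data frame with one row per locus called in the deme:
#'   `locus_id`, `n_called`, `p_major`, `het_obs`, `het_exp`, `pi`, `f_is`.
#' @export
locus_summary <- function(g, deme) {
  if (!deme %in% levels(g$deme)) stop("deme not present: ", deme)
  sub <- g$calls[g$deme == deme, , drop = FALSE]
  if (nrow(sub) == 0) stop("deme is empty: ", deme)
  n <- colSums(!is.na(sub))
  keep <- n > 0
  sub <- sub[, keep, drop = FALSE]
  n <- n[keep]
  p_alt <- colSums(sub, na.rm = TRUE) / (2 * n)
  p_major <- pmax(p_alt, 1 - p_alt)
  ho <- colSums(sub == 1L, na.rm = TRUE) / n
  he <- 2 * p_alt * (1 - p_alt)
  pi <- he * (2 * n) / pmax(2 * n - 1, 1)
  fis <- ifelse(pi > 0, 1 - ho / pi, NA_real_)
  data.frame(locus_id = g$locus_ids[keep], n_called = n, p_major = p_major,
             het_obs = ho, het_exp = he, pi = pi, f_is = fis,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-deme standing-variation summary
#'
#' For each deme (or one deme), reports the number of private alleles
#' (alleles seen in that deme and in no other), the fraction of variant loci
#' that are polymorphic within the deme, and the means over variant loci of
#' major-allele frequency, observed/expected heterozygosity and nucleotide
#' diversity; `f_is` is the unweighted mean over loci polymorphic in the
#' deme.
#'
#' @param g a [genotype_matrix()] (with at least two demes for private
#'   alleles to be meaningful).
#' @param deme a single deme label.
#' @return `summarize_population`: a one-row data frame;
#'   `summarize_populations`: one row per deme.
#' @export
summarize_population <- function(g, deme) {
  if (!deme %in% levels(g$deme)) stop("deme not present: ", deme)
  af <- deme_allele_freqs(g)
  d <- match(deme, rownames(af$freq))
  ls <- locus_summary(g, deme)
  idx <- match(ls$locus_id, g$locus_ids)
  # allele presence per deme: ref allele present iff freq < 1, alt iff > 0
  alt_here <- af$freq[d, idx] > 0
  ref_here <- af$freq[d, idx] < 1
  others <- af$freq[-d, idx, drop = FALSE]
  alt_elsewhere <- colSums(others > 0, na.rm = TRUE) > 0
  ref_elsewhere <- colSums(others < 1, na.rm = TRUE) > 0
  private <- sum(alt_here & !alt_elsewhere, na.rm = TRUE) +
    sum(ref_here & !ref_elsewhere, na.rm = TRUE)
  poly <- ls$p_major < 1
  data.frame(deme = deme,
             n_ind = sum(g$deme == deme),
             n_loci = nrow(ls),
             private = private,
             pct_polymorphic = 100 * mean(poly),
             p_major = mean(ls$p_major),
             het_obs = mean(ls$het_obs),
             het_exp = mean(ls$het_exp),
             pi = mean(ls$pi),
             f_is = mean(ls$f_is[poly], na.rm = TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname summarize_population
#' @export
summarize_populations <- function(g) {
  do.call(rbind, lapply(levels(g$deme), function(d) summarize_population(g, d)))
}

#' Hardy-Weinberg expected genotype counts
#'
#' From observed counts `(nAA, nAa, naa)` at a biallelic locus, computes the
#' allele frequency `p = (2 nAA + nAa) / 2n` and the expected counts
#' `n * (p^2, 2pq, q^2)`. The total is conserved exactly.
#'
#' @param counts numeric vector of three genotype counts.
#' @return Numeric vector of three expected counts.
#' @examples
#' hwe_expected(c(24, 0, 3))  # 21.33, 5.33, 0.33
#' @export
hwe_expected <- function(counts) {
  if (length(counts) != 3 || any(counts < 0)) {
    stop("`counts` must be three non-negative genotype counts")
  }
  n <- sum(counts)
  if (n == 0) stop("all genotype counts are zero")
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  q <- 1 - p
  unname(n * c(p^2, 2 * p * q, q^2))
}

#' Hardy-Weinberg goodness-of-fit test
#'
#' Pearson chi-square of observed against [hwe_expected()] counts with 1
#' degree of freedom (biallelic locus; one parameter estimated from the
#' data), no continuity correction. Cells with zero expectation (a fixed
#' allele) contribute nothing; an expected count below 1 in a segregating
#' class triggers a warning rather than an automatic exact test.
#'
#' @param counts numeric vector of three genotype counts `(nAA, nAa, naa)`.
#' @return `list(chi2, df, p)`.
#' @examples
#' hwe_test(c(24, 0, 3))  # chi2 = 27, p ~ 2e-7
#' @export
hwe_test <- function(counts) {
  expected <- hwe_expected(counts)
  nz <- expected > 0
  if (any(expected[nz] < 1)) {
    warning("expected genotype count below 1; chi-square approximation is rough")
  }
  chi2 <- sum((counts[nz] - expected[nz])^2 / expected[nz])
  list(chi2 = chi2, df = 1L, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Apply the RAD-seq style locus filter cascade
#'
#' Reproduces the study-style genotype-matrix filters: calls below a depth
#' threshold are first set missing (when per-call depth is available),
#' individuals with too few called loci are dropped, then each locus must be
#' (in order of reporting) called in at least `min_ind_fraction` of the
#' retained individuals, called in at least `min_pops` demes, have overall
#' minor-allele frequency at least `min_maf`, and have overall
#' `F_IS > min_fis` (an excess-heterozygosity guard). The first failing rule
#' is logged per rejected locus. Filtering is idempotent.
#'
#' @param g a [genotype_matrix()].
#' @param min_ind_fraction minimum fraction of individuals with a call.
#' @param min_pops minimum number of demes with at least one call; `"all"`
#'   requires every deme.
#' @param min_maf minimum overall minor-allele frequency.
#' @param min_fis loci with pooled `F_IS <= min_fis` are removed.
#' @param min_depth calls with depth below this are masked (needs `depth`).
#' @param min_loci_per_ind drop individuals with fewer called loci; `NULL`
#'   disables the individual filter.
#' @return `list(genotypes = <filtered genotype_matrix>,
#'   rejected = <data frame locus_id, reason>,
#'   dropped_individuals = <character>)`.
#' @export
apply_filters <- function(g, min_ind_fraction = 0.75, min_pops = 6,
                          min_maf = 0.02, min_fis = -0.3, min_depth = 4,
                          min_loci_per_ind = NULL) {
  if (!is.null(g$depth)) {
    g$calls[g$depth < min_depth] <- NA_integer_
  }
  dropped <- character(0)
  if (!is.null(min_loci_per_ind)) {
    called_per_ind <- rowSums(!is.na(g$calls))
    drop <- called_per_ind < min_loci_per_ind
    if (all(drop)) stop("individual filter would drop every individual")
    if (any(drop)) {
      dropped <- g$ids[drop]
      g <- g[!drop, ]
    }
  }
  if (identical(min_pops, "all")) min_pops <- nlevels(g$deme)
  st <- pooled_locus_stats(g)
  frac_called <- st$n / nrow(g$calls)
  af <- deme_allele_freqs(g)
  pops_called <- colSums(af$n > 0)
  reason <- rep(NA_character_, ncol(g$calls))
  reason[is.na(reason) & frac_called < min_ind_fraction] <- "min_ind_fraction"
  reason[is.na(reason) & pops_called < min_pops] <- "min_pops"
  reason[is.na(reason) & st$maf < min_maf] <- "min_maf"
  reason[is.na(reason) & !is.na(st$f_is) & st$f_is <= min_fis] <- "min_fis"
  keep <- is.na(reason)
  list(genotypes = g[, keep],
       rejected = data.frame(locus_id = g$locus_ids[!keep],
                             reason = reason[!keep],
                             row.names = NULL, stringsAsFactors = FALSE),
       dropped_individuals = dropped)
}

# Weir & Cockerham (1984) per-locus variance components for biallelic loci,
# vectorised over loci. freq/n/het are demes x loci matrices: alt-allele
# frequency, called individuals, observed-heterozygote counts.
wc_components <- function(freq, n, het) {
  use <- n > 0 & !is.na(freq)
  nn <- n * use
  r <- colSums(use)                       # demes with data, per locus
  nsum <- colSums(nn)                     # total individuals
  nbar <- nsum / r
  nc <- (nsum - colSums(nn^2) / nsum) / (r - 1)
  f0 <- freq
  f0[!use] <- 0
  pbar <- colSums(nn * f0) / nsum
  s2 <- colSums(nn * (f0 - rep(pbar, each = nrow(f0)))^2 * use) /
    ((r - 1) * nbar)
  hbar <- colSums(het * use) / nsum       # observed het proportion, pooled
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  valid <- r >= 2 & nbar > 1 & is.finite(nc) & nc > 0
  data.frame(a = ifelse(valid, a, NA_real_),
             b = ifelse(valid, b, NA_real_),
             c = ifelse(valid, cc, NA_real_),
             r = r)
}

#' Weir-Cockerham theta (F_ST)
#'
#' Estimates per-locus and multilocus theta from the 1984 Weir-Cockerham
#' variance components: among-deme (`a`), among-individual-within-deme
#' (`b`) and within-individual (`c`). Per-locus theta is `a / (a + b + c)`;
#' the multilocus estimate is the ratio of sums `sum(a) / sum(a + b + c)`
#' over informative loci. Negative per-locus values are retained (not
#' truncated), keeping the ratio of sums unbiased. Loci with data in fewer
#' than two demes, or monomorphic in the subset, are skipped and logged.
#'
#' @param g a [genotype_matrix()].
#' @param demes optional subset of deme labels to use.
#' @return An object of class `wc_fst`: `list(theta, per_locus, components,
#'   excluded)`, where `per_locus` is a named vector and `components` holds
#'   the per-locus `a`, `b`, `c`.
#' @examples
#' g <- sim_island(sim_config(n_demes = 4, n_loci = 200, seed = 7))
#' wc_fst(g)$theta
#' @export
wc_fst <- function(g, demes = NULL) {
  if (!is.null(demes)) {
    missing_d <- setdiff(demes, levels(g$deme))
    if (length(missing_d)) stop("unknown deme(s): ",
                                paste(missing_d, collapse = ", "))
    g <- g[g$deme %in% demes, ]
  }
  if (nlevels(g$deme) < 2) stop("theta needs at least two demes")
  af <- deme_allele_freqs(g)
  het <- deme_het_counts(g)
  comp <- wc_components(af$freq, af$n, het)
  denom <- comp$a + comp$b + comp$c
  informative <- !is.na(denom) & denom > 0
  if (!any(informative)) stop("no informative locus in the chosen subset")
  per_locus <- rep(NA_real_, ncol(g$calls))
  per_locus[informative] <- comp$a[informative] / denom[informative]
  names(per_locus) <- g$locus_ids
  theta <- sum(comp$a[informative]) / sum(denom[informative])
  structure(list(theta = theta, per_locus = per_locus,
                 components = comp,
                 excluded = g$locus_ids[!informative]),
            class = "wc_fst")
}

#' @export
print.wc_fst <- function(x, ...) {
  ok <- !is.na(x$per_locus)
  cat(sprintf("Weir-Cockerham theta: %.4f (%d informative loci", x$theta,
              sum(ok)))
  if (length(x$excluded)) cat(",", length(x$excluded), "skipped")
  cat(")\n")
  invisible(x)
}

#' Pairwise Weir-Cockerham F_ST matrix
#'
#' Applies [wc_fst()] to every pair of demes.
#'
#' @param g a [genotype_matrix()] with at least two demes.
#' @return A [labeled_matrix()] of pairwise multilocus theta (0 diagonal).
#' @export
pairwise_fst <- function(g) {
  demes <- levels(g$deme)
  if (length(demes) < 2) stop("need at least two demes")
  m <- matrix(0, length(demes), length(demes),
              dimnames = list(demes, demes))
  for (i in seq_along(demes)[-1]) {
    for (j in seq_len(i - 1)) {
      th <- wc_fst(g, demes = demes[c(i, j)])$theta
      m[i, j] <- m[j, i] <- th
    }
  }
  labeled_matrix(m)
}

#' Permutation significance of pairwise F_ST
#'
#' Tests theta > 0 for one deme pair by permuting deme labels among the
#' pair's individuals: `p = (1 + #(theta_perm >= theta_obs)) / (n_perm + 1)`.
#'
#' @param g a [genotype_matrix()].
#' @param pair two deme labels.
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed.
#' @return `list(theta, p, n_perm)`.
#' @export
fst_significance <- function(g, pair, n_perm = 999, seed = NULL) {
  if (length(pair) != 2) stop("`pair` must name two demes")
  if (n_perm < 99) stop("`n_perm` must be >= 99")
  sub <- g[g$deme %in% pair, ]
  obs <- wc_fst(sub)$theta
  labels <- as.character(sub$deme)
  with_seed(seed, {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      sub$deme <- factor(sample(labels))
      exceed <- exceed + (wc_fst(sub)$theta >= obs)
    }
    list(theta = obs, p = (1 + exceed) / (n_perm + 1), n_perm = n_perm)
  })
}
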