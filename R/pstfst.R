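# The central selection test: variance components, P_ST, the chi-square
# scaled neutral null, p-values, and F_STQ at a single diallelic marker.

#' One-way random-effects variance components
#'
#' Method-of-moments (ANOVA) decomposition of a trait into between- and
#' within-population components, with the unequal-group-size correction
#' `n0 = (N - sum(n_i^2)/N) / (k - 1)`: `sigma2_W` is the pooled
#' within-group mean square and `sigma2_B = (MSB - MSW) / n0`, truncated at
#' zero.
#'
#' @param values numeric trait measurements.
#' @param groups population labels, same length as `values`; at least two
#'   groups with at least two observations each.
#' @return An object of class `variance_components`: `list(sigma2_B,
#'   sigma2_W, n_pops, group_sizes, ms_between, ms_within)`.
#' @examples
#' ph <- simulate_neutral_phenotype(rep(30, 7), fst = 0.1, seed = 1)
#' variance_components(ph$trait, ph$deme)
#' @export
variance_components <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  n_i <- table(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  small <- names(n_i)[n_i < 2]
  if (length(small)) {
    stop("group(s) with fewer than two observations: ",
         paste(small, collapse = ", "))
  }
  k <- nlevels(groups)
  N <- length(values)
  means <- tapply(values, groups, mean)
  ssw <- sum((values - means[groups])^2)
  msw <- ssw / (N - k)
  if (msw <= 0) stop("degenerate input: within-group variance is zero")
  grand <- mean(values)
  ssb <- sum(n_i * (means - grand)^2)
  msb <- ssb / (k - 1)
  n0 <- (N - sum(n_i^2) / N) / (k - 1)
  s2b <- max(0, (msb - msw) / n0)
  structure(list(sigma2_B = s2b, sigma2_W = msw, n_pops = k,
                 group_sizes = as.integer(n_i), ms_between = msb,
                 ms_within = msw),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("variance components: sigma2_B = %.4g, sigma2_W = %.4g (%d pops, n = %s)\n",
              x$sigma2_B, x$sigma2_W, x$n_pops,
              paste(x$group_sizes, collapse = "/")))
  invisible(x)
}

#' Phenotypic differentiation P_ST
#'
#' `P_ST = sigma2_B / (sigma2_B + 2 * sigma2_W)`, the phenotypic analogue of
#' Q_ST (assuming fully additive, fully heritable variation).
#'
#' @param sigma2_B between-population variance, or a
#'   [variance_components()] object (then `sigma2_W` is taken from it).
#' @param sigma2_W within-population variance (> 0).
#' @return P_ST in `[0, 1)`.
#' @examples
#' pst(1, 1)  # 1/3
#' @export
pst <- function(sigma2_B, sigma2_W = NULL) {
  if (inherits(sigma2_B, "variance_components")) {
    vc <- sigma2_B
    sigma2_B <- vc$sigma2_B
    sigma2_W <- vc$sigma2_W
  }
  if (is.null(sigma2_W) || any(sigma2_W <= 0)) stop("`sigma2_W` must be > 0")
  if (any(sigma2_B < 0)) stop("`sigma2_B` must be >= 0")
  sigma2_B / (sigma2_B + 2 * sigma2_W)
}

#' Neutral between-population variance at a given F_ST
#'
#' The neutral-drift expectation `sigma2_B = 2 * F_ST * sigma2_W /
#' (1 - F_ST)`; the sigma2_B at which P_ST equals F_ST.
#'
#' @param fst neutral differentiation in (0, 1).
#' @param sigma2_W within-population variance.
#' @return The neutral between-population variance (trait units squared).
#' @examples
#' neutral_sigma2b(1/3, 3)  # 3
#' @export
neutral_sigma2b <- function(fst, sigma2_W) {
  stop_if_not_prob(fst, "fst")
  2 * fst * sigma2_W / (1 - fst)
}

#' Build the chi-square scaled neutral null for P_ST - F_ST
#'
#' Simulates the sampling distribution of a neutral `P_ST - F_ST`: each draw
#' scales the neutral between-population variance by an independent
#' `chisq(df) / df` factor (so the scaled variance has the neutral
#' expectation) and converts it to `P_ST - fst`. `df` is the number of
#' phenotyped populations minus one. With `scale_by_df = FALSE` the raw
#' chi-square multiplier is used instead (sensitivity variant).
#'
#' @param fst neutral F_ST in (0, 1).
#' @param sigma2_W within-population variance (> 0).
#' @param df chi-square degrees of freedom (>= 1).
#' @param n_draws number of draws (>= 1000; default 10000).
#' @param seed RNG seed.
#' @param scale_by_df divide the chi-square draw by `df` (default) so that
#'   the null variance is unbiased.
#' @return An object of class `neutral_null`: `list(draws, n_draws, df,
#'   fst, sigma2_W, seed, scale_by_df)`.
#' @export
build_neutral_null <- function(fst, sigma2_W = 1, df = 6, n_draws = 10000,
                               seed = NULL, scale_by_df = TRUE) {
  stop_if_not_prob(fst, "fst")
  if (sigma2_W <= 0) stop("`sigma2_W` must be > 0")
  if (df < 1) stop("`df` must be >= 1")
  if (n_draws < 1000) stop("`n_draws` must be >= 1000")
  s2b0 <- neutral_sigma2b(fst, sigma2_W)
  draws <- with_seed(seed, {
    mult <- rchisq(n_draws, df = df)
    if (scale_by_df) mult <- mult / df
    pst(mult * s2b0, sigma2_W) - fst
  })
  structure(list(draws = draws, n_draws = n_draws, df = df, fst = fst,
                 sigma2_W = sigma2_W, seed = seed, scale_by_df = scale_by_df),
            class = "neutral_null")
}

#' @export
print.neutral_null <- function(x, ...) {
  cat(sprintf(
    "neutral P_ST - F_ST null: %d draws, df = %d, fst = %.3f (median %.4f)\n",
    x$n_draws, x$df, x$fst, median(x$draws)))
  invisible(x)
}

#' Selection p-value against the neutral null
#'
#' Compares an observed P_ST (or F_STQ) with the neutral distribution:
#' `p = #(draws >= observed - fst) / n_draws`, the upper-tail quantile of
#' the null lying beyond the observed divergence. A p of exactly 0 (no draw
#' beyond the observation) is reported verbatim and is the signature of
#' selection; resolution is `1 / n_draws`.
#'
#' @param observed observed P_ST or F_STQ (in `[0, 1)`).
#' @param null a [build_neutral_null()] object.
#' @param fst the neutral F_ST; must match the null's.
#' @param mode `"phenotype"` or `"qtl"`, recorded in the result.
#' @return An object of class `selection_test`: `list(pst, observed_diff,
#'   p, mode, n_draws)`.
#' @export
selection_pvalue <- function(observed, null, fst = null$fst,
                             mode = c("phenotype", "qtl")) {
  stopifnot(inherits(null, "neutral_null"))
  mode <- match.arg(mode)
  if (abs(fst - null$fst) > 1e-12) {
    stop("`fst` does not match the null's fst (", null$fst, ")")
  }
  if (observed < 0 || observed >= 1) stop("`observed` must be in [0, 1)")
  diff <- observed - fst
  p <- sum(null$draws >= diff) / null$n_draws
  structure(list(pst = observed, observed_diff = diff, p = p, mode = mode,
                 n_draws = null$n_draws),
            class = "selection_test")
}

#' @export
print.selection_test <- function(x, ...) {
  cat(sprintf("%s divergence: %.3f (observed - F_ST = %+.3f), p = %s\n",
              if (x$mode == "qtl") "F_STQ" else "P_ST",
              x$pst, x$observed_diff,
              if (x$p == 0) sprintf("0 (< %.4g)", 1 / x$n_draws)
              else format(x$p)))
  invisible(x)
}

#' P_ST - F_ST selection test
#'
#' The package's central fit: estimates variance components for a trait
#' with population as a random effect ([variance_components()]), converts
#' them to P_ST, builds the chi-square scaled neutral null at the supplied
#' neutral F_ST and returns the upper-tail p-value. Under no selection the
#' observed P_ST sits inside the null (`p > 0`); selection is evidenced as
#' the observation escaping the null (`p = 0`).
#'
#' @param formula `trait ~ population`, evaluated in `data`.
#' @param data data frame holding the trait and population columns.
#' @param fst neutral F_ST in (0, 1), typically a multilocus
#'   Weir-Cockerham estimate from non-genic SNPs ([wc_fst()]).
#' @param df chi-square degrees of freedom; defaults to the number of
#'   populations minus one.
#' @param n_draws null draws (default 10000).
#' @param seed RNG seed for the null.
#' @param scale_by_df see [build_neutral_null()].
#' @return An object of class `pst_fst`: the [variance_components()], the
#'   P_ST, the [build_neutral_null()] object and the `selection_test`
#'   result, with `print` and `summary` methods.
#' @examples
#' ph <- simulate_neutral_phenotype(rep(30, 7), fst = 0.1, seed = 2)
#' fit <- pst_fst(trait ~ deme, ph, fst = 0.1, seed = 3)
#' fit
#' @export
pst_fst <- function(formula, data, fst, df = NULL, n_draws = 10000,
                    seed = NULL, scale_by_df = TRUE) {
  mf <- model.frame(formula, data)
  if (ncol(mf) != 2) stop("formula must be of the form trait ~ population")
  vc <- variance_components(mf[[1]], mf[[2]])
  if (is.null(df)) df <- vc$n_pops - 1L
  null <- build_neutral_null(fst, vc$sigma2_W, df = df, n_draws = n_draws,
                             seed = seed, scale_by_df = scale_by_df)
  test <- selection_pvalue(pst(vc), null, fst)
  structure(list(call = match.call(), vc = vc, pst = test$pst, fst = fst,
                 null = null, test = test),
            class = "pst_fst")
}

#' @export
print.pst_fst <- function(x, ...) {
  cat("P_ST-F_ST selection test\n")
  cat(sprintf("  P_ST = %.3f, neutral F_ST = %.3f, P_ST - F_ST = %+.3f\n",
              x$pst, x$fst, x$test$observed_diff))
  cat(sprintf("  null: %d draws, chi-square df = %d\n",
              x$null$n_draws, x$null$df))
  cat(sprintf("  p = %s\n",
              if (x$test$p == 0) sprintf("0 (< %.4g)", 1 / x$null$n_draws)
              else format(x$test$p)))
  invisible(x)
}

#' @export
summary.pst_fst <- function(object, ...) {
  q <- quantile(object$null$draws, c(0.025, 0.5, 0.975))
  cat("P_ST-F_ST selection test\n\n")
  print(object$vc)
  cat(sprintf("P_ST            : %.4f\n", object$pst))
  cat(sprintf("neutral F_ST    : %.4f\n", object$fst))
  cat(sprintf("observed - F_ST : %+.4f\n", object$test$observed_diff))
  cat(sprintf("null 2.5/50/97.5%%: %+.4f / %+.4f / %+.4f (df = %d)\n",
              q[1], q[2], q[3], object$null$df))
  cat(sprintf("one-sided p     : %s\n",
              if (object$test$p == 0)
                sprintf("0 (< %.4g)", 1 / object$null$n_draws)
              else format(object$test$p)))
  invisible(object)
}

#' F_ST at a single quantitative-trait locus (F_STQ)
#'
#' Recodes diallelic CC/CL/LL genotypes (e.g. the Stn382 marker linked to
#' Eda) as L-allele dosages and runs the Weir-Cockerham estimator on the
#' single locus, so F_STQ is directly comparable with genome-wide theta.
#'
#' @param genotypes character vector of `"CC"`, `"CL"`, `"LL"` (NA allowed).
#' @param deme deme label per individual.
#' @param pairwise if `TRUE`, return the pairwise [labeled_matrix()]
#'   instead of the global estimate.
#' @return Global theta (numeric), or a pairwise matrix.
#' @examples
#' fstq(c("CC", "CC", "LL", "LL"), c("a", "a", "b", "b"))  # 1
#' @export
fstq <- function(genotypes, deme, pairwise = FALSE) {
  bad <- !is.na(genotypes) & !(genotypes %in% c("CC", "CL", "LL"))
  if (any(bad)) stop("genotypes must be CC, CL or LL")
  dosage <- c(CC = 0L, CL = 1L, LL = 2L)[genotypes]
  g <- genotype_matrix(matrix(dosage, ncol = 1,
                              dimnames = list(NULL, "stn382")),
                       deme = deme)
  alt <- sum(dosage, na.rm = TRUE)
  n_called <- sum(!is.na(dosage))
  if (n_called == 0 || alt == 0 || alt == 2 * n_called) {
    stop("locus is monomorphic across all demes; F_STQ undefined")
  }
  if (pairwise) pairwise_fst(g) else wc_fst(g)$theta
}
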