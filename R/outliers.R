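# POD-calibrated per-locus differentiation outlier scans and the
# marine-freshwater contrast comparison.

#' POD-calibrated F_ST outlier scan
#'
#' Scans per-locus Weir-Cockerham theta against an empirical threshold
#' calibrated on a pseudo-observed data set (POD): neutral genotypes are
#' simulated under the Balding-Nichols island model with the drift parameter
#' set to the observed multilocus theta, the observed deme sizes and
#' missingness, and ancestral frequencies resampled from the observed
#' pooled allele-frequency spectrum. The threshold is the requested quantile
#' of the POD per-locus theta distribution; loci with observed theta above
#' it are flagged.
#'
#' @param g a [genotype_matrix()] with at least two demes.
#' @param n_pod_loci number of neutral POD loci to simulate.
#' @param quantile_level POD quantile defining the threshold, in (0.5, 1).
#' @param seed RNG seed (fixed seed gives identical flags).
#' @return An object of class `outlier_scan`: `list(stat, threshold,
#'   quantile, flags, pod_stat, theta_hat, pod_seed)`, with `stat` the named
#'   per-locus theta and `flags` the flagged locus ids.
#' @examples
#' g <- sim_island(sim_config(n_demes = 4, n_loci = 300, fst = 0.05, seed = 5))
#' pod_scan(g, n_pod_loci = 500, seed = 6)
#' @export
pod_scan <- function(g, n_pod_loci = 1000, quantile_level = 0.99,
                     seed = NULL) {
  if (quantile_level <= 0.5 || quantile_level >= 1) {
    stop("`quantile_level` must be in (0.5, 1)")
  }
  if (nlevels(g$deme) < 2) stop("need at least two demes")
  obs <- wc_fst(g)
  theta_hat <- min(max(obs$theta, 1e-4), 0.99)
  pooled <- pooled_locus_stats(g)
  anc_pool <- pooled$maf[!is.na(pooled$maf) & pooled$maf > 0]
  anc_pool <- pmin(pmax(anc_pool, 0.01), 0.5)
  if (!length(anc_pool)) anc_pool <- c(0.1, 0.25, 0.4)
  sizes <- as.integer(table(g$deme))
  miss <- mean(is.na(g$calls))
  pod_theta <- with_seed(seed, {
    p <- sample(anc_pool, n_pod_loci, replace = TRUE)
    freqs <- t(vapply(seq_along(sizes),
                      function(d) bn_draw(p, theta_hat),
                      numeric(n_pod_loci)))
    rownames(freqs) <- levels(g$deme)
    pod <- simulate_genotypes(freqs, sizes, missing_rate = miss)
    wc_fst(pod)$per_locus
  })
  pod_theta <- pod_theta[!is.na(pod_theta)]
  threshold <- unname(quantile(pod_theta, quantile_level))
  stat <- obs$per_locus
  flags <- names(stat)[!is.na(stat) & stat > threshold]
  structure(list(stat = stat, threshold = threshold,
                 quantile = quantile_level, flags = flags,
                 pod_stat = pod_theta, theta_hat = theta_hat,
                 pod_seed = seed),
            class = "outlier_scan")
}

#' @export
print.outlier_scan <- function(x, ...) {
  n <- sum(!is.na(x$stat))
  cat(sprintf(
    "POD outlier scan: %d / %d loci above the %.1f%% threshold (%.4f; multilocus theta %.4f)\n",
    length(x$flags), n, 100 * x$quantile, x$threshold, x$theta_hat))
  invisible(x)
}

#' Marine-freshwater outlier contrasts
#'
#' Runs a pair-specific [pod_scan()] for every (marine deme, freshwater
#' deme) pair over the harmonised locus set (loci with an informative theta
#' in every contrast), and tabulates how consistently each locus is flagged
#' across contrasts.
#'
#' @param g a [genotype_matrix()].
#' @param freshwater the derived (freshwater) deme label.
#' @param marine marine deme labels; defaults to all other demes.
#' @param n_pod_loci,quantile_level,seed passed to [pod_scan()] (each
#'   contrast gets a seed derived from `seed`).
#' @return An object of class `contrast_table`: `list(theta, flags,
#'   thresholds, n_flagged, histogram)` where `theta` and `flags` are
#'   loci x contrast matrices, `n_flagged` counts the contrasts flagging
#'   each locus and `histogram` tabulates loci flagged in exactly k of K
#'   contrasts.
#' @export
contrast_outliers <- function(g, freshwater, marine = NULL,
                              n_pod_loci = 1000, quantile_level = 0.99,
                              seed = NULL) {
  if (!freshwater %in% levels(g$deme)) {
    stop("freshwater deme not present: ", freshwater)
  }
  if (is.null(marine)) marine <- setdiff(levels(g$deme), freshwater)
  if (length(marine) == 0) stop("no marine demes to contrast against")
  if (freshwater %in% marine) {
    stop("freshwater deme must be distinct from the marine demes")
  }
  pair_theta <- lapply(marine, function(m) {
    wc_fst(g, demes = c(m, freshwater))$per_locus
  })
  informative <- Reduce(`&`, lapply(pair_theta, function(v) !is.na(v)))
  loci <- g$locus_ids[informative]
  if (!length(loci)) stop("no locus informative in every contrast")
  scans <- lapply(seq_along(marine), function(i) {
    sub <- g[g$deme %in% c(marine[i], freshwater), loci]
    pod_scan(sub, n_pod_loci = n_pod_loci,
             quantile_level = quantile_level,
             seed = derive_seed(seed, i))
  })
  theta <- vapply(scans, function(s) s$stat[loci], numeric(length(loci)))
  flags <- vapply(scans, function(s) loci %in% s$flags, logical(length(loci)))
  dimnames(theta) <- dimnames(flags) <- list(loci, marine)
  n_flagged <- rowSums(flags)
  hist_tab <- table(factor(n_flagged[n_flagged > 0],
                           levels = seq_along(marine)))
  structure(list(theta = theta, flags = flags,
                 thresholds = setNames(vapply(scans, `[[`, 0, "threshold"),
                                       marine),
                 n_flagged = n_flagged, histogram = hist_tab),
            class = "contrast_table")
}

#' @export
print.contrast_table <- function(x, ...) {
  K <- ncol(x$flags)
  any_f <- sum(x$n_flagged > 0)
  cat(sprintf("marine-freshwater contrasts: %d loci x %d contrasts\n",
              nrow(x$theta), K))
  cat(sprintf("  %d loci flagged in >= 1 contrast; %d in all %d\n",
              any_f, sum(x$n_flagged == K), K))
  invisible(x)
}

#' Discordant loci across contrasts
#'
#' A locus is discordant when its per-locus F_ST shows little
#' differentiation (below `low`) in at least one contrast but great
#' differentiation (above `high`) in another. Also reports the per-locus
#' F_ST range (max - min across contrasts): its maximum and its mean over
#' all loci.
#'
#' @param x a [contrast_outliers()] result or a loci x contrasts numeric
#'   matrix of per-locus F_ST (at least two contrasts).
#' @param low,high the discordance thresholds (defaults 0.05 and 0.25).
#' @return `list(count, loci, max_range, mean_range)`.
#' @examples
#' m <- rbind(L1 = c(0.02, 0.60), L2 = c(0.10, 0.20))
#' discordant_loci(m)  # L1 discordant, range 0.58
#' @export
discordant_loci <- function(x, low = 0.05, high = 0.25) {
  m <- if (inherits(x, "contrast_table")) x$theta else as.matrix(x)
  if (ncol(m) < 2) stop("need at least two contrasts")
  lo <- apply(m, 1, min, na.rm = TRUE)
  hi <- apply(m, 1, max, na.rm = TRUE)
  disc <- lo < low & hi > high
  rng <- hi - lo
  list(count = sum(disc),
       loci = rownames(m)[disc] %||% which(disc),
       max_range = max(rng),
       mean_range = mean(rng))
}
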