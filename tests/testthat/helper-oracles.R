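# Independent oracles and small fixture builders used across the suite.

# Quick genotype_matrix from a plain matrix (rows = individuals).
make_g <- function(calls, deme, ...) {
  genotype_matrix(as.matrix(calls), deme = deme, ...)
}

# Direct scalar evaluation of the Weir & Cockerham (1984) variance
# components a, b, c for a single biallelic locus: an explicit per-deme
# loop kept deliberately separate from the package's vectorised code path.
wc_direct <- function(calls, deme) {
  idx <- split(seq_along(calls), deme)
  idx <- lapply(idx, function(i) i[!is.na(calls[i])])
  idx <- idx[vapply(idx, length, 0L) > 0]
  r <- length(idx)
  if (r < 2) return(c(a = NA, b = NA, c = NA))
  n <- vapply(idx, length, 0L)
  p <- vapply(idx, function(i) sum(calls[i]) / (2 * length(i)), 0)
  h <- vapply(idx, function(i) mean(calls[i] == 1L), 0)
  nbar <- mean(n)
  if (nbar <= 1) return(c(a = NA, b = NA, c = NA))
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c(a = a, b = b, c = hbar / 2)
}

# Brute-force per-deme summary by exhaustive enumeration over loci.
summary_oracle <- function(calls, deme, target) {
  demes <- unique(deme)
  private <- 0L
  poly <- 0L
  n_var <- 0L
  for (j in seq_len(ncol(calls))) {
    x <- calls[deme == target, j]
    x <- x[!is.na(x)]
    if (!length(x)) next
    n_var <- n_var + 1L
    here <- character(0)
    if (any(x > 0)) here <- c(here, "alt")
    if (any(x < 2)) here <- c(here, "ref")
    if (length(here) == 2) poly <- poly + 1L
    for (al in here) {
      seen_elsewhere <- FALSE
      for (d in setdiff(demes, target)) {
        y <- calls[deme == d, j]
        y <- y[!is.na(y)]
        if (al == "alt" && any(y > 0)) seen_elsewhere <- TRUE
        if (al == "ref" && any(y < 2)) seen_elsewhere <- TRUE
      }
      if (!seen_elsewhere) private <- private + 1L
    }
  }
  list(private = private, pct_polymorphic = 100 * poly / n_var,
       n_loci = n_var)
}

# Neutral island-model loci plus a block of loci fixed for alternative
# alleles between the first deme and the rest (planted outliers).
planted_g <- function(n_demes = 2, n_per = 25, n_neutral = 50, n_out = 5,
                      fst = 0.05, seed = 1) {
  cfg <- sim_config(n_demes = n_demes, n_per_deme = n_per,
                    n_loci = n_neutral, fst = fst, seed = seed)
  g <- sim_island(cfg)
  out <- matrix(0L, nrow(g$calls), n_out)
  out[g$deme == levels(g$deme)[1], ] <- 2L
  genotype_matrix(cbind(g$calls, out), deme = g$deme,
                  locus_ids = c(g$locus_ids, paste0("planted", seq_len(n_out))))
}

# Per-locus a, b, c through the package's vectorised internals.
wc_fst_components_for_test <- function(g) {
  af <- stickpop:::deme_allele_freqs(g)
  stickpop:::wc_components(af$freq, af$n, stickpop:::deme_het_counts(g))
}

# Brute-force discordance rule over a loci x contrasts matrix.
discordance_oracle <- function(m, low = 0.05, high = 0.25) {
  disc <- logical(nrow(m))
  rng <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    disc[i] <- min(v) < low && max(v) > high
    rng[i] <- max(v) - min(v)
  }
  list(count = sum(disc), max_range = max(rng), mean_range = mean(rng))
}
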