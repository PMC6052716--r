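#' Configuration for the island-model genotype simulator
#'
#' Describes a Balding-Nichols island model: each deme's allele frequency at
#' a locus is drawn `Beta(p(1-F)/F, (1-p)(1-F)/F)` around an ancestral
#' frequency `p`, so the drift parameter `F` equals the expected
#' Weir-Cockerham F_ST between demes -- which makes parameter recovery a
#' direct acceptance surface. Hierarchical structure (the "clusters of demes"
#' pattern seen along the NE Pacific coast) is produced by a two-stage draw:
#' ancestral -> cluster frequency at `f_between`, then cluster -> deme at the
#' member demes' `fst`.
#'
#' The defaults emulate the study system the package targets: 8 marine demes
#' of 30 diploids, 2000 biallelic SNPs, ancestral minor-allele frequencies
#' uniform on (0.05, 0.5), drift parameter 0.10 (the middle of the 0.02-0.18
#' pairwise range typical of structured marine stickleback).
#'
#' @param n_demes number of demes (>= 2).
#' @param n_per_deme diploid individuals per deme; scalar or length `n_demes`.
#' @param n_loci number of biallelic loci.
#' @param fst per-deme drift parameter in (0, 1); scalar or length `n_demes`.
#' @param clusters optional hierarchical structure: a list of
#'   `list(members = <deme indices>, f_between = <cluster-level F>)`; demes
#'   in a cluster first share a cluster frequency drawn at `f_between`, then
#'   drift from it at their own `fst`. Demes not named in any cluster drift
#'   straight from the ancestral frequency.
#' @param maf_range range of the uniform ancestral allele-frequency
#'   distribution.
#' @param missing_rate fraction of calls set missing uniformly at random,
#'   in `[0, 1)`.
#' @param freshwater optional derived-deme block exercising the outlier scan:
#'   `list(n = <size>, fst = <drift F, typically 0.18-0.27>,
#'   n_adaptive = <count>, adaptive_freq = <near-1 frequency>)`. The extra
#'   deme drifts at the larger `fst`, and at `n_adaptive` randomly chosen
#'   loci its frequency of the *minor marine* allele is forced to
#'   `adaptive_freq` (near fixation), mimicking freshwater-adaptive loci.
#' @param seed RNG seed; identical configuration and seed give bit-identical
#'   output.
#' @return A list of class `sim_config`.
#' @seealso [simulate_deme_freqs()], [sim_island()]
#' @export
sim_config <- function(n_demes = 8, n_per_deme = 30, n_loci = 2000,
                       fst = 0.10, clusters = NULL,
                       maf_range = c(0.05, 0.5), missing_rate = 0,
                       freshwater = NULL, seed = NULL) {
  if (n_demes < 2) stop("`n_demes` must be >= 2")
  n_per_deme <- rep_len(as.integer(n_per_deme), n_demes)
  fst <- rep_len(as.double(fst), n_demes)
  stop_if_not_prob(fst, "fst")
  if (missing_rate < 0 || missing_rate >= 1) stop("`missing_rate` must be in [0, 1)")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] >= 1 ||
      maf_range[1] > maf_range[2]) {
    stop("`maf_range` must be an increasing pair inside (0, 1)")
  }
  if (!is.null(clusters)) {
    for (cl in clusters) {
      if (is.null(cl$members) || is.null(cl$f_between))
        stop("each cluster needs `members` and `f_between`")
      stop_if_not_prob(cl$f_between, "f_between")
      if (any(cl$members < 1 | cl$members > n_demes))
        stop("cluster members out of range")
    }
    if (anyDuplicated(unlist(lapply(clusters, `[[`, "members"))))
      stop("a deme may belong to at most one cluster")
  }
  if (!is.null(freshwater)) {
    freshwater$n <- as.integer(freshwater$n %||% 15L)
    freshwater$fst <- freshwater$fst %||% 0.22
    stop_if_not_prob(freshwater$fst, "freshwater$fst")
    freshwater$n_adaptive <- as.integer(freshwater$n_adaptive %||% 5L)
    freshwater$adaptive_freq <- freshwater$adaptive_freq %||% 0.98
    stop_if_not_prob(freshwater$adaptive_freq, "freshwater$adaptive_freq")
  }
  structure(list(n_demes = n_demes, n_per_deme = n_per_deme, n_loci = n_loci,
                 fst = fst, clusters = clusters, maf_range = maf_range,
                 missing_rate = missing_rate, freshwater = freshwater,
                 seed = seed),
            class = "sim_config")
}

# One Balding-Nichols draw of length n around frequencies p at drift F.
bn_draw <- function(p, f) {
  stop_if_not_prob(f, "F")
  rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

#' Simulate per-deme allele frequencies under the island model
#'
#' @param cfg a [sim_config()].
#' @return A `n_demes x n_loci` matrix of alternate-allele frequencies with
#'   deme row names, the ancestral frequencies in attribute `ancestral_p`,
#'   and (when `cfg$freshwater` is set) the freshwater deme appended as the
#'   last row with its forced loci in attribute `adaptive_loci`.
#' @examples
#' f <- simulate_deme_freqs(sim_config(n_demes = 4, n_loci = 50, seed = 1))
#' dim(f)
#' @export
simulate_deme_freqs <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    p <- runif(cfg$n_loci, cfg$maf_range[1], cfg$maf_range[2])
    base <- matrix(rep(p, each = cfg$n_demes), nrow = cfg$n_demes)
    if (!is.null(cfg$clusters)) {
      for (cl in cfg$clusters) {
        clp <- bn_draw(p, cl$f_between)
        for (d in cl$members) base[d, ] <- clp
      }
    }
    freqs <- matrix(NA_real_, cfg$n_demes, cfg$n_loci,
                    dimnames = list(paste0("deme", seq_len(cfg$n_demes)), NULL))
    for (d in seq_len(cfg$n_demes)) freqs[d, ] <- bn_draw(base[d, ], cfg$fst[d])
    attr(freqs, "ancestral_p") <- p
    if (!is.null(cfg$freshwater)) {
      fw <- bn_draw(p, cfg$freshwater$fst)
      adaptive <- sort(sample.int(cfg$n_loci, cfg$freshwater$n_adaptive))
      marine_mean <- colMeans(freqs)
      # push the freshwater deme to near-fixation for the minor marine allele
      fw[adaptive] <- ifelse(marine_mean[adaptive] <= 0.5,
                             cfg$freshwater$adaptive_freq,
                             1 - cfg$freshwater$adaptive_freq)
      freqs <- rbind(freqs, freshwater = fw)
      attr(freqs, "ancestral_p") <- p
      attr(freqs, "adaptive_loci") <- adaptive
    }
    freqs
  })
}

#' Simulate diploid genotypes from deme allele frequencies
#'
#' Each individual's dosage at each locus is Binomial(2, deme frequency);
#' missing calls are placed uniformly at random.
#'
#' @param freqs demes x loci frequency matrix (rows named by deme).
#' @param deme_sizes individuals per deme; scalar or one per row of `freqs`.
#' @param missing_rate fraction of calls set to `NA`, in `[0, 1)`.
#' @param seed RNG seed.
#' @param locus_ids optional locus identifiers; defaults to a `chrN:pos`
#'   scheme so VCF round trips preserve them.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(freqs, deme_sizes, missing_rate = 0,
                               seed = NULL, locus_ids = NULL) {
  freqs <- as.matrix(freqs)
  if (any(freqs < 0 | freqs > 1, na.rm = TRUE))
    stop("frequencies must lie in [0, 1]")
  k <- nrow(freqs)
  deme_sizes <- rep_len(as.integer(deme_sizes), k)
  if (missing_rate < 0 || missing_rate >= 1) stop("`missing_rate` must be in [0, 1)")
  demes <- rownames(freqs) %||% paste0("deme", seq_len(k))
  n_loci <- ncol(freqs)
  if (is.null(locus_ids)) {
    chrom <- ((seq_len(n_loci) - 1L) %% 21L) + 1L
    locus_ids <- sprintf("chr%02d:%d", chrom, 1000L * seq_len(n_loci))
  }
  with_seed(seed, {
    calls <- matrix(NA_integer_, sum(deme_sizes), n_loci)
    row0 <- 0L
    for (d in seq_len(k)) {
      nd <- deme_sizes[d]
      calls[row0 + seq_len(nd), ] <-
        matrix(rbinom(nd * n_loci, 2L, rep(freqs[d, ], each = nd)), nd)
      row0 <- row0 + nd
    }
    if (missing_rate > 0) {
      calls[runif(length(calls)) < missing_rate] <- NA_integer_
    }
    genotype_matrix(calls, deme = rep(demes, deme_sizes),
                    locus_ids = locus_ids,
                    ids = paste0(rep(demes, deme_sizes), "_",
                                 unlist(lapply(deme_sizes, seq_len))))
  })
}

#' Simulate a full island-model genotype data set
#'
#' Convenience wrapper: draws deme frequencies with [simulate_deme_freqs()]
#' then genotypes with [simulate_genotypes()], carrying the freshwater
#' adaptive loci (if configured) through as an attribute.
#'
#' @inheritParams simulate_deme_freqs
#' @return A [genotype_matrix()]; attribute `adaptive_loci` holds the locus
#'   ids of any forced freshwater-adaptive loci.
#' @export
sim_island <- function(cfg) {
  freqs <- simulate_deme_freqs(cfg)
  sizes <- cfg$n_per_deme
  if (!is.null(cfg$freshwater)) sizes <- c(sizes, cfg$freshwater$n)
  g <- simulate_genotypes(freqs, sizes, missing_rate = cfg$missing_rate,
                          seed = derive_seed(cfg$seed %||% NULL, 1))
  if (!is.null(attr(freqs, "adaptive_loci"))) {
    attr(g, "adaptive_loci") <- g$locus_ids[attr(freqs, "adaptive_loci")]
  }
  g
}

#' Simulate a neutrally diverging quantitative trait
#'
#' Generates trait values whose between-deme variance equals the neutral
#' expectation at a given F_ST: deme means are
#' `Normal(0, 2 * fst * sigma2_W / (1 - fst))` and individuals scatter
#' around their deme mean with variance `sigma2_W`. Used to calibrate the
#' type-I error of the P_ST-F_ST test.
#'
#' @param deme_sizes individuals per deme (length = number of demes).
#' @param fst neutral differentiation in (0, 1).
#' @param sigma2_W within-deme trait variance (> 0).
#' @param seed RNG seed.
#' @return A data frame with columns `id`, `deme`, `trait`; the generating
#'   between-deme variance is attached as attribute `sigma2_B`.
#' @examples
#' ph <- simulate_neutral_phenotype(rep(30, 7), fst = 0.1, seed = 1)
#' attr(ph, "sigma2_B")  # 2 * 0.1 * 1 / 0.9
#' @export
simulate_neutral_phenotype <- function(deme_sizes, fst, sigma2_W = 1,
                                       seed = NULL) {
  stop_if_not_prob(fst, "fst")
  if (sigma2_W <= 0) stop("`sigma2_W` must be > 0")
  k <- length(deme_sizes)
  if (k < 2) stop("need at least two demes")
  s2b <- 2 * fst * sigma2_W / (1 - fst)
  with_seed(seed, {
    mu <- rnorm(k, 0, sqrt(s2b))
    deme <- rep(paste0("deme", seq_len(k)), deme_sizes)
    trait <- rnorm(sum(deme_sizes), rep(mu, deme_sizes), sqrt(sigma2_W))
    out <- data.frame(id = paste0(deme, "_", unlist(lapply(deme_sizes, seq_len))),
                      deme = deme, trait = trait,
                      stringsAsFactors = FALSE)
    attr(out, "sigma2_B") <- s2b
    out
  })
}

#' Simulate Eda-linked plate phenotypes
#'
#' Draws Stn382 genotypes in Hardy-Weinberg proportions at each deme's
#' low-plated (L) allele frequency, then plate counts Poisson-distributed
#' around a genotype-specific mean, with a keel flag for the keeled genotype
#' classes. Mirrors the marine pattern of plate number decreasing with the
#' number of L alleles.
#'
#' @param deme_sizes individuals per deme; names (if any) become deme labels.
#' @param eda_freqs per-deme frequency of the L allele, in `[0, 1]`.
#' @param plate_means named mean total plate count per genotype
#'   (`CC`, `CL`, `LL`); must be non-negative.
#' @param keeled named logical: whether each genotype class carries a caudal
#'   keel.
#' @param keel_mean mean keel-plate count for keeled fish.
#' @param seed RNG seed.
#' @return A data frame with columns `id`, `deme`, `stn382`,
#'   `plates_anterior`, `plates_keel`, `plates_total`.
#' @export
simulate_eda_plates <- function(deme_sizes, eda_freqs,
                                plate_means = c(CC = 62, CL = 45, LL = 8),
                                keeled = c(CC = TRUE, CL = TRUE, LL = FALSE),
                                keel_mean = 4, seed = NULL) {
  k <- length(deme_sizes)
  eda_freqs <- rep_len(eda_freqs, k)
  stop_if_not_prob(eda_freqs, "eda_freqs", open = FALSE)
  if (any(plate_means < 0)) stop("plate means must be non-negative")
  stopifnot(all(c("CC", "CL", "LL") %in% names(plate_means)),
            all(c("CC", "CL", "LL") %in% names(keeled)))
  demes <- names(deme_sizes) %||% paste0("deme", seq_len(k))
  with_seed(seed, {
    rows <- lapply(seq_len(k), function(d) {
      n <- deme_sizes[d]
      f <- eda_freqs[d]                     # L-allele frequency
      gt <- c("CC", "CL", "LL")[1L + rbinom(n, 2L, f)]
      total <- rpois(n, plate_means[gt])
      has_keel <- keeled[gt]
      keel <- ifelse(has_keel, pmin(total, 1L + rpois(n, keel_mean)), 0L)
      data.frame(id = paste0(demes[d], "_", seq_len(n)), deme = demes[d],
                 stn382 = gt, plates_anterior = total - keel,
                 plates_keel = keel, plates_total = total,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
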