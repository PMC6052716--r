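# End-to-end pipeline: simulate -> filter -> summaries/F_ST -> IBD ->
# P_ST-F_ST -> outlier scan -> marine-freshwater contrasts, with
# reproducible per-stage seeds and file outputs.

#' Default demonstration pipeline configuration
#'
#' A compact configuration exercising every stage on simulated data plus
#' the packaged coastal fixture matrices for the isolation-by-distance
#' stage. All stage seeds are derived deterministically from `seed`, so a
#' rerun with the same configuration is byte-identical.
#'
#' @param seed global seed.
#' @return A nested configuration list understood by [run_pipeline()].
#' @export
demo_config <- function(seed = 1) {
  list(
    seed = seed,
    simulate = list(n_demes = 6, n_per_deme = 25, n_loci = 400, fst = 0.08,
                    missing_rate = 0.05,
                    freshwater = list(n = 15, fst = 0.22, n_adaptive = 5,
                                      adaptive_freq = 0.98)),
    filters = list(min_ind_fraction = 0.75, min_pops = 4, min_maf = 0.02,
                   min_fis = -0.3),
    phenotype = list(sigma2_W = 1, fst = 0.08,
                     eda_freqs = c(0.6, 0.5, 0.4, 0.2, 0.05, 0)),
    pstfst = list(n_draws = 10000),
    ibd = list(use_packaged = TRUE, exclusions = list(character(0), "AK01"),
               n_perm = 999),
    outliers = list(quantile_level = 0.99, n_pod_loci = 1000)
  )
}

#' Run the full analysis pipeline
#'
#' Chains the package's stages in the order of the study design: simulate
#' (or load) genotypes, apply the filter cascade, per-deme summaries and
#' pairwise F_ST, Mantel isolation-by-distance, the P_ST-F_ST and
#' F_STQ-F_ST selection tests on a simulated neutral trait and Eda-linked
#' plates, a marine POD outlier scan, and (when a freshwater deme is
#' configured) marine-freshwater contrasts with the discordance summary.
#' Per-stage CSV/JSON outputs and a deterministic `report.json` are written
#' to `out_dir`.
#'
#' @param config a configuration list as from [demo_config()], or the path
#'   of a YAML file holding one. Instead of a `simulate` block, a
#'   `genotypes` entry may point to a genotype CSV ([read_genotypes_csv()]).
#' @param out_dir output directory (created if needed).
#' @return The report, invisibly: a nested list also written as
#'   `report.json`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("stickpop_run_")) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  seed <- config$seed %||% 1
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = seed)

  # stage 1: genotypes ------------------------------------------------------
  if (!is.null(config$genotypes)) {
    if (!file.exists(config$genotypes)) {
      stop("genotype file not found: ", config$genotypes)
    }
    g <- read_genotypes_csv(config$genotypes)
  } else {
    sc <- config$simulate %||% list()
    cfg <- sim_config(n_demes = sc$n_demes %||% 6,
                      n_per_deme = sc$n_per_deme %||% 25,
                      n_loci = sc$n_loci %||% 400,
                      fst = sc$fst %||% 0.08,
                      clusters = sc$clusters,
                      missing_rate = sc$missing_rate %||% 0,
                      freshwater = sc$freshwater,
                      seed = derive_seed(seed, 1))
    g <- sim_island(cfg)
    write_genotypes_csv(g, file.path(out_dir, "genotypes.csv"))
  }
  report$genotypes <- list(n_ind = nrow(g$calls), n_loci = ncol(g$calls),
                           demes = levels(g$deme))

  # stage 2: filter cascade -------------------------------------------------
  fc <- config$filters %||% list()
  filt <- apply_filters(g,
                        min_ind_fraction = fc$min_ind_fraction %||% 0.75,
                        min_pops = fc$min_pops %||% nlevels(g$deme) - 2,
                        min_maf = fc$min_maf %||% 0.02,
                        min_fis = fc$min_fis %||% -0.3)
  gf <- filt$genotypes
  write.csv(filt$rejected, file.path(out_dir, "filter_rejections.csv"),
            row.names = FALSE)
  report$filters <- list(n_kept = ncol(gf$calls),
                         n_rejected = nrow(filt$rejected))

  # stage 3: summaries and F_ST --------------------------------------------
  summ <- summarize_populations(gf)
  write.csv(summ, file.path(out_dir, "population_summary.csv"),
            row.names = FALSE)
  pw <- pairwise_fst(gf)
  write.csv(as.data.frame(unclass(pw)), file.path(out_dir, "pairwise_fst.csv"))
  global_theta <- wc_fst(gf)$theta
  report$popgen <- list(global_theta = global_theta,
                        pairwise_range = range(pw[lower.tri(pw)]))

  # stage 4: isolation by distance ------------------------------------------
  ibd_cfg <- config$ibd %||% list()
  if (isTRUE(ibd_cfg$use_packaged)) {
    fx <- load_coastal_fixture()
    ibd <- ibd_report(fx$distance, fx$fst,
                      exclusions = ibd_cfg$exclusions %||% list(character(0)),
                      n_perm = ibd_cfg$n_perm %||% 999,
                      seed = derive_seed(seed, 4))
    write.csv(ibd, file.path(out_dir, "ibd_report.csv"), row.names = FALSE)
    report$ibd <- lapply(seq_len(nrow(ibd)), function(i)
      list(excluded = ibd$excluded[i], r = ibd$r[i], p = ibd$p[i]))
  }

  # stage 5: selection on phenotypes ----------------------------------------
  pc <- config$phenotype %||% list()
  marine <- setdiff(levels(gf$deme), "freshwater")
  sizes <- as.integer(table(gf$deme)[marine])
  trait_fst <- pc$fst %||% global_theta
  ph <- simulate_neutral_phenotype(sizes, fst = trait_fst,
                                   sigma2_W = pc$sigma2_W %||% 1,
                                   seed = derive_seed(seed, 5))
  fit <- pst_fst(trait ~ deme, ph, fst = trait_fst,
                 n_draws = config$pstfst$n_draws %||% 10000,
                 seed = derive_seed(seed, 6))
  eda <- simulate_eda_plates(setNames(sizes, marine),
                             eda_freqs = rep_len(pc$eda_freqs %||% 0.3,
                                                 length(sizes)),
                             seed = derive_seed(seed, 7))
  write.csv(eda, file.path(out_dir, "phenotypes.csv"), row.names = FALSE)
  fq <- tryCatch(fstq(eda$stn382, eda$deme), error = function(e) NA_real_)
  report$pstfst <- list(pst = fit$pst, fst = trait_fst, p = fit$test$p,
                        sigma2_B = fit$vc$sigma2_B,
                        sigma2_W = fit$vc$sigma2_W, fstq = fq)
  if (!is.na(fq)) {
    fq_test <- selection_pvalue(fq, fit$null, trait_fst, mode = "qtl")
    report$pstfst$fstq_p <- fq_test$p
  }

  # stage 6: marine outlier scan --------------------------------------------
  oc <- config$outliers %||% list()
  g_marine <- gf[gf$deme %in% marine, ]
  scan <- pod_scan(g_marine, n_pod_loci = oc$n_pod_loci %||% 1000,
                   quantile_level = oc$quantile_level %||% 0.99,
                   seed = derive_seed(seed, 8))
  write.csv(data.frame(locus_id = names(scan$stat), theta = scan$stat,
                       flagged = names(scan$stat) %in% scan$flags,
                       row.names = NULL),
            file.path(out_dir, "outlier_scan.csv"), row.names = FALSE)
  report$outliers <- list(n_flagged = length(scan$flags),
                          threshold = scan$threshold)

  # stage 7: marine-freshwater contrasts ------------------------------------
  if ("freshwater" %in% levels(gf$deme)) {
    ct <- contrast_outliers(gf, "freshwater", marine,
                            n_pod_loci = oc$n_pod_loci %||% 1000,
                            quantile_level = oc$quantile_level %||% 0.99,
                            seed = derive_seed(seed, 9))
    disc <- discordant_loci(ct)
    report$contrasts <- list(
      n_loci = nrow(ct$theta),
      n_flagged_any = sum(ct$n_flagged > 0),
      n_flagged_all = sum(ct$n_flagged == ncol(ct$flags)),
      histogram = as.integer(ct$histogram),
      discordant = disc$count,
      max_range = disc$max_range,
      mean_range = disc$mean_range)
    write.csv(data.frame(locus_id = rownames(ct$theta), ct$theta,
                         n_flagged = ct$n_flagged, check.names = FALSE),
              file.path(out_dir, "contrast_outliers.csv"), row.names = FALSE)
  }

  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  writeLines(json, file.path(out_dir, "report.json"))
  invisible(report)
}
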