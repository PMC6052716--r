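# Lateral-plate morph classification and Stn382/Eda genotype handling.

plate_morph_levels <- c("LPNK", "PPK", "FPK", "LPK", "PPNK", "UNCLASSIFIED")

#' Classify lateral-plate morphs
#'
#' Assigns each fish to one of the five plate morphs from its anterior,
#' caudal-keel and total plate counts:
#' \describe{
#'   \item{FPK}{fully plated, keeled: total >= 60 (checked first).}
#'   \item{LPK}{low plated with keel: < 20 anterior plates, at least one
#'     keel plate, total < 60.}
#'   \item{LPNK}{low plated, no keel: < 20 anterior plates, no keel plate.}
#'   \item{PPK}{partially plated, keeled: 21-59 total plates with at least
#'     one keel plate and >= 20 anterior plates.}
#'   \item{PPNK}{partially plated, no keel: > 20 anterior plates, no keel
#'     plate.}
#' }
#' The published definitions leave a boundary gap -- exactly 20 anterior
#' plates with no keel (and, with a keel, a total of exactly 20) is covered
#' by neither the low-plated (`< 20`) nor the partially-plated (`> 20` /
#' `21-59`) rule. Rather than inventing a rule, such fish are returned as
#' `UNCLASSIFIED`.
#'
#' @param anterior,keel,total non-negative plate counts (vectorised);
#'   `total` must be >= `anterior`.
#' @return Factor with levels LPNK, PPK, FPK, LPK, PPNK, UNCLASSIFIED;
#'   exactly one class per fish.
#' @examples
#' classify_plate_morph(10, 0, 10)   # LPNK
#' classify_plate_morph(30, 2, 32)   # PPK
#' classify_plate_morph(58, 4, 62)   # FPK
#' @export
classify_plate_morph <- function(anterior, keel, total) {
  n <- max(length(anterior), length(keel), length(total))
  anterior <- rep_len(anterior, n)
  keel <- rep_len(keel, n)
  total <- rep_len(total, n)
  if (any(c(anterior, keel, total) < 0, na.rm = TRUE)) {
    stop("plate counts must be non-negative")
  }
  if (any(total < anterior, na.rm = TRUE)) {
    stop("`total` must be >= `anterior`")
  }
  out <- rep("UNCLASSIFIED", n)
  out[total >= 60] <- "FPK"
  sub <- total < 60
  out[sub & anterior < 20 & keel >= 1] <- "LPK"
  out[sub & anterior < 20 & keel == 0] <- "LPNK"
  out[sub & anterior >= 20 & keel >= 1 & total >= 21 & total <= 59] <- "PPK"
  out[sub & anterior > 20 & keel == 0] <- "PPNK"
  out[is.na(anterior) | is.na(keel) | is.na(total)] <- NA
  factor(out, levels = plate_morph_levels)
}

#' Code Stn382 allele sizes as Eda genotypes
#'
#' The Stn382 microsatellite linked to Eda yields a 218 bp "fully plated"
#' allele (C) and a 158 bp "low plated" allele (L); an unordered pair of
#' fragment sizes maps to CC, CL or LL.
#'
#' @param a1,a2 fragment sizes in base pairs, each 218 or 158 (vectorised).
#' @return Character vector of `"CC"`, `"CL"`, `"LL"`.
#' @examples
#' code_stn382(218, 218)  # CC
#' code_stn382(158, 218)  # CL
#' @export
code_stn382 <- function(a1, a2) {
  ok <- function(x) is.na(x) | x %in% c(218, 158)
  if (!all(ok(a1)) || !all(ok(a2))) {
    stop("allele sizes must be 218 (C) or 158 (L)")
  }
  n_l <- (a1 == 158) + (a2 == 158)
  c("CC", "CL", "LL")[n_l + 1L]
}

#' Deme-by-morph and deme-by-genotype frequency tables
#'
#' Cross-tabulates phenotype records by deme and plate morph (classifying
#' with [classify_plate_morph()] when no `morph` column is present) and by
#' deme and Stn382 genotype. Marginals equal the record counts.
#'
#' @param records phenotype data frame with columns `deme`, plate counts
#'   and/or `stn382` (see [read_phenotypes()]).
#' @return `list(morph = , genotype = )` of contingency tables (either may
#'   be `NULL` when the relevant columns are absent).
#' @export
morph_frequency_table <- function(records) {
  if (nrow(records) == 0) stop("no phenotype records")
  morph_tab <- NULL
  if ("morph" %in% names(records)) {
    morph_tab <- table(deme = records$deme,
                       morph = factor(records$morph,
                                      levels = plate_morph_levels))
  } else if (all(c("plates_anterior", "plates_keel", "plates_total") %in%
                 names(records))) {
    morph <- classify_plate_morph(records$plates_anterior,
                                  records$plates_keel,
                                  records$plates_total)
    morph_tab <- table(deme = records$deme, morph = morph)
  }
  geno_tab <- NULL
  if ("stn382" %in% names(records)) {
    geno_tab <- table(deme = records$deme,
                      stn382 = factor(records$stn382,
                                      levels = c("CC", "CL", "LL")))
  }
  list(morph = morph_tab, genotype = geno_tab)
}
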