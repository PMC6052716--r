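#' Read a VCF file into a genotype matrix
#'
#' Parses diploid GT calls from a VCF (via \pkg{vcfR}) into alternate-allele
#' dosages. Multi-allelic records are skipped with a warning; `./.` (or
#' `.|.`) becomes a missing call. Locus identifiers are `CHROM:POS`
#' (1-based, the VCF convention).
#'
#' @param path VCF file.
#' @param pops optional deme mapping: a data frame (or CSV path) with columns
#'   `id`, `deme` covering every sample in the VCF. Without it all samples
#'   are placed in a single deme `"pop1"`.
#' @return A [genotype_matrix()].
#' @seealso [write_vcf()], [write_pop_map()]
#' @export
read_vcf <- function(path, pops = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- v@fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- paste0(v@fix[, "CHROM"], ":", v@fix[, "POS"])
  gt <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  dos[gt == "0/0"] <- 0L
  dos[gt %in% c("0/1", "1/0")] <- 1L
  dos[gt == "1/1"] <- 2L
  unparsed <- !is.na(gt) & gt != "./." & is.na(dos)
  if (any(unparsed)) stop("malformed GT field(s), e.g. ", gt[unparsed][1])
  calls <- t(dos)
  samples <- colnames(gt)
  if (is.null(pops)) {
    deme <- rep("pop1", length(samples))
  } else {
    if (is.character(pops)) pops <- read.csv(pops, stringsAsFactors = FALSE)
    deme <- pops$deme[match(samples, pops$id)]
    if (anyNA(deme)) {
      stop("no deme for sample(s): ",
           paste(samples[is.na(deme)], collapse = ", "))
    }
  }
  genotype_matrix(calls, deme = deme, locus_ids = ids, ids = samples)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a VCF 4.2 file with a GT-only FORMAT, one ALT allele per record and
#' placeholder A/C alleles. Locus ids of the form `chrom:pos` are split back
#' into CHROM/POS so that write -> read round trips preserve identifiers.
#'
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  m <- regmatches(g$locus_ids, regexec("^(.*):([0-9]+)$", g$locus_ids))
  chrom <- vapply(seq_along(m), function(i)
    if (length(m[[i]])) m[[i]][2] else g$locus_ids[i], "")
  pos <- vapply(seq_along(m), function(i)
    if (length(m[[i]])) m[[i]][3] else "1", "")
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", ncol(g$calls), nrow(g$calls))
  filled <- !is.na(t(g$calls))
  gt[filled] <- code[as.character(t(g$calls)[filled])]
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", g$ids), collapse = "\t"),
             paste(chrom, pos, ".", "A", "C", ".", "PASS", ".", "GT",
                   apply(gt, 1, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read the deme mapping sidecar
#'
#' VCF carries no population labels, so the deme mapping travels in a small
#' CSV with columns `id`, `deme`.
#'
#' @param g a [genotype_matrix()].
#' @param path CSV file.
#' @return `path`, invisibly.
#' @export
write_pop_map <- function(g, path) {
  write.csv(data.frame(id = g$ids, deme = as.character(g$deme)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read genotypes as CSV
#'
#' Plain-text alternative to VCF: rows are individuals, columns are loci,
#' values 0/1/2/NA, with leading `id` and `deme` columns.
#'
#' @param g a [genotype_matrix()].
#' @param path CSV file.
#' @return `write_genotypes_csv`: `path` invisibly;
#'   `read_genotypes_csv`: a [genotype_matrix()].
#' @export
write_genotypes_csv <- function(g, path) {
  df <- data.frame(id = g$ids, deme = as.character(g$deme),
                   g$calls, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_csv
#' @export
read_genotypes_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  calls <- as.matrix(df[, setdiff(names(df), c("id", "deme")), drop = FALSE])
  genotype_matrix(calls, deme = df$deme, ids = df$id)
}

#' Read phenotype records
#'
#' Loads a phenotype CSV with the package's canonical columns (`id`, `deme`,
#' optional `sex`, plate counts, `stn382`, optional PC scores `pc1`...),
#' validating count invariants.
#'
#' @param path CSV file.
#' @return A data frame of phenotype records.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "deme")
  if (!all(need %in% names(df)))
    stop("phenotype table must have columns id, deme")
  cnt <- intersect(c("plates_anterior", "plates_keel", "plates_total"),
                   names(df))
  for (col in cnt) {
    if (any(df[[col]] < 0, na.rm = TRUE)) stop(col, " must be >= 0")
  }
  if (all(c("plates_total", "plates_anterior") %in% names(df)) &&
      any(df$plates_total < df$plates_anterior, na.rm = TRUE)) {
    stop("plates_total must be >= plates_anterior")
  }
  if ("stn382" %in% names(df)) {
    bad <- !is.na(df$stn382) & !(df$stn382 %in% c("CC", "CL", "LL"))
    if (any(bad)) stop("stn382 values must be CC, CL, LL or missing")
  }
  df
}

#' Labelled symmetric matrix
#'
#' Distance and F_ST matrices are plain numeric matrices with identical row
#' and column labels; this validates one (symmetry to 1e-12, matching
#' labels, empty-diagonal semantics).
#'
#' @param values square numeric matrix.
#' @param labels ordered labels; defaults to `rownames(values)`.
#' @return The labelled matrix, with class `labeled_matrix` prepended.
#' @export
labeled_matrix <- function(values, labels = rownames(values)) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix must be square")
  if (is.null(labels) || length(labels) != nrow(values))
    stop("label count must equal dimension")
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-12)
    stop("matrix is not symmetric (tolerance 1e-12)")
  dimnames(values) <- list(labels, labels)
  diag(values) <- 0
  class(values) <- c("labeled_matrix", class(values))
  values
}

#' Load the packaged coastal distance and F_ST fixture
#'
#' Published pairwise along-coast distances (km) and global pairwise
#' Weir-Cockerham F_ST among eight northeast Pacific marine stickleback
#' sampling sites (CA01..AK01, California to Alaska), shipped as CSV. These
#' drive the isolation-by-distance examples and tests.
#'
#' @return `list(distance = , fst = )`, both [labeled_matrix()] objects
#'   (8 x 8, 28 site pairs each).
#' @examples
#' fx <- load_coastal_fixture()
#' fx$fst["CA01", "OR02"]
#' @export
load_coastal_fixture <- function() {
  read_one <- function(name) {
    path <- system.file("extdata", name, package = "stickpop", mustWork = TRUE)
    m <- as.matrix(read.csv(path, row.names = 1, comment.char = "#",
                            check.names = FALSE))
    labeled_matrix(m)
  }
  list(distance = read_one("coastal_distance_km.csv"),
       fst = read_one("coastal_fst.csv"))
}
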