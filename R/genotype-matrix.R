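#' Diploid genotype matrix with deme labels
#'
#' The substrate of all F-statistics in the package: an individuals-by-loci
#' matrix of alternate-allele dosages (0, 1, 2 or `NA` for a missing call),
#' a deme (population) label per individual, unique locus identifiers
#' (`chrom:pos` where the data come from VCF) and, optionally, per-call read
#' depth used by the filter cascade.
#'
#' @param calls integer matrix, individuals x loci, values in \{0, 1, 2, NA\}.
#' @param deme character or factor of length `nrow(calls)`; every individual
#'   must have a deme label.
#' @param locus_ids unique locus identifiers; defaults to `colnames(calls)`.
#' @param ids individual identifiers; defaults to `rownames(calls)`.
#' @param depth optional numeric matrix of the same shape as `calls` holding
#'   per-call read depth.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `deme` (factor), `locus_ids`, `ids`, `depth`.
#' @examples
#' g <- genotype_matrix(rbind(a = c(0, 1), b = c(2, NA)),
#'                      deme = c("P1", "P2"),
#'                      locus_ids = c("chr1:10", "chr1:99"))
#' dim(g)
#' @export
genotype_matrix <- function(calls, deme, locus_ids = colnames(calls),
                            ids = rownames(calls), depth = NULL) {
  calls <- as.matrix(calls)
  if (!is.numeric(calls)) stop("`calls` must be a numeric matrix")
  bad <- !is.na(calls) & !(calls %in% c(0, 1, 2))
  if (any(bad)) stop("`calls` may only contain 0, 1, 2 or NA")
  storage.mode(calls) <- "integer"
  if (length(deme) != nrow(calls)) {
    stop("`deme` must have one label per individual (", nrow(calls), ")")
  }
  if (anyNA(deme)) stop("every individual must have a deme label")
  if (is.null(locus_ids)) locus_ids <- paste0("L", seq_len(ncol(calls)))
  locus_ids <- as.character(locus_ids)
  if (length(locus_ids) != ncol(calls)) stop("`locus_ids` length mismatch")
  if (anyDuplicated(locus_ids)) stop("`locus_ids` must be unique")
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(calls)))
  dimnames(calls) <- list(as.character(ids), locus_ids)
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    if (!all(dim(depth) == dim(calls))) stop("`depth` shape mismatch")
    dimnames(depth) <- dimnames(calls)
  }
  structure(list(calls = calls, deme = factor(deme),
                 locus_ids = locus_ids, ids = as.character(ids),
                 depth = depth),
            class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param i individual index (logical, integer or id).
#' @param j locus index (logical, integer or locus id).
#' @param ... ignored.
#' @return A `genotype_matrix` restricted to the selected individuals/loci.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  genotype_matrix(x$calls[i, j, drop = FALSE],
                  deme = as.character(x$deme)[
                    if (is.character(i)) match(i, x$ids) else i],
                  depth = if (!is.null(x$depth)) x$depth[i, j, drop = FALSE])
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "individuals x",
      ncol(x$calls), "loci\n")
  tab <- table(x$deme)
  cat("demes:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "),
      "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("missing calls: %.2f%%%s\n", 100 * miss,
              if (is.null(x$depth)) "" else "; per-call depth present"))
  invisible(x)
}

# Per-deme alternate-allele frequencies and call counts.
# Returns list(freq, n) each demes x loci; n is the number of called
# individuals (not alleles).
deme_allele_freqs <- function(g) {
  called <- !is.na(g$calls)
  alt <- g$calls
  alt[!called] <- 0L
  n <- rowsum(called + 0, g$deme)
  s <- rowsum(alt, g$deme)
  freq <- s / (2 * n)
  freq[n == 0] <- NA_real_
  list(freq = freq, n = n)
}

# Per-deme observed-heterozygote counts (demes x loci).
deme_het_counts <- function(g) {
  het <- (g$calls == 1L)
  het[is.na(het)] <- FALSE
  rowsum(het + 0, g$deme)
}
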