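#' @useDynLib snpdemog, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dhyper optim pchisq quantile rbeta rbinom runif sd setNames
#'   var rnorm median cor p.adjust complete.cases
#' @importFrom utils read.table write.table head combn
NULL

#' Missing-genotype sentinel
#'
#' Genotypes are stored as alternate-allele counts (0, 1, 2); missing calls use
#' the conventional STRUCTURE missing code -9.
#' @export
MISSING <- -9L

#' Construct a genotype matrix
#'
#' The central data container of the package: an individuals x loci matrix of
#' diploid genotype codes (0, 1, 2 = number of copies of the alternate allele,
#' [MISSING] for no call) together with a population label for every
#' individual.  All downstream statistics are invariant to which of a locus'
#' two alleles is labelled "alternate".
#'
#' @param calls integer matrix, individuals in rows and loci in columns, with
#'   unique row and column names.  Entries must be 0, 1, 2 or [MISSING].
#' @param populations character vector of population labels, either named by
#'   individual id or in row order of `calls`.
#' @return an object of class `genotype_matrix`: a list with elements `calls`
#'   (integer matrix), `individual_ids`, `locus_ids` and `population` (named
#'   character vector).
#' @export
genotype_matrix <- function(calls, populations) {
  if (!is.matrix(calls)) stop("'calls' must be a matrix")
  storage.mode(calls) <- "integer"
  if (is.null(dimnames(calls))) dimnames(calls) <- list(NULL, NULL)
  if (is.null(rownames(calls)) && nrow(calls) > 0)
    rownames(calls) <- paste0("ind", seq_len(nrow(calls)))
  if (is.null(colnames(calls)) && ncol(calls) > 0)
    colnames(calls) <- paste0("locus", seq_len(ncol(calls)))
  if (anyDuplicated(rownames(calls))) stop("individual ids must be unique")
  if (anyDuplicated(colnames(calls))) stop("locus ids must be unique")
  bad <- !(calls %in% c(0L, 1L, 2L, MISSING))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or MISSING (-9)")
  populations <- as.character(populations)
  if (!is.null(names(populations))) {
    if (!setequal(names(populations), rownames(calls)))
      stop("population labels must cover exactly the individual ids")
    populations <- populations[rownames(calls)]
  } else {
    if (length(populations) != nrow(calls))
      stop("one population label per individual required")
    names(populations) <- rownames(calls)
  }
  if (anyNA(populations)) stop("population labels may not be NA")
  structure(list(calls = calls,
                 individual_ids = rownames(calls),
                 locus_ids = colnames(calls),
                 population = populations),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "individuals x", ncol(x$calls),
      "loci\n")
  tab <- table(x$population)
  cat("populations:", paste(names(tab), "(", tab, ")", collapse = ", "), "\n")
  miss <- mean(x$calls == MISSING)
  cat(sprintf("missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param i individual selector (ids, indices or logical).
#' @param j locus selector.
#' @param ... ignored.
#' @return the subsetted `genotype_matrix`.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  calls <- x$calls[i, j, drop = FALSE]
  genotype_matrix(calls, x$population[rownames(calls)])
}

#' Population labels of a genotype matrix
#' @param x a [genotype_matrix()].
#' @return named character vector of population labels.
#' @export
populations <- function(x) x$population

#' Restrict a genotype matrix to selected populations
#' @param x a [genotype_matrix()].
#' @param pops character vector of population labels to keep.
#' @return the subsetted `genotype_matrix`.
#' @export
subset_populations <- function(x, pops) {
  keep <- x$individual_ids[x$population %in% pops]
  if (length(keep) == 0) stop("no individuals in requested populations")
  x[keep, ]
}

# ---- internal helpers ------------------------------------------------------

# calls with MISSING replaced by NA, numeric
calls_na <- function(x) {
  m <- x$calls
  m[m == MISSING] <- NA_integer_
  m
}

# per-locus alternate allele frequency (missing-aware); NaN if all missing
locus_freq <- function(calls) {
  m <- calls
  m[m == MISSING] <- NA_integer_
  n <- colSums(!is.na(m))
  colSums(m, na.rm = TRUE) / (2 * n)
}

# per-locus call rate
locus_call_rate <- function(calls) colMeans(calls != MISSING)

# per-individual call rate
indiv_call_rate <- function(calls) rowMeans(calls != MISSING)

#' Haplotype alignment container
#'
#' Holds equal-length aligned haplotype sequences (e.g. mitochondrial control
#' region) with one population label per sequence.
#'
#' @param sequences character vector of equal-length strings over
#'   `A,C,G,T,-,N` (case-insensitive), named by sequence id.
#' @param populations character vector of population labels, named by sequence
#'   id or in the order of `sequences`.
#' @return an object of class `haplotype_alignment`.
#' @export
haplotype_alignment <- function(sequences, populations) {
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  if (anyDuplicated(names(sequences))) stop("sequence ids must be unique")
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) > 1)
    stop("alignment length error: sequences have unequal lengths (",
         paste(unique(lens), collapse = ", "), ")")
  if (any(grepl("[^ACGTN-]", sequences)))
    stop("sequences may only contain A, C, G, T, N, -")
  populations <- as.character(populations)
  if (!is.null(names(populations))) {
    if (!setequal(names(populations), names(sequences)))
      stop("population labels must cover exactly the sequence ids")
    populations <- populations[names(sequences)]
  } else {
    if (length(populations) != length(sequences))
      stop("one population label per sequence required")
    names(populations) <- names(sequences)
  }
  structure(list(sequence_ids = names(sequences), sequences = sequences,
                 population = populations),
            class = "haplotype_alignment")
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat("haplotype_alignment:", length(x$sequences), "sequences of length",
      nchar(x$sequences[1]), "\n")
  tab <- table(x$population)
  cat("populations:", paste(names(tab), "(", tab, ")", collapse = ", "), "\n")
  invisible(x)
}
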