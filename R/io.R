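# Readers and writers for the standard formats a DArT-style SNP study touches:
# STRUCTURE text, DArT two-row CSV, minimal VCF, and aligned FASTA.

#' Read a STRUCTURE-format genotype file
#'
#' Supports the two common dialects: two rows per individual with one column
#' per locus (default), and one row per individual with two adjacent columns
#' per locus.  The dialect is auto-detected (consecutive duplicate individual
#' ids indicate the two-row layout; an optional header row of locus names
#' disambiguates by column-count parity) and the choice is reported via
#' `message()`.  Each row starts with an individual id and a population label.
#'
#' Genotypes are recoded to alternate-allele counts.  The "alternate" allele
#' at each locus is the one with the larger allele label, which makes
#' write/read round trips exact; every downstream statistic is invariant to
#' this orientation.  The per-locus allele labelling is recorded in the
#' `"orientation"` attribute of the result.
#'
#' @param path path to the STRUCTURE file.
#' @param missing_code integer code used for missing alleles (default -9).
#' @param one_row force the one-row dialect (`TRUE`), the two-row dialect
#'   (`FALSE`), or auto-detect (`NULL`, default).
#' @return a [genotype_matrix()] with an `"orientation"` attribute
#'   (data.frame: locus, ref, alt allele labels).
#' @export
read_structure <- function(path, missing_code = -9L, one_row = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty STRUCTURE file: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)

  header <- NULL
  first_data <- 1L
  if (length(fields) > 1 && nf[1] < nf[2]) {
    header <- fields[[1]]
    first_data <- 2L
  }
  data <- fields[first_data:length(fields)]
  nfd <- lengths(data)
  if (length(unique(nfd)) > 1) {
    bad <- which(nfd != nfd[1])[1] + first_data - 1L
    stop("format error: ragged row at line ", bad, " of ", path)
  }
  ncols <- nfd[1] - 2L
  if (ncols < 1) stop("format error: no genotype columns in ", path)
  ids <- vapply(data, `[`, "", 1L)
  pops <- vapply(data, `[`, "", 2L)

  if (is.null(one_row)) {
    if (!is.null(header)) {
      one_row <- (ncols == 2L * length(header))
    } else {
      nr <- length(ids)
      one_row <- !(nr %% 2 == 0 &&
                   all(ids[seq(1, nr, 2)] == ids[seq(2, nr, 2)]))
    }
    message("read_structure: detected ",
            if (one_row) "one-row (two columns per locus)" else
              "two-row (two rows per individual)", " dialect")
  }

  g <- matrix(NA_character_, length(data), ncols)
  for (i in seq_along(data)) g[i, ] <- data[[i]][-(1:2)]

  if (one_row) {
    n_loci <- ncols %/% 2L
    if (ncols %% 2L != 0)
      stop("format error: odd genotype column count in one-row dialect")
    a1 <- g[, seq(1, ncols, 2), drop = FALSE]
    a2 <- g[, seq(2, ncols, 2), drop = FALSE]
    ind_ids <- ids
    ind_pops <- pops
  } else {
    if (length(data) %% 2 != 0)
      stop("format error: odd row count in two-row dialect")
    r1 <- seq(1, length(data), 2)
    if (any(ids[r1] != ids[r1 + 1]))
      stop("format error: consecutive rows do not pair by individual id")
    n_loci <- ncols
    a1 <- g[r1, , drop = FALSE]
    a2 <- g[r1 + 1, , drop = FALSE]
    ind_ids <- ids[r1]
    ind_pops <- pops[r1]
  }

  locus_ids <- if (!is.null(header) && length(header) == n_loci) header else
    paste0("locus", seq_len(n_loci))
  miss <- as.character(missing_code)
  calls <- matrix(MISSING, length(ind_ids), n_loci,
                  dimnames = list(ind_ids, locus_ids))
  ref <- alt <- rep(NA_character_, n_loci)
  for (l in seq_len(n_loci)) {
    x1 <- a1[, l]; x2 <- a2[, l]
    ok <- x1 != miss & x2 != miss
    alleles <- sort(unique(c(x1[ok], x2[ok])))
    suppressWarnings({
      num <- as.numeric(alleles)
    })
    if (!anyNA(num)) alleles <- alleles[order(num)]
    if (length(alleles) > 2)
      stop("biallelic violation: locus ", locus_ids[l], " has ",
           length(alleles), " alleles (", paste(alleles, collapse = ","), ")")
    if (length(alleles) >= 1) {
      ref[l] <- alleles[1]
      alt[l] <- if (length(alleles) == 2) alleles[2] else NA_character_
      cnt <- (x1 == alt[l]) + (x2 == alt[l])
      if (is.na(alt[l])) cnt <- rep(0L, length(x1))
      calls[ok, l] <- as.integer(cnt[ok])
    }
  }
  gm <- genotype_matrix(calls, ind_pops)
  attr(gm, "orientation") <- data.frame(locus = locus_ids, ref = ref,
                                        alt = alt, stringsAsFactors = FALSE)
  gm
}

#' Write a genotype matrix in STRUCTURE format
#'
#' Writes the two-row dialect (or one-row with `one_row = TRUE`) with a header
#' line of locus names, allele labels 1 (reference) and 2 (alternate), and -9
#' for missing alleles.  Re-reading with [read_structure()] recovers the calls,
#' ids and population labels exactly.
#'
#' @param x a [genotype_matrix()].
#' @param path output file path.
#' @param one_row write the one-row dialect instead.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, one_row = FALSE) {
  calls <- x$calls
  a1 <- ifelse(calls == MISSING, -9L, ifelse(calls >= 1L, 2L, 1L))
  a2 <- ifelse(calls == MISSING, -9L, ifelse(calls == 2L, 2L, 1L))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(calls), collapse = "\t"), con)
  for (i in seq_len(nrow(calls))) {
    id <- rownames(calls)[i]
    pop <- x$population[id]
    if (one_row) {
      inter <- as.vector(rbind(a1[i, ], a2[i, ]))
      writeLines(paste(c(id, pop, inter), collapse = "\t"), con)
    } else {
      writeLines(paste(c(id, pop, a1[i, ]), collapse = "\t"), con)
      writeLines(paste(c(id, pop, a2[i, ]), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Per-locus metadata accompanying a DArT-style SNP matrix
#'
#' @param locus_id character vector of locus ids.
#' @param call_rate,repeatability numeric in `[0, 1]`.
#' @param mean_depth non-negative numeric.
#' @param tag_id character, the sequenced tag (clone) each SNP belongs to.
#' @param position_in_tag non-negative integer position of the SNP in its tag.
#' @param tag_sequence optional character tag sequences (`NA` allowed).
#' @return a `locus_metadata` data.frame.
#' @export
locus_metadata <- function(locus_id, call_rate, repeatability, mean_depth,
                           tag_id, position_in_tag,
                           tag_sequence = NA_character_) {
  out <- data.frame(locus_id = as.character(locus_id),
                    call_rate = call_rate,
                    repeatability = repeatability,
                    mean_depth = mean_depth,
                    tag_id = as.character(tag_id),
                    position_in_tag = as.integer(position_in_tag),
                    tag_sequence = as.character(tag_sequence),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$locus_id)) stop("one metadata record per locus_id")
  rates <- c(out$call_rate, out$repeatability)
  if (any(rates < 0 | rates > 1, na.rm = TRUE))
    stop("call_rate and repeatability must lie in [0, 1]")
  if (any(out$mean_depth < 0, na.rm = TRUE)) stop("mean_depth must be >= 0")
  class(out) <- c("locus_metadata", "data.frame")
  out
}

dart_required_cols <- c("AlleleID", "CloneID", "SnpPosition", "CallRate",
                        "RepAvg", "AvgDepth", "TrimmedSequence")

#' Read a DArT two-row CSV
#'
#' Parses the two-row-per-locus DArT scoring dialect: metadata columns
#' (`AlleleID`, `CloneID`, `SnpPosition`, `CallRate`, `RepAvg`, `AvgDepth`,
#' `TrimmedSequence`) followed by one column per individual; the first row of
#' each pair scores presence of the reference allele, the second of the SNP
#' (alternate) allele, with `-` for no call.
#'
#' @param path path to the CSV file.
#' @param populations optional named character vector mapping individual id to
#'   population label; unlisted individuals get `"unknown"`.
#' @return a list with elements `matrix` (a [genotype_matrix()]) and
#'   `metadata` (a [locus_metadata()] data.frame aligned with the locus ids).
#' @export
read_dart_csv <- function(path, populations = NULL) {
  df <- read.table(path, sep = ",", header = TRUE, check.names = FALSE,
                   colClasses = "character")
  missing_cols <- setdiff(dart_required_cols, names(df))
  if (length(missing_cols) > 0)
    stop("DArT CSV is missing required metadata column(s): ",
         paste(missing_cols, collapse = ", "),
         " (need ", paste(dart_required_cols, collapse = ", "), ")")
  ind_cols <- setdiff(names(df), dart_required_cols)
  if (length(ind_cols) == 0) stop("DArT CSV has no individual columns")
  if (nrow(df) %% 2 != 0)
    stop("format error: DArT two-row CSV must have an even number of rows")
  r_ref <- seq(1, nrow(df), 2)
  r_alt <- r_ref + 1
  locus_ids <- df$AlleleID[r_ref]
  if (any(df$AlleleID[r_alt] != locus_ids))
    stop("format error: row pairs do not share AlleleID")
  score <- function(rows) {
    m <- as.matrix(df[rows, ind_cols, drop = FALSE])
    suppressWarnings(storage.mode(m) <- "integer")
    m
  }
  sref <- score(r_ref)
  salt <- score(r_alt)
  calls <- matrix(MISSING, length(ind_cols), length(locus_ids),
                  dimnames = list(ind_cols, locus_ids))
  for (l in seq_along(locus_ids)) {
    rr <- sref[l, ]; aa <- salt[l, ]
    ok <- !is.na(rr) & !is.na(aa) & (rr + aa > 0)
    g <- ifelse(aa == 0L, 0L, ifelse(rr == 1L & aa == 1L, 1L, 2L))
    calls[ok, l] <- g[ok]
  }
  if (is.null(populations)) populations <- setNames(
    rep("unknown", length(ind_cols)), ind_cols)
  pop <- setNames(rep("unknown", length(ind_cols)), ind_cols)
  common <- intersect(names(populations), ind_cols)
  pop[common] <- populations[common]
  meta <- locus_metadata(
    locus_id = locus_ids,
    call_rate = as.numeric(df$CallRate[r_alt]),
    repeatability = as.numeric(df$RepAvg[r_alt]),
    mean_depth = as.numeric(df$AvgDepth[r_alt]),
    tag_id = df$CloneID[r_alt],
    position_in_tag = as.integer(df$SnpPosition[r_alt]),
    tag_sequence = ifelse(df$TrimmedSequence[r_alt] == "",
                          NA_character_, df$TrimmedSequence[r_alt]))
  list(matrix = genotype_matrix(calls, pop), metadata = meta)
}

#' Write a genotype matrix plus metadata as a DArT two-row CSV
#'
#' @param x a [genotype_matrix()].
#' @param metadata a [locus_metadata()] covering the loci of `x`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dart_csv <- function(x, metadata, path) {
  metadata <- metadata[match(x$locus_ids, metadata$locus_id), ]
  if (anyNA(metadata$locus_id))
    stop("metadata must cover every locus of the matrix")
  calls <- x$calls
  n_loci <- ncol(calls)
  rows <- vector("list", 2 * n_loci)
  for (l in seq_len(n_loci)) {
    g <- calls[, l]
    rr <- ifelse(g == MISSING, "-", ifelse(g <= 1L, "1", "0"))
    aa <- ifelse(g == MISSING, "-", ifelse(g >= 1L, "1", "0"))
    m <- metadata[l, ]
    base <- c(m$locus_id, m$tag_id, m$position_in_tag, m$call_rate,
              m$repeatability, m$mean_depth,
              ifelse(is.na(m$tag_sequence), "", m$tag_sequence))
    rows[[2 * l - 1]] <- c(base, rr)
    rows[[2 * l]] <- c(base, aa)
  }
  out <- do.call(rbind, rows)
  colnames(out) <- c(dart_required_cols, rownames(calls))
  write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits VCF v4.2 with GT-only diploid records.  DArT tags carry no genomic
#' coordinates, so records are placed on a dummy contig at 1-based positions in
#' locus order.  Missing genotypes become `./.`.
#'
#' @param x a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  calls <- x$calls
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=snpdemog",
               sprintf("##contig=<ID=tags,length=%d>", max(1L, ncol(calls))),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(calls)), collapse = "\t"), con)
  gt <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (l in seq_len(ncol(calls))) {
    g <- calls[, l]
    gtxt <- ifelse(g == MISSING, "./.", gt[as.character(g)])
    writeLines(paste(c("tags", l, colnames(calls)[l], "A", "T", ".", "PASS",
                       ".", "GT", gtxt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read an aligned FASTA file as a haplotype alignment
#'
#' @param path path to the FASTA file (equal-length aligned sequences).
#' @param populations named character vector (or two-column data.frame with
#'   columns `id` and `population`) mapping sequence id to population label.
#' @return a [haplotype_alignment()].
#' @export
read_fasta_alignment <- function(path, populations) {
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna), function(s)
    paste(toupper(s), collapse = ""), "")
  names(seqs) <- names(dna)
  if (is.data.frame(populations))
    populations <- setNames(as.character(populations$population),
                            populations$id)
  if (!all(names(seqs) %in% names(populations)))
    stop("population labels missing for: ",
         paste(setdiff(names(seqs), names(populations)), collapse = ", "))
  haplotype_alignment(seqs, populations[names(seqs)])
}

#' Write a haplotype alignment as FASTA
#'
#' @param x a [haplotype_alignment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x$sequences))
    writeLines(c(paste0(">", x$sequence_ids[i]), x$sequences[i]), con)
  invisible(path)
}
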