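test_that("STRUCTURE write/read round trip is the identity", {
  x <- random_matrix(10, 20, n_pops = 3, miss_rate = 0.1, seed = 7)
  f <- withr::local_tempfile(fileext = ".str")
  write_structure(x, f)
  y <- suppressMessages(read_structure(f))
  expect_identical(y$calls, x$calls)
  expect_identical(y$population, x$population)

  # one-row dialect round trip
  f2 <- withr::local_tempfile(fileext = ".str")
  write_structure(x, f2, one_row = TRUE)
  y2 <- suppressMessages(read_structure(f2))
  expect_identical(y2$calls, x$calls)
})

test_that("degenerate and malformed STRUCTURE inputs are handled", {
  # 2 individuals x 1 locus, everything missing
  f <- withr::local_tempfile()
  writeLines(c("L1", "a p1 -9", "a p1 -9", "b p1 -9", "b p1 -9"), f)
  y <- suppressMessages(read_structure(f))
  expect_equal(dim(y$calls), c(2L, 1L))
  expect_true(all(y$calls == MISSING))

  # ragged row names the offending line
  f2 <- withr::local_tempfile()
  writeLines(c("a p1 1 2", "a p1 1", "b p1 1 2", "b p1 2 2"), f2)
  expect_error(suppressMessages(read_structure(f2)), "line 2")

  # more than two alleles at a locus
  f3 <- withr::local_tempfile()
  writeLines(c("a p1 1", "a p1 2", "b p1 3", "b p1 1"), f3)
  expect_error(suppressMessages(read_structure(f3)), "biallelic")
})

test_that("DArT CSV reader recovers the fixture and checks its columns", {
  fx <- make_qc_fixture(seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_dart_csv(fx$matrix, fx$metadata, f)
  got <- read_dart_csv(f, populations = fx$matrix$population)
  expect_identical(got$matrix$calls, fx$matrix$calls)
  expect_equal(got$metadata$tag_id, fx$metadata$tag_id)
  expect_equal(got$metadata$mean_depth, fx$metadata$mean_depth)
  expect_equal(got$metadata$repeatability, fx$metadata$repeatability)
  expect_equal(got$metadata$tag_sequence, fx$metadata$tag_sequence)

  # dropping the repeatability column raises an error naming it
  df <- read.table(f, sep = ",", header = TRUE, check.names = FALSE)
  df$RepAvg <- NULL
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.table(df, f2, sep = ",", row.names = FALSE, quote = FALSE)
  expect_error(read_dart_csv(f2), "RepAvg")
})

test_that("VCF output has one record per locus and encodes missing as ./.", {
  x <- random_matrix(10, 20, miss_rate = 0.15, seed = 2)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(x, f)
  lines <- readLines(f)
  records <- lines[!startsWith(lines, "#")]
  expect_length(records, 20)
  header <- lines[startsWith(lines, "#CHROM")]
  expect_length(strsplit(header, "\t")[[1]], 9 + 10)
  n_missing_gt <- sum(vapply(strsplit(records, "\t"), function(r)
    sum(r[-(1:9)] == "./."), 0L))
  expect_equal(n_missing_gt, sum(x$calls == MISSING))

  # empty matrix still yields a valid, record-free file
  x0 <- genotype_matrix(x$calls[, 0, drop = FALSE], x$population)
  f0 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(x0, f0)
  expect_true(all(startsWith(readLines(f0), "#")))
})

test_that("FASTA alignment IO preserves sequences and labels", {
  aln <- simulate_mtdna(5, n_per_pop = 4, seq_length = 60, seed = 11)
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta_alignment(aln, f)
  got <- read_fasta_alignment(f, aln$population)
  expect_identical(got$sequences, aln$sequences)
  expect_identical(got$population, aln$population)

  # unequal lengths are an error
  expect_error(haplotype_alignment(c(a = "ACGT", b = "ACG"),
                                   c(a = "p", b = "p")),
               "length")
})

test_that("allele re-orientation leaves orientation-free statistics unchanged", {
  x <- random_matrix(16, 30, n_pops = 2, miss_rate = 0.05, seed = 5)
  set.seed(9)
  y <- flip_loci(x, sample(colnames(x$calls), 12))
  dx <- diversity_table(x); dy <- diversity_table(y)
  expect_equal(dx$He, dy$He, tolerance = 1e-12)
  expect_equal(dx$Ho, dy$Ho, tolerance = 1e-12)
  expect_equal(snpdemog:::wc_theta_multilocus(x$calls, x$population),
               snpdemog:::wc_theta_multilocus(y$calls, y$population),
               tolerance = 1e-12)
  ax <- afs_from_matrix(x, "pop1", "pop2", c(8, 8))
  ay <- afs_from_matrix(y, "pop1", "pop2", c(8, 8))
  expect_equal(ax$entries, ay$entries, tolerance = 1e-10)
})
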