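test_that("HWE exact test matches the enumeration oracle", {
  # monomorphic data cannot deviate
  expect_equal(hwe_exact_test(25, 0, 0), 1)
  # all heterozygotes, 100 diploids
  expect_equal(hwe_exact_test(0, 100, 0), oracle_hwe_p(0, 100, 0),
               tolerance = 1e-12)
  # small worked table
  expect_equal(hwe_exact_test(3, 5, 2), oracle_hwe_p(3, 5, 2),
               tolerance = 1e-12)
  expect_error(hwe_exact_test(0, 0, 0), "undefined")
})

test_that("minor allele frequency is missing-aware", {
  calls <- rbind(c(1L, 0L), c(1L, 1L), c(1L, 2L), c(1L, MISSING))
  rownames(calls) <- paste0("i", 1:4); colnames(calls) <- c("A", "B")
  x <- genotype_matrix(calls, rep("p", 4))
  expect_equal(maf(x, "A"), 0.5)           # every individual heterozygous
  expect_equal(maf(x, "B"), 3 / 6)         # {0,1,2,NA} -> 3 alt of 6 copies
  calls[, "B"] <- 0L
  x2 <- genotype_matrix(calls, rep("p", 4))
  expect_equal(maf(x2, "B"), 0)
})

test_that("genotypic r-squared behaves at its boundaries", {
  x <- random_matrix(10, 4, seed = 3)
  expect_equal(ld_r2(x, 1, 1), 1)
  # hand-computed correlation on a perturbed duplicate
  g <- x$calls[, 1]
  g2 <- g; g2[1] <- ifelse(g2[1] == 0L, 1L, g2[1] - 1L)
  calls <- cbind(a = g, b = g2)
  rownames(calls) <- rownames(x$calls)
  y <- genotype_matrix(calls, x$population)
  num <- sum((g - mean(g)) * (g2 - mean(g2)))
  den <- sqrt(sum((g - mean(g))^2) * sum((g2 - mean(g2))^2))
  expect_equal(ld_r2(y, "a", "b"), (num / den)^2, tolerance = 1e-12)
  # independent loci stay uncorrelated in expectation
  z <- random_matrix(500, 40, seed = 8)
  r2 <- vapply(seq(1, 39, 2), function(j) ld_r2(z, j, j + 1), 0)
  expect_lt(mean(r2), 0.05)
})

test_that("LD pruning removes exactly one member of a perfect pair", {
  x <- random_matrix(20, 10, seed = 4)
  expect_identical(ld_prune(x), colnames(x$calls))  # nothing correlated
  calls <- cbind(x$calls, dup = x$calls[, 3])
  y <- genotype_matrix(calls, x$population)
  kept <- ld_prune(y)
  expect_length(kept, 10)
  # equal call rates: the later locus of the pair is dropped
  expect_true("L3" %in% kept)
  expect_false("dup" %in% kept)
  # three mutually identical loci -> two removed, earliest kept
  calls3 <- cbind(x$calls[, 1:4], c1 = x$calls[, 2], c2 = x$calls[, 2])
  z <- genotype_matrix(calls3, x$population)
  expect_identical(ld_prune(z), colnames(calls3)[1:4])
})

test_that("Hamming paralog filter matches an all-pairs expectation", {
  tags <- c(a = strrep("A", 20), b = strrep("C", 20),
            c = paste0(strrep("A", 18), "GG"),   # distance 0.10 to a
            d = strrep("G", 20), e = strrep("T", 20))
  meta <- locus_metadata(names(tags),
                         call_rate = c(1, 1, 0.9, 1, 1),
                         repeatability = 0.99, mean_depth = 20,
                         tag_id = names(tags), position_in_tag = 1L,
                         tag_sequence = unname(tags))
  kept <- hamming_filter(meta, 0.25)
  expect_setequal(as.vector(kept), c("a", "b", "d", "e"))  # c loses on call rate
  # all mutually distant tags pass
  kept2 <- hamming_filter(meta[c(1, 2, 4, 5), ], 0.25)
  expect_length(kept2, 4)
})

test_that("the full filter chain reproduces the fixture ground truth", {
  fx <- make_qc_fixture(seed = 1)
  out <- apply_filters(fx$matrix, fx$metadata)
  expect_identical(colnames(out$matrix$calls), fx$expected_loci)
  expect_identical(rownames(out$matrix$calls), fx$expected_individuals)
  expect_equal(out$report$loci_remaining, fx$expected_report$loci_remaining)
  expect_equal(out$report$individuals_remaining,
               fx$expected_report$individuals_remaining)
})

test_that("filtering is idempotent and attrition sums to the dimensions", {
  fx <- make_qc_fixture(seed = 2)
  out <- apply_filters(fx$matrix, fx$metadata)
  again <- apply_filters(out$matrix, fx$metadata)
  expect_identical(dim(again$matrix$calls), dim(out$matrix$calls))
  expect_true(all(again$report$loci_removed == 0))
  expect_true(all(again$report$individuals_removed == 0))
  rep <- out$report
  expect_equal(sum(rep$loci_removed),
               ncol(fx$matrix$calls) - ncol(out$matrix$calls))
  expect_equal(sum(rep$individuals_removed),
               nrow(fx$matrix$calls) - nrow(out$matrix$calls))
  expect_true(all(diff(rep$loci_remaining) <= 0))
})

test_that("a clean matrix passes every filter untouched", {
  set.seed(10)
  calls <- matrix(rbinom(40 * 30, 2, rep(runif(30, 0.3, 0.7), each = 40)),
                  40, 30)
  rownames(calls) <- paste0("i", 1:40)
  colnames(calls) <- paste0("L", 1:30)
  x <- genotype_matrix(calls, rep(c("A", "B"), each = 20))
  meta <- locus_metadata(colnames(calls), call_rate = 1, repeatability = 0.99,
                         mean_depth = 20, tag_id = colnames(calls),
                         position_in_tag = 1L,
                         tag_sequence = vapply(1:30, function(i)
                           paste(sample(c("A", "C", "G", "T"), 30,
                                        TRUE), collapse = ""), ""))
  out <- apply_filters(x, meta)
  expect_true(all(out$report$loci_removed == 0))
  expect_true(all(out$report$individuals_removed == 0))
})

test_that("default thresholds are the standard DArT-pipeline values", {
  cfg <- filter_config()
  expect_equal(cfg$min_locus_call_rate, 0.90)
  expect_equal(cfg$min_indiv_call_rate, 0.80)
  expect_equal(cfg$min_depth, 5)
  expect_equal(cfg$min_repeatability, 0.95)
  expect_equal(cfg$hamming_threshold, 0.25)
  expect_equal(cfg$hwe_alpha, 1e-5)
  expect_equal(cfg$ld_r2_max, 0.80)
  expect_equal(cfg$max_locus_missing, 0.10)
  expect_equal(cfg$min_maf, 0.02)
})
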