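test_that("diversity indices hit their closed forms on extreme inputs", {
  # every call heterozygous: Ho = 1, unbiased He = 0.5 * 2n/(2n-1), FIS < 0
  n <- 8
  calls <- matrix(1L, n, 5, dimnames = list(paste0("i", 1:n), paste0("L", 1:5)))
  x <- genotype_matrix(calls, rep("p", n))
  dt <- diversity_table(x, rarefaction_size = 2 * n)
  expect_equal(dt$Ho, 1)
  expect_equal(dt$He, 0.5 * 2 * n / (2 * n - 1))
  expect_lt(dt$FIS, 0)
})

test_that("diversity table equals a hand computation on a 4x3 matrix", {
  calls <- rbind(c(0L, 1L, 2L),
                 c(1L, 1L, 2L),
                 c(0L, 0L, 1L),
                 c(2L, 1L, 2L))
  dimnames(calls) <- list(paste0("i", 1:4), paste0("L", 1:3))
  x <- genotype_matrix(calls, rep("p", 4))
  dt <- diversity_table(x, rarefaction_size = 8)
  p <- c(3, 3, 7) / 8
  ho <- c(1, 3, 1) / 4
  he <- 2 * p * (1 - p) * 8 / 7
  expect_equal(dt$Ho, mean(ho), tolerance = 1e-12)
  expect_equal(dt$He, mean(he), tolerance = 1e-12)
  expect_equal(dt$FIS, 1 - sum(ho) / sum(he), tolerance = 1e-12)
  expect_equal(dt$MLH, mean(ho), tolerance = 1e-12)
})

test_that("sMLH is 1 for identical individuals and matches hand computation", {
  calls <- matrix(rep(c(0L, 1L, 1L, 2L), 3), 4, 3,
                  dimnames = list(paste0("i", 1:4), paste0("L", 1:3)))
  x <- genotype_matrix(calls, rep("p", 4))
  # het counts (0,3,3,0) over summed per-locus mean heterozygosity 3*0.5
  expect_equal(unname(smlh(x)), c(0, 2, 2, 0), tolerance = 1e-12)
  # all individuals identical -> every value 1
  calls2 <- matrix(1L, 5, 4, dimnames = list(paste0("i", 1:5),
                                             paste0("L", 1:4)))
  expect_equal(unname(smlh(genotype_matrix(calls2, rep("p", 5)))), rep(1, 5))
  # 3x2 with one missing call: explicit arithmetic
  calls3 <- rbind(c(1L, 0L), c(1L, MISSING), c(0L, 2L))
  dimnames(calls3) <- list(paste0("i", 1:3), c("A", "B"))
  s <- smlh(genotype_matrix(calls3, rep("p", 3)))
  mh <- c(2 / 3, 0)  # mean observed het per locus among typed
  expect_equal(unname(s),
               c(1 / sum(mh), 1 / mh[1], 0), tolerance = 1e-12)
  # population mean of sMLH is ~1 without missing data
  x4 <- random_matrix(20, 50, seed = 6)
  expect_equal(mean(smlh(x4)), 1, tolerance = 1e-6)
})

test_that("rarefied allelic richness equals the subsample enumeration", {
  # monomorphic data: exactly one allele whatever the subsample
  calls <- matrix(0L, 6, 3, dimnames = list(paste0("i", 1:6),
                                            paste0("L", 1:3)))
  ar <- allelic_richness(genotype_matrix(calls, rep("p", 6)), g = 6)
  expect_equal(ar$table$AR, 1)
  # 2-locus toy vs exhaustive enumeration over all g-subsets of gene copies
  calls2 <- rbind(c(0L, 1L), c(1L, 1L), c(2L, 0L), c(0L, 2L))
  dimnames(calls2) <- list(paste0("i", 1:4), c("A", "B"))
  x <- genotype_matrix(calls2, rep("p", 4))
  g <- 5
  oracle <- vapply(1:2, function(l) {
    copies <- unlist(lapply(calls2[, l], function(gt)
      c(rep(1, gt), rep(0, 2 - gt))))
    subs <- combn(length(copies), g)
    mean(apply(subs, 2, function(s) length(unique(copies[s]))))
  }, 0)
  got <- allelic_richness(x, g = g)$per_locus$p
  expect_equal(unname(got), oracle, tolerance = 1e-12)
})

test_that("pairwise Weir-Cockerham theta hits its null and fixation limits", {
  # same allele frequencies in both labels -> theta about 0
  x <- random_matrix(100, 500, n_pops = 2, seed = 12)
  fst <- wc_fst_pairwise(x, n_permutations = 0)
  expect_lt(abs(fst$fst["pop1", "pop2"]), 0.01)
  # fixed difference at every locus -> theta = 1
  calls <- rbind(matrix(0L, 10, 20), matrix(2L, 10, 20))
  dimnames(calls) <- list(paste0("i", 1:20), paste0("L", 1:20))
  y <- genotype_matrix(calls, rep(c("a", "b"), each = 10))
  expect_equal(unname(wc_fst_pairwise(y, 0)$fst["a", "b"]), 1)
  # permutation p-value is significant for structured data
  z <- simulate_island_genotypes(2, 2, 20, 200, seed = 3)
  pf <- wc_fst_pairwise(z, n_permutations = 99, seed = 1)
  expect_lt(pf$p_value["deme1", "deme2"], 0.05)
})

test_that("AMOVA components match a hand computation and the null", {
  # 6 individuals, 2 populations, 1 locus: gametic sums of squares by hand
  calls <- matrix(c(0L, 1L, 0L, 2L, 2L, 1L), 6, 1,
                  dimnames = list(paste0("i", 1:6), "L1"))
  x <- genotype_matrix(calls, rep(c("a", "b"), each = 3))
  res <- amova(x, n_permutations = 0)
  # SS on 0/1 gene copies: total 6 alt of 12, 1 of 6 and 5 of 6 per pop,
  # 2 heterozygous individuals
  ss_total <- 6 * 6 / 12
  ss_wp <- 1 * 5 / 6 + 5 * 1 / 6
  ss_wi <- 2 / 2
  sigma_w <- ss_wi / 6
  sigma_b <- ((ss_wp - ss_wi) / 4 - sigma_w) / 2
  c_a <- (12 - (36 + 36) / 12) / 1
  sigma_a <- ((ss_total - ss_wp) / 1 - sigma_w - 2 * sigma_b) / c_a
  expect_equal(unname(res$components["within_individuals"]), sigma_w,
               tolerance = 1e-12)
  expect_equal(unname(res$components["among_individuals"]), sigma_b,
               tolerance = 1e-12)
  expect_equal(unname(res$components["among"]), sigma_a, tolerance = 1e-12)
  expect_equal(res$fst, sigma_a / (sigma_a + sigma_b + sigma_w),
               tolerance = 1e-12)

  # one population split at random in two -> FST ~ 0, p large
  y <- random_matrix(40, 200, n_pops = 1, seed = 13)
  set.seed(4)
  pops <- sample(rep(c("u", "v"), each = 20))
  y2 <- genotype_matrix(y$calls, setNames(pops, rownames(y$calls)))
  res2 <- amova(y2, n_permutations = 99, seed = 2)
  expect_lt(abs(res2$fst), 0.02)
  expect_gt(res2$p_value, 0.05)
})

test_that("AMOVA FST and Weir-Cockerham theta agree on balanced data", {
  x <- simulate_island_genotypes(2, 6, 25, 800, seed = 21)
  a <- amova(x, n_permutations = 0)$fst
  w <- snpdemog:::wc_theta_multilocus(x$calls, x$population)
  expect_lt(abs(a - w), 0.02)
})

test_that("PhiST spans its 0 and 1 limits and matches direct recomputation", {
  # both populations sample the same haplotype pool
  aln0 <- simulate_mtdna(0, n_per_pop = 8, seq_length = 300, seed = 5,
                         within_divergence = 4)
  p0 <- phi_st(aln0, n_permutations = 49, seed = 1)
  expect_lt(abs(p0$fst), 0.15)
  expect_gt(p0$p_value, 0.05)
  # two fully distinct clades with zero within-clade diversity
  aln1 <- simulate_mtdna(8, n_per_pop = 5, seq_length = 300, seed = 6,
                         within_divergence = 0)
  expect_equal(phi_st(aln1, n_permutations = 0)$fst, 1)
  # known-divergence alignment equals an independent variance-component
  # recomputation from the pairwise-difference matrix
  aln <- simulate_mtdna(10, n_per_pop = 6, seq_length = 400, seed = 7,
                        within_divergence = 2)
  res <- phi_st(aln, n_permutations = 0)
  seqs <- strsplit(aln$sequences, "")
  n <- length(seqs)
  d2 <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    d2[i, j] <- d2[j, i] <- sum(seqs[[i]] != seqs[[j]])
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- sum(d2[1:6, 1:6][upper.tri(diag(6))]) / 6 +
    sum(d2[7:12, 7:12][upper.tri(diag(6))]) / 6
  sw <- ssw / (n - 2)
  sa <- ((sst - ssw) - sw) / 6
  expect_equal(res$fst, sa / (sa + sw), tolerance = 1e-12)
})

test_that("statistics are invariant to individual and locus ordering", {
  x <- random_matrix(14, 25, n_pops = 2, miss_rate = 0.05, seed = 30)
  set.seed(31)
  y <- x[sample(rownames(x$calls)), sample(colnames(x$calls))]
  expect_equal(snpdemog:::wc_theta_multilocus(x$calls, x$population),
               snpdemog:::wc_theta_multilocus(y$calls, y$population),
               tolerance = 1e-12)
  dx <- diversity_table(x); dy <- diversity_table(y)
  expect_equal(dx$He, dy$He, tolerance = 1e-12)
  expect_equal(amova(x, 0)$fst, amova(y, 0)$fst, tolerance = 1e-12)
})

test_that("island-model theta approaches the migration-drift expectation", {
  # d-deme island model: FST ~ 1/(1 + 4Nm (d/(d-1))^2), with 4Nm the total
  # scaled immigration per deme
  x <- simulate_island_genotypes(2, 9, 25, 4000, seed = 17)
  th <- snpdemog:::wc_theta_multilocus(x$calls, x$population)
  expect_lt(abs(th - 1 / (1 + 9 * 4)), 0.02)
})
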