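test_that("K = 1 reduces to observed allele frequencies in closed form", {
  x <- random_matrix(15, 40, seed = 2)
  fit <- admixture_fit(x, K = 1, seed = 1, n_restarts = 1)
  expect_true(all(abs(fit$Q - 1) < 1e-8))
  p <- colMeans(x$calls) / 2
  expect_equal(unname(fit$F[1, ]), unname(p), tolerance = 1e-4)
  g <- x$calls
  ll <- sum(ifelse(g == 1, log(2), 0) + g * log(rep(p, each = 15)) +
              (2 - g) * log(rep(1 - p, each = 15)))
  expect_equal(fit$loglik, ll, tolerance = 1e-3)
})

test_that("EM log-likelihood is monotone and Q rows sum to one", {
  x <- simulate_island_genotypes(2, 4, 15, 200, seed = 5)
  fit <- admixture_fit(x, K = 2, seed = 3, n_restarts = 1)
  expect_true(all(diff(fit$trace) > -1e-6))
  expect_equal(unname(rowSums(fit$Q)), rep(1, nrow(fit$Q)), tolerance = 1e-8)
  # relabeling clusters leaves the likelihood unchanged
  ll_perm <- snpdemog:::admix_loglik(snpdemog:::calls_na(x),
                                     fit$Q[, 2:1], fit$F[2:1, ])
  expect_equal(ll_perm, snpdemog:::admix_loglik(snpdemog:::calls_na(x),
                                                fit$Q, fit$F),
               tolerance = 1e-9)
})

test_that("cross-validation selects the true number of clusters", {
  sp <- model_spec("S_nomig")
  x <- simulate_genotypes(sp, c(nu1 = 1, nu2 = 1, T1 = 0.4), 15, 400,
                          seed = 9)
  ce <- choose_k(x, K_range = 1:3, n_folds = 3, seed = 4, max_iter = 300)
  expect_equal(ce$K[which.min(ce$cross_entropy)], 2)
  # no structure: K = 1 is not beaten
  y <- random_matrix(24, 300, n_pops = 1, seed = 10)
  ce1 <- choose_k(y, K_range = 1:2, n_folds = 3, seed = 5, max_iter = 300)
  expect_lte(ce1$cross_entropy[1], ce1$cross_entropy[2] + 0.002)
})

test_that("top-FST locus ranking recovers planted fixed differences", {
  x <- random_matrix(40, 500, n_pops = 2, seed = 6)
  planted <- sample(colnames(x$calls), 10)
  calls <- x$calls
  calls[x$population == "pop1", planted] <- 0L
  calls[x$population == "pop2", planted] <- 2L
  y <- genotype_matrix(calls, x$population)
  top <- top_fst_loci(y, "pop1", "pop2", n = 10)
  expect_setequal(top, planted)
  # n = n_loci returns every locus
  expect_setequal(top_fst_loci(y, "pop1", "pop2", n = 500),
                  colnames(calls))
  # the conventional default panel size
  expect_equal(eval(formals(top_fst_loci)$n), 300)
})

test_that("hybrid category table is closed and correctly shaped", {
  h <- hybrid_categories()
  expect_equal(h$g00 + h$g01 + h$g11, rep(1, 6))
  expect_identical(h$name, c("P0", "P1", "F1", "F2", "BC0", "BC1"))
  expect_equal(h[h$name == "F2", c("g00", "g01", "g11")],
               data.frame(g00 = 0.25, g01 = 0.5, g11 = 0.25, row.names = 4L))
})

test_that("an all-heterozygous individual with fixed parents is an F1", {
  cfg <- swarm_config(c(P0 = 10, P1 = 10, F1 = 2), n_loci = 100,
                      fixed_difference = 1, seed = 21)
  x <- simulate_hybrid_swarm(cfg)
  res <- hybrid_classify(x, parental = c("P0", "P1"), sweeps = 800,
                         burnin = 200, thin = 5, n_chains = 2, seed = 3)
  expect_equal(unname(rowSums(res$posterior)), rep(1, nrow(res$posterior)),
               tolerance = 1e-8)
  f1 <- rownames(res$posterior)[x$population == "F1"]
  expect_true(all(res$posterior[f1, "F1"] >= 0.99))
  expect_true(all(res$modal[f1] == "F1"))
})

test_that("backcrosses are recovered from a simulated swarm", {
  cfg <- swarm_config(c(P0 = 15, P1 = 15, BC0 = 20), n_loci = 300,
                      target_fst = 0.3, seed = 8)
  x <- simulate_hybrid_swarm(cfg)
  res <- hybrid_classify(x, parental = c("P0", "P1"), sweeps = 1200,
                         burnin = 300, thin = 5, n_chains = 2, seed = 5)
  bc <- rownames(res$posterior)[x$population == "BC0"]
  expect_gte(mean(res$modal[bc] == "BC0"), 0.9)
})
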