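test_that("generators are bit-identical under a fixed seed", {
  sp <- model_spec("S_asymig")
  p <- c(nu1 = 1, nu2 = 0.5, m12 = 1, m21 = 2, T1 = 0.8)
  expect_identical(simulate_genotypes(sp, p, 8, 100, seed = 5)$calls,
                   simulate_genotypes(sp, p, 8, 100, seed = 5)$calls)
  cfg <- swarm_config(c(P0 = 5, F1 = 5), 50, fixed_difference = 0.5, seed = 2)
  expect_identical(simulate_hybrid_swarm(cfg)$calls,
                   simulate_hybrid_swarm(cfg)$calls)
  expect_identical(simulate_mtdna(4, 3, 100, seed = 9)$sequences,
                   simulate_mtdna(4, 3, 100, seed = 9)$sequences)
  fx1 <- make_qc_fixture(seed = 4); fx2 <- make_qc_fixture(seed = 4)
  expect_identical(fx1$matrix$calls, fx2$matrix$calls)
})

test_that("panmictic and island-model genotypes match their expectations", {
  g <- simulate_genotypes(model_spec("SNM_split"), c(T1 = 1e-9), 20, 1500,
                          seed = 7)
  expect_lt(abs(snpdemog:::wc_theta_multilocus(g$calls, g$population)), 0.01)
  expect_true(all(colSums(g$calls) > 0))  # every locus segregates
  # 2-deme island model at total immigration 9: 1/(1 + 9 * (d/(d-1))^2)
  gi <- simulate_island_genotypes(2, 9, 25, 3000, seed = 8)
  expect_lt(abs(snpdemog:::wc_theta_multilocus(gi$calls, gi$population) -
                  1 / 37), 0.02)
})

test_that("hybrid swarm genotypes follow Mendelian expectations", {
  cfg <- swarm_config(c(P0 = 30, P1 = 30, F1 = 20, F2 = 40), n_loci = 400,
                      fixed_difference = 1, seed = 11)
  x <- simulate_hybrid_swarm(cfg)
  f1 <- x$calls[x$population == "F1", ]
  expect_true(all(f1 == 1L))
  f2 <- x$calls[x$population == "F2", ]
  expect_lt(abs(mean(f2 == 1L) - 0.5), 3 / sqrt(length(f2)))
  # pure parentals are in Hardy-Weinberg equilibrium
  cfg2 <- swarm_config(c(P0 = 50), n_loci = 300, target_fst = 0.2, seed = 12)
  y <- simulate_hybrid_swarm(cfg2)
  pvals <- apply(y$calls, 2, function(g)
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2)))
  expect_gte(mean(pvals >= 1e-5), 0.99)
})

test_that("QC fixture per-step removals match the planted violations", {
  fx <- make_qc_fixture(seed = 6)
  out <- apply_filters(fx$matrix, fx$metadata)
  rep <- out$report
  removed <- setNames(rep$loci_removed, rep$step)
  expect_equal(removed[["monomorphic"]], 3)
  expect_equal(removed[["locus_call_rate"]], 3)
  expect_equal(rep$individuals_removed[rep$step == "indiv_call_rate"], 2)
  expect_equal(removed[["min_depth"]], 3)
  expect_equal(removed[["repeatability"]], 3)
  expect_equal(removed[["one_snp_per_tag"]], 2)
  expect_equal(removed[["hamming"]], 1)
  expect_equal(removed[["hwe"]], 2)
  expect_equal(removed[["ld_prune"]], 2)
  expect_equal(removed[["locus_missingness"]], 1)
  expect_equal(removed[["maf"]], 2)
})

test_that("mtDNA divergence drives PhiST monotonically", {
  aln <- simulate_mtdna(0, 6, 400, seed = 3, within_divergence = 2)
  expect_lt(abs(phi_st(aln, n_permutations = 0)$fst), 0.2)
  aln2 <- simulate_mtdna(10, 6, 400, seed = 3, within_divergence = 0)
  expect_equal(phi_st(aln2, n_permutations = 0)$fst, 1)
  phis <- vapply(c(0.5, 2, 8, 24, 60), function(dv)
    phi_st(simulate_mtdna(dv, 8, 500, seed = 13, within_divergence = 3),
           n_permutations = 0)$fst, 0)
  expect_true(all(diff(phis) > 0))
})

test_that("the two coalescent readouts cross-validate on every model", {
  cases <- list(
    list(m = "SNM_split", p = c(T1 = 0.6)),
    list(m = "S_nomig", p = c(nu1 = 2, nu2 = 0.4, T1 = 0.7)),
    list(m = "S_asymig", p = c(nu1 = 1, nu2 = 0.6, m12 = 1.5, m21 = 0.3,
                               T1 = 1)),
    list(m = "S_nomig_secont", p = c(nu1 = 1, nu2 = 0.5, m12 = 2, m21 = 1,
                                     T1 = 2, T2 = 0.2)),
    list(m = "secont_asymig_size", p = c(nu1 = 2, nu2 = 0.5, nu1b = 0.8,
                                         nu2b = 0.8, m12 = 1, m21 = 2,
                                         T1 = 1.5, T2 = 0.2)),
    list(m = "S_asymig_size", p = c(nu1 = 1.5, nu2 = 0.7, nu1b = 1.2,
                                    nu2b = 0.4, m12 = 2, m21 = 4,
                                    T1 = 0.5, T2 = 0.2)),
    list(m = "S_nomig_size", p = c(nu1 = 2, nu2 = 0.8, nu1b = 1.2,
                                   nu2b = 0.3, T1 = 1, T2 = 0.3)))
  for (cs in cases) {
    sp <- model_spec(cs$m)
    g <- simulate_genotypes(sp, cs$p, 8, 6000, seed = 19)
    emp <- afs_from_matrix(g, "pop1", "pop2", c(16, 16))
    exp_afs <- fold_afs(expected_afs(sp, cs$p, c(16, 16),
                                     n_replicates = 40000, seed = 20))
    pe <- emp$entries[!emp$mask] / afs_total(emp)
    pm <- exp_afs$entries[!exp_afs$mask] / afs_total(exp_afs)
    # total-variation distance between the two normalized spectra; the
    # multinomial sampling scale at 6000 loci over ~140 cells is ~0.036
    tv <- sum(abs(pe - pm)) / 2
    expect_lt(tv, 0.07)
  }
})
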