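test_that("spectrum construction localizes fixed differences and folds them", {
  # one locus fixed-different between the populations at projection (4, 4)
  calls <- rbind(matrix(0L, 4, 1), matrix(2L, 4, 1))
  dimnames(calls) <- list(paste0("i", 1:8), "L1")
  x <- genotype_matrix(calls, rep(c("a", "b"), each = 4))
  afs <- afs_from_matrix(x, "a", "b", c(4, 4))
  expect_equal(afs_total(afs), 1)
  # mass folds onto the minor-allele cell of the (0,4)/(4,0) pair
  expect_equal(afs$entries[1, 5] + afs$entries[5, 1], 1)
})

test_that("projection to own size is the identity and conserves mass", {
  set.seed(3)
  e <- matrix(rexp(9 * 7), 9, 7)
  afs <- joint_afs(e)
  same <- project_afs(afs, 8, 6)
  expect_equal(same$entries, e, tolerance = 1e-12)
  down <- project_afs(afs, 5, 4)
  expect_equal(sum(down$entries), sum(e), tolerance = 1e-10)
  folded <- fold_afs(afs)
  expect_equal(afs_total(folded),
               sum(e) - e[1, 1] - e[9, 7], tolerance = 1e-12)
})

test_that("matrix projection equals the subsample enumeration oracle", {
  x <- random_matrix(8, 50, n_pops = 2, miss_rate = 0.05, seed = 14)
  proj <- c(6, 6)
  got <- afs_from_matrix(x, "pop1", "pop2", proj)
  # oracle: average the folded spectrum over every subsample of gene copies
  ent <- matrix(0, proj[1] + 1, proj[2] + 1)
  dropped <- 0
  for (l in seq_len(ncol(x$calls))) {
    copies <- lapply(c("pop1", "pop2"), function(pp) {
      g <- x$calls[x$population == pp, l]
      g <- g[g != MISSING]
      unlist(lapply(g, function(gt) c(rep(1, gt), rep(0, 2 - gt))))
    })
    if (length(copies[[1]]) < proj[1] || length(copies[[2]]) < proj[2]) {
      dropped <- dropped + 1
      next
    }
    s1 <- combn(length(copies[[1]]), proj[1])
    s2 <- combn(length(copies[[2]]), proj[2])
    w1 <- tabulate(apply(s1, 2, function(s) sum(copies[[1]][s])) + 1,
                   proj[1] + 1) / ncol(s1)
    w2 <- tabulate(apply(s2, 2, function(s) sum(copies[[2]][s])) + 1,
                   proj[2] + 1) / ncol(s2)
    ent <- ent + w1 %o% w2
  }
  oracle <- fold_afs(joint_afs(ent))
  expect_equal(got$entries, oracle$entries, tolerance = 1e-10)
  expect_equal(attr(got, "n_dropped"), dropped)
})

test_that("constant-size spectrum is proportional to 1/i", {
  e <- expected_afs(model_spec("SNM_split"), c(T1 = 1e-9), c(12, 0),
                    n_replicates = 60000, seed = 5)
  sfs <- rowSums(e$entries)[2:12]
  expect_equal(sfs / sfs[1], 1 / (1:11), tolerance = 0.05)
})

test_that("a vanishing split time recovers the panmictic spectrum", {
  sp <- model_spec("S_nomig")
  near0 <- expected_afs(sp, c(nu1 = 0.5, nu2 = 0.5, T1 = 1e-9), c(10, 10),
                        n_replicates = 40000, seed = 6)
  pan <- expected_afs(model_spec("SNM_split"), c(T1 = 1e-9), c(20, 0),
                      n_replicates = 40000, seed = 7)
  # pool the two-population spectrum by total derived count (note the
  # halved sizes double the coalescent clock)
  pooled <- vapply(0:20, function(k) {
    sum(near0$entries[outer(0:10, 0:10, `+`) == k])
  }, 0) / 2
  expect_equal(pooled[2:20] / pooled[2], rowSums(pan$entries)[2:20] /
                 rowSums(pan$entries)[2], tolerance = 0.12)
})

test_that("deep isolation leaves almost all polymorphism private", {
  e <- expected_afs(model_spec("S_nomig"),
                    c(nu1 = 1, nu2 = 1, T1 = 5), c(10, 10),
                    n_replicates = 20000, seed = 8)
  ent <- e$entries
  ent[1, 1] <- 0; ent[11, 11] <- 0
  private <- sum(ent[, 1]) + sum(ent[1, ])
  expect_gte(private / sum(ent), 0.95)
})

test_that("the composite likelihood profiles theta and honors the mask", {
  set.seed(9)
  m <- matrix(rexp(5 * 5) + 0.2, 5, 5)
  data <- joint_afs(3.7 * m, folded = FALSE)
  model <- joint_afs(m, folded = FALSE)
  res <- afs_loglik(data, model)
  expect_equal(res$theta_hat,
               sum(data$entries[!data$mask]) / sum(m[!model$mask]))
  # theta_hat maximizes the likelihood over rescalings
  lls <- vapply(seq(0.5, 2, by = 0.05), function(s) {
    mu <- res$theta_hat * s * m[!model$mask]
    sum(data$entries[!data$mask] * log(mu) - mu -
          lgamma(data$entries[!data$mask] + 1))
  }, 0)
  expect_equal(which.max(lls), which(abs(seq(0.5, 2, 0.05) - 1) < 1e-9))
  # hand-computed 2x2 (one unmasked-corner-free cell layout)
  d2 <- joint_afs(matrix(c(0, 3, 2, 0), 2, 2))
  m2 <- joint_afs(matrix(c(0, 1, 4, 0), 2, 2))
  r2 <- afs_loglik(d2, m2)
  th <- 5 / 5
  expect_equal(r2$loglik, 3 * log(th * 1) - th * 1 - lgamma(4) +
                 2 * log(th * 4) - th * 4 - lgamma(3), tolerance = 1e-12)
  # masked cells are inert
  d3 <- data; d3$entries[1, 1] <- 99; d3$entries[5, 5] <- 99
  expect_equal(afs_loglik(d3, model)$loglik, res$loglik)
})

test_that("epoch assembly validates the time ordering", {
  sp <- model_spec("S_nomig_secont")
  expect_error(expected_afs(sp, c(nu1 = 1, nu2 = 1, m12 = 1, m21 = 1,
                                  T1 = 0.1, T2 = 0.5), c(4, 4), 100, 1),
               "parameter-order")
})

test_that("a simple split model refits its own simulation", {
  sp <- model_spec("S_nomig")
  # a short split keeps plenty of shared ancestral polymorphism, which is
  # what pins the overall coalescent scale of (nu1, nu2, T1)
  truth <- c(nu1 = 1, nu2 = 1, T1 = 0.5)
  rec <- sapply(1:3, function(r) {
    g <- simulate_genotypes(sp, truth, 10, 2000, seed = 40 + r)
    d <- afs_from_matrix(g, "pop1", "pop2", c(20, 20))
    fit <- fit_model(d, sp, seed = 50 + r, n_screen = 25, n_start = 2,
                     n_perturb = 1, profile_levels = c(0.4, 2),
                     screen_replicates = 2000, search_replicates = 4000,
                     polish_replicates = 8000, finish_replicates = 15000,
                     maxit = 150)
    fit$params
  })
  expect_lt(abs(median(rec["T1", ]) - 0.5), 0.125)
  expect_lt(abs(median(rec["nu1", ]) - 1), 0.2)
  expect_lt(abs(median(rec["nu2", ]) - 1), 0.2)
})

test_that("AIC prefers the generating model over a constrained one", {
  sp_true <- model_spec("S_nomig")
  truth <- c(nu1 = 4, nu2 = 0.25, T1 = 1)
  wins <- 0
  for (r in 1:4) {
    g <- simulate_genotypes(sp_true, truth, 10, 1000, seed = 70 + r)
    d <- afs_from_matrix(g, "pop1", "pop2", c(20, 20))
    light <- list(n_screen = 20, n_start = 2, n_perturb = 1,
                  profile_levels = c(1),
                  screen_replicates = 2000, search_replicates = 3000,
                  polish_replicates = 6000, finish_replicates = 12000,
                  maxit = 120)
    f1 <- do.call(fit_model, c(list(d, sp_true, seed = 80 + r), light))
    f0 <- do.call(fit_model, c(list(d, model_spec("SNM_split"),
                                    seed = 90 + r), light))
    rank <- model_select(list(f1, f0))
    if (rank$model[1] == "S_nomig") wins <- wins + 1
  }
  expect_gte(wins, 3)
})

test_that("model ranking arithmetic follows AIC", {
  mk <- function(model, k, ll) structure(
    list(model = model, k = k, loglik = ll, AIC = 2 * k - 2 * ll,
         data_fingerprint = c(n1 = 20, n2 = 20, total = 100)),
    class = "fit_result")
  r <- model_select(list(mk("a", 4, -100), mk("b", 6, -100)))
  expect_equal(r$model, c("a", "b"))
  expect_equal(r$delta_AIC, c(0, 4))
  # two extra parameters buying only 2 log-likelihood units lose
  r2 <- model_select(list(mk("small", 4, -100), mk("big", 7, -98)))
  expect_equal(r2$model[1], "small")
  expect_equal(r2$delta_AIC[2], 2)
  r3 <- model_select(list(mk("only", 4, -10)))
  expect_equal(r3$weight, 1)
  expect_error(model_select(list(mk("a", 4, -1),
                                 structure(list(model = "x", k = 2,
                                                loglik = -1, AIC = 6,
                                                data_fingerprint =
                                                  c(n1 = 10, n2 = 10,
                                                    total = 5)),
                                           class = "fit_result"))),
               "different data")
})

test_that("unit conversion is exact and invertible", {
  mu <- 8e-8; L <- 5000
  expect_equal(to_biological_units(list(theta = 4 * mu * L), mu = mu,
                                   L = L)$N_ref, 1)
  pars <- list(theta = 481, nu1 = 0.26, nu2 = 0.1, m12 = 2.15, m21 = 22.39,
               T1 = 14.91, T2 = 0.148)
  rep <- to_biological_units(pars, mu = mu, L = L, generation_time = 6)
  back <- from_biological_units(rep)
  for (nm in c("theta", "T1", "T2", "m12", "m21"))
    expect_equal(back[[nm]], pars[[nm]], tolerance = 1e-10)
  expect_equal(eval(formals(to_biological_units)$mu), 8e-8)
})

test_that("rejection ABC is symmetric for identical candidates and finds the truth", {
  sp <- model_spec("S_nomig")
  truth <- c(nu1 = 1, nu2 = 0.2, T1 = 1.5)
  g <- simulate_genotypes(sp, truth, 15, 400, seed = 100)
  pri <- list(nu1 = c(0.05, 10), nu2 = c(0.05, 10), T1 = c(0.05, 10),
              m12 = c(0.01, 20), m21 = c(0.01, 20))
  twin <- abc_model_choice(g, list(sp, sp), pri, n_sims_per_model = 150,
                           tolerance = 0.1, seed = 7, n_per_pop = 15,
                           n_loci = 400)
  expect_lt(abs(twin$posterior[1] - 0.5), 0.25)
  # truth (isolation) vs a heavily migrating alternative
  duel <- abc_model_choice(g, list(sp, model_spec("S_asymig")), pri,
                           n_sims_per_model = 250, tolerance = 0.06,
                           seed = 8, n_per_pop = 15, n_loci = 400)
  expect_gt(duel$posterior["S_nomig"], 0.5)
  expect_true(duel$gof_quantile >= 0 && duel$gof_quantile <= 1)
})
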