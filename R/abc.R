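# Rejection-ABC model choice as an independent cross-check on the
# composite-likelihood model selection: candidate demographic scenarios are
# simulated with parameters drawn from log-uniform priors, reduced to summary
# statistics, and the posterior model probabilities are the per-model shares
# of the accepted (nearest) simulations.

#' Summary statistics of a two-population genotype matrix
#'
#' The ABC summary vector: per-population mean expected heterozygosity,
#' multilocus Weir-Cockerham FST, per-population private-polymorphism
#' fractions, per-population mean minor-allele frequency, and quartiles of
#' the pooled minor-allele frequency distribution.
#'
#' @param x a [genotype_matrix()] with exactly two populations.
#' @return named numeric vector of 10 summaries.
#' @export
genotype_summaries <- function(x) {
  pops <- unique(x$population)
  if (length(pops) != 2) stop("exactly two populations expected")
  m <- calls_na(x)
  stats_of <- function(pp) {
    sub <- m[x$population == pp, , drop = FALSE]
    n <- colSums(!is.na(sub))
    p <- colSums(sub, na.rm = TRUE) / (2 * pmax(n, 1))
    he <- 2 * p * (1 - p) * (2 * n) / pmax(2 * n - 1, 1)
    list(he = mean(he[n > 0]), p = p, poly = p > 0 & p < 1)
  }
  s1 <- stats_of(pops[1]); s2 <- stats_of(pops[2])
  fst <- wc_theta_multilocus(x$calls, x$population)
  pool_p <- colMeans(m, na.rm = TRUE) / 2
  pool_maf <- pmin(pool_p, 1 - pool_p)
  qs <- quantile(pool_maf, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  c(he1 = s1$he, he2 = s2$he, fst = fst,
    private1 = mean(s1$poly & !s2$poly),
    private2 = mean(s2$poly & !s1$poly),
    maf1 = mean(pmin(s1$p, 1 - s1$p)),
    maf2 = mean(pmin(s2$p, 1 - s2$p)),
    maf_q25 = qs[1], maf_q50 = qs[2], maf_q75 = qs[3])
}

#' Rejection-ABC model choice over demographic scenarios
#'
#' For each candidate model, parameters are drawn from log-uniform priors and
#' genotypes simulated with [simulate_genotypes()]; summaries are compared to
#' the observed ones by Euclidean distance after normalizing every summary by
#' its SD across all simulations.  The nearest `tolerance` fraction is
#' accepted; the posterior probability of each model is its share of the
#' accepted set.  Goodness-of-fit for the best model is the
#' posterior-predictive quantile of the observed distance to the accepted
#' cloud's centroid.
#'
#' @param data a two-population [genotype_matrix()] (or a named summary
#'   vector as produced by [genotype_summaries()]).
#' @param specs list of [model_spec()] candidates.
#' @param priors named list of `c(lower, upper)` prior ranges (log-uniform);
#'   must cover every free parameter of every candidate.
#' @param n_sims_per_model simulations per candidate (production default
#'   1e6; use ~1e4 or less interactively).
#' @param tolerance accepted fraction of all simulations (default 0.01).
#' @param seed integer seed.
#' @param n_per_pop,n_loci size of each simulated dataset (defaults 20
#'   diploids per population, 500 loci).
#' @return list with `posterior` (named model probabilities), `n_accepted`,
#'   `best_model`, `gof_quantile`, and the accepted parameter draws per model.
#' @export
abc_model_choice <- function(data, specs, priors, n_sims_per_model = 1e6,
                             tolerance = 0.01, seed = 1, n_per_pop = 20,
                             n_loci = 500) {
  obs <- if (inherits(data, "genotype_matrix")) genotype_summaries(data)
         else data
  set.seed(seed)
  names(specs) <- make.unique(vapply(specs, `[[`, "", "name"))
  draws <- list(); sums <- list(); model_of <- character(0)
  sim_seed <- sample.int(2^31 - 1, length(specs) * n_sims_per_model)
  row <- 0L
  for (spec_name in names(specs)) {
    ms <- specs[[spec_name]]
    need <- ms$free_params
    if (!all(need %in% names(priors)))
      stop("priors missing for: ",
           paste(setdiff(need, names(priors)), collapse = ", "))
    for (s in seq_len(n_sims_per_model)) {
      row <- row + 1L
      repeat {
        pars <- vapply(need, function(nm) {
          rg <- priors[[nm]]
          exp(runif(1, log(rg[1]), log(rg[2])))
        }, 0)
        if (!("T2" %in% need) || pars["T1"] > pars["T2"]) break
      }
      g <- simulate_genotypes(ms, pars, n_per_pop, n_loci,
                              seed = sim_seed[row])
      draws[[row]] <- pars
      sums[[row]] <- genotype_summaries(g)
      model_of[row] <- spec_name
    }
  }
  S <- do.call(rbind, sums)
  sds <- apply(S, 2, sd)
  sds[sds == 0 | !is.finite(sds)] <- 1
  Z <- sweep(S, 2, sds, "/")
  zobs <- obs[colnames(S)] / sds
  dist <- sqrt(rowSums(sweep(Z, 2, zobs)^2))
  n_acc <- max(1L, floor(tolerance * length(dist)))
  if (n_acc < 1) {
    warning("no acceptances at the requested tolerance; widening")
    n_acc <- 1L
  }
  acc <- order(dist)[seq_len(n_acc)]
  post <- table(factor(model_of[acc], levels = names(specs))) / n_acc
  best <- names(which.max(post))
  # goodness of fit: observed distance to the accepted centroid, as a
  # quantile of the accepted points' own distances to that centroid
  accZ <- Z[acc, , drop = FALSE]
  ctr <- colMeans(accZ)
  d_acc <- sqrt(rowSums(sweep(accZ, 2, ctr)^2))
  d_obs <- sqrt(sum((zobs - ctr)^2))
  gof <- mean(d_acc >= d_obs)
  list(posterior = c(post), n_accepted = n_acc, best_model = best,
       gof_quantile = gof,
       accepted = split(draws[acc], model_of[acc]))
}
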