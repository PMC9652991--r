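# Shared fixtures: small genotype matrices built in code.

# random genotype matrix with optional missingness
random_matrix <- function(n_ind = 10, n_loci = 20, n_pops = 2,
                          miss_rate = 0, seed = 1) {
  set.seed(seed)
  calls <- matrix(rbinom(n_ind * n_loci, 2, runif(n_loci, 0.2, 0.8)[
    rep(seq_len(n_loci), each = n_ind)]), n_ind, n_loci)
  if (miss_rate > 0)
    calls[runif(n_ind * n_loci) < miss_rate] <- MISSING
  pops <- rep(paste0("pop", seq_len(n_pops)), length.out = n_ind)
  rownames(calls) <- paste0("ind", seq_len(n_ind))
  colnames(calls) <- paste0("L", seq_len(n_loci))
  genotype_matrix(calls, setNames(pops, rownames(calls)))
}

# flip the allele orientation (0 <-> 2) of selected loci
flip_loci <- function(x, loci) {
  calls <- x$calls
  for (l in loci) {
    g <- calls[, l]
    calls[, l] <- ifelse(g == MISSING, MISSING, 2L - g)
  }
  genotype_matrix(calls, x$population)
}

# independent HWE exact-test oracle: exact enumeration with choose()
# products over all compatible heterozygote counts
oracle_hwe_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  na <- 2 * n2 + n1
  nm <- min(na, 2 * n - na)
  if (nm == 0) return(1)
  hs <- seq(nm %% 2, nm, by = 2)
  w <- vapply(hs, function(h) {
    choose(n, (nm - h) / 2) * choose(n - (nm - h) / 2, h) * 2^h
  }, 0)
  p <- w / sum(w)
  obs <- p[hs == n1]
  sum(p[p <= obs * (1 + 1e-12)])
}
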