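# FDIST-style outlier detection: a coalescent null of (He, FST) pairs is
# simulated under a hierarchical island model whose migration rates are
# calibrated so that the realized mean FST matches the observed multilocus
# FST; observed loci are then scored against the conditional null
# distribution of FST given heterozygosity, with Benjamini-Hochberg FDR
# control.

# epochs for a stationary island model
island_epochs <- function(nu, M) {
  d <- length(nu)
  list(list(t_end = Inf, popmap = seq_len(d), nu = nu,
            M = as.matrix(M)))
}

# hierarchical island migration matrix: each deme receives total scaled
# migration mw from the other demes of its group and mb from all demes of
# other groups (split equally among sources)
hier_island_matrix <- function(n_groups, demes_per_group, mw, mb) {
  d <- n_groups * demes_per_group
  grp <- rep(seq_len(n_groups), each = demes_per_group)
  M <- matrix(0, d, d)
  for (a in seq_len(d)) for (b in seq_len(d)) {
    if (a == b) next
    M[a, b] <- if (grp[a] == grp[b]) mw / (demes_per_group - 1) else
      mb / (d - demes_per_group)
  }
  M
}

# per-locus n/p/h matrices from the C++ genotype-count output
np_from_counts <- function(counts, npop) {
  L <- nrow(counts)
  n_mat <- p_mat <- h_mat <- matrix(0, npop, L)
  for (p in seq_len(npop)) {
    n0 <- counts[, 3 * p - 2]; n1 <- counts[, 3 * p - 1]; n2 <- counts[, 3 * p]
    n <- n0 + n1 + n2
    n_mat[p, ] <- n
    p_mat[p, ] <- (n1 + 2 * n2) / (2 * pmax(n, 1))
    h_mat[p, ] <- n1 / pmax(n, 1)
  }
  list(n = n_mat, p = p_mat, h = h_mat)
}

# sample-size-weighted mean unbiased within-population expected
# heterozygosity, per locus
hs_from_np <- function(np) {
  n <- np$n; p <- np$p
  he <- 2 * p * (1 - p) * (2 * n) / pmax(2 * n - 1, 1)
  colSums(n * he) / pmax(colSums(n), 1)
}

# observed per-locus (theta, Hs) for a genotype matrix
locus_theta_hs <- function(x) {
  pops <- unique(x$population)
  n_mat <- p_mat <- h_mat <- matrix(0, length(pops), ncol(x$calls))
  for (k in seq_along(pops)) {
    sub <- x$calls[x$population == pops[k], , drop = FALSE]
    sub[sub == MISSING] <- NA_integer_
    n_mat[k, ] <- colSums(!is.na(sub))
    p_mat[k, ] <- colSums(sub, na.rm = TRUE) / (2 * pmax(n_mat[k, ], 1))
    h_mat[k, ] <- colSums(sub == 1L, na.rm = TRUE) / pmax(n_mat[k, ], 1)
  }
  comp <- wc_abc(n_mat, p_mat, h_mat)
  den <- comp$a + comp$b + comp$c
  theta <- comp$a / den
  theta[!is.finite(theta)] <- NA_real_
  hs <- hs_from_np(list(n = n_mat, p = p_mat))
  mtheta <- sum(comp$a, na.rm = TRUE) /
    sum(den[!is.na(comp$a)], na.rm = TRUE)
  list(theta = theta, hs = hs, multilocus = mtheta)
}

# simulate n_loci island-model loci; returns list(theta, hs, multilocus)
fdist_simulate <- function(epochs, sample_sizes, sample_demes, n_loci, seed) {
  counts <- .coal_sim_genotype_counts_cpp(as.integer(sample_sizes),
                                          as.integer(sample_demes),
                                          epochs, as.integer(n_loci), seed)
  np <- np_from_counts(counts, length(sample_sizes))
  comp <- wc_abc(np$n, np$p, np$h)
  den <- comp$a + comp$b + comp$c
  theta <- comp$a / den
  theta[!is.finite(theta)] <- NA_real_
  list(theta = theta, hs = hs_from_np(np),
       multilocus = sum(comp$a, na.rm = TRUE) /
         sum(den[!is.na(comp$a)], na.rm = TRUE))
}

#' Neutral (He, FST) null table under a hierarchical island model
#'
#' Simulates independent biallelic loci by structured coalescent under a
#' hierarchical island model (groups of demes, faster migration within than
#' between groups) and returns per-locus Weir-Cockerham FST and within-deme
#' expected heterozygosity.  When `target_fst` is given, a single multiplier
#' on the migration matrix is calibrated by bisection so that the realized
#' mean (multilocus) FST matches the target to within `calib_tol`.
#'
#' @param sample_sizes diploid sample sizes, one per sampled population.
#' @param target_fst observed multilocus FST the null should reproduce, or
#'   `NULL` to use the supplied rates as-is.
#' @param n_sims number of simulated loci in the final table (default 1e5).
#' @param seed integer seed.
#' @param n_groups,demes_per_group hierarchical island structure (2 x 5
#'   default).
#' @param migration_within,migration_between base scaled migration rates
#'   (2*N*m) received by each deme from its own group / other groups.
#' @param calib_loci loci per calibration iteration (default 1500).
#' @param calib_tol calibration tolerance on mean FST (default 0.005).
#' @param max_iter maximum calibration iterations (default 50).
#' @return data.frame with columns `he` and `fst`, one row per simulated
#'   locus, with attributes `realized_fst`, `migration_multiplier` and
#'   `calibration_trace`.
#' @export
fdist_null <- function(sample_sizes, target_fst = NULL, n_sims = 1e5,
                       seed = 1, n_groups = 2, demes_per_group = 5,
                       migration_within = 10, migration_between = 1,
                       calib_loci = 1500, calib_tol = 0.005, max_iter = 50) {
  if (n_sims < 1000) stop("n_sims must be >= 1000")
  d <- n_groups * demes_per_group
  npop <- length(sample_sizes)
  if (npop > d) stop("more sampled populations than demes")
  # spread sampled populations across groups
  i <- seq_len(npop) - 1
  sample_demes <- (i %% n_groups) * demes_per_group + (i %/% n_groups) + 1
  nu <- rep(1, d)
  base_M <- hier_island_matrix(n_groups, demes_per_group, migration_within,
                               migration_between)
  mult <- 1
  trace <- NULL
  if (!is.null(target_fst)) {
    f <- function(s, it) {
      eps <- island_epochs(nu, base_M * s)
      sim <- fdist_simulate(eps, sample_sizes, sample_demes, calib_loci,
                            seed + 7919 * it)
      sim$multilocus
    }
    # bracket on the migration multiplier: x50 in each direction spans mean
    # FST from ~0.002 to ~0.6 around the base rates while keeping the
    # strong-migration endpoint simulable (event counts scale with migration)
    lo <- 0.02; hi <- 50
    flo <- f(lo, 0); fhi <- f(hi, 1)
    if (!(flo > target_fst && fhi < target_fst))
      stop("calibration failed: target FST ", target_fst,
           " outside achievable range [", round(fhi, 4), ", ",
           round(flo, 4), "]")
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      mid <- sqrt(lo * hi)
      fm <- f(mid, it + 1)
      trace <- rbind(trace, data.frame(iter = it, multiplier = mid,
                                       mean_fst = fm))
      if (abs(fm - target_fst) <= calib_tol) { mult <- mid; converged <- TRUE
        break }
      if (fm > target_fst) lo <- mid else hi <- mid
      mult <- mid
    }
    if (!converged) {
      print(trace)
      stop("FST calibration did not converge in ", max_iter, " iterations")
    }
  }
  eps <- island_epochs(nu, base_M * mult)
  sim <- fdist_simulate(eps, sample_sizes, sample_demes, n_sims, seed)
  out <- data.frame(he = sim$hs, fst = sim$theta)
  attr(out, "realized_fst") <- sim$multilocus
  attr(out, "migration_multiplier") <- mult
  attr(out, "calibration_trace") <- trace
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up procedure (via [stats::p.adjust()]) with the rejection set
#' at level `alpha`.
#'
#' @param p_values numeric p-values in `(0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return list with `q` (monotone q-values) and `reject` (logical).
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  q <- p.adjust(p_values, method = "BH")
  list(q = q, reject = !is.na(q) & q <= alpha)
}

#' Scan loci for FST outliers against a simulated neutral null
#'
#' Each locus gets a two-sided empirical p-value for its FST conditional on
#' its heterozygosity: null loci are binned by He (width `bin_width`, adjacent
#' bins pooled until at least `min_bin` null points are available), and the
#' tail probabilities are computed within the pooled bin, with an exponential
#' tail fitted beyond the null's 95% quantile so extreme observations are not
#' floored at one over the table size.  Benjamini-Hochberg
#' q-values flag loci as `divergent` (high FST) or `balancing` (low FST) at
#' `fdr_alpha`; monomorphic or unbinnable loci are `untestable`.
#'
#' @param x a [genotype_matrix()].
#' @param null_table data.frame from [fdist_null()] (columns `he`, `fst`).
#' @param fdr_alpha FDR level (default 0.05).
#' @param bin_width He bin width (default 0.05).
#' @param min_bin minimum null points per (pooled) bin (default 50).
#' @return data.frame per locus: `locus`, `fst`, `he`, `p`, `q`, `flag`.
#' @export
outlier_scan <- function(x, null_table, fdr_alpha = 0.05, bin_width = 0.05,
                         min_bin = 50) {
  obs <- locus_theta_hs(x)
  out <- outlier_scan_stats(obs$theta, obs$hs, null_table, fdr_alpha,
                            bin_width, min_bin)
  out$locus <- colnames(x$calls)
  out[, c("locus", "fst", "he", "p", "q", "flag")]
}

# One-sided tail probability of `obs` against null draws, with an
# exponential tail fitted to the exceedances beyond the 95% quantile.
# Finite simulation tables floor empirical p-values at ~1/n, which makes a
# single extreme outlier undetectable after multiple-testing correction;
# smoothing the extreme tail (in the spirit of generalized-Pareto smoothing
# of permutation p-values) removes the floor while agreeing with the
# empirical estimate inside the null's support.
tail_p <- function(obs, null, upper = TRUE, tail_frac = 0.05) {
  n <- length(null)
  emp <- if (upper) (1 + sum(null >= obs)) / (1 + n) else
    (1 + sum(null <= obs)) / (1 + n)
  if (emp > tail_frac || n < 60) return(emp)
  if (upper) {
    u <- quantile(null, 1 - tail_frac, names = FALSE)
    exc <- null[null > u] - u
    if (length(exc) < 10 || mean(exc) <= 0) return(emp)
    max(1e-300, min(emp, tail_frac * exp(-(obs - u) / mean(exc))))
  } else {
    u <- quantile(null, tail_frac, names = FALSE)
    exc <- u - null[null < u]
    if (length(exc) < 10 || mean(exc) <= 0) return(emp)
    max(1e-300, min(emp, tail_frac * exp(-(u - obs) / mean(exc))))
  }
}

# core scan on precomputed per-locus (theta, hs)
outlier_scan_stats <- function(theta, hs, null_table, fdr_alpha = 0.05,
                               bin_width = 0.05, min_bin = 50) {
  if (nrow(null_table) < 1000) stop("null table needs >= 1000 entries")
  nt <- null_table[is.finite(null_table$fst) & is.finite(null_table$he), ]
  breaks <- seq(0, 0.5 + bin_width, by = bin_width)
  nbin <- length(breaks) - 1
  null_bin <- pmin(pmax(findInterval(nt$he, breaks, rightmost.closed = TRUE),
                        1), nbin)
  L <- length(theta)
  p <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    if (!is.finite(theta[l]) || !is.finite(hs[l]) || hs[l] <= 0)
      next
    b <- pmin(pmax(findInterval(hs[l], breaks, rightmost.closed = TRUE),
                   1), nbin)
    width <- 0
    repeat {
      sel <- null_bin >= b - width & null_bin <= b + width
      if (sum(sel) >= min_bin || (b - width < 1 && b + width > nbin)) break
      width <- width + 1
    }
    fst0 <- nt$fst[sel]
    if (length(fst0) < 2) next
    p_hi <- tail_p(theta[l], fst0, upper = TRUE)
    p_lo <- tail_p(theta[l], fst0, upper = FALSE)
    p[l] <- min(1, 2 * min(p_hi, p_lo))
  }
  fdr <- bh_fdr(ifelse(is.na(p), 1, p), fdr_alpha)
  q <- ifelse(is.na(p), NA_real_, fdr$q)
  flag <- rep("neutral", L)
  flag[is.na(p)] <- "untestable"
  med_fst <- median(nt$fst, na.rm = TRUE)
  sig <- !is.na(p) & fdr$reject
  flag[sig & theta > med_fst] <- "divergent"
  flag[sig & theta <= med_fst] <- "balancing"
  data.frame(fst = theta, he = hs, p = p, q = q, flag = flag,
             stringsAsFactors = FALSE)
}
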