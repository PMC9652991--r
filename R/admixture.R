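# Maximum-likelihood admixture (ancestry-proportion) inference: the binomial
# likelihood prod_i prod_l C(2,g) x^g (1-x)^(2-g) with x_il = sum_k q_ik f_kl
# is maximized by alternating EM updates of the ancestry proportions Q and
# cluster allele frequencies F, with multiple random restarts.  K is chosen
# by masked-entry cross-validation.

F_EPS <- 1e-6

admix_loglik <- function(G, Q, F) {
  X <- Q %*% F
  ok <- !is.na(G)
  g <- G[ok]; x <- X[ok]
  sum(ifelse(g == 1L, log(2), 0) + g * log(x) + (2 - g) * log1p(-x))
}

#' Fit an admixture model by EM
#'
#' @param x a [genotype_matrix()].
#' @param K number of ancestral clusters.
#' @param seed integer seed for the restarts.
#' @param max_iter maximum EM iterations per restart (default 2000).
#' @param tol convergence threshold on the log-likelihood increase
#'   (default 1e-6).
#' @param n_restarts random restarts; the best likelihood wins (default 3).
#' @return an `admixture_fit` list: `Q` (individuals x K, rows sum to 1),
#'   `F` (K x loci cluster allele frequencies), `loglik`, `trace`
#'   (log-likelihood per iteration of the winning restart), `K`, `seed`,
#'   `converged`.
#' @export
admixture_fit <- function(x, K, seed = 1, max_iter = 2000, tol = 1e-6,
                          n_restarts = 3) {
  G <- calls_na(x)
  n <- nrow(G); L <- ncol(G)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K may not exceed the number of individuals")
  typed <- !is.na(G)
  L_i <- rowSums(typed)
  if (any(L_i == 0)) stop("individuals with no typed loci are not supported")
  p_l <- colMeans(G, na.rm = TRUE) / 2
  p_l[is.na(p_l)] <- 0.5

  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + 1000 * (r - 1))
    Q <- matrix(rgamma(n * K, 1), n, K)
    Q <- Q / rowSums(Q)
    F <- matrix(pmin(1 - F_EPS, pmax(F_EPS,
                                     rep(p_l, each = K) * 0.8 +
                                       runif(K * L) * 0.2)), K, L)
    G0 <- G; G0[!typed] <- 0L
    trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      X <- Q %*% F
      sum1 <- matrix(0, n, K)  # expected alt-allele copies per cluster
      sumT <- matrix(0, n, K)  # expected total copies per cluster
      f_num <- matrix(0, K, L)
      f_den <- matrix(0, K, L)
      for (k in seq_len(K)) {
        W1 <- (Q[, k, drop = TRUE] %o% F[k, ]) / X * G0
        W0 <- (Q[, k, drop = TRUE] %o% (1 - F[k, ])) / (1 - X) * (2L - G0)
        W1[!typed] <- 0; W0[!typed] <- 0
        sum1[, k] <- rowSums(W1)
        sumT[, k] <- rowSums(W1) + rowSums(W0)
        f_num[k, ] <- colSums(W1)
        f_den[k, ] <- colSums(W1) + colSums(W0)
      }
      Q <- sumT / (2 * L_i)
      Q <- Q / rowSums(Q)
      # keep the K x L shape: pmin/pmax take attributes from their first
      # argument
      F <- matrix(pmin(1 - F_EPS, pmax(F_EPS, f_num / pmax(f_den, 1e-300))),
                  K, L)
      ll <- admix_loglik(G, Q, F)
      if (ll < ll_old - 1e-8)
        warning("EM log-likelihood decreased at iteration ", it)
      trace <- c(trace, ll)
      if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
      ll_old <- ll
    }
    if (is.null(best) || trace[length(trace)] > best$loglik) {
      best <- list(Q = Q, F = F, loglik = trace[length(trace)],
                   trace = trace, K = K, seed = seed, converged = converged)
    }
  }
  rownames(best$Q) <- rownames(G)
  colnames(best$F) <- colnames(G)
  class(best) <- "admixture_fit"
  best
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat("admixture_fit: K =", x$K, ", log-likelihood =",
      format(x$loglik, digits = 8),
      if (x$converged) "(converged)" else "(max iterations reached)", "\n")
  invisible(x)
}

#' Choose K by masked-genotype cross-validation
#'
#' For each candidate K, a fraction of the non-missing genotype entries is
#' masked, the model is fitted to the masked data, and the predictive
#' cross-entropy `-mean log P(g | q f)` is scored on the held-out entries,
#' averaged over replicate folds.  The K with the smallest cross-entropy is
#' best supported.
#'
#' @param x a [genotype_matrix()].
#' @param K_range candidate K values (default 1:5).
#' @param mask_fraction fraction of non-missing entries to hold out
#'   (default 0.05).
#' @param n_folds replicate folds per K (default 10).
#' @param seed integer seed.
#' @param ... passed to [admixture_fit()] (e.g. `max_iter`).
#' @return data.frame with columns `K`, `cross_entropy`, `sd`.
#' @export
choose_k <- function(x, K_range = 1:5, mask_fraction = 0.05, n_folds = 10,
                     seed = 1, ...) {
  G <- calls_na(x)
  typed_idx <- which(!is.na(G))
  out <- lapply(K_range, function(K) {
    ce <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      set.seed(seed + 131 * f + 7)
      mask <- NULL
      for (try in 1:20) {
        cand <- sample(typed_idx, round(mask_fraction * length(typed_idx)))
        Gm <- G
        Gm[cand] <- NA_integer_
        ok_l <- colSums(!is.na(Gm)) > 0
        ok_i <- rowSums(!is.na(Gm)) > 0
        if (all(ok_l) && all(ok_i)) { mask <- cand; break }
      }
      if (is.null(mask))
        stop("could not draw a mask without emptying a row or column")
      calls_m <- Gm
      calls_m[is.na(calls_m)] <- MISSING
      xm <- genotype_matrix(calls_m, x$population)
      fit <- admixture_fit(xm, K, seed = seed + 977 * f, n_restarts = 1, ...)
      X <- fit$Q %*% fit$F
      g <- G[mask]; xh <- pmin(1 - F_EPS, pmax(F_EPS, X[mask]))
      ce[f] <- -mean(ifelse(g == 1L, log(2), 0) + g * log(xh) +
                       (2 - g) * log1p(-xh))
    }
    data.frame(K = K, cross_entropy = mean(ce), sd = sd(ce))
  })
  do.call(rbind, out)
}

#' Top-FST locus selection between two parental populations
#'
#' Ranks loci by their per-locus Weir-Cockerham theta between the two
#' designated populations (descending, ties broken by locus order,
#' undefined/monomorphic loci last) and returns the top `n`.
#'
#' @param x a [genotype_matrix()].
#' @param popA,popB the two parental population labels.
#' @param n number of loci to keep (default 300).
#' @return character vector of locus ids.
#' @export
top_fst_loci <- function(x, popA, popB, n = 300) {
  if (n > ncol(x$calls)) stop("n exceeds the number of loci")
  sel <- x$population %in% c(popA, popB)
  theta <- wc_theta_per_locus(x$calls[sel, , drop = FALSE],
                              x$population[sel])
  ord <- order(-ifelse(is.na(theta), -Inf, theta), seq_along(theta))
  colnames(x$calls)[ord[seq_len(n)]]
}
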